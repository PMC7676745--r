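test_that("closed-form rupture probability: symmetry, quantiles, steps", {
  expect_equal(prob_rupture_closed_form(5, 1, 5, 1), 0.5)
  expect_equal(prob_rupture_closed_form(1.96 * sqrt(2), 1, 0, 1), 0.975,
               tolerance = 1e-4)
  expect_equal(prob_rupture_closed_form(1, 0, 2, 0), 0)
  expect_equal(prob_rupture_closed_form(2, 0, 1, 0), 1)
  # strict inequality: a tie counts as non-rupture
  expect_equal(prob_rupture_closed_form(1, 0, 1, 0), 0)
})

test_that("Monte-Carlo rupture probability matches the analytic oracle", {
  # constant stress, independent log-normal strength
  mu2 <- log(400); s2 <- 0.25
  pred <- wall_prediction(c(log(2), 4.5, 7.7, mu2),
                          diag(c(0.1, 0.2, 0.2, s2)^2))
  stress <- 350
  mc <- prob_rupture_mc(function(th) stress, pred, n_eval = 10000L,
                        seed = 4L)
  cf <- prob_rupture_closed_form(log(stress), 0, mu2, s2)
  se <- sqrt(cf * (1 - cf) / 10000)
  expect_lt(abs(mc$p_rupt - cf), 3 * se)
  expect_equal(mc$mc_standard_error,
               sqrt(mc$p_rupt * (1 - mc$p_rupt) / 10000))

  # equal stress and strength distributions: p about one half
  mc2 <- prob_rupture_mc(function(th) 400, pred, n_eval = 10000L,
                         seed = 5L)
  expect_lt(abs(mc2$p_rupt - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("correlations in the joint distribution move the estimate", {
  # stress transmits t; negative t-strength correlation widens the
  # stress-minus-strength distribution and lifts the tail probability
  sfun <- function(th) 160 * th[1]^2
  sds <- c(0.25, 0.2, 0.2, 0.25)
  mu <- c(0, 4.5, 7.7, log(320))
  S_ind <- diag(sds^2)
  S_neg <- S_ind
  S_neg[1, 4] <- S_neg[4, 1] <- -0.85 * sds[1] * sds[4]
  p_ind <- prob_rupture_mc(sfun, wall_prediction(mu, S_ind), 10000L,
                           seed = 6L)
  p_neg <- prob_rupture_mc(sfun, wall_prediction(mu, S_neg), 10000L,
                           seed = 6L)
  se <- sqrt(0.25 / 10000)
  expect_gt(abs(p_neg$p_rupt - p_ind$p_rupt), 3 * se)
})

test_that("estimate is stable under reordering of the covariance factorization", {
  sfun <- function(th) 300 * th[1]^2
  sds <- c(0.25, 0.2, 0.2, 0.25)
  mu <- c(0, 4.5, 7.7, log(320))
  S <- diag(sds^2)
  S[1, 4] <- S[4, 1] <- -0.5 * sds[1] * sds[4]
  # permute (t, sigma_gamma block retained) and permute back
  perm <- c(4L, 2L, 3L, 1L)
  sfun_perm <- function(th) 300 * th[1]^2  # consumed after un-permutation
  p1 <- prob_rupture_mc(sfun, wall_prediction(mu, S), 20000L, seed = 7L)
  # same distribution, different Cholesky through permuted assembly
  Sp <- S[perm, perm]
  mup <- mu[perm]
  set.seed(8L)
  Z <- matrix(rnorm(20000 * 4), ncol = 4)
  draws <- sweep(Z %*% chol(Sp), 2, mup, `+`)[, order(perm)]
  p2 <- mean(300 * exp(draws[, 1])^2 > exp(draws[, 4]))
  se <- 3 * sqrt(0.25 / 20000)
  expect_lt(abs(p1$p_rupt - p2), 2 * 3 * se)
})

test_that("rupture probability is monotone in a stress shift", {
  pred <- wall_prediction(c(log(2), 4.5, 7.7, log(400)),
                          diag(c(0.1, 0.2, 0.2, 0.25)^2))
  shifts <- c(0.8, 1.0, 1.3, 1.8)
  ps <- vapply(shifts, function(c0)
    prob_rupture_mc(function(th) c0 * 300, pred, 10000L, seed = 9L)$p_rupt,
    0)
  expect_true(all(diff(ps) >= 0))
})

test_that("RPI is the stress/strength ratio with log-normal mean strength", {
  expect_equal(round(rpi(291.70, mean_strength = 912.004), 3), 0.320)
  expect_equal(rpi(500, mean_strength = 500), 1)
  expect_equal(rpi(300, mean_strength = 600) * 2,
               rpi(300, mean_strength = 300))
  expect_error(rpi(300, mean_strength = 0), "strength")

  # default mean strength from the predictive log-moments
  pred <- wall_prediction(c(log(2), 4.5, 7.7, log(900)),
                          diag(c(0.1, 0.2, 0.2, 0.3)^2))
  expected_strength <- exp(log(900) + 0.3^2 / 2)
  expect_equal(rpi(function(th) 450, pred), 450 / expected_strength)
})

test_that("PRRI equals the joint probability when its assumptions hold", {
  # diagonal covariance, stress depending on thickness only
  pred <- wall_prediction(c(log(1.8), 4.5, 7.7, log(330)),
                          diag(c(0.3, 0.2, 0.2, 0.2)^2))
  sfun <- function(th) 250 * th[1]
  p_joint <- prob_rupture_mc(sfun, pred, 10000L, seed = 10L)
  p_prri <- prri(sfun, pred, 10000L, seed = 11L)
  se <- sqrt(p_joint$p_rupt * (1 - p_joint$p_rupt) / 10000)
  expect_lt(abs(p_prri - p_joint$p_rupt), 3 * se + 3 * se)

  # zero thickness variance and constant stress: the Phi form
  pred0 <- wall_prediction(c(log(1.8), 4.5, 7.7, log(330)),
                           diag(c(1e-12, 0.2, 0.2, 0.25)^2))
  p0 <- prri(function(th) 300, pred0, 20000L, seed = 12L)
  cf <- prob_rupture_closed_form(log(300), 0, log(330), 0.25)
  expect_lt(abs(p0 - cf), 3 * sqrt(cf * (1 - cf) / 20000))

  # stress distribution identical to the strength distribution
  predh <- wall_prediction(c(log(330), 4.5, 7.7, log(330)),
                           diag(c(0.25, 0.2, 0.2, 0.25)^2))
  ph <- prri(function(th) th[1], predh, 10000L, seed = 13L)
  expect_lt(abs(ph - 0.5), 3 * sqrt(0.25 / 10000))

  # the literal printed variant makes the thickness integration vacuous
  pl <- prri(sfun, pred, 10000L, seed = 14L, literal = TRUE)
  cfl <- prob_rupture_closed_form(log(250 * 1.8), 0, log(330), 0.2)
  expect_lt(abs(pl - cfl), 3 * sqrt(cfl * (1 - cfl) / 10000))
})

test_that("the full per-patient assessment assembles coherent fields", {
  sds <- c(0.088, 0.967, 0.817, 0.174)
  D <- diag(sds)
  pred <- wall_prediction(c(0.415, 4.504, 7.723, 6.729),
                          D %*% default_log_theta_corr() %*% D)
  mb <- membrane_balloon_model()
  rr <- suppressWarnings(assess_rupture_risk(
    mb, pred, active_config(n_grid = 2000L, n_eval = 5000L, seed = 15L)))
  expect_gte(rr$p_rupt, 0); expect_lte(rr$p_rupt, 1)
  expect_gte(rr$prri, 0); expect_lte(rr$prri, 1)
  expect_gt(rr$rpi, 0)
  expect_gt(rr$sigma_at_mean, 0)
  expect_equal(rr$mc_standard_error,
               sqrt(rr$p_rupt * (1 - rr$p_rupt) / rr$n_eval))
  # the surrogate agrees with the forward model at the mean parameters
  direct <- balloon_stress(mb, exp(pred$mu_log[1:3]))
  expect_lt(abs(rr$sigma_at_mean - direct) / direct, 0.05)
})
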