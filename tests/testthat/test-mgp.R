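test_that("kernel evaluates the constant + linear + RBF form", {
  hp <- mgp_hyperparams(zeta = c(1, 1, 1, 1), S = rep(1, 4), L = diag(4))
  x0 <- rep(0, 8)
  expect_equal(mgp_kernel(x0, x0, hp), 2)  # zeta1 + zeta3 at zero distance

  e1 <- c(1, rep(0, 7)); e2 <- c(0, 1, rep(0, 6))
  expect_equal(mgp_kernel(e1, e2, hp), 1 + 0 + exp(-2))

  hp2 <- mgp_hyperparams(zeta = c(0.7, 1e-12, 1e-12, 1), S = rep(1, 4),
                         L = diag(4))
  expect_equal(mgp_kernel(rnorm(8), rnorm(8), hp2), 0.7, tolerance = 1e-10)

  expect_error(mgp_hyperparams(zeta = c(-1, 1, 1, 1), S = rep(1, 4),
                               L = diag(4)), "positive")
})

test_that("log marginal likelihood: closed form and scaling behaviour", {
  # single record, unit coregionalization and noise, zero targets:
  # four independent N(0, 2) observations of 0
  hp <- mgp_hyperparams(zeta = c(0.5, 1e-12, 0.5, 1), S = rep(1, 4),
                        L = diag(4))
  X <- matrix(0, 1L, 3L)
  Y <- matrix(0, 1L, 4L)
  m <- aaarisk:::mgp_model_(X, Y, hp, jitter = 0)
  expect_equal(mgp_log_marginal(m), -0.5 * 4 * log(2) - 2 * log(2 * pi),
               tolerance = 1e-12)

  # growing the targets at fixed covariance strictly lowers the value
  set.seed(1)
  Y2 <- matrix(rnorm(4), 1L, 4L)
  m1 <- aaarisk:::mgp_model_(X, Y2, hp, jitter = 0)
  m10 <- aaarisk:::mgp_model_(X, 10 * Y2, hp, jitter = 0)
  expect_lt(mgp_log_marginal(m10), mgp_log_marginal(m1))
})

test_that("Kronecker-structured likelihood matches the dense oracle", {
  set.seed(42)
  hp <- toy_hp()
  X <- matrix(rnorm(15), 5L, 3L)
  Y <- matrix(rnorm(20), 5L, 4L)
  m <- aaarisk:::mgp_model_(X, Y, hp, jitter = 0)
  expect_equal(mgp_log_marginal(m), dense_log_marginal(X, Y, hp),
               tolerance = 1e-8)
})

test_that("prediction matches the dense oracle and is a valid Gaussian", {
  set.seed(43)
  hp <- toy_hp()
  X <- matrix(rnorm(9), 3L, 3L)
  Y <- matrix(rnorm(12), 3L, 4L)
  m <- aaarisk:::mgp_model_(X, Y, hp, jitter = 0)
  xs <- rnorm(3)
  pred <- predict(m, xs)
  oracle <- dense_predict(X, Y, hp, xs)
  expect_equal(unname(pred$mu_log), oracle$mu, tolerance = 1e-8)
  expect_equal(unname(pred$Sigma_log), unname(oracle$Sigma),
               tolerance = 1e-8)
  ev <- eigen(pred$Sigma_log, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-10))
})

test_that("noise-free limit interpolates; far-field reverts to the prior", {
  set.seed(44)
  L <- toy_hp()$L
  X <- matrix(rnorm(12), 4L, 3L)
  Y <- matrix(rnorm(16), 4L, 4L)
  hp_small_s <- mgp_hyperparams(zeta = c(0.5, 0.3, 0.8, 0.7),
                                S = rep(1e-10, 4), L = L)
  m <- aaarisk:::mgp_model_(X, Y, hp_small_s)
  pred <- predict(m, X[2L, ])
  expect_equal(unname(pred$mu_log), Y[2L, ], tolerance = 1e-3)

  # RBF-only kernel: far away, covariance -> Omega k(x*,x*) + S
  hp_rbf <- mgp_hyperparams(zeta = c(1e-12, 1e-12, 0.8, 0.7),
                            S = c(0.2, 0.3, 0.25, 0.15), L = L)
  m2 <- aaarisk:::mgp_model_(X, Y, hp_rbf, jitter = 0)
  far <- rep(60, 3)
  pred2 <- predict(m2, far)
  Om <- L %*% t(L)
  expect_equal(unname(pred2$Sigma_log),
               unname(Om * mgp_kernel(far, far, hp_rbf) + diag(hp_rbf$S)),
               tolerance = 1e-8)
  expect_equal(unname(pred2$mu_log), unname(m2$center), tolerance = 1e-8)
})

test_that("model 1 reproduces hand-computed population log-moments", {
  props <- data.frame(t = c(exp(0), exp(1), exp(2)),
                      alpha = rep(1, 3), beta = rep(1, 3),
                      sigma_gamma = rep(1, 3))
  coh <- aaa_cohort(1:3, data.frame(x = rnorm(3)), props)
  expect_warning(pred <- model1_cohort_lognormal(coh), "degenerate")
  expect_equal(unname(pred$mu_log[["t"]]), 1)
  expect_equal(unname(sqrt(pred$Sigma_log[1, 1])), sqrt(2 / 3))
  expect_equal(unname(pred$Sigma_log[2, 2]), 0)  # constant column
})

test_that("freezing the off-diagonal of L gives the independent-output model", {
  coh <- toy_cohort(n = 10L, seed = 50L)
  f2 <- mgp_fit(coh, kind = "model2", restarts = 2L, seed = 1L, maxit = 40L)
  expect_equal(unname(f2$Omega[upper.tri(f2$Omega)]), rep(0, 6))
  # rebuild as a model-3 object with the same (block-diagonal) params:
  # predictions must coincide
  f3 <- aaarisk:::mgp_model_(f2$X, f2$Y, f2$hp, f2$center, f2$jitter)
  xs <- rnorm(3)
  p2 <- predict(f2, xs)
  p3 <- predict(f3, xs)
  expect_equal(p2$mu_log, p3$mu_log, tolerance = 1e-8)
  expect_equal(p2$Sigma_log, p3$Sigma_log, tolerance = 1e-8)
})

test_that("duplicating a record never inflates predictive variance", {
  set.seed(51)
  hp <- toy_hp()
  X <- matrix(rnorm(12), 4L, 3L)
  Y <- matrix(rnorm(16), 4L, 4L)
  m1 <- aaarisk:::mgp_model_(X, Y, hp)
  m2 <- aaarisk:::mgp_model_(rbind(X, X[1L, ]), rbind(Y, Y[1L, ]), hp)
  for (k in 1:5) {
    xs <- rnorm(3)
    v1 <- diag(predict(m1, xs)$Sigma_log)
    v2 <- diag(predict(m2, xs)$Sigma_log)
    expect_true(all(v2 <= v1 + 1e-9))
  }
})

test_that("predictive entropy has the Gaussian closed form", {
  pred <- wall_prediction(rep(0, 4), diag(4))
  expect_equal(predictive_entropy(pred), 2 * log(2 * pi * exp(1)),
               tolerance = 1e-12)
  expect_equal(predictive_entropy(pred), 5.6758, tolerance = 1e-4)
})

test_that("fitted models serialize to JSON and reload exactly", {
  coh <- toy_cohort(n = 8L, seed = 52L)
  fit <- mgp_fit(coh, restarts = 1L, seed = 1L, maxit = 30L)
  path <- file.path(tempdir(), "mgp.json")
  write_mgp(fit, path)
  back <- read_mgp(path)
  xs <- rnorm(3)
  expect_equal(predict(fit, xs)$mu_log, predict(back, xs)$mu_log,
               tolerance = 1e-12)
  expect_equal(mgp_log_marginal(fit), mgp_log_marginal(back),
               tolerance = 1e-12)
})
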