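test_that("read_cohort round-trips and enforces alignment", {
  coh <- toy_cohort(n = 3L, patients = c(1L, 1L, 2L))
  expect_equal(n_records(coh), 3L)
  expect_equal(n_patients(coh), 2L)

  tmp <- file.path(tempdir(), "rt")
  paths <- write_cohort(coh, tmp)
  back <- read_cohort(paths[["noninvasive"]], paths[["invasive"]])
  expect_identical(back$patient_id, coh$patient_id)
  expect_equal(as.matrix(back$features), as.matrix(coh$features),
               ignore_attr = TRUE)
  expect_equal(as.matrix(back$properties), as.matrix(coh$properties),
               ignore_attr = TRUE)

  # mismatched ids across the two files
  ni <- utils::read.csv(paths[["noninvasive"]])
  ni$patient_id <- c(1L, 2L, 3L)
  bad <- file.path(tempdir(), "bad_noninvasive.csv")
  utils::write.csv(ni, bad, row.names = FALSE)
  expect_error(read_cohort(bad, paths[["invasive"]]), "alignment")

  # mismatched row counts
  utils::write.csv(ni[1:2, ], bad, row.names = FALSE)
  expect_error(read_cohort(bad, paths[["invasive"]]), "alignment")

  # non-numeric feature cell
  ni2 <- utils::read.csv(paths[["noninvasive"]])
  ni2[[2L]] <- as.character(ni2[[2L]])
  ni2[2L, 2L] <- "oops"
  utils::write.csv(ni2, bad, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(bad, paths[["invasive"]]), "parse error")
})

test_that("preprocess drops features over the missingness threshold and imputes medians", {
  set.seed(3)
  X <- data.frame(a = rnorm(10), b = rnorm(10), c = rnorm(10),
                  d = rnorm(10), e = rnorm(10))
  X$a[1:4] <- NA           # 40% missing -> feature dropped
  X$b[1:2] <- NA           # 20% missing; rows 1-2 then miss 1/4 = 25%
                           # of surviving features -> kept and imputed
  props <- data.frame(t = rep(1.5, 10), alpha = rep(100, 10),
                      beta = rep(3000, 10), sigma_gamma = rep(900, 10))
  coh <- aaa_cohort(1:10, X, props)
  out <- preprocess_cohort(coh)

  expect_identical(out$stats$dropped_features, "a")
  expect_named(out$cohort$features, c("b", "c", "d", "e"))
  expect_equal(n_records(out$cohort), 10L)
  # imputed cells equal the median of the 8 observed values, then z-scored
  med_b <- median(X$b[3:10])
  expect_equal(unname(out$stats$median[["b"]]), med_b)
  imputed_raw <- out$cohort$features$b[1:2] * out$stats$scale[["b"]] +
    out$stats$mean[["b"]]
  expect_equal(imputed_raw, rep(med_b, 2L))
})

test_that("normalization is z-score with population sd, and preprocess is idempotent", {
  coh <- toy_cohort(n = 12L, seed = 5L)
  out <- preprocess_cohort(coh)
  Z <- as.matrix(out$cohort$features)
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_lt(max(abs(sqrt(colMeans(sweep(Z, 2, colMeans(Z))^2)) - 1)), 1e-10)

  again <- preprocess_cohort(out$cohort)
  expect_equal(as.matrix(again$cohort$features), Z, tolerance = 1e-12)
  expect_identical(again$cohort$patient_id, out$cohort$patient_id)

  # records missing too many surviving features are dropped
  X <- as.data.frame(matrix(rnorm(30), 10, 3))
  X[1L, ] <- NA
  coh2 <- aaa_cohort(1:10, X, data.frame(t = rep(1, 10), alpha = rep(1, 10),
                                         beta = rep(1, 10),
                                         sigma_gamma = rep(1, 10)))
  out2 <- preprocess_cohort(coh2)
  expect_equal(n_records(out2$cohort), 9L)
  expect_identical(out2$stats$dropped_records, 1L)
})

test_that("normalization stats transform new patients identically and survive JSON", {
  coh <- toy_cohort(n = 10L, seed = 9L)
  out <- preprocess_cohort(coh)
  raw <- coh$features[3L, ]
  z <- apply_normalization(out$stats, raw)
  expect_equal(drop(z), unlist(out$cohort$features[3L, ]),
               ignore_attr = TRUE, tolerance = 1e-12)

  path <- file.path(tempdir(), "norm.json")
  write_norm_stats(out$stats, path)
  st2 <- read_norm_stats(path)
  expect_equal(apply_normalization(st2, raw), z, tolerance = 1e-12)
})

test_that("spearman correlations: monotone transforms, ties, constant columns", {
  n <- 5L
  f <- c(1.2, 3.4, 2.2, 5.5, 4.1)
  props <- data.frame(t = exp(f), alpha = exp(-f), beta = exp(f)^3,
                      sigma_gamma = c(2, 2, 1, 4, 3))
  coh <- aaa_cohort(1:n, data.frame(x = f, const = rep(1, n)), props)
  rho <- spearman_correlations(coh)
  expect_equal(rho["x", "t"], 1)           # strictly monotone increasing
  expect_equal(rho["x", "alpha"], -1)      # reversed ranks
  expect_equal(rho["x", "beta"], 1)        # invariant under cubing
  expect_true(all(is.na(rho["const", ])))  # undefined, not zero

  # tie handling: equals Pearson correlation of average ranks
  manual <- cor(rank(f), rank(props$sigma_gamma))
  expect_equal(rho["x", "sigma_gamma"], manual, tolerance = 1e-12)
})

test_that("forward selection stops at the first non-improvement", {
  coh <- toy_cohort(n = 10L, p = 4L, seed = 21L)
  names(coh$features) <- paste0("f", 1:4)

  scores <- c(5, 3, 4, 2)  # improves only for the first two additions
  sc <- function(sub) scores[ncol(sub$features)]
  sel <- forward_feature_selection(coh, paste0("f", 1:4), score = sc)
  expect_identical(sel, c("f1", "f2"))

  # constant score: only the first candidate beats the +Inf baseline
  sel1 <- forward_feature_selection(coh, paste0("f", 1:4),
                                    score = function(sub) 1)
  expect_identical(sel1, "f1")

  expect_error(forward_feature_selection(coh, character(),
                                         score = function(sub) 1), "empty")
})

test_that("forward selection finds the features that drive the properties", {
  # synthetic cohort where only features 1 and 3 carry signal
  W <- matrix(0, 8L, 4L)
  W[1L, ] <- c(0.08, 0.5, 0.4, 0.12)
  W[3L, ] <- c(-0.06, -0.6, 0.3, -0.1)
  cfg <- cohort_config(n_patients = 60L, samples_per_patient = 1L,
                       link_weights = W, seed = 42L,
                       log_theta_sd = c(0.05, 0.3, 0.25, 0.08))
  coh <- generate_cohort(cfg)
  pp <- preprocess_cohort(coh)
  # penalized linear-model score (cheap stand-in honouring the contract)
  sc <- function(sub) {
    X <- as.matrix(sub$features)
    LY <- log(as.matrix(sub$properties))
    sum(vapply(1:4, function(d) stats::AIC(stats::lm(LY[, d] ~ X)), 0))
  }
  sel <- forward_feature_selection(pp$cohort, score = sc)
  expect_true(all(c("max_diameter", "aaa_length") %in% sel))
})
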