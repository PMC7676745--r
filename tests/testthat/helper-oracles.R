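# Shared fixtures and independent dense-matrix oracles used across the
# test files. The oracles deliberately assemble the full stacked
# covariance with kronecker() and solve() so they share no code path
# with the package's eigenstructure-based implementation.

# Small complete cohort with arbitrary but fixed numbers.
toy_cohort <- function(n = 6L, p = 3L, seed = 11L, patients = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  props <- data.frame(t = exp(rnorm(n, 0.5, 0.1)),
                      alpha = exp(rnorm(n, 4.5, 0.5)),
                      beta = exp(rnorm(n, 7.7, 0.5)),
                      sigma_gamma = exp(rnorm(n, 6.7, 0.2)))
  if (is.null(patients)) patients <- seq_len(n)
  aaa_cohort(patients, as.data.frame(X), props)
}

# Fixed small multi-output GP hyperparameters.
toy_hp <- function() {
  L <- diag(c(1, 0.8, 0.6, 0.9))
  L[2, 1] <- 0.3; L[4, 3] <- -0.2; L[3, 1] <- 0.1
  mgp_hyperparams(zeta = c(0.5, 0.3, 0.8, 0.7),
                  S = c(0.2, 0.3, 0.25, 0.15), L = L)
}

# Dense-oracle pieces: stacked covariance, log marginal, prediction.
dense_stacked_cov <- function(X, hp, jitter = 0) {
  n <- nrow(X)
  K <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    mgp_kernel(X[i, ], X[j, ], hp)))
  K <- K + diag(jitter * mean(diag(K)), n)
  Om <- hp$L %*% t(hp$L)
  kronecker(Om, K) + kronecker(diag(hp$S), diag(n))
}

dense_log_marginal <- function(X, Y, hp, jitter = 0) {
  A <- dense_stacked_cov(X, hp, jitter)
  v <- as.numeric(Y)  # output-major stacking
  n <- nrow(X)
  ld <- as.numeric(determinant(A, logarithm = TRUE)$modulus)
  drop(-0.5 * ld - 0.5 * t(v) %*% solve(A, v) - 2 * n * log(2 * pi))
}

dense_predict <- function(X, Y, hp, xs, jitter = 0) {
  n <- nrow(X)
  A <- dense_stacked_cov(X, hp, jitter)
  Om <- hp$L %*% t(hp$L)
  ks <- vapply(seq_len(n), function(i) mgp_kernel(xs, X[i, ], hp), 0)
  OK <- kronecker(Om, matrix(ks, ncol = 1L))
  v <- as.numeric(Y)
  mu <- drop(t(OK) %*% solve(A, v))
  Sig <- Om * mgp_kernel(xs, xs, hp) + diag(hp$S) - t(OK) %*% solve(A, OK)
  list(mu = mu, Sigma = (Sig + t(Sig)) / 2)
}

# Sample records from the multi-output GP prior at given inputs,
# exponentiated into an aaa_cohort around fixed log-centres.
sample_mgp_prior_cohort <- function(X, hp, patient_id, seed,
                                    centres = c(0.48, 4.5, 7.7, 6.7)) {
  set.seed(seed)
  n <- nrow(X)
  A <- dense_stacked_cov(X, hp) + diag(1e-8, 4L * n)
  Y <- matrix(drop(t(chol(A)) %*% rnorm(4L * n)), n, 4L)
  props <- as.data.frame(exp(sweep(Y, 2L, centres, `+`)))
  names(props) <- aaa_property_names()
  aaa_cohort(patient_id, as.data.frame(X), props)
}

# Hyperparameters of the identifiable recovery regime: RBF-dominant,
# short length scale, small noise (noise vs signal separated through
# replicated inputs per patient).
recovery_truth <- function() {
  R <- diag(4)
  R[1, 4] <- R[4, 1] <- -0.5
  R[2, 3] <- R[3, 2] <- 0.4
  R[1, 2] <- R[2, 1] <- 0.25
  sds <- c(0.3, 0.8, 0.6, 0.25)
  Om <- diag(sds) %*% R %*% diag(sds)
  list(hp = mgp_hyperparams(zeta = c(0.01, 0.01, 1, 3),
                            S = c(0.01, 0.02, 0.015, 0.01),
                            L = t(chol(Om))),
       corr = R)
}

# Dense universal-Kriging oracle following the closed-form expressions
# directly with solve(); standardizes inputs the same way the
# implementation does (the basis/kernel are defined on those
# coordinates).
dense_kriging <- function(X, y, zeta, nugget_rel = 1e-10) {
  lo <- apply(X, 2L, min)
  span <- apply(X, 2L, max) - lo
  span[span == 0] <- 1
  U <- sweep(sweep(X, 2L, lo), 2L, span, `/`)
  basis <- function(u) {
    c(1, u[1], u[2], u[3], u[1] * u[2], u[1] * u[3], u[2] * u[3],
      u[1] * u[2] * u[3])
  }
  kern <- function(u1, u2) {
    zeta[1] * exp(-0.5 * sum((u1 - u2)^2 / zeta[2:4]))
  }
  n <- nrow(U)
  K <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    kern(U[i, ], U[j, ]))) + diag(nugget_rel * zeta[1], n)
  H <- t(vapply(seq_len(n), function(i) basis(U[i, ]), numeric(8L)))
  A <- t(H) %*% solve(K, H)
  eta <- solve(A, t(H) %*% solve(K, y))
  m <- 8L
  ll <- drop(-0.5 * t(y) %*% solve(K, y) +
               0.5 * t(t(H) %*% solve(K, y)) %*% solve(A, t(H) %*% solve(K, y)) -
               0.5 * as.numeric(determinant(K, log = TRUE)$modulus) -
               0.5 * as.numeric(determinant(A, log = TRUE)$modulus) -
               (n - m) / 2 * log(2 * pi))
  predict_at <- function(xs) {
    us <- (xs - lo) / span
    ks <- vapply(seq_len(n), function(i) kern(us, U[i, ]), 0)
    hs <- basis(us)
    r <- hs - t(H) %*% solve(K, ks)
    mu <- drop(t(ks) %*% solve(K, y) + t(r) %*% eta)
    v <- drop(kern(us, us) - nugget_rel * zeta[1] - t(ks) %*% solve(K, ks) +
                t(r) %*% solve(A, r))
    c(mean = mu, var = max(v, 0))
  }
  list(ll = ll, predict_at = predict_at)
}

# Mann-Whitney AUC oracle via average ranks (ties get half credit).
mann_whitney_auc <- function(values, positive) {
  r <- rank(values)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
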