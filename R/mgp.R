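# Multi-output Gaussian-process regression for the four log vessel-wall
# properties. The four outputs share one covariance function over the
# clinical features; between-output covariance is the coregionalization
# matrix Omega = L L', and independent per-output noise S_dd is added.
# The stacked covariance is Omega (x) K + S (x) I_n (output-major
# stacking), which is factorized through the two small eigensystems
# instead of the dense 4n x 4n matrix:
#   Omega (x) K + S (x) I = (S^1/2 (x) I)(Omega~ (x) K + I)(S^1/2 (x) I),
#   Omega~ = S^-1/2 Omega S^-1/2 = U D U',  K = V Lam V'
# so the middle factor has eigenvalues D_d * Lam_i + 1.

#' Covariance function of the multi-output GP
#'
#' `zeta1 + zeta2 <xi, xj> + zeta3 exp(-zeta4 ||xi - xj||^2)`: a constant
#' plus linear plus RBF kernel over normalized clinical features.
#'
#' @param xi,xj Numeric feature vectors of equal length.
#' @param hp Hyperparameters: a list with element `zeta` (length 4, all
#'   strictly positive), e.g. from [mgp_hyperparams()].
#' @return Scalar covariance value.
#' @export
mgp_kernel <- function(xi, xj, hp) {
  z <- hp$zeta
  stopifnot_positive_(z, "kernel parameters zeta")
  d <- xi - xj
  z[1L] + z[2L] * sum(xi * xj) + z[3L] * exp(-z[4L] * sum(d * d))
}

# Kernel matrix between rows of X1 and X2.
mgp_kernel_matrix_ <- function(X1, X2, zeta) {
  G <- X1 %*% t(X2)
  n1 <- rowSums(X1^2)
  n2 <- rowSums(X2^2)
  D2 <- outer(n1, n2, `+`) - 2 * G
  D2[D2 < 0] <- 0
  zeta[1L] + zeta[2L] * G + zeta[3L] * exp(-zeta[4L] * D2)
}

#' Bundle multi-output GP hyperparameters
#'
#' @param zeta Length-4 positive kernel parameters.
#' @param S Length-4 positive noise variances (one per output).
#' @param L 4x4 lower-triangular Cholesky factor of the coregionalization
#'   matrix `Omega = L L'` (positive diagonal, free off-diagonal).
#' @return List of class `mgp_hyperparams`.
#' @export
mgp_hyperparams <- function(zeta, S, L) {
  stopifnot_positive_(zeta, "zeta")
  stopifnot_positive_(S, "noise variances S")
  L <- as.matrix(L)
  stopifnot(all(dim(L) == c(4L, 4L)))
  if (max(abs(L[upper.tri(L)])) > 0) {
    stop("L must be lower triangular", call. = FALSE)
  }
  stopifnot_positive_(diag(L), "diagonal of L")
  structure(list(zeta = zeta, S = S, L = L), class = "mgp_hyperparams")
}

# Assemble the cached factorization for given data and hyperparameters.
# Y is the n x 4 matrix of (already centred) log targets.
mgp_model_ <- function(X, Y, hp, center = rep(0, 4L), jitter = 1e-8,
                       eK = NULL, K = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(nrow(Y) == n, ncol(Y) == 4L)
  if (is.null(K)) {
    K <- mgp_kernel_matrix_(X, X, hp$zeta)
    K <- K + diag(jitter * mean(diag(K)), n)
  }
  if (is.null(eK)) eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eK$values) <= 0) {
    stop("kernel matrix singular despite jitter", call. = FALSE)
  }
  Omega <- hp$L %*% t(hp$L)
  s_half_inv <- 1 / sqrt(hp$S)
  Omega_t <- Omega * outer(s_half_inv, s_half_inv)
  eO <- eigen((Omega_t + t(Omega_t)) / 2, symmetric = TRUE)
  W <- outer(eK$values, eO$values) + 1  # n x 4 eigenvalues of middle factor
  if (min(W) <= 0) {
    stop("stacked covariance not positive definite", call. = FALSE)
  }
  Yt <- t(eK$vectors) %*% sweep(Y, 2L, s_half_inv, `*`) %*% eO$vectors
  structure(
    list(X = X, Y = Y, center = center, hp = hp, jitter = jitter,
         K = K, V = eK$vectors, lam = eK$values,
         Omega = Omega, U = eO$vectors, d = eO$values,
         s_half_inv = s_half_inv, W = W, Yt = Yt, n = n),
    class = "mgp")
}

# A^-1 vec(M) for the stacked covariance A, returned in the same n x 4
# matrix layout as M.
mgp_solve_ <- function(model, M) {
  M1 <- sweep(M, 2L, model$s_half_inv, `*`)
  M2 <- t(model$V) %*% M1 %*% model$U
  M3 <- M2 / model$W
  M4 <- model$V %*% M3 %*% t(model$U)
  sweep(M4, 2L, model$s_half_inv, `*`)
}

#' Log marginal likelihood of a multi-output GP model
#'
#' `-1/2 log|Omega (x) K + S (x) I| - 1/2 vec' (.)^-1 vec - 2 n log(2 pi)`,
#' evaluated through the Kronecker eigenstructure rather than the dense
#' stacked matrix.
#'
#' @param model An `mgp` model (from [mgp_fit()] or internal assembly).
#' @return Scalar log marginal likelihood (natural log).
#' @export
mgp_log_marginal <- function(model) {
  logdet <- model$n * sum(log(model$hp$S)) + sum(log(model$W))
  quad <- sum(model$Yt^2 / model$W)
  -0.5 * logdet - 0.5 * quad - 2 * model$n * log(2 * pi)
}

#' @export
logLik.mgp <- function(object, ...) {
  ll <- mgp_log_marginal(object)
  attr(ll, "df") <- if (identical(object$kind, "model2")) 12L else 18L
  class(ll) <- "logLik"
  ll
}

# ---- fitting ---------------------------------------------------------------

# Pack/unpack the optimizer parameter vector. Positivity of zeta, S and
# diag(L) is enforced by optimizing their logarithms; the six
# subdiagonal entries of L are unconstrained and dropped for the
# independent-output variant (model 2).
mgp_pack_ <- function(hp, diag_omega) {
  low <- c(hp$L[2, 1], hp$L[3, 1], hp$L[4, 1],
           hp$L[3, 2], hp$L[4, 2], hp$L[4, 3])
  th <- c(log(hp$zeta), log(hp$S), log(diag(hp$L)))
  if (!diag_omega) th <- c(th, low)
  th
}

mgp_unpack_ <- function(th, diag_omega) {
  L <- diag(exp(th[9:12]))
  if (!diag_omega) {
    L[2, 1] <- th[13]; L[3, 1] <- th[14]; L[4, 1] <- th[15]
    L[3, 2] <- th[16]; L[4, 2] <- th[17]; L[4, 3] <- th[18]
  }
  mgp_hyperparams(zeta = exp(th[1:4]), S = exp(th[5:8]), L = L)
}

#' Fit the multi-output Gaussian-process regression model
#'
#' Maximizes the log marginal likelihood over the 18 hyperparameters
#' (4 kernel parameters, 4 noise variances, 10 entries of the Cholesky
#' factor of the coregionalization matrix) by seeded multi-start
#' quasi-Newton optimization on log-transformed positive parameters.
#' `kind = "model2"` freezes the off-diagonal of `L` at zero, giving four
#' independent GPs with a shared kernel (the uncorrelated baseline).
#'
#' Targets are the natural logs of the invasive properties; each output is
#' centred on its training mean internally (the centre is restored in
#' predictions), which keeps the zero-mean prior assumption innocuous.
#'
#' @param cohort A preprocessed, complete `aaa_cohort` (features already
#'   normalized).
#' @param kind `"model3"` (correlated outputs, default) or `"model2"`.
#' @param restarts Number of seeded optimizer starts, default 10.
#' @param seed Integer seed controlling the starts.
#' @param maxit Iteration cap per start.
#' @param jitter Relative diagonal jitter added to the kernel matrix.
#' @param norm_stats Optional `aaa_norm_stats` to attach for later use.
#' @return Object of class `mgp` with `print`, `predict`, `coef` and
#'   `logLik` methods.
#' @export
mgp_fit <- function(cohort, kind = c("model3", "model2"), restarts = 10L,
                    seed = 1L, maxit = 100L, jitter = 1e-8,
                    norm_stats = NULL) {
  kind <- match.arg(kind)
  diag_omega <- kind == "model2"
  X <- as.matrix(cohort$features)
  Y <- log(as.matrix(cohort$properties))
  center <- colMeans(Y)
  Yc <- sweep(Y, 2L, center)
  n <- nrow(X)

  C <- crossprod(Yc) / n + diag(1e-6, 4L)
  L0 <- t(chol(0.5 * C))
  if (diag_omega) L0 <- diag(sqrt(diag(0.5 * C)))
  hp0 <- mgp_hyperparams(
    zeta = c(0.1, 0.1, 0.5, 1 / (2 * max(1L, ncol(X)))),
    S = pmax(0.5 * diag(C), 1e-4),
    L = L0)
  th0 <- mgp_pack_(hp0, diag_omega)
  npos <- 12L
  lower <- c(rep(-12, npos), rep(-30, length(th0) - npos))
  upper <- c(rep(8, npos), rep(30, length(th0) - npos))

  # the kernel eigendecomposition only depends on zeta: cache it across
  # objective evaluations (most finite-difference perturbations touch
  # only the noise / coregionalization parameters)
  kcache <- new.env(parent = emptyenv())
  nll <- function(th) {
    hp <- tryCatch(mgp_unpack_(th, diag_omega), error = function(e) NULL)
    if (is.null(hp)) return(1e10)
    eK <- NULL; Kc <- NULL
    if (!is.null(kcache$zeta) && identical(kcache$zeta, hp$zeta)) {
      eK <- kcache$eK; Kc <- kcache$K
    }
    m <- tryCatch(mgp_model_(X, Yc, hp, center, jitter, eK = eK, K = Kc),
                  error = function(e) NULL)
    if (is.null(m)) return(1e10)
    kcache$zeta <- hp$zeta
    kcache$eK <- list(values = m$lam, vectors = m$V)
    kcache$K <- m$K
    v <- -mgp_log_marginal(m)
    if (!is.finite(v)) 1e10 else v
  }

  fits <- with_seed_(seed, {
    starts <- lapply(seq_len(restarts), function(r) {
      if (r == 1L) th0 else th0 + stats::rnorm(length(th0), sd = 0.7)
    })
    lapply(starts, function(st) {
      tryCatch(
        stats::optim(st, nll, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = maxit)),
        error = function(e) list(value = Inf, error = conditionMessage(e)))
    })
  })
  vals <- vapply(fits, function(f) f$value, 0)
  if (!any(is.finite(vals) & vals < 1e10)) {
    msgs <- unlist(lapply(fits, function(f) f$error %||% "non-finite objective"))
    stop("mgp_fit: all optimizer restarts failed: ",
         paste(unique(msgs), collapse = "; "), call. = FALSE)
  }
  best <- fits[[which.min(vals)]]
  hp <- mgp_unpack_(best$par, diag_omega)
  model <- mgp_model_(X, Yc, hp, center, jitter)
  model$kind <- kind
  model$norm_stats <- norm_stats
  model$opt <- list(value = -best$value, restarts = restarts, seed = seed,
                    convergence = best$convergence)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mgp <- function(x, ...) {
  cat(sprintf("Multi-output GP (%s): %d records, %d features\n",
              x$kind %||% "custom", x$n, ncol(x$X)))
  cat(sprintf("  log marginal likelihood: %.4f\n", mgp_log_marginal(x)))
  cat("  coregionalization correlations (Omega):\n")
  R <- stats::cov2cor(x$Omega)
  dimnames(R) <- list(aaa_property_names(), aaa_property_names())
  print(round(R, 3))
  invisible(x)
}

#' @export
coef.mgp <- function(object, ...) {
  hp <- object$hp
  stats::setNames(
    c(hp$zeta, hp$S, diag(hp$L),
      hp$L[2, 1], hp$L[3, 1], hp$L[4, 1],
      hp$L[3, 2], hp$L[4, 2], hp$L[4, 3]),
    c(paste0("zeta", 1:4), paste0("S", 1:4, 1:4),
      "L11", "L22", "L33", "L44", "L21", "L31", "L41", "L32", "L42", "L43"))
}

# ---- prediction ------------------------------------------------------------

#' Predictive distribution of the log vessel-wall properties
#'
#' For a feature vector `xi*` (normalized with the training statistics),
#' returns the joint Gaussian over `(log t, log alpha, log beta,
#' log sigma_gamma)`: mean `(Omega (x) k*)' A^-1 vec(Y)` plus the training
#' centre, covariance `Omega k(xi*, xi*) + S - (Omega (x) k*)' A^-1
#' (Omega (x) k*)`, symmetrized and eigenvalue-floored at zero.
#'
#' @param object A fitted `mgp`.
#' @param newdata Normalized feature vector, or matrix with one row per
#'   point (a list of predictions is then returned).
#' @param ... Unused.
#' @return A `wall_prediction` (fields `mu_log`, `Sigma_log`), or a list
#'   of them for multiple rows.
#' @export
predict.mgp <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != ncol(object$X)) {
    stop(sprintf("feature dimension mismatch: got %d, model has %d",
                 ncol(newdata), ncol(object$X)), call. = FALSE)
  }
  preds <- lapply(seq_len(nrow(newdata)), function(i) {
    xs <- newdata[i, ]
    kstar <- drop(mgp_kernel_matrix_(object$X, matrix(xs, nrow = 1L),
                                     object$hp$zeta))
    kss <- mgp_kernel(xs, xs, object$hp)
    alpha <- mgp_solve_(object, object$Y)
    mu <- drop(object$Omega %*% (t(alpha) %*% kstar)) + object$center
    Ms <- lapply(1:4, function(d) outer(kstar, object$Omega[, d]))
    Bs <- lapply(Ms, function(M) mgp_solve_(object, M))
    Tm <- matrix(0, 4L, 4L)
    for (d in 1:4) for (dp in d:4) {
      Tm[d, dp] <- Tm[dp, d] <- sum(Ms[[d]] * Bs[[dp]])
    }
    Sig <- object$Omega * kss + diag(object$hp$S) - Tm
    wall_prediction(mu, psd_clean_(Sig))
  })
  if (length(preds) == 1L) preds[[1L]] else preds
}

#' Construct a predictive distribution over the log-properties
#'
#' @param mu_log Length-4 mean of (log t, log alpha, log beta,
#'   log sigma_gamma).
#' @param Sigma_log 4x4 symmetric positive semi-definite covariance.
#' @return Object of class `wall_prediction`.
#' @export
wall_prediction <- function(mu_log, Sigma_log) {
  mu_log <- stats::setNames(as.numeric(mu_log), aaa_property_names())
  Sigma_log <- as.matrix(Sigma_log)
  stopifnot(length(mu_log) == 4L, all(dim(Sigma_log) == c(4L, 4L)))
  if (max(abs(Sigma_log - t(Sigma_log))) > 1e-8) {
    stop("Sigma_log must be symmetric", call. = FALSE)
  }
  dimnames(Sigma_log) <- list(aaa_property_names(), aaa_property_names())
  structure(list(mu_log = mu_log, Sigma_log = Sigma_log),
            class = "wall_prediction")
}

#' @export
print.wall_prediction <- function(x, ...) {
  sd <- sqrt(pmax(diag(x$Sigma_log), 0))
  df <- data.frame(mean_log = x$mu_log, sd_log = sd,
                   mean_physical = exp(x$mu_log + sd^2 / 2))
  cat("Predictive distribution of log wall properties:\n")
  print(round(df, 4))
  cat(sprintf("entropy: %.4f nats\n", predictive_entropy(x)))
  invisible(x)
}

#' Draw joint samples of the invasive properties
#'
#' @param object A `wall_prediction`.
#' @param nsim Number of samples.
#' @param seed Integer seed.
#' @param log Return log-space samples if `TRUE` (default physical space).
#' @param ... Unused.
#' @return `nsim` x 4 matrix of samples.
#' @export
simulate.wall_prediction <- function(object, nsim = 1L, seed = NULL,
                                     log = FALSE, ...) {
  S <- with_seed_(seed, rmvnorm_(nsim, object$mu_log, object$Sigma_log))
  colnames(S) <- aaa_property_names()
  if (log) S else exp(S)
}

#' Differential entropy of a predictive distribution
#'
#' `H = 1/2 log((2 pi e)^4 |Sigma|)` in nats; the per-patient predictive
#' entropy used to benchmark the regression models.
#'
#' @param pred A `wall_prediction`.
#' @return Scalar entropy in nats (`-Inf` for a degenerate covariance).
#' @export
predictive_entropy <- function(pred) {
  d <- determinant(pred$Sigma_log, logarithm = TRUE)
  if (d$sign <= 0) return(-Inf)
  0.5 * (4 * log(2 * pi * exp(1)) + as.numeric(d$modulus))
}

#' Cohort log-normal baseline (Model 1)
#'
#' Treats the four properties as independent log-normals with log-space
#' means and population variances computed across all records, yielding
#' one predictive distribution shared by every patient (the cohort-based
#' baseline underlying the PRRI).
#'
#' @param cohort An `aaa_cohort`.
#' @return A `wall_prediction` with diagonal covariance.
#' @export
model1_cohort_lognormal <- function(cohort) {
  P <- as.matrix(cohort$properties)
  if (any(P <= 0)) stop("non-positive property value", call. = FALSE)
  LP <- log(P)
  mu <- colMeans(LP)
  v <- colMeans(sweep(LP, 2L, mu)^2)  # population variance
  if (any(v == 0)) {
    warning("degenerate cohort: zero log-variance in at least one property")
  }
  wall_prediction(mu, diag(v))
}

# ---- serialization ---------------------------------------------------------

#' Serialize / deserialize a fitted multi-output GP as JSON
#'
#' Stores the hyperparameter vector (in the canonical 18-entry layout),
#' the training features and log-targets, the output centres and, when
#' attached, the normalization statistics.
#'
#' @param model A fitted `mgp`.
#' @param path File path.
#' @return `read_mgp` returns the reassembled `mgp`.
#' @export
write_mgp <- function(model, path) {
  obj <- list(
    kind = model$kind %||% "model3",
    hyperparams = as.list(coef(model)),
    center = as.numeric(model$center),
    jitter = model$jitter,
    X = apply(model$X, 1L, as.numeric, simplify = FALSE),
    Y_centered = apply(model$Y, 1L, as.numeric, simplify = FALSE),
    n = model$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mgp
#' @export
read_mgp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- obj$hyperparams
  L <- diag(c(h$L11, h$L22, h$L33, h$L44))
  L[2, 1] <- h$L21; L[3, 1] <- h$L31; L[4, 1] <- h$L41
  L[3, 2] <- h$L32; L[4, 2] <- h$L42; L[4, 3] <- h$L43
  hp <- mgp_hyperparams(zeta = c(h$zeta1, h$zeta2, h$zeta3, h$zeta4),
                        S = c(h$S11, h$S22, h$S33, h$S44), L = L)
  as_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
  X <- as_mat(obj$X)
  Y <- as_mat(obj$Y_centered)
  m <- mgp_model_(X, Y, hp, center = obj$center, jitter = obj$jitter)
  m$kind <- obj$kind
  m
}
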