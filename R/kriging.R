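# Universal Kriging surrogate of the log maximum wall stress over
# theta = (t, alpha, beta): noise-free squared-exponential GP with an
# explicit trilinear trend under a vague coefficient prior, so any
# target in the span of the trend basis is reproduced exactly.

#' Trilinear trend basis
#'
#' `h(theta) = [1, t, alpha, beta, t*alpha, t*beta, alpha*beta,
#' t*alpha*beta]` in that order.
#'
#' @param params A [wall_params()] or numeric triple (t, alpha, beta).
#' @return Length-8 numeric vector.
#' @export
trilinear_basis <- function(params) {
  p <- as.numeric(params)
  t <- p[1L]; a <- p[2L]; b <- p[3L]
  c(1, t, a, b, t * a, t * b, a * b, t * a * b)
}

# Basis matrix (rows = points) for an n x 3 input matrix.
trilinear_basis_matrix_ <- function(X) {
  t <- X[, 1L]; a <- X[, 2L]; b <- X[, 3L]
  cbind(1, t, a, b, t * a, t * b, a * b, t * a * b)
}

# Squared-exponential kernel on standardized coordinates:
# k(u, u') = zeta1 * exp(-1/2 sum_j (u_j - u'_j)^2 / Lambda_j),
# Lambda = diag(zeta2, zeta3, zeta4).
kriging_kernel_matrix_ <- function(U1, U2, zeta) {
  iv <- 1 / zeta[2:4]
  D2 <- 0
  for (j in 1:3) {
    D2 <- D2 + outer(U1[, j], U2[, j], `-`)^2 * iv[j]
  }
  zeta[1L] * exp(-0.5 * D2)
}

# Assemble all cached quantities for given data and hyperparameters.
kriging_assemble_ <- function(X, y, zeta, nugget_rel = 1e-10) {
  n <- nrow(X)
  lo <- apply(X, 2L, min)
  span <- apply(X, 2L, max) - lo
  span[span == 0] <- 1
  U <- sweep(sweep(X, 2L, lo), 2L, span, `/`)

  # trend basis on the standardized coordinates (same span as on raw
  # theta: the affine map preserves the multilinear monomial span) with
  # pivoted-QR reduction to a full-rank sub-basis for degenerate designs
  Hfull <- trilinear_basis_matrix_(U)
  qrH <- qr(Hfull)
  r <- qrH$rank
  cols <- sort(qrH$pivot[seq_len(r)])
  H <- Hfull[, cols, drop = FALSE]
  m <- ncol(H)

  K <- kriging_kernel_matrix_(U, U, zeta)
  K <- K + diag(nugget_rel * zeta[1L], n)
  R <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  # whitened generalized least squares: with K = R'R, the trend
  # coefficients solve the ordinary problem R^-T H eta = R^-T y by QR,
  # avoiding the squared condition number of forming H'K^-1 H
  Ht <- backsolve(R, H, transpose = TRUE)
  yt <- backsolve(R, y, transpose = TRUE)
  qrHt <- qr(Ht)
  if (qrHt$rank < m) return(NULL)
  eta_bar <- qr.coef(qrHt, yt)
  Ra <- qr.R(qrHt)                    # P'AP = Ra'Ra with pivot P (sign-safe)
  pivot <- qrHt$pivot
  resid_wh <- yt - drop(Ht %*% eta_bar)

  list(X = X, y = y, zeta = zeta, nugget_rel = nugget_rel,
       lo = lo, span = span, U = U, H = H, cols = cols, m = m, n = n,
       R = R, Ht = Ht, Ra = Ra, pivot = pivot, eta_bar = eta_bar,
       resid_wh = resid_wh)
}

# Marginal log likelihood (restricted form): -1/2 y'K^-1 y + 1/2 y'C y
# - 1/2 log|K| - 1/2 log|A| - (n - m)/2 log(2 pi), with
# C = K^-1 H (H'K^-1 H)^-1 H' K^-1.
kriging_ll_ <- function(cache) {
  # -1/2 y'K^-1 y + 1/2 y'C y equals the generalized-residual quadratic
  # form -1/2 (y - H eta_bar)' K^-1 (y - H eta_bar), computed on the
  # whitened residual for stability
  quad <- sum(cache$resid_wh^2)
  logdetK <- 2 * sum(log(diag(cache$R)))
  logdetA <- 2 * sum(log(abs(diag(cache$Ra))))
  -0.5 * quad - 0.5 * logdetK - 0.5 * logdetA -
    (cache$n - cache$m) / 2 * log(2 * pi)
}

#' Fit the universal Kriging surrogate
#'
#' Noise-free interpolation of `outputs` (log stresses) over wall
#' parameters, with hyperparameters (signal variance and three
#' length-scale parameters acting on internally standardized coordinates)
#' chosen by seeded multi-start maximization of the restricted marginal
#' likelihood. A relative nugget of `1e-10` times the signal variance is
#' added for conditioning. With exactly as many points as trend basis
#' functions the residual likelihood is degenerate and the heuristic
#' starting hyperparameters are kept unchanged.
#'
#' @param inputs n x 3 matrix of (t, alpha, beta) rows (or a list of
#'   [wall_params()]); at least 8 points for a full-rank trend.
#' @param outputs Numeric vector of log maximum wall stresses.
#' @param restarts Number of seeded optimizer starts, default 10.
#' @param seed Integer seed.
#' @param start Optional length-4 hyperparameter vector used as the first
#'   optimizer start (e.g. a previous fit's, when updating).
#' @param nugget_rel Relative nugget, default `1e-10`.
#' @return Object of class `kriging` with `print`, `predict` and `logLik`
#'   methods.
#' @export
kriging_fit <- function(inputs, outputs, restarts = 10L, seed = 1L,
                        start = NULL, nugget_rel = 1e-10) {
  X <- if (is.list(inputs)) do.call(rbind, lapply(inputs, as.numeric))
       else as.matrix(inputs)
  y <- as.numeric(outputs)
  stopifnot(ncol(X) == 3L, nrow(X) == length(y))
  n <- nrow(X)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  zeta0 <- c(vy, 0.09, 0.09, 0.09)

  probe <- kriging_assemble_(X, y, zeta0, nugget_rel)
  if (is.null(probe)) stop("kriging_fit: singular kernel at start",
                           call. = FALSE)
  m <- probe$m
  if (m < 8L) {
    warning(sprintf("degenerate design: trend basis reduced to rank %d", m))
  }
  if (n < m) stop(sprintf("need at least %d points for the trend basis", m),
                  call. = FALSE)

  if (n == m) {
    # pure trend interpolation: no residual degrees of freedom, keep start
    cache <- probe
  } else {
    lv <- log(vy)
    lower <- c(lv - 30, rep(log(1e-4), 3L))
    upper <- c(lv + 10, rep(log(1e4), 3L))
    nll <- function(lz) {
      cc <- kriging_assemble_(X, y, exp(lz), nugget_rel)
      if (is.null(cc)) return(1e10)
      v <- -kriging_ll_(cc)
      if (!is.finite(v)) 1e10 else v
    }
    starts <- with_seed_(seed, {
      s <- lapply(seq_len(max(1L, restarts)), function(r) {
        log(zeta0) + if (r == 1L) 0 else stats::rnorm(4L, sd = 1.2)
      })
      if (!is.null(start)) s[[1L]] <- log(pmax(start, 1e-300))
      s
    })
    fits <- lapply(starts, function(st) {
      tryCatch(stats::optim(pmin(pmax(st, lower), upper), nll,
                            method = "L-BFGS-B", lower = lower,
                            upper = upper, control = list(maxit = 200L)),
               error = function(e) list(value = Inf))
    })
    vals <- vapply(fits, function(f) f$value, 0)
    if (!any(is.finite(vals) & vals < 1e10)) {
      stop("kriging_fit: non-finite likelihood at all restarts",
           call. = FALSE)
    }
    best <- fits[[which.min(vals)]]
    cache <- kriging_assemble_(X, y, exp(best$par), nugget_rel)
  }
  structure(cache, class = "kriging")
}

#' @export
print.kriging <- function(x, ...) {
  cat(sprintf(paste0("Universal Kriging surrogate: %d points, trend rank ",
                     "%d\n  zeta = (%.4g, %.4g, %.4g, %.4g)\n"),
              x$n, x$m, x$zeta[1], x$zeta[2], x$zeta[3], x$zeta[4]))
  invisible(x)
}

#' Restricted marginal log likelihood of a Kriging model
#'
#' @param model A fitted `kriging`.
#' @return Scalar log likelihood.
#' @export
kriging_log_marginal <- function(model) kriging_ll_(model)

#' @export
logLik.kriging <- function(object, ...) {
  ll <- kriging_ll_(object)
  attr(ll, "df") <- 4L
  class(ll) <- "logLik"
  ll
}

#' Predict log maximum wall stress
#'
#' Mean `k*' K^-1 y + r' eta_bar` and variance
#' `k(th*, th*) - k*' K^-1 k* + r' (H K^-1 H')^-1 r` (clipped at zero),
#' where `r = h* - H K^-1 k*` carries the trend-coefficient uncertainty
#' of the vague prior.
#'
#' @param object A fitted `kriging`.
#' @param newdata n x 3 matrix of (t, alpha, beta) rows, a numeric triple,
#'   or a [wall_params()].
#' @param ... Unused.
#' @return List with numeric vectors `mean` and `sd` of the log stress.
#' @export
predict.kriging <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(as.numeric(newdata), nrow = 1L)
       else as.matrix(newdata)
  stopifnot(ncol(X) == 3L)
  U <- sweep(sweep(X, 2L, object$lo), 2L, object$span, `/`)
  Ks <- kriging_kernel_matrix_(object$U, U, object$zeta)   # n x q
  # a test point coinciding with a training point carries the nugget
  # too, so the model interpolates exactly there
  nug <- object$nugget_rel * object$zeta[1L]
  for (i in seq_len(object$n)) {
    same <- rowSums(abs(sweep(U, 2L, object$U[i, ]))) == 0
    if (any(same)) Ks[i, same] <- Ks[i, same] + nug
  }
  Hs <- trilinear_basis_matrix_(U)[, object$cols, drop = FALSE]
  Kst <- backsolve(object$R, Ks, transpose = TRUE)         # R^-T k*
  # mean in the stable form h*' eta_bar + k*' K^-1 (y - H eta_bar)
  mean <- drop(Hs %*% object$eta_bar) +
    drop(crossprod(Kst, object$resid_wh))
  var_gp <- object$zeta[1L] - colSums(Kst^2)
  Rmat <- Hs - crossprod(Kst, object$Ht)                   # q x m
  z <- backsolve(object$Ra, t(Rmat[, object$pivot, drop = FALSE]),
                 transpose = TRUE)                         # m x q
  var_trend <- colSums(z^2)
  v <- pmax(var_gp + var_trend, 0)
  list(mean = mean, sd = sqrt(v))
}

#' Add training points to a Kriging surrogate
#'
#' @param object A fitted `kriging`.
#' @param new_input Numeric triple or matrix of new (t, alpha, beta) rows.
#' @param new_output Corresponding log stresses.
#' @param restarts,seed Refit settings; the current hyperparameters seed
#'   the first optimizer start.
#' @param ... Unused.
#' @return The refitted `kriging`.
#' @export
update.kriging <- function(object, new_input, new_output, restarts = 3L,
                           seed = 1L, ...) {
  Xn <- if (is.null(dim(new_input))) matrix(as.numeric(new_input), nrow = 1L)
        else as.matrix(new_input)
  kriging_fit(rbind(object$X, Xn), c(object$y, as.numeric(new_output)),
              restarts = restarts, seed = seed, start = object$zeta,
              nugget_rel = object$nugget_rel)
}

#' Serialize / deserialize a Kriging surrogate as JSON
#'
#' @param model A fitted `kriging`.
#' @param path File path.
#' @return `read_kriging` returns the reassembled `kriging`.
#' @export
write_kriging <- function(model, path) {
  obj <- list(inputs = apply(model$X, 1L, as.numeric, simplify = FALSE),
              outputs = as.numeric(model$y),
              zeta = as.numeric(model$zeta),
              nugget_rel = model$nugget_rel,
              basis = "trilinear")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kriging
#' @export
read_kriging <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  X <- if (is.matrix(obj$inputs)) obj$inputs else
    do.call(rbind, lapply(obj$inputs, as.numeric))
  cache <- kriging_assemble_(X, as.numeric(obj$outputs),
                             as.numeric(obj$zeta), obj$nugget_rel)
  structure(cache, class = "kriging")
}
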