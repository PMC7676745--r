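# Internal helpers shared across the package.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All user-facing stochastic functions are
# routed through this so a seed argument never clobbers the session RNG.
with_seed_ <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Multivariate normal log-density via Cholesky; x may be a matrix with one
# point per row.
dmvnorm_log_ <- function(x, mean, sigma) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  p <- ncol(x)
  R <- chol(sigma)
  z <- backsolve(R, t(x) - mean, transpose = TRUE)
  -0.5 * p * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(z^2)
}

dmvnorm_ <- function(x, mean, sigma) exp(dmvnorm_log_(x, mean, sigma))

# Draw n samples from N(mean, sigma); rows are samples. Uses the upper
# Cholesky factor; sampling is reproducible given the surrounding seed.
rmvnorm_ <- function(n, mean, sigma) {
  p <- length(mean)
  R <- chol(sigma)
  z <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
  sweep(z %*% R, 2L, mean, `+`)
}

stopifnot_positive_ <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("%s must be strictly positive and finite", what), call. = FALSE)
  }
  invisible(x)
}

is_scalar_number_ <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Symmetrize and floor the eigenvalues of a covariance matrix at zero.
psd_clean_ <- function(S) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values < 0)) {
    S <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    S <- (S + t(S)) / 2
  }
  S
}
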