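# Density- and stress-weighted active training of the Kriging surrogate.
# Acquisition mass concentrates where the surrogate is uncertain, the
# patient-specific parameter density is high, and the predicted stress is
# large, so expensive forward-model evaluations are spent where they
# matter for the rupture probability.

#' Active-learning configuration
#'
#' @param n_init Total initial design size (default 8; the predictive mean
#'   is always one of the initial points).
#' @param n_grid Acquisition grid size (default 10000).
#' @param n_eval Monte-Carlo sample size for downstream rupture
#'   probabilities (default 10000).
#' @param tol Convergence tolerance on the change of the grid-averaged
#'   acquisition value (default 1e-4).
#' @param max_iters Safety cap on acquisition iterations (default 200).
#' @param seed Integer seed; the full training run is reproducible given
#'   the seed, configuration and forward model.
#' @param fit_restarts,update_restarts Optimizer restarts for the initial
#'   fit and per-iteration refits.
#' @return List of class `active_config`.
#' @export
active_config <- function(n_init = 8L, n_grid = 10000L, n_eval = 10000L,
                          tol = 1e-4, max_iters = 200L, seed = 1L,
                          fit_restarts = 5L, update_restarts = 2L) {
  stopifnot(n_init >= 8L, tol > 0, n_grid >= 1L, n_eval >= 1L)
  structure(list(n_init = as.integer(n_init), n_grid = as.integer(n_grid),
                 n_eval = as.integer(n_eval), tol = tol,
                 max_iters = as.integer(max_iters), seed = as.integer(seed),
                 fit_restarts = as.integer(fit_restarts),
                 update_restarts = as.integer(update_restarts)),
            class = "active_config")
}

#' Acquisition function for one grid point
#'
#' `psi(Theta) = sd_log_stress(theta) * p(log Theta) * mean_log_stress(theta)`
#' with `theta` the (t, alpha, beta) components of `Theta`. The wall
#' strength enters only through the density. Negative predicted log
#' stresses (sub-kPa stresses) are clamped to zero with a warning.
#'
#' @param surrogate A fitted `kriging`.
#' @param point Length-4 vector of log (t, alpha, beta, sigma_gamma).
#' @param density Value of the predictive density at `point`.
#' @return Scalar acquisition value (non-negative).
#' @export
acquisition_psi <- function(surrogate, point, density) {
  as.numeric(acquisition_psi_vec_(surrogate, matrix(point, nrow = 1L),
                                  density))
}

acquisition_psi_vec_ <- function(surrogate, points, densities,
                                 warn = TRUE) {
  theta <- exp(points[, 1:3, drop = FALSE])
  pr <- predict(surrogate, theta)
  mu <- pr$mean
  clamped <- any(mu < 0)
  if (clamped) {
    if (warn) {
      warning("negative predicted log stress clamped to 0 in acquisition")
    }
    mu <- pmax(mu, 0)
  }
  structure(pr$sd * densities * mu, clamped = clamped)
}

#' Acquisition grid over the log-parameter box
#'
#' A seeded Latin-hypercube sample of `n_grid` points over the box
#' `mu_log +/- 3` marginal standard deviations, with the predictive
#' density evaluated exactly at each point. The grid is intentionally
#' uniform over the box rather than density-distributed: the acquisition
#' function already weights by the density.
#'
#' @param predictive A `wall_prediction`.
#' @param n_grid Number of points.
#' @param seed Integer seed.
#' @return List of class `acquisition_grid` with `points` (n_grid x 4 log
#'   coordinates) and `densities`.
#' @export
acquisition_grid <- function(predictive, n_grid = 10000L, seed = 1L) {
  sd <- sqrt(pmax(diag(predictive$Sigma_log), 0))
  lo <- predictive$mu_log - 3 * sd
  hi <- predictive$mu_log + 3 * sd
  pts <- with_seed_(seed, lhs::randomLHS(n_grid, 4L))
  pts <- sweep(sweep(pts, 2L, hi - lo, `*`), 2L, lo, `+`)
  dens <- dmvnorm_(pts, predictive$mu_log, predictive$Sigma_log)
  structure(list(points = pts, densities = dens, lo = lo, hi = hi),
            class = "acquisition_grid")
}

#' Select the next forward-model evaluation point
#'
#' Returns the (t, alpha, beta) components of the grid point maximizing
#' the acquisition function; ties resolve to the lowest grid index. If
#' every acquisition value is zero the highest-density grid point is
#' returned as a degenerate fallback.
#'
#' @param surrogate A fitted `kriging`.
#' @param grid An [acquisition_grid()].
#' @return A [wall_params()] triple.
#' @export
next_point <- function(surrogate, grid) {
  stopifnot(nrow(grid$points) >= 1L)
  psi <- acquisition_psi_vec_(surrogate, grid$points, grid$densities)
  i <- if (all(psi == 0)) {
    message("all acquisition values zero; falling back to densest point")
    which.max(grid$densities)
  } else {
    which.max(psi)
  }
  th <- exp(grid$points[i, 1:3])
  wall_params(th[1L], th[2L], th[3L])
}

#' Actively train the Kriging surrogate of the wall stress
#'
#' Implements the density- and stress-weighted active training loop:
#' an initial seeded Latin-hypercube design of `n_init - 1` points over
#' the `+/- 3` sigma log-space box plus the predictive mean itself is
#' evaluated with the forward model and interpolated; then, while the
#' grid-averaged acquisition value `psi_hat` still changes by more than
#' `tol` between iterations, the acquisition maximizer is evaluated and
#' the surrogate refitted. Forward-model failures are logged and the
#' failing point's grid weight zeroed; more than three consecutive
#' failures abort the run.
#'
#' @param forward A forward model accepted by [as_forward_model()].
#' @param predictive A `wall_prediction` with positive-definite
#'   covariance.
#' @param config An [active_config()].
#' @return Object of class `surrogate_training`: `model` (the `kriging`),
#'   `log` (data frame of iteration, psi_hat, proposed theta, stress),
#'   `psi_hat` (history), `n_evals`, and the acquisition `grid`.
#' @export
train_surrogate_active <- function(forward, predictive,
                                   config = active_config()) {
  fwd <- as_forward_model(forward)
  sd4 <- sqrt(diag(predictive$Sigma_log))
  if (any(sd4 <= 0)) stop("predictive covariance must be positive definite",
                          call. = FALSE)
  lo <- (predictive$mu_log - 3 * sd4)[1:3]
  hi <- (predictive$mu_log + 3 * sd4)[1:3]

  # initial design: n_init - 1 space-filling points plus the mean
  design <- with_seed_(config$seed, lhs::randomLHS(config$n_init - 1L, 3L))
  design <- sweep(sweep(design, 2L, hi - lo, `*`), 2L, lo, `+`)
  design <- rbind(design, predictive$mu_log[1:3])
  replacements <- with_seed_(config$seed + 1L,
                             lhs::randomLHS(4L * config$n_init, 3L))
  replacements <- sweep(sweep(replacements, 2L, hi - lo, `*`), 2L, lo, `+`)

  X <- matrix(numeric(0), ncol = 3L)
  ystress <- numeric(0)
  failures <- list()
  consec_fail <- 0L
  try_eval <- function(log_theta) {
    th <- exp(log_theta)
    s <- tryCatch(fwd(th), error = function(e) {
      failures[[length(failures) + 1L]] <<- list(
        theta = th, message = conditionMessage(e))
      NA_real_
    })
    if (is.na(s)) {
      consec_fail <<- consec_fail + 1L
      if (consec_fail > 3L) {
        stop("active training aborted: more than 3 consecutive ",
             "forward-model failures", call. = FALSE)
      }
    } else {
      consec_fail <<- 0L
      X <<- rbind(X, th)
      ystress <<- c(ystress, s)
    }
    s
  }
  ri <- 1L
  for (i in seq_len(nrow(design))) {
    s <- try_eval(design[i, ])
    while (is.na(s) && ri <= nrow(replacements)) {
      s <- try_eval(replacements[ri, ])
      ri <- ri + 1L
    }
  }
  if (nrow(X) < config$n_init) {
    stop("could not assemble the initial design", call. = FALSE)
  }

  surrogate <- kriging_fit(X, log(ystress), restarts = config$fit_restarts,
                           seed = config$seed)
  grid <- acquisition_grid(predictive, config$n_grid, config$seed + 2L)

  clamped_any <- FALSE
  psi_of <- function(model) {
    v <- acquisition_psi_vec_(model, grid$points, grid$densities,
                              warn = FALSE)
    clamped_any <<- clamped_any || isTRUE(attr(v, "clamped"))
    mean(v)
  }
  psi_hist <- psi_of(surrogate)
  log_rows <- list(data.frame(iteration = 1L, psi_hat = psi_hist[1L],
                              t = NA_real_, alpha = NA_real_,
                              beta = NA_real_, stress = NA_real_))
  psi_prev <- 0           # psi_hat_0
  psi_cur <- psi_hist[1L]
  iter <- 1L
  while (abs(psi_cur - psi_prev) > config$tol && iter < config$max_iters) {
    theta_next <- suppressWarnings(next_point(surrogate, grid))
    s <- tryCatch(fwd(as.numeric(theta_next)), error = function(e) {
      failures[[length(failures) + 1L]] <<- list(
        theta = as.numeric(theta_next), message = conditionMessage(e))
      NA_real_
    })
    if (is.na(s)) {
      consec_fail <- consec_fail + 1L
      if (consec_fail > 3L) {
        stop("active training aborted: more than 3 consecutive ",
             "forward-model failures", call. = FALSE)
      }
      # penalize the failing point so it is not proposed again
      j <- which.min(colSums((t(grid$points[, 1:3]) -
                                log(as.numeric(theta_next)))^2))
      grid$densities[j] <- 0
      next
    }
    consec_fail <- 0L
    surrogate <- update(surrogate, as.numeric(theta_next), log(s),
                        restarts = config$update_restarts,
                        seed = config$seed + 10L + iter)
    iter <- iter + 1L
    psi_prev <- psi_cur
    psi_cur <- psi_of(surrogate)
    psi_hist <- c(psi_hist, psi_cur)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      iteration = iter, psi_hat = psi_cur, t = theta_next[1L],
      alpha = theta_next[2L], beta = theta_next[3L], stress = s)
  }
  if (clamped_any) {
    warning("negative predicted log stresses were clamped to 0 in the ",
            "acquisition function during training")
  }
  structure(
    list(model = surrogate, log = do.call(rbind, log_rows),
         psi_hat = psi_hist, n_evals = nrow(surrogate$X),
         failures = failures, grid = grid, converged =
           abs(psi_cur - psi_prev) <= config$tol),
    class = "surrogate_training")
}

#' @export
print.surrogate_training <- function(x, ...) {
  cat(sprintf(paste0("Active surrogate training: %d forward-model ",
                     "evaluations, %d iterations, final psi_hat %.3g ",
                     "(%sconverged)\n"),
              x$n_evals, length(x$psi_hat), utils::tail(x$psi_hat, 1L),
              if (x$converged) "" else "not "))
  if (length(x$failures)) {
    cat(sprintf("  %d forward-model failures were skipped\n",
                length(x$failures)))
  }
  invisible(x)
}

#' @export
plot.surrogate_training <- function(x, ...) {
  graphics::plot(seq_along(x$psi_hat), x$psi_hat, type = "b",
                 xlab = "training iteration",
                 ylab = expression(hat(psi)), ...)
  invisible(x)
}

#' Write the active-training log as delimited text
#'
#' @param training A `surrogate_training`.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_training_log <- function(training, path) {
  utils::write.csv(training$log, path, row.names = FALSE)
  invisible(path)
}
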