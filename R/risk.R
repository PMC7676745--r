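# Rupture risk indices: the Monte-Carlo probability of rupture over the
# joint predictive distribution of the wall properties, plus the
# deterministic stress/strength ratio (RPI) and the independent-marginal
# probabilistic index (PRRI) as comparators.

# Mean log stress function from a surrogate / forward model / constant.
log_stress_fn_ <- function(object) {
  if (inherits(object, "kriging")) {
    function(theta) predict(object, theta)$mean
  } else if (inherits(object, "membrane_balloon")) {
    f <- as_forward_model(object)
    function(theta) log(apply(theta, 1L, f))
  } else if (is.function(object)) {
    function(theta) log(apply(theta, 1L, object))
  } else if (is_scalar_number_(object)) {
    function(theta) rep(log(object), nrow(theta))
  } else {
    stop("cannot interpret stress model", call. = FALSE)
  }
}

#' Monte-Carlo probability of rupture
#'
#' Draws `n_eval` joint samples of the four log wall properties from the
#' predictive distribution (correlations included, via the Cholesky
#' factor), compares the surrogate's mean log stress at each sampled
#' (t, alpha, beta) against the sampled log wall strength, and returns
#' the exceedance fraction. The inequality is strict: ties count as
#' non-rupture.
#'
#' @param surrogate A fitted `kriging`, a forward-model function or
#'   `membrane_balloon` (stress in kPa), or a constant stress in kPa.
#' @param predictive A `wall_prediction` with positive-definite
#'   covariance.
#' @param n_eval Number of Monte-Carlo samples, default 10000.
#' @param seed Integer seed, default 1.
#' @return List with `p_rupt` (probability in \[0, 1\]),
#'   `mc_standard_error` (`sqrt(p (1 - p) / n_eval)`) and `n_eval`.
#' @export
prob_rupture_mc <- function(surrogate, predictive, n_eval = 10000L,
                            seed = 1L) {
  fn <- log_stress_fn_(surrogate)
  S <- with_seed_(seed,
                  rmvnorm_(n_eval, predictive$mu_log, predictive$Sigma_log))
  theta <- exp(S[, 1:3, drop = FALSE])
  p <- mean(fn(theta) > S[, 4L])
  list(p_rupt = p, mc_standard_error = sqrt(p * (1 - p) / n_eval),
       n_eval = as.integer(n_eval))
}

#' Closed-form rupture probability under independent Gaussians
#'
#' If the log stress and log strength are independent Gaussians
#' `N(mu1, s1^2)` and `N(mu2, s2^2)`, the exceedance probability is
#' `Phi((mu1 - mu2) / sqrt(s1^2 + s2^2))`. Serves as the analytic oracle
#' for validating the Monte-Carlo estimator. With both standard
#' deviations zero the indicator is a step with the strict-inequality
#' convention (a tie counts as non-rupture).
#'
#' @param mu1,s1 Mean and standard deviation of the log stress.
#' @param mu2,s2 Mean and standard deviation of the log strength.
#' @return Probability in \[0, 1\].
#' @export
prob_rupture_closed_form <- function(mu1, s1, mu2, s2) {
  stopifnot(s1 >= 0, s2 >= 0)
  if (s1 == 0 && s2 == 0) {
    return(as.numeric(mu1 > mu2))
  }
  stats::pnorm((mu1 - mu2) / sqrt(s1^2 + s2^2))
}

#' Rupture potential index
#'
#' The deterministic stress/strength ratio: the wall stress evaluated at
#' the predictive mean parameters divided by the predicted mean wall
#' strength in physical space. By default the mean strength is the
#' log-normal mean `exp(mu_log + sigma_log^2 / 2)`; a directly known
#' physical-space mean strength (e.g. from a published table) can be
#' supplied instead via `mean_strength`.
#'
#' @param stress_model A fitted `kriging`, forward-model function or
#'   `membrane_balloon`, or a precomputed stress at the mean in kPa.
#' @param predictive A `wall_prediction` (used for the mean parameters
#'   and, unless `mean_strength` is given, the mean strength).
#' @param mean_strength Optional mean wall strength in kPa.
#' @return Dimensionless RPI (> 0).
#' @export
rpi <- function(stress_model, predictive = NULL, mean_strength = NULL) {
  if (is_scalar_number_(stress_model)) {
    stress <- stress_model
  } else {
    if (is.null(predictive)) stop("predictive required", call. = FALSE)
    theta_mean <- matrix(exp(predictive$mu_log[1:3]), nrow = 1L)
    stress <- exp(log_stress_fn_(stress_model)(theta_mean))
  }
  if (is.null(mean_strength)) {
    if (is.null(predictive)) stop("predictive required", call. = FALSE)
    mean_strength <- exp(predictive$mu_log[4L] +
                           predictive$Sigma_log[4L, 4L] / 2)
  }
  if (mean_strength <= 0) stop("zero or negative wall strength",
                               call. = FALSE)
  unname(stress / mean_strength)
}

#' Probabilistic rupture risk index
#'
#' Monte-Carlo expectation over independent marginals of log thickness
#' and log strength only, with the stiffness parameters held at their
#' predictive (log-space) means: the cohort-uncertainty comparator index.
#' The printed formula evaluates the stress at the mean log thickness
#' inside the indicator, which would make the thickness integration
#' vacuous; the default evaluates the stress at each sampled thickness,
#' and `literal = TRUE` restores the printed variant for comparison.
#'
#' @param surrogate As in [prob_rupture_mc()].
#' @param predictive A `wall_prediction`; only the (log t, log
#'   sigma_gamma) marginals are sampled.
#' @param n_eval,seed Monte-Carlo settings.
#' @param literal Evaluate the stress at the mean log thickness
#'   (printed-formula variant), default `FALSE`.
#' @return Probability in \[0, 1\].
#' @export
prri <- function(surrogate, predictive, n_eval = 10000L, seed = 1L,
                 literal = FALSE) {
  fn <- log_stress_fn_(surrogate)
  mu <- predictive$mu_log
  sd_t <- sqrt(predictive$Sigma_log[1L, 1L])
  sd_g <- sqrt(predictive$Sigma_log[4L, 4L])
  with_seed_(seed, {
    log_t <- stats::rnorm(n_eval, mu[1L], sd_t)
    log_g <- stats::rnorm(n_eval, mu[4L], sd_g)
    if (literal) log_t <- rep(mu[1L], n_eval)
    theta <- cbind(exp(log_t), exp(mu[2L]), exp(mu[3L]))
    mean(fn(theta) > log_g)
  })
}

#' Full per-patient risk assessment
#'
#' Runs the complete post-regression pipeline for one patient: trains the
#' Kriging surrogate with active learning against the forward model,
#' then computes the probability of rupture and the comparator indices.
#'
#' @param forward A forward model accepted by [as_forward_model()].
#' @param predictive A `wall_prediction` for the patient.
#' @param config An [active_config()]; its `n_eval` and `seed` drive the
#'   Monte-Carlo stage.
#' @return Object of class `risk_result` with fields `p_rupt`,
#'   `sigma_at_mean` (kPa), `rpi`, `prri`, `n_eval`,
#'   `mc_standard_error`, plus the `training` object.
#' @export
assess_rupture_risk <- function(forward, predictive,
                                config = active_config()) {
  training <- train_surrogate_active(forward, predictive, config)
  surrogate <- training$model
  theta_mean <- matrix(exp(predictive$mu_log[1:3]), nrow = 1L)
  sigma_at_mean <- exp(predict(surrogate, theta_mean)$mean)
  mc <- prob_rupture_mc(surrogate, predictive, config$n_eval,
                        config$seed + 500L)
  structure(
    list(p_rupt = mc$p_rupt, sigma_at_mean = sigma_at_mean,
         rpi = rpi(surrogate, predictive),
         prri = prri(surrogate, predictive, config$n_eval,
                     config$seed + 501L),
         n_eval = mc$n_eval, mc_standard_error = mc$mc_standard_error,
         training = training),
    class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat("Rupture risk assessment\n")
  cat(sprintf("  stress at predictive mean: %.2f kPa\n", x$sigma_at_mean))
  cat(sprintf("  RPI:    %.3f\n", x$rpi))
  cat(sprintf("  PRRI:   %.2f %%\n", 100 * x$prri))
  cat(sprintf("  P_rupt: %.2f %% (MC se %.2f %%, n_eval = %d)\n",
              100 * x$p_rupt, 100 * x$mc_standard_error, x$n_eval))
  cat(sprintf("  forward-model evaluations: %d\n", x$training$n_evals))
  invisible(x)
}

#' Serialize a risk result as JSON
#'
#' @param result A `risk_result`.
#' @param path File path.
#' @return Invisibly, the path.
#' @export
write_risk_result <- function(result, path) {
  obj <- list(p_rupt = result$p_rupt, sigma_at_mean = result$sigma_at_mean,
              rpi = result$rpi, prri = result$prri, n_eval = result$n_eval,
              mc_standard_error = result$mc_standard_error,
              forward_evals = result$training$n_evals)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
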