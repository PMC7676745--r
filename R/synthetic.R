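#' Configuration for the synthetic-cohort generator
#'
#' The generator emulates the statistical structure of the tissue-sample
#' database the framework assumes: several tissue samples per patient,
#' log-normally distributed invasive properties whose log-space moments
#' default to the published cohort values, configurable cross-correlations
#' among the log-properties, and an optional noisy linear link from the
#' standardized clinical features to the log-properties.
#'
#' @param n_patients Number of patients.
#' @param samples_per_patient Either a single integer, or a list
#'   `list(sizes =, prob =)` giving a distribution over small per-patient
#'   sample counts. The default mixes 1-4 samples with mean about 2.2,
#'   matching a database of roughly 251 samples from 113 patients.
#' @param log_theta_mean,log_theta_sd Length-4 log-space means and standard
#'   deviations of (t, alpha, beta, sigma_gamma); defaults are the cohort
#'   values (0.484, 4.543, 7.685, 6.704) and (0.105, 1.036, 0.758, 0.183).
#' @param log_theta_corr 4x4 correlation matrix for the log-properties;
#'   defaults use rho(t, sigma_gamma) = -0.3214, rho(beta, sigma_gamma) =
#'   0.2274, rho(t, beta) = -0.1966, rho(alpha, beta) = 0.1413, others 0.
#' @param link_weights 8x4 matrix coupling standardized features to the
#'   log-properties; default all-zero (marginals then exactly the
#'   configured log-normal moments).
#' @param feature_means,feature_sds Length-8 feature moments in the order
#'   [aaa_feature_names()]; defaults are the cohort column values
#'   (62.91, 24.10, 111.84, 24.58, 221.33, 13.27, 30.39, 89.95) and
#'   (17.57, 11.19, 28.30, 6.55, 82.10, 2.20, 2.46, 6.61).
#' @param noise_sd Length-4 extra independent per-record noise on the
#'   log-properties, default 0.
#' @param seed Integer seed; identical seed gives an identical cohort.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 113L,
                          samples_per_patient = list(
                            sizes = 1:4, prob = c(0.35, 0.3, 0.2, 0.15)),
                          log_theta_mean = c(0.484, 4.543, 7.685, 6.704),
                          log_theta_sd = c(0.105, 1.036, 0.758, 0.183),
                          log_theta_corr = default_log_theta_corr(),
                          link_weights = matrix(0, 8L, 4L),
                          feature_means = c(62.91, 24.10, 111.84, 24.58,
                                            221.33, 13.27, 30.39, 89.95),
                          feature_sds = c(17.57, 11.19, 28.30, 6.55,
                                          82.10, 2.20, 2.46, 6.61),
                          noise_sd = c(0, 0, 0, 0),
                          seed = 1L) {
  if (is.numeric(samples_per_patient) && length(samples_per_patient) == 1L) {
    samples_per_patient <- list(sizes = as.integer(samples_per_patient),
                                prob = 1)
  }
  stopifnot(length(log_theta_mean) == 4L, length(log_theta_sd) == 4L,
            length(noise_sd) == 4L,
            all(dim(log_theta_corr) == c(4L, 4L)),
            length(feature_means) == length(feature_sds))
  stopifnot_positive_(log_theta_sd, "log_theta_sd")
  stopifnot_positive_(feature_sds, "feature_sds")
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative", call. = FALSE)
  if (max(abs(log_theta_corr - t(log_theta_corr))) > 1e-12 ||
      max(abs(diag(log_theta_corr) - 1)) > 1e-12) {
    stop("log_theta_corr must be symmetric with unit diagonal", call. = FALSE)
  }
  link_weights <- as.matrix(link_weights)
  if (!all(dim(link_weights) == c(length(feature_means), 4L))) {
    stop("link_weights must be n_features x 4", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients),
         samples_per_patient = samples_per_patient,
         log_theta_mean = log_theta_mean, log_theta_sd = log_theta_sd,
         log_theta_corr = log_theta_corr, link_weights = link_weights,
         feature_means = feature_means, feature_sds = feature_sds,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_log_theta_corr <- function() {
  R <- diag(4)
  rownames(R) <- colnames(R) <- aaa_property_names()
  R["t", "sigma_gamma"] <- R["sigma_gamma", "t"] <- -0.3214
  R["beta", "sigma_gamma"] <- R["sigma_gamma", "beta"] <- 0.2274
  R["t", "beta"] <- R["beta", "t"] <- -0.1966
  R["alpha", "beta"] <- R["beta", "alpha"] <- 0.1413
  R
}

#' Generate a synthetic cohort
#'
#' Per patient, the eight features are drawn from independent Gaussians
#' with the configured moments (geometric features truncated at zero).
#' Per tissue sample, the log-properties are the configured means plus the
#' linear link applied to the patient's standardized features, plus
#' multivariate Gaussian noise with the configured marginal standard
#' deviations and correlations (and optional extra independent noise),
#' then exponentiated.
#'
#' @param config A [cohort_config()].
#' @return An [aaa_cohort()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  D <- diag(config$log_theta_sd)
  Sigma <- D %*% config$log_theta_corr %*% D
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("assembled log-property covariance is not positive definite",
         call. = FALSE)
  }
  with_seed_(config$seed, {
    spp <- config$samples_per_patient
    counts <- if (length(spp$sizes) == 1L) {
      rep(spp$sizes, config$n_patients)
    } else {
      sample(spp$sizes, config$n_patients, replace = TRUE, prob = spp$prob)
    }
    p <- length(config$feature_means)
    feats_pat <- sweep(
      sweep(matrix(stats::rnorm(config$n_patients * p), ncol = p),
            2L, config$feature_sds, `*`),
      2L, config$feature_means, `+`)
    geom <- seq_len(min(4L, p))  # diameters and lengths are non-negative
    feats_pat[, geom] <- pmax(feats_pat[, geom], 0)
    z_pat <- sweep(sweep(feats_pat, 2L, config$feature_means),
                   2L, config$feature_sds, `/`)

    pid <- rep(seq_len(config$n_patients), counts)
    n <- length(pid)
    signal <- z_pat[pid, , drop = FALSE] %*% config$link_weights
    eps <- rmvnorm_(n, rep(0, 4L), Sigma)
    if (any(config$noise_sd > 0)) {
      eps <- eps + sweep(matrix(stats::rnorm(n * 4L), ncol = 4L),
                         2L, config$noise_sd, `*`)
    }
    log_theta <- sweep(signal + eps, 2L, config$log_theta_mean, `+`)
    props <- as.data.frame(exp(log_theta))
    names(props) <- aaa_property_names()
    feats <- as.data.frame(feats_pat[pid, , drop = FALSE])
    names(feats) <- if (p == 8L) aaa_feature_names() else
      paste0("feature_", seq_len(p))
    aaa_cohort(pid, feats, props)
  })
}

#' Inject missingness into a cohort's features
#'
#' Optional companion to [generate_cohort()] for exercising the
#' preprocessing filters: each feature cell is independently set to `NA`
#' with probability `rate`.
#'
#' @param cohort An `aaa_cohort`.
#' @param rate Missingness probability per cell, default 0.
#' @param seed Integer seed.
#' @return The cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, rate = 0, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(cohort)
  with_seed_(seed, {
    X <- as.matrix(cohort$features)
    mask <- matrix(stats::runif(length(X)) < rate, nrow = nrow(X))
    X[mask] <- NA_real_
    cohort$features <- as.data.frame(X)
    cohort
  })
}
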