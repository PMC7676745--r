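#' Spearman rank correlations between features and invasive properties
#'
#' Computes the Spearman rank correlation (average ranks for ties) between
#' every feature column and every invasive property of a complete,
#' preprocessed cohort. A constant column has no defined rank correlation
#' and is reported as `NA`, never as zero.
#'
#' @param cohort A complete (no missing cells) `aaa_cohort` with at least
#'   three records.
#' @return Numeric matrix, features in rows, properties in columns, entries
#'   in \[-1, 1\] or `NA`.
#' @export
spearman_correlations <- function(cohort) {
  X <- as.matrix(cohort$features)
  Y <- as.matrix(cohort$properties)
  if (nrow(X) < 3L) stop("need at least 3 records", call. = FALSE)
  if (any(is.na(X))) stop("run preprocess_cohort() first: missing values",
                          call. = FALSE)
  out <- suppressWarnings(stats::cor(X, Y, method = "spearman"))
  const_x <- apply(X, 2L, function(v) length(unique(v)) == 1L)
  const_y <- apply(Y, 2L, function(v) length(unique(v)) == 1L)
  out[const_x, ] <- NA_real_
  out[, const_y] <- NA_real_
  out
}

#' Sequential forward feature selection
#'
#' Greedy wrapper selection: candidates are visited in a fixed order
#' (by default, descending maximum absolute Spearman correlation with the
#' four invasive properties, ties broken by original column order) and
#' each is appended while the score of the grown feature set improves.
#' The empty model scores `+Inf`, so the first candidate is always
#' accepted; selection stops at the first non-improvement.
#'
#' @param cohort A complete, preprocessed `aaa_cohort`.
#' @param candidate_features Character vector of feature names in visiting
#'   order; by default ordered by correlation strength as above.
#' @param score Function taking an `aaa_cohort` (restricted to the current
#'   feature set) and returning a numeric score where smaller is better.
#'   Defaults to the leave-one-patient-out mean patient standardized mean
#'   square error of the multi-output GP, [loocv_benchmark()] with
#'   `model_kind = "model3"`.
#' @param ... Passed to the default score's [loocv_benchmark()] call
#'   (e.g. `restarts`, `seed`).
#' @return Character vector of selected feature names, in selection order.
#' @export
forward_feature_selection <- function(cohort, candidate_features = NULL,
                                      score = NULL, ...) {
  if (is.null(candidate_features)) {
    rho <- spearman_correlations(cohort)
    strength <- apply(abs(rho), 1L, max, na.rm = TRUE)
    strength[!is.finite(strength)] <- -Inf
    # order(-strength) is stable, so ties keep original column order
    candidate_features <- rownames(rho)[order(-strength)]
  }
  if (length(candidate_features) == 0L) {
    stop("empty candidate list", call. = FALSE)
  }
  if (is.null(score)) {
    dots <- list(...)
    score <- function(sub) {
      do.call(loocv_benchmark,
              c(list(sub, model_kind = "model3"), dots))$e_psmse
    }
  }
  selected <- character()
  best <- Inf
  for (cand in candidate_features) {
    trial <- c(selected, cand)
    sub <- aaa_cohort(cohort$patient_id,
                      cohort$features[trial],
                      cohort$properties)
    s <- score(sub)
    if (is.finite(s) && s < best) {
      selected <- trial
      best <- s
    } else {
      break
    }
  }
  selected
}
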