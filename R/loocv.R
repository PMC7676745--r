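#' Leave-one-patient-out benchmark of the regression models
#'
#' Holds out all records of one patient at a time, refits (models 2 and 3)
#' or recomputes cohort statistics (model 1) on the remaining records,
#' and scores the held-out predictions with two criteria:
#' \describe{
#'   \item{PSMSE}{patient standardized mean square error: per patient and
#'     output, the mean over the patient's records of
#'     `(log value - predicted mean)^2 / predicted variance`, averaged
#'     over the four outputs and over patients. The scoring rule is
#'     pluggable via `psmse_fn` since conventions differ between groups.}
#'   \item{PPE}{patient predictive entropy: the Gaussian differential
#'     entropy `1/2 log((2 pi e)^4 |Sigma|)` of the patient's predictive
#'     distribution, in nats, averaged over patients.}
#' }
#'
#' @param cohort A complete, preprocessed `aaa_cohort` with >= 2 patients.
#' @param model_kind `"model1"` (cohort log-normal), `"model2"`
#'   (independent GPs) or `"model3"` (correlated multi-output GP).
#' @param restarts,seed,maxit Passed to [mgp_fit()] for models 2/3.
#' @param psmse_fn Optional replacement scoring hook with signature
#'   `(log_targets_matrix, prediction)` returning the patient's PSMSE.
#' @return List with `per_patient` (data frame of patient id, psmse, ppe),
#'   `e_psmse` and `e_ppe` (means over patients).
#' @export
loocv_benchmark <- function(cohort,
                            model_kind = c("model3", "model2", "model1"),
                            restarts = 3L, seed = 1L, maxit = 60L,
                            psmse_fn = NULL) {
  model_kind <- match.arg(model_kind)
  ids <- unique(cohort$patient_id)
  if (length(ids) < 2L) stop("need at least 2 patients", call. = FALSE)
  if (is.null(psmse_fn)) {
    psmse_fn <- function(LY, pred) {
      v <- pmax(diag(pred$Sigma_log), .Machine$double.eps)
      mean(colMeans(sweep(sweep(LY, 2L, pred$mu_log)^2, 2L, v, `/`)))
    }
  }
  rows <- lapply(ids, function(id) {
    hold <- cohort$patient_id == id
    if (!any(hold)) {
      warning(sprintf("patient %s has zero records; skipped", id))
      return(NULL)
    }
    train <- aaa_cohort(cohort$patient_id[!hold],
                        cohort$features[!hold, , drop = FALSE],
                        cohort$properties[!hold, , drop = FALSE])
    LY <- log(as.matrix(cohort$properties[hold, , drop = FALSE]))
    if (model_kind == "model1") {
      pred <- model1_cohort_lognormal(train)
      preds <- rep(list(pred), sum(hold))
    } else {
      fit <- mgp_fit(train, kind = model_kind, restarts = restarts,
                     seed = seed, maxit = maxit)
      p <- predict(fit, as.matrix(cohort$features[hold, , drop = FALSE]))
      preds <- if (inherits(p, "wall_prediction")) list(p) else p
    }
    psmse <- mean(vapply(seq_along(preds), function(i) {
      psmse_fn(LY[i, , drop = FALSE], preds[[i]])
    }, 0))
    ppe <- mean(vapply(preds, predictive_entropy, 0))
    data.frame(patient_id = id, psmse = psmse, ppe = ppe)
  })
  per_patient <- do.call(rbind, rows)
  list(per_patient = per_patient,
       e_psmse = mean(per_patient$psmse),
       e_ppe = mean(per_patient$ppe))
}
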