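# Case-control evaluation layer: group summaries, relative differences
# between the asymptomatic and symptomatic/ruptured groups, and ROC/AUC
# discrimination analysis over per-patient risk indices.

index_columns_ <- function() c("d_max", "sigma_vm", "rpi", "prri", "p_rupt")

#' Read a per-patient index table
#'
#' Delimited text with columns `patient_id`, `group` (two labels,
#' `asymptomatic` and `symptomatic/ruptured`), optionally `ruptured`
#' (0/1), and the indices `d_max` (mm), `sigma_vm` (kPa), `rpi`, `prri`
#' (%), `p_rupt` (%).
#'
#' @param path CSV path.
#' @return Data frame of class `index_table`.
#' @export
read_index_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("patient_id", "group", index_columns_())
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("index table missing columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (length(unique(df$group)) != 2L) {
    stop("group labels must be binary", call. = FALSE)
  }
  vals <- as.matrix(df[index_columns_()])
  if (any(!is.finite(vals))) stop("non-finite index value", call. = FALSE)
  class(df) <- c("index_table", "data.frame")
  df
}

#' Bundled case-control index table
#'
#' The published per-patient results for the 36 diameter-matched AAAs
#' (18 asymptomatic, 18 symptomatic/ruptured): maximum diameter, wall
#' stress at the predictive mean, RPI, PRRI and the rupture probability,
#' plus a flag for the 11 ruptured cases. These printed values make the
#' evaluation layer testable without the finite-element stress solver.
#'
#' @return Data frame of class `index_table`.
#' @export
case_control_fixture <- function() {
  read_index_table(system.file("extdata", "case_control_indices.csv",
                               package = "aaarisk", mustWork = TRUE))
}

#' Per-group summary statistics
#'
#' Mean, standard deviation and quartiles per index and group. The
#' standard deviation convention for the published footer rows is the
#' population one (divide by n); the sample version is reported
#' alongside. Percentiles use linear interpolation between order
#' statistics, so the median of an even count is the midpoint of the
#' central pair.
#'
#' @param table An `index_table` (or data frame with `group` and index
#'   columns).
#' @param columns Index columns to summarize.
#' @return Data frame with one row per (group, index): `mean`, `sd_pop`,
#'   `sd_sample`, `p25`, `p50`, `p75`.
#' @export
group_summary <- function(table, columns = index_columns_()) {
  if (is.null(table$group) || nrow(table) == 0L) {
    stop("empty table or missing group column", call. = FALSE)
  }
  groups <- unique(table$group)
  rows <- list()
  for (g in groups) {
    sub <- table[table$group == g, , drop = FALSE]
    if (nrow(sub) == 0L) stop("empty group", call. = FALSE)
    for (cn in columns) {
      v <- sub[[cn]]
      n <- length(v)
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, index = cn, n = n, mean = mean(v),
        sd_pop = sqrt(mean((v - mean(v))^2)),
        sd_sample = stats::sd(v),
        p25 = q[1L], p50 = q[2L], p75 = q[3L])
    }
  }
  do.call(rbind, rows)
}

#' Relative difference between two group statistics
#'
#' `100 |q_sr - q_a| / q_a`, the percentage difference of the
#' symptomatic/ruptured group's statistic relative to the asymptomatic
#' group's. Scale-invariant: multiplying both values by a positive
#' constant leaves it unchanged.
#'
#' @param q_a Asymptomatic-group statistic (non-zero).
#' @param q_sr Symptomatic/ruptured-group statistic.
#' @return Percentage.
#' @export
relative_difference <- function(q_a, q_sr) {
  if (any(q_a == 0)) stop("zero denominator in relative difference",
                          call. = FALSE)
  100 * abs(q_sr - q_a) / q_a
}

#' Relative mean and median differences for every index
#'
#' @param table An `index_table`.
#' @param asymptomatic Label of the reference (asymptomatic) group;
#'   defaults to `"asymptomatic"`.
#' @param columns Index columns.
#' @return Data frame with rows `delta_mean` and `delta_median` (percent),
#'   one column per index; `NA` where the reference statistic is zero and
#'   the relative difference is undefined.
#' @export
relative_differences <- function(table, asymptomatic = "asymptomatic",
                                 columns = index_columns_()) {
  gs <- group_summary(table, columns)
  other <- setdiff(unique(gs$group), asymptomatic)
  if (length(other) != 1L) stop("expected exactly two groups", call. = FALSE)
  out <- sapply(columns, function(cn) {
    a <- gs[gs$group == asymptomatic & gs$index == cn, ]
    s <- gs[gs$group == other & gs$index == cn, ]
    safe <- function(x, y) tryCatch(relative_difference(x, y),
                                    error = function(e) NA_real_)
    c(delta_mean = safe(a$mean, s$mean),
      delta_median = safe(a$p50, s$p50))
  })
  as.data.frame(out)
}

#' ROC curve and AUC for one index
#'
#' Sweeps the classification threshold over the unique index values
#' (symptomatic/ruptured is the positive class, higher index = more
#' positive), reports true/false positive rates, and computes the area
#' under the curve by the trapezoid rule. Tied index values contribute
#' half credit, so the AUC equals the Mann-Whitney statistic
#' `U / (n1 n2)`. A constant index yields the degenerate diagonal and
#' AUC 0.5 with a warning.
#'
#' @param table An `index_table`.
#' @param index Name of the index column.
#' @param positive Group label treated as positive; defaults to
#'   `"symptomatic/ruptured"`.
#' @return List of class `aaa_roc`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_curve <- function(table, index, positive = "symptomatic/ruptured") {
  v <- table[[index]]
  y <- table$group == positive
  if (!any(y) || all(y)) stop("both groups must be non-empty", call. = FALSE)
  if (length(unique(v)) == 1L) {
    warning("constant index: degenerate ROC curve, AUC 0.5")
    return(structure(list(thresholds = unique(v), tpr = c(0, 1),
                          fpr = c(0, 1), auc = 0.5, index = index),
                     class = "aaa_roc"))
  }
  thr <- sort(unique(v), decreasing = TRUE)
  tpr <- vapply(thr, function(th) mean(v[y] >= th), 0)
  fpr <- vapply(thr, function(th) mean(v[!y] >= th), 0)
  tpr <- c(0, tpr)
  fpr <- c(0, fpr)
  if (utils::tail(tpr, 1L) != 1 || utils::tail(fpr, 1L) != 1) {
    tpr <- c(tpr, 1)
    fpr <- c(fpr, 1)
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 index = index),
            class = "aaa_roc")
}

#' @export
print.aaa_roc <- function(x, ...) {
  cat(sprintf("ROC for %s: AUC = %.4f (%d thresholds)\n",
              x$index, x$auc, length(x$thresholds)))
  invisible(x)
}

#' @export
plot.aaa_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("%s (AUC = %.3f)", x$index, x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Run the case-control evaluation
#'
#' Two entry modes. Given an `index_table` (precomputed per-patient
#' indices, e.g. the bundled fixture), computes group summaries, relative
#' differences and ROC/AUC for every index. Given an `aaa_cohort` plus
#' group labels and a forward model, first computes the indices in an
#' individual prospective scenario: each patient's records are removed
#' from the database, the regression model is refitted on the remainder,
#' the surrogate actively trained and all four indices computed; failures
#' are collected, not fatal.
#'
#' @param x An `index_table`, or an `aaa_cohort`.
#' @param groups For the cohort mode: named vector or function mapping
#'   patient id to group label.
#' @param forward For the cohort mode: forward model for
#'   [as_forward_model()].
#' @param config For the cohort mode: [active_config()].
#' @param mgp_restarts,mgp_maxit For the cohort mode: [mgp_fit()]
#'   settings.
#' @return List of class `case_control_report`: `table`, `summary`,
#'   `relative`, `roc` (per index), `failures`.
#' @export
run_case_control <- function(x, groups = NULL, forward = NULL,
                             config = active_config(), mgp_restarts = 3L,
                             mgp_maxit = 60L) {
  failures <- list()
  if (inherits(x, "aaa_cohort")) {
    if (is.null(groups) || is.null(forward)) {
      stop("cohort mode needs `groups` and `forward`", call. = FALSE)
    }
    glab <- if (is.function(groups)) {
      stats::setNames(vapply(unique(x$patient_id), groups, ""),
                      unique(x$patient_id))
    } else {
      groups
    }
    rows <- list()
    for (id in unique(x$patient_id)) {
      res <- tryCatch({
        hold <- x$patient_id == id
        train <- aaa_cohort(x$patient_id[!hold],
                            x$features[!hold, , drop = FALSE],
                            x$properties[!hold, , drop = FALSE])
        fit <- mgp_fit(train, restarts = mgp_restarts, seed = config$seed,
                       maxit = mgp_maxit)
        xi <- as.matrix(x$features[hold, , drop = FALSE])[1L, ]
        pred <- predict(fit, xi)
        risk <- assess_rupture_risk(forward, pred, config)
        data.frame(patient_id = as.character(id),
                   group = unname(glab[[as.character(id)]]),
                   d_max = NA_real_,
                   sigma_vm = risk$sigma_at_mean, rpi = risk$rpi,
                   prri = 100 * risk$prri, p_rupt = 100 * risk$p_rupt)
      }, error = function(e) {
        failures[[length(failures) + 1L]] <<- list(
          patient_id = id, message = conditionMessage(e))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
    tab <- do.call(rbind, rows)
    class(tab) <- c("index_table", "data.frame")
  } else {
    tab <- x
  }
  columns <- intersect(index_columns_(), names(tab))
  columns <- columns[vapply(columns, function(cn)
    !any(is.na(tab[[cn]])), TRUE)]
  rocs <- lapply(columns, function(cn)
    roc_curve(tab, cn, positive = setdiff(unique(tab$group),
                                          "asymptomatic")[1L]))
  names(rocs) <- columns
  structure(
    list(table = tab,
         summary = group_summary(tab, columns),
         relative = relative_differences(tab, columns = columns),
         roc = rocs, failures = failures),
    class = "case_control_report")
}

#' @export
print.case_control_report <- function(x, ...) {
  cat(sprintf("Case-control report: %d patients, %d failures\n",
              nrow(x$table), length(x$failures)))
  cat("\nRelative differences (%):\n")
  print(round(x$relative, 2))
  cat("\nAUC:\n")
  print(round(vapply(x$roc, function(r) r$auc, 0), 4))
  invisible(x)
}
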