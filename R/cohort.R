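#' Canonical column names
#'
#' Column order for the eight non-invasive clinical features and the four
#' invasive vessel-wall properties used throughout the package.
#'
#' @return Character vector of column names.
#' @export
aaa_feature_names <- function() {
  c("max_diameter", "thrombus_thickness", "aaa_length", "subrenal_diameter",
    "thrombocytes", "hemoglobin", "mch", "mcv")
}

#' @rdname aaa_feature_names
#' @export
aaa_property_names <- function() {
  c("t", "alpha", "beta", "sigma_gamma")
}

#' Construct a paired AAA cohort dataset
#'
#' A cohort is an ordered collection of records, each pairing a patient's
#' non-invasive clinical features with the invasive vessel-wall properties
#' measured on one tissue sample. Patients may contribute several records;
#' the integer `patient_id` identifies which records share a patient and is
#' the grouping unit for leave-one-patient-out validation.
#'
#' @param patient_id Integer vector, one entry per record.
#' @param features Data frame of numeric feature columns (missing values
#'   allowed, marked `NA`).
#' @param properties Data frame with columns `t`, `alpha`, `beta`,
#'   `sigma_gamma` (mm, kPa, kPa, kPa); all values must be strictly
#'   positive so the log transform is defined.
#' @return An object of class `aaa_cohort`.
#' @export
aaa_cohort <- function(patient_id, features, properties) {
  patient_id <- as.integer(patient_id)
  features <- as.data.frame(features)
  properties <- as.data.frame(properties)
  n <- length(patient_id)
  if (n < 1L) stop("cohort must contain at least one record", call. = FALSE)
  if (nrow(features) != n || nrow(properties) != n) {
    stop("patient_id, features and properties must have one row per record",
         call. = FALSE)
  }
  if (!setequal(names(properties), aaa_property_names())) {
    stop("properties must have columns t, alpha, beta, sigma_gamma",
         call. = FALSE)
  }
  properties <- properties[aaa_property_names()]
  for (nm in names(features)) {
    if (!is.numeric(features[[nm]])) {
      stop(sprintf("feature column '%s' is not numeric", nm), call. = FALSE)
    }
  }
  pm <- as.matrix(properties)
  if (any(is.na(pm)) || any(pm <= 0)) {
    stop("invasive properties must be complete and strictly positive",
         call. = FALSE)
  }
  structure(
    list(patient_id = patient_id, features = features,
         properties = properties),
    class = "aaa_cohort")
}

#' @export
print.aaa_cohort <- function(x, ...) {
  cat(sprintf("AAA cohort: %d records from %d patients\n",
              nrow(x$features), length(unique(x$patient_id))))
  cat(sprintf("  features (%d): %s\n", ncol(x$features),
              paste(names(x$features), collapse = ", ")))
  nmiss <- sum(is.na(as.matrix(x$features)))
  if (nmiss > 0) cat(sprintf("  missing feature cells: %d\n", nmiss))
  invisible(x)
}

#' Number of records in a cohort
#' @param x An `aaa_cohort`.
#' @return Integer record count.
#' @export
n_records <- function(x) length(x$patient_id)

#' Number of distinct patients in a cohort
#' @param x An `aaa_cohort`.
#' @return Integer patient count.
#' @export
n_patients <- function(x) length(unique(x$patient_id))

#' Read a paired cohort from delimited text
#'
#' Reads two comma-separated tables with a header row and a leading
#' `patient_id` column: a non-invasive table (clinical features, missing
#' cells empty or `NA`) and an invasive table with columns `t`, `alpha`,
#' `beta`, `sigma_gamma`. The two tables must be row-aligned: equal row
#' counts and identical patient indices per row.
#'
#' @param noninvasive_table,invasive_table Paths to the two CSV files.
#' @return An [aaa_cohort()] preserving the row order of the files.
#' @export
read_cohort <- function(noninvasive_table, invasive_table) {
  ni <- utils::read.csv(noninvasive_table, check.names = FALSE)
  iv <- utils::read.csv(invasive_table, check.names = FALSE)
  if (nrow(ni) != nrow(iv)) {
    stop(sprintf("alignment error: %d non-invasive rows vs %d invasive rows",
                 nrow(ni), nrow(iv)), call. = FALSE)
  }
  if (names(ni)[1L] != "patient_id" || names(iv)[1L] != "patient_id") {
    stop("first column of both tables must be 'patient_id'", call. = FALSE)
  }
  if (!isTRUE(all.equal(as.integer(ni[[1L]]), as.integer(iv[[1L]])))) {
    stop("alignment error: patient indices differ between the two tables",
         call. = FALSE)
  }
  feats <- ni[-1L]
  for (j in seq_along(feats)) {
    if (!is.numeric(feats[[j]])) {
      bad <- which(!is.na(feats[[j]]) & is.na(suppressWarnings(
        as.numeric(feats[[j]]))))
      stop(sprintf("parse error: non-numeric value in column '%s', row %d",
                   names(feats)[j], if (length(bad)) bad[1L] else NA_integer_),
           call. = FALSE)
    }
  }
  props <- iv[-1L]
  for (j in seq_along(props)) {
    if (!is.numeric(props[[j]])) {
      stop(sprintf("parse error: non-numeric value in column '%s'",
                   names(props)[j]), call. = FALSE)
    }
  }
  # geometry columns are raw measurements here: must be non-negative
  for (nm in intersect(names(feats),
                       c("max_diameter", "thrombus_thickness",
                         "aaa_length", "subrenal_diameter"))) {
    bad <- which(is.finite(feats[[nm]]) & feats[[nm]] < 0)
    if (length(bad)) {
      stop(sprintf("negative value in geometric feature '%s' (row %d)",
                   nm, bad[1L]), call. = FALSE)
    }
  }
  aaa_cohort(ni[[1L]], feats, props)
}

#' Write a cohort as the paired delimited schema
#'
#' Writes `<prefix>_noninvasive.csv` and `<prefix>_invasive.csv` in the
#' same schema [read_cohort()] expects, so a write/read cycle round-trips.
#'
#' @param cohort An `aaa_cohort`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, prefix) {
  ni <- cbind(patient_id = cohort$patient_id, cohort$features)
  iv <- cbind(patient_id = cohort$patient_id, cohort$properties)
  p1 <- paste0(prefix, "_noninvasive.csv")
  p2 <- paste0(prefix, "_invasive.csv")
  utils::write.csv(ni, p1, row.names = FALSE, quote = FALSE)
  utils::write.csv(iv, p2, row.names = FALSE, quote = FALSE)
  invisible(c(noninvasive = p1, invasive = p2))
}

#' Preprocess a cohort: missingness filters, imputation, normalization
#'
#' Applies, in order: (1) drop any feature missing in more than
#' `feature_missing_threshold` of the records; (2) drop any record missing
#' more than `patient_missing_threshold` of the surviving features;
#' (3) impute remaining missing cells with the per-feature median over the
#' surviving records; (4) z-score each surviving feature (population
#' standard deviation). The returned statistics allow a new patient's
#' features to be transformed identically via [apply_normalization()].
#'
#' Imputation uses the full surviving dataset once, not per
#' cross-validation fold; the small optimistic bias this induces in
#' downstream validation scores is a deliberate, documented property of
#' the preprocessing pipeline.
#'
#' @param cohort An `aaa_cohort`.
#' @param feature_missing_threshold,patient_missing_threshold Fractions in
#'   (0, 1); defaults 0.30.
#' @return List with elements `cohort` (the transformed `aaa_cohort`) and
#'   `stats` (an `aaa_norm_stats` object recording per-feature median,
#'   mean and scale, plus dropped features/records).
#' @export
preprocess_cohort <- function(cohort,
                              feature_missing_threshold = 0.30,
                              patient_missing_threshold = 0.30) {
  stopifnot(feature_missing_threshold > 0, feature_missing_threshold < 1,
            patient_missing_threshold > 0, patient_missing_threshold < 1)
  X <- as.matrix(cohort$features)
  n <- nrow(X)

  frac_missing_feat <- colMeans(is.na(X))
  keep_feat <- frac_missing_feat <= feature_missing_threshold
  dropped_features <- colnames(X)[!keep_feat]
  X <- X[, keep_feat, drop = FALSE]
  if (ncol(X) == 0L) stop("all features dropped by missingness filter",
                          call. = FALSE)

  frac_missing_rec <- rowMeans(is.na(X))
  keep_rec <- frac_missing_rec <= patient_missing_threshold
  if (!any(keep_rec)) stop("all records dropped by missingness filter",
                           call. = FALSE)
  dropped_records <- which(!keep_rec)
  X <- X[keep_rec, , drop = FALSE]

  medians <- apply(X, 2L, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- medians[j]
  }

  means <- colMeans(X)
  scales <- sqrt(colMeans(sweep(X, 2L, means)^2))  # population sd
  if (any(scales == 0)) {
    # constant column: leave it centred but unscaled
    scales[scales == 0] <- 1
  }
  Z <- sweep(sweep(X, 2L, means), 2L, scales, `/`)

  out <- aaa_cohort(cohort$patient_id[keep_rec],
                    as.data.frame(Z),
                    cohort$properties[keep_rec, , drop = FALSE])
  stats <- structure(
    list(feature_names = colnames(Z),
         median = medians, mean = means, scale = scales,
         dropped_features = dropped_features,
         dropped_records = dropped_records),
    class = "aaa_norm_stats")
  list(cohort = out, stats = stats)
}

#' @export
print.aaa_norm_stats <- function(x, ...) {
  cat("Normalization statistics for", length(x$feature_names), "features\n")
  print(data.frame(median = x$median, mean = x$mean, scale = x$scale))
  if (length(x$dropped_features)) {
    cat("dropped features:", paste(x$dropped_features, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Transform new feature rows with stored normalization statistics
#'
#' @param stats An `aaa_norm_stats` from [preprocess_cohort()].
#' @param features Data frame (or single named numeric vector) of raw
#'   feature values; missing cells are imputed with the stored medians.
#' @return Numeric matrix of normalized features, columns in training order.
#' @export
apply_normalization <- function(stats, features) {
  if (is.null(dim(features))) features <- as.data.frame(as.list(features))
  miss <- setdiff(stats$feature_names, names(features))
  if (length(miss)) {
    stop(sprintf("missing feature columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  X <- as.matrix(features[stats$feature_names])
  for (j in seq_len(ncol(X))) {
    X[is.na(X[, j]), j] <- stats$median[j]
  }
  sweep(sweep(X, 2L, stats$mean), 2L, stats$scale, `/`)
}

#' Serialize / deserialize normalization statistics as JSON
#'
#' @param stats An `aaa_norm_stats`.
#' @param path File path.
#' @return `read_norm_stats` returns an `aaa_norm_stats`.
#' @export
write_norm_stats <- function(stats, path) {
  obj <- lapply(seq_along(stats$feature_names), function(j) {
    list(median = stats$median[[j]], mean = stats$mean[[j]],
         scale = stats$scale[[j]])
  })
  names(obj) <- stats$feature_names
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_norm_stats
#' @export
read_norm_stats <- function(path) {
  obj <- jsonlite::read_json(path)
  nm <- names(obj)
  structure(
    list(feature_names = nm,
         median = stats::setNames(vapply(obj, function(e) e$median, 0), nm),
         mean = stats::setNames(vapply(obj, function(e) e$mean, 0), nm),
         scale = stats::setNames(vapply(obj, function(e) e$scale, 0), nm),
         dropped_features = character(), dropped_records = integer()),
    class = "aaa_norm_stats")
}
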