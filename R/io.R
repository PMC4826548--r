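# Sniff the delimiter from the header line: tab wins if present, else comma.
sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) stop("empty file: ", path)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a log2 expression matrix from delimited text
#'
#' Reads a TSV/CSV with one header row and one id column and returns a
#' numeric matrix oriented samples x features regardless of the on-disk
#' orientation. When `known_samples` is supplied, orientation is detected by
#' id overlap with the annotation; `orientation` overrides detection.
#'
#' @param path file path.
#' @param orientation one of `"auto"`, `"samples_in_rows"`,
#'   `"features_in_rows"`.
#' @param known_samples optional character vector of sample ids (e.g. from the
#'   sample annotation table) used for auto-detection.
#' @return numeric matrix, samples in rows, features in columns.
#' @export
read_expression <- function(path,
                            orientation = c("auto", "samples_in_rows",
                                            "features_in_rows"),
                            known_samples = NULL) {
  orientation <- match.arg(orientation)
  sep <- sniff_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"")
  if (nrow(raw) == 0 || ncol(raw) < 2)
    stop("expression file must have one id column and at least one data column: ", path)
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicate row ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cols <- colnames(raw)[-1]
  if (anyDuplicated(cols))
    stop("duplicate column ids in ", path, ": ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-numeric cell in %s at row '%s' (line %d), column '%s': '%s'",
      path, ids[bad[1]], bad[1] + 1L, cols[bad[2]], mat[bad[1], bad[2]]))
  }
  dimnames(num) <- list(ids, cols)

  flip <- switch(orientation,
    samples_in_rows = FALSE,
    features_in_rows = TRUE,
    auto = {
      if (!is.null(known_samples)) {
        in_rows <- length(intersect(ids, known_samples))
        in_cols <- length(intersect(cols, known_samples))
        in_cols > in_rows
      } else FALSE  # conventional orientation assumed
    })
  if (flip) num <- t(num)
  assert_expr(num)
  num
}

#' Write an expression matrix as TSV (samples in rows)
#'
#' @param expr numeric matrix, samples x features.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  assert_expr(expr)
  df <- data.frame(sample_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the sample annotation table
#'
#' Expects columns `sample_id`, `patient_id`, `batch`.
#'
#' @param path file path (TSV or CSV; delimiter sniffed).
#' @return data.frame.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.table(path, sep = sniff_sep(path), header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "patient_id", "batch")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("sample table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in sample table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df
}

#' Read the patient clinical table
#'
#' Expects columns `patient_id`, `recurrence`, `time_months` (or `time_days`
#' with `time_unit = "days"`), `event`, and optionally `milan`,
#' `vascular_invasion`, `focality`, `n_tumors`. Times given in days are
#' converted to months by dividing by 30.44.
#'
#' @param path file path.
#' @param time_unit `"months"` (default) or `"days"`.
#' @return data.frame with times in months.
#' @export
read_patient_table <- function(path, time_unit = c("months", "days")) {
  time_unit <- match.arg(time_unit)
  df <- utils::read.table(path, sep = sniff_sep(path), header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"patient_id" %in% colnames(df)) stop("patient table missing 'patient_id'")
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient ids in patient table")
  if (time_unit == "days") {
    tcol <- if ("time_days" %in% colnames(df)) "time_days" else "time_months"
    df$time_months <- df[[tcol]] / 30.44
    df[[setdiff(tcol, "time_months")]] <- NULL
  }
  need <- c("recurrence", "time_months", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("patient table missing columns: ",
                         paste(miss, collapse = ", "))
  for (col in c("recurrence", "event", "vascular_invasion"))
    if (col %in% colnames(df)) df[[col]] <- as.logical(df[[col]])
  if (any(df$event & !df$recurrence))
    stop("patient table inconsistent: event = TRUE requires recurrence = TRUE")
  if (any(df$time_months < 0)) stop("negative survival times in patient table")
  if (all(c("focality", "n_tumors") %in% colnames(df))) {
    bad <- (df$n_tumors > 1) != (df$focality == "MULTIFOCAL")
    if (any(bad))
      stop("focality must be MULTIFOCAL exactly when n_tumors > 1; offending patients: ",
           paste(df$patient_id[bad], collapse = ", "))
  }
  df
}

#' Join and validate expression, sample and patient tables
#'
#' Every expression sample must have an annotation row whose patient has a
#' clinical row; violations are errors listing the offending ids. Patients
#' present only in the clinical table are retained (with a warning) for
#' survival-only analyses.
#'
#' @param expr expression matrix (samples x features).
#' @param samples sample annotation data.frame.
#' @param patients patient clinical data.frame.
#' @return object of class `mir_cohort`: list with `expr`, `samples`,
#'   `patients`, `patient_samples` (named list of sample ids per patient with
#'   expression data) and `dropped` (counts of unmatched records).
#' @export
join_cohort <- function(expr, samples, patients) {
  assert_expr(expr)
  orphan <- setdiff(rownames(expr), samples$sample_id)
  if (length(orphan))
    stop("expression samples with no annotation row: ",
         paste(orphan, collapse = ", "))
  ann <- samples[match(rownames(expr), samples$sample_id), , drop = FALSE]
  no_clin <- setdiff(ann$patient_id, patients$patient_id)
  if (length(no_clin))
    stop("annotated samples whose patient has no clinical row: ",
         paste(no_clin, collapse = ", "))
  extra_ann <- setdiff(samples$sample_id, rownames(expr))
  surv_only <- setdiff(patients$patient_id, ann$patient_id)
  if (length(surv_only))
    warning("patients with no expression samples (retained for survival-only analyses): ",
            paste(surv_only, collapse = ", "))
  structure(list(
    expr = expr,
    samples = ann,
    patients = patients,
    patient_samples = split(ann$sample_id, ann$patient_id),
    dropped = list(annotation_without_expression = length(extra_ann),
                   patients_without_expression = length(surv_only))
  ), class = "mir_cohort")
}

#' @export
print.mir_cohort <- function(x, ...) {
  cat(sprintf("mir_cohort: %d samples x %d features, %d patients (%d expression-free)\n",
              nrow(x$expr), ncol(x$expr), nrow(x$patients),
              x$dropped$patients_without_expression))
  invisible(x)
}
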