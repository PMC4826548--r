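#' Group patients by the clusters their samples occupy
#'
#' The central heterogeneity construct: a patient is `C1_ONLY` if every
#' clustered sample lies in cluster 1, `C2_ONLY` if every sample lies in
#' cluster 2, and `MIXED` if it has at least one sample in each cluster.
#'
#' @param assignment named integer vector in {1, 2}, sample id -> cluster
#'   (e.g. `model$assignment` from [orient_clusters()]).
#' @param sample_to_patient named character vector, sample id -> patient id.
#' @return object of class `patient_groups`: data.frame with `patient_id`,
#'   `group` plus attributes `group_counts` (patients per group) and
#'   `sample_counts` (samples per group).
#' @export
group_patients <- function(assignment, sample_to_patient) {
  if (is.null(names(assignment))) stop("'assignment' must be named by sample id")
  if (!all(assignment %in% 1:2)) stop("cluster assignment must be 1 or 2")
  ids <- names(assignment)
  pat <- as.character(lookup(sample_to_patient, ids, "patient mapping"))
  grp <- tapply(assignment, pat, function(cl) {
    if (all(cl == 1L)) "C1_ONLY" else if (all(cl == 2L)) "C2_ONLY" else "MIXED"
  })
  unclustered <- setdiff(unique(sample_to_patient), pat)
  if (length(unclustered))
    warning("patients with no clustered samples excluded from grouping: ",
            paste(unclustered, collapse = ", "))
  out <- data.frame(patient_id = names(grp),
                    group = factor(as.character(grp),
                                   levels = c("C1_ONLY", "C2_ONLY", "MIXED")),
                    stringsAsFactors = FALSE)
  out <- out[order(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "group_counts") <- table(out$group)
  attr(out, "sample_counts") <- table(
    factor(as.character(grp)[match(pat, names(grp))],
           levels = c("C1_ONLY", "C2_ONLY", "MIXED")))
  class(out) <- c("patient_groups", "data.frame")
  out
}

#' Build the patient-disjoint training set
#'
#' Training classes tie the sample clusters to patient outcomes: POOR
#' training samples sit in cluster 1 and come from recurrent patients, GOOD
#' training samples sit in cluster 2 and come from non-recurrent patients.
#' With `restrict_to_pure = TRUE` (default) only pure patients contribute —
#' POOR = samples of recurrent `C1_ONLY` patients, GOOD = samples of
#' non-recurrent `C2_ONLY` patients — which guarantees by construction that
#' no patient has samples in both the training and the test set. With
#' `restrict_to_pure = FALSE` the per-sample rule is applied literally (all
#' recurrent-patient samples in cluster 1, all non-recurrent-patient samples
#' in cluster 2) and patient-disjointness is verified afterwards; violations
#' are an error unless `allow_leakage = TRUE`.
#'
#' @param groups a `patient_groups` object from [group_patients()].
#' @param assignment named cluster assignment (sample id -> 1/2).
#' @param sample_to_patient named character vector, sample id -> patient id.
#' @param recurrence named logical vector per patient.
#' @param restrict_to_pure restrict training to pure-group patients (default).
#' @param allow_leakage keep a leaking split instead of erroring
#'   (only meaningful with `restrict_to_pure = FALSE`).
#' @return object of class `mir_training`: list with `train` (data.frame:
#'   sample_id, patient_id, class in {POOR, GOOD}), `test_ids`, and
#'   `violations` (patients spanning both sets; empty unless leakage allowed).
#' @export
build_training_labels <- function(groups, assignment, sample_to_patient,
                                  recurrence, restrict_to_pure = TRUE,
                                  allow_leakage = FALSE) {
  ids <- names(assignment)
  pat <- as.character(lookup(sample_to_patient, ids, "patient mapping"))
  rec <- as.logical(lookup(recurrence, pat, "recurrence status"))
  grp <- groups$group[match(pat, groups$patient_id)]

  if (restrict_to_pure) {
    poor <- rec & grp == "C1_ONLY"
    good <- !rec & grp == "C2_ONLY"
  } else {
    poor <- rec & assignment == 1L
    good <- !rec & assignment == 2L
  }
  cls <- ifelse(poor, "POOR", ifelse(good, "GOOD", NA))
  train <- data.frame(sample_id = ids[!is.na(cls)],
                      patient_id = pat[!is.na(cls)],
                      class = cls[!is.na(cls)],
                      stringsAsFactors = FALSE)
  test_ids <- ids[is.na(cls)]
  out <- structure(list(train = train, test_ids = test_ids,
                        violations = character(0),
                        restrict_to_pure = restrict_to_pure),
                   class = "mir_training")
  chk <- verify_patient_disjoint(out, sample_to_patient)
  if (!chk$ok) {
    out$violations <- chk$violators
    if (!allow_leakage)
      stop("patients with samples in both training and test sets: ",
           paste(chk$violators, collapse = ", "),
           " (use allow_leakage = TRUE to keep this split)")
  }
  out
}

#' Verify the train/test split is patient-disjoint
#'
#' @param training a `mir_training` object (or any list with `train$sample_id`
#'   plus `train$patient_id` and `test_ids`).
#' @param sample_to_patient named character vector, sample id -> patient id.
#' @return list with `ok` (logical) and `violators` (patient ids in both sets).
#' @export
verify_patient_disjoint <- function(training, sample_to_patient) {
  train_pat <- unique(as.character(
    lookup(sample_to_patient, training$train$sample_id, "patient mapping")))
  if (length(training$test_ids) == 0) {
    warning("empty test set: disjointness holds vacuously")
    return(list(ok = TRUE, violators = character(0)))
  }
  test_pat <- unique(as.character(
    lookup(sample_to_patient, training$test_ids, "patient mapping")))
  violators <- sort(intersect(train_pat, test_pat))
  list(ok = length(violators) == 0, violators = violators)
}

#' @export
print.mir_training <- function(x, ...) {
  cat(sprintf(
    "mir_training: %d POOR + %d GOOD training samples, %d test samples (%s)\n",
    sum(x$train$class == "POOR"), sum(x$train$class == "GOOD"),
    length(x$test_ids),
    if (x$restrict_to_pure) "pure-patient rule" else "literal per-sample rule"))
  invisible(x)
}
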