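#' Patient-level min/max summarization
#'
#' The comparison method: for each patient and each feature in the chosen
#' subset, record the minimum and the maximum expression across the
#' patient's samples. Single-sample patients have min = max; the result is
#' invariant to sample order and commutes with adding a constant to all
#' expression values.
#'
#' @param expr numeric matrix, samples x features.
#' @param sample_to_patient named character vector, sample id -> patient id.
#' @param features feature ids to summarize (non-empty).
#' @return numeric matrix, patients x (2 * length(features)); columns named
#'   `<feature>.min` / `<feature>.max`.
#' @export
summarize_minmax <- function(expr, sample_to_patient, features) {
  assert_expr(expr)
  if (length(features) == 0) stop("empty feature subset")
  miss <- setdiff(features, colnames(expr))
  if (length(miss)) stop("features absent from expression matrix: ",
                         paste(miss, collapse = ", "))
  pat <- as.character(lookup(sample_to_patient, rownames(expr),
                             "patient mapping"))
  ids <- sort(unique(pat))
  x <- expr[, features, drop = FALSE]
  mins <- apply(x, 2, function(col) tapply(col, pat, min)[ids])
  maxs <- apply(x, 2, function(col) tapply(col, pat, max)[ids])
  if (length(ids) == 1) {  # apply() drops to vectors for one patient
    mins <- matrix(mins, nrow = 1, dimnames = list(ids, features))
    maxs <- matrix(maxs, nrow = 1, dimnames = list(ids, features))
  }
  out <- cbind(mins, maxs)
  colnames(out) <- c(paste0(features, ".min"), paste0(features, ".max"))
  out[, as.vector(rbind(paste0(features, ".min"), paste0(features, ".max"))),
      drop = FALSE]
}

#' Run the min/max comparison analysis
#'
#' Clusters patients (k = 2, same machinery as the sample-level pipeline) on
#' their min/max profiles, orients so cluster 1 is recurrence-enriched, and
#' evaluates the two patient clusters by Kaplan-Meier, log-rank and a Cox
#' model of cluster-1 versus cluster-2 membership.
#'
#' @param minmax matrix from [summarize_minmax()].
#' @param patients patient clinical data.frame (`patient_id`, `recurrence`,
#'   `time_months`, `event`).
#' @param seed integer seed for the k-means restarts.
#' @param n_init number of k-means restarts.
#' @return list of class `minmax_result`: `cluster` (named 1/2 per patient),
#'   `km` (list of `km_curve` per cluster), `logrank` (`logrank_result`),
#'   `cox` (`cox_result` for cluster 1 vs 2).
#' @export
run_minmax_analysis <- function(minmax, patients, seed = 1L, n_init = 25) {
  fit <- fit_two_means(minmax, n_init = n_init, seed = seed)
  # patients play the role of samples: identity sample->patient map
  idmap <- stats::setNames(rownames(minmax), rownames(minmax))
  rec <- stats::setNames(patients$recurrence, patients$patient_id)
  model <- orient_clusters(fit, minmax, idmap, rec)
  cl <- model$assignment

  idx <- match(names(cl), patients$patient_id)
  tm <- patients$time_months[idx]
  ev <- patients$event[idx]
  km <- lapply(split(seq_along(cl), cl),
               function(i) km_estimate(tm[i], ev[i]))
  lr <- if (length(unique(cl)) > 1) logrank_test(tm, ev, cl) else NULL
  cox <- if (length(unique(cl)) > 1) {
    cox_fit(tm, ev, cbind(cluster1 = as.numeric(cl == 1L)))
  } else NULL
  structure(list(cluster = cl, km = km, logrank = lr, cox = cox,
                 model = model),
            class = "minmax_result")
}
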