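#' Two-group k-means clustering of samples
#'
#' Lloyd's algorithm with k = 2 on unscaled log2 expression, Euclidean
#' distance, best of `n_init` random restarts by total within-cluster sum of
#' squares. Initial centers are drawn as two distinct data rows per restart;
#' the full set of restart objectives is kept so the selection can be audited.
#'
#' @param expr numeric matrix, samples x features.
#' @param n_init number of random restarts.
#' @param seed integer seed making the restarts reproducible.
#' @return object of class `mir_kmeans`: `centers` (2 x features), `cluster`
#'   (named integer vector in {1, 2}, raw/unoriented labels), `tot_withinss`,
#'   `all_withinss` (objective of every restart), `degenerate` flag.
#' @export
fit_two_means <- function(expr, n_init = 25, seed = 1L) {
  assert_expr(expr)
  n <- nrow(expr)
  if (n < 2) stop("need at least 2 samples to fit 2 clusters")
  set.seed(seed)

  if (all(expr == rep(expr[1, ], each = n))) {
    warning("all samples identical: degenerate clustering (both centers equal)")
    centers <- expr[c(1, 1), , drop = FALSE]
    rownames(centers) <- c("1", "2")
    return(structure(list(
      centers = centers,
      cluster = stats::setNames(rep(1L, n), rownames(expr)),
      tot_withinss = 0, all_withinss = 0, degenerate = TRUE
    ), class = "mir_kmeans"))
  }

  best <- NULL
  all_wss <- numeric(0)
  for (r in seq_len(n_init)) {
    # draw two distinct rows as initial centers (guards duplicated samples)
    init <- NULL
    for (try in 1:100) {
      idx <- sample.int(n, 2)
      if (any(expr[idx[1], ] != expr[idx[2], ])) {
        init <- expr[idx, , drop = FALSE]
        break
      }
    }
    if (is.null(init)) next
    km <- stats::kmeans(expr, centers = init, algorithm = "Lloyd",
                        iter.max = 100)
    all_wss <- c(all_wss, km$tot.withinss)
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  structure(list(
    centers = best$centers,
    cluster = stats::setNames(as.integer(best$cluster), rownames(expr)),
    tot_withinss = best$tot.withinss,
    all_withinss = all_wss,
    degenerate = FALSE
  ), class = "mir_kmeans")
}

# Euclidean distance from every row of x to a single center vector.
row_dist <- function(x, center) {
  sqrt(rowSums(sweep(x, 2, center, "-")^2))
}

#' Orient a raw 2-cluster fit so cluster 1 is recurrence-enriched
#'
#' The cluster holding the higher fraction of samples from recurrent patients
#' is named cluster 1 (tie: the smaller cluster). Per-sample distances to the
#' oriented centers (`d1`, `d2`), the difference `M = d2 - d1` and the
#' average `A = (d1 + d2) / 2` are computed after orientation, and each
#' sample is assigned to its nearer center, ties going to cluster 1
#' (`assignment == 1` exactly when `M >= 0`).
#'
#' @param fit a `mir_kmeans` object from [fit_two_means()].
#' @param expr the expression matrix the fit was computed on.
#' @param sample_to_patient named character vector mapping sample id to
#'   patient id.
#' @param recurrence named logical vector per patient.
#' @return object of class `mir_cluster_model` with `centers` (rows `"1"`,
#'   `"2"`), `assignment`, `d1`, `d2`, `M`, `A` (all named by sample) and
#'   `orientation_meta` (the rule applied and the recurrent fractions).
#' @export
orient_clusters <- function(fit, expr, sample_to_patient, recurrence) {
  if (!inherits(fit, "mir_kmeans")) stop("'fit' must come from fit_two_means()")
  assert_expr(expr)
  ids <- names(fit$cluster)
  if (!identical(sort(ids), sort(rownames(expr))))
    stop("'expr' must hold exactly the samples the model was fitted on")
  expr <- expr[ids, , drop = FALSE]
  pat <- as.character(lookup(sample_to_patient, ids, "patient mapping"))
  rec <- as.logical(lookup(recurrence, pat, "recurrence status"))
  if (anyNA(rec)) stop("recurrence status missing (NA) for some patients")

  if (fit$degenerate) {
    frac <- c(NA_real_, NA_real_)
    cluster1 <- 1L
    rule <- "degenerate fit: orientation arbitrary"
  } else {
    frac <- vapply(1:2, function(k) {
      ink <- fit$cluster == k
      if (!any(ink)) 0 else mean(rec[ink])
    }, numeric(1))
    sizes <- tabulate(fit$cluster, 2)
    if (frac[1] != frac[2]) {
      cluster1 <- which.max(frac)
      rule <- "higher recurrent-sample fraction"
    } else {
      cluster1 <- which.min(sizes)
      rule <- "tie on recurrent fraction: smaller cluster"
    }
  }
  ord <- if (cluster1 == 1L) c(1L, 2L) else c(2L, 1L)
  centers <- fit$centers[ord, , drop = FALSE]
  rownames(centers) <- c("1", "2")

  d1 <- row_dist(expr, centers[1, ])
  d2 <- row_dist(expr, centers[2, ])
  M <- d2 - d1
  A <- (d1 + d2) / 2
  assignment <- stats::setNames(ifelse(M >= 0, 1L, 2L), ids)

  structure(list(
    centers = centers,
    assignment = assignment,
    d1 = stats::setNames(d1, ids),
    d2 = stats::setNames(d2, ids),
    M = stats::setNames(M, ids),
    A = stats::setNames(A, ids),
    orientation_meta = list(rule = rule, recurrent_fraction = frac,
                            raw_cluster1 = cluster1),
    degenerate = fit$degenerate
  ), class = "mir_cluster_model")
}

#' @export
print.mir_cluster_model <- function(x, ...) {
  cat(sprintf("mir_cluster_model: %d samples (cluster 1: %d, cluster 2: %d); %s\n",
              length(x$assignment), sum(x$assignment == 1L),
              sum(x$assignment == 2L), x$orientation_meta$rule))
  invisible(x)
}

#' Per-sample M/A distance statistics
#'
#' Tabulates, for each sample, its cluster assignment, the distances to the
#' two oriented centers and the derived statistics `M = d2 - d1` (positive
#' for samples nearer the recurrence-enriched center) and
#' `A = (d1 + d2) / 2` (large for samples far from both centers), plus a
#' patient-level mark distinguishing samples of pure cluster-1 patients,
#' pure cluster-2 patients and mixed patients.
#'
#' @param model a `mir_cluster_model` from [orient_clusters()].
#' @param sample_to_patient named character vector, sample id -> patient id.
#' @return data.frame: sample_id, patient_id, cluster, d1, d2, M, A,
#'   patient_mark in {"all-cluster-1", "all-cluster-2", "mixed"}.
#' @export
ma_statistics <- function(model, sample_to_patient) {
  if (!inherits(model, "mir_cluster_model"))
    stop("'model' must come from orient_clusters()")
  ids <- names(model$assignment)
  pat <- as.character(lookup(sample_to_patient, ids, "patient mapping"))
  per_pat <- tapply(model$assignment, pat, function(cl) {
    if (all(cl == 1L)) "all-cluster-1"
    else if (all(cl == 2L)) "all-cluster-2"
    else "mixed"
  })
  data.frame(
    sample_id = ids,
    patient_id = pat,
    cluster = as.integer(model$assignment),
    d1 = as.numeric(model$d1),
    d2 = as.numeric(model$d2),
    M = as.numeric(model$M),
    A = as.numeric(model$A),
    patient_mark = as.character(per_pat[pat]),
    stringsAsFactors = FALSE
  )
}

#' Two-dimensional embedding for visualization
#'
#' PCA (deterministic, via [stats::prcomp()] on centered, unscaled values) or
#' a compact exact-gradient t-SNE (seeded). The embedding is for plots only
#' and is never used for inference.
#'
#' @param expr numeric matrix, samples x features.
#' @param method `"pca"` or `"tsne"`.
#' @param seed integer seed (t-SNE only).
#' @param perplexity t-SNE perplexity; capped at `(n - 1) / 3`.
#' @param max_iter t-SNE gradient iterations.
#' @return numeric matrix, samples x 2, rownames = sample ids.
#' @export
embed_2d <- function(expr, method = c("pca", "tsne"), seed = 1L,
                     perplexity = 30, max_iter = 300) {
  method <- match.arg(method)
  assert_expr(expr)
  if (nrow(expr) < 3) stop("need at least 3 samples to embed")
  coords <- switch(method,
    pca = {
      pc <- stats::prcomp(expr, center = TRUE, scale. = FALSE)
      sc <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
      if (ncol(sc) < 2) sc <- cbind(sc, 0)
      unname(sc)
    },
    tsne = tsne_exact(expr, seed = seed, perplexity = perplexity,
                      max_iter = max_iter)
  )
  dimnames(coords) <- list(rownames(expr), c("dim1", "dim2"))
  coords
}
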