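#' Fit per-feature quartile discretization breakpoints
#'
#' Estimates, for every feature, the breakpoints (min, Q1, Q2, Q3, max) from
#' the training samples only, using linear-interpolation empirical
#' percentiles. Features whose training values are constant collapse to a
#' single degenerate interval and are flagged; their mutual information is
#' defined as 0.
#'
#' @param expr_train numeric matrix restricted to training samples
#'   (samples x features), at least 4 rows.
#' @return object of class `mir_discretization`: `breaks` (features x 5
#'   matrix with columns min, q1, q2, q3, max) and `degenerate` (named
#'   logical per feature).
#' @export
fit_discretization <- function(expr_train) {
  assert_expr(expr_train)
  if (nrow(expr_train) < 4)
    stop("need at least 4 training samples to estimate quartiles")
  qs <- t(apply(expr_train, 2, stats::quantile,
                probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE))
  colnames(qs) <- c("min", "q1", "q2", "q3", "max")
  structure(list(
    breaks = qs,
    degenerate = stats::setNames(qs[, "min"] == qs[, "max"], rownames(qs))
  ), class = "mir_discretization")
}

#' Map expression values to quartile intervals
#'
#' Half-open convention: interval 1 = [min, Q1), 2 = [Q1, Q2), 3 = [Q2, Q3),
#' 4 = [Q3, +Inf). Values below the training minimum clamp to interval 1, so
#' test-time values always discretize. Degenerate (constant) features map
#' everything to interval 1.
#'
#' @param values numeric vector of expression values for one feature.
#' @param breaks length-5 vector (min, Q1, Q2, Q3, max) for that feature, or
#'   a row of `mir_discretization$breaks`.
#' @return integer vector of interval indices in 1..4.
#' @export
discretize <- function(values, breaks) {
  if (any(!is.finite(values))) stop("non-finite expression value in discretize()")
  if (breaks[1] == breaks[5]) return(rep(1L, length(values)))
  idx <- findInterval(values, breaks[2:4]) + 1L
  pmin.int(pmax.int(idx, 1L), 4L)
}

#' Discretize a whole expression matrix
#'
#' @param disc a `mir_discretization` object.
#' @param expr numeric matrix (samples x features); features must be present
#'   in the discretization model.
#' @return integer matrix of interval indices, same dimnames as `expr`.
#' @export
apply_discretization <- function(disc, expr) {
  assert_expr(expr)
  miss <- setdiff(colnames(expr), rownames(disc$breaks))
  if (length(miss)) stop("no breakpoints fitted for features: ",
                         paste(miss, collapse = ", "))
  out <- vapply(colnames(expr),
                function(f) discretize(expr[, f], disc$breaks[f, ]),
                integer(nrow(expr)))
  dimnames(out) <- dimnames(expr)
  out
}

#' Mutual information between a discretized feature and the class label
#'
#' Plug-in estimate from empirical joint frequencies,
#' computed as H(X) + H(Y) - H(X, Y); cells with zero joint probability
#' contribute nothing. Natural log by default.
#'
#' @param x discretized feature values (interval indices) over the training
#'   samples.
#' @param y class labels, same length.
#' @param unit `"nats"` (natural log, default) or `"bits"` (log base 2).
#' @return nonnegative mutual information.
#' @export
mutual_information <- function(x, y, unit = c("nats", "bits")) {
  unit <- match.arg(unit)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 2) stop("need at least 2 samples")
  if (length(unique(y)) < 2) {
    warning("single class present: mutual information is 0")
    return(0)
  }
  tab <- table(x, y)
  p <- tab / sum(tab)
  ent <- function(pr) {
    pr <- pr[pr > 0]
    -sum(pr * log(pr))
  }
  mi <- ent(rowSums(p)) + ent(colSums(p)) - ent(p)
  mi <- max(mi, 0)  # guard tiny negative rounding
  if (unit == "bits") mi / log(2) else mi
}

#' Mutual-information scores for every feature
#'
#' Discretizes the training expression with the fitted breakpoints and
#' scores each feature's association with the class labels. Degenerate
#' features score 0.
#'
#' @param expr_train numeric matrix, training samples x features.
#' @param labels character vector of class labels aligned with the rows of
#'   `expr_train` (or named by sample id).
#' @param disc optional `mir_discretization`; fitted from `expr_train` if
#'   missing.
#' @param unit `"nats"` or `"bits"`.
#' @return data.frame of class `mi_scores`: feature_id, mi, rank (1-based
#'   dense rank, 1 = largest), degenerate flag; sorted by rank with ties
#'   broken by feature id.
#' @export
mi_scores <- function(expr_train, labels, disc = NULL,
                      unit = c("nats", "bits")) {
  unit <- match.arg(unit)
  assert_expr(expr_train)
  if (!is.null(names(labels))) labels <- labels[rownames(expr_train)]
  if (length(labels) != nrow(expr_train))
    stop("'labels' must align with the rows of 'expr_train'")
  if (is.null(disc)) disc <- fit_discretization(expr_train)
  dx <- apply_discretization(disc, expr_train)
  single_class <- length(unique(labels)) < 2
  if (single_class)
    warning("single class present: all mutual-information scores are 0")
  mi <- vapply(colnames(dx), function(f) {
    if (disc$degenerate[f] || single_class) 0
    else mutual_information(dx[, f], labels, unit = unit)
  }, numeric(1))
  ord <- order(-mi, names(mi))
  out <- data.frame(feature_id = names(mi)[ord],
                    mi = unname(mi[ord]),
                    rank = match(-mi[ord], sort(unique(-mi))),
                    degenerate = unname(disc$degenerate[names(mi)[ord]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("mi_scores", "data.frame")
  out
}

#' Select top features by mutual information
#'
#' Descending sort with ties broken lexicographically by feature id. By
#' default the top `k` features are returned; with `gap_rule = TRUE` the cut
#' is placed instead before the largest consecutive drop in the sorted
#' scores.
#'
#' @param scores an `mi_scores` data.frame (or any data.frame with
#'   `feature_id` and `mi`).
#' @param k number of features (default 5); ignored when `gap_rule = TRUE`.
#' @param gap_rule select all features before the largest consecutive drop.
#' @return character vector of selected feature ids, in rank order.
#' @export
rank_and_select <- function(scores, k = 5, gap_rule = FALSE) {
  ord <- order(-scores$mi, scores$feature_id)
  sorted <- scores[ord, , drop = FALSE]
  if (gap_rule) {
    drops <- -diff(sorted$mi)
    k <- which.max(drops)
  } else {
    if (k > nrow(sorted))
      stop(sprintf("k = %d exceeds the number of features (%d)", k, nrow(sorted)))
  }
  sorted$feature_id[seq_len(k)]
}
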