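#' Fit the nearest-center biomarker model
#'
#' Class centers are the per-class mean expression vectors of the selected
#' features over the training samples only.
#'
#' @param expr numeric matrix, samples x features (must contain the training
#'   samples and selected features).
#' @param training a `mir_training` object from [build_training_labels()]
#'   (or a data.frame with `sample_id` and `class`).
#' @param features character vector of selected feature ids.
#' @return object of class `biomarker_model`: `features`, `center_poor`,
#'   `center_good`.
#' @export
fit_biomarker <- function(expr, training, features) {
  assert_expr(expr)
  train <- if (inherits(training, "mir_training")) training$train else training
  miss <- setdiff(features, colnames(expr))
  if (length(miss)) stop("selected features absent from expression matrix: ",
                         paste(miss, collapse = ", "))
  miss_s <- setdiff(train$sample_id, rownames(expr))
  if (length(miss_s)) stop("training samples absent from expression matrix: ",
                           paste(miss_s, collapse = ", "))
  poor_ids <- train$sample_id[train$class == "POOR"]
  good_ids <- train$sample_id[train$class == "GOOD"]
  if (length(poor_ids) == 0 || length(good_ids) == 0)
    stop("both classes need at least one training sample (got ",
         length(poor_ids), " POOR, ", length(good_ids), " GOOD)")
  structure(list(
    features = features,
    center_poor = colMeans(expr[poor_ids, features, drop = FALSE]),
    center_good = colMeans(expr[good_ids, features, drop = FALSE])
  ), class = "biomarker_model")
}

#' Assign prognosis to samples by nearest class center
#'
#' Euclidean distance over the selected features; ties go to POOR (the
#' conservative call for a recurrence biomarker).
#'
#' @param model a `biomarker_model`.
#' @param expr numeric matrix (samples x features) holding at least the
#'   model's features; rows are the samples to classify.
#' @return named character vector, `"POOR"`/`"GOOD"` per sample.
#' @export
assign_samples <- function(model, expr) {
  assert_expr(expr)
  miss <- setdiff(model$features, colnames(expr))
  if (length(miss)) stop("missing feature values for: ",
                         paste(miss, collapse = ", "))
  x <- expr[, model$features, drop = FALSE]
  d_poor <- row_dist(x, model$center_poor)
  d_good <- row_dist(x, model$center_good)
  stats::setNames(ifelse(d_poor <= d_good, "POOR", "GOOD"), rownames(expr))
}

#' Patient-level prognosis from per-sample calls
#'
#' A patient is POOR if all samples are POOR, GOOD if all are GOOD, and
#' MIXED otherwise; the result is invariant to sample order.
#'
#' @param sample_calls named character vector (`"POOR"`/`"GOOD"`) per sample.
#' @param sample_to_patient named character vector, sample id -> patient id.
#' @return named character vector per patient: `"POOR"`, `"MIXED"` or `"GOOD"`.
#' @export
classify_patients <- function(sample_calls, sample_to_patient) {
  if (length(sample_calls) == 0) stop("no sample calls supplied")
  if (!all(sample_calls %in% c("POOR", "GOOD")))
    stop("sample calls must be 'POOR' or 'GOOD'")
  pat <- as.character(lookup(sample_to_patient, names(sample_calls),
                             "patient mapping"))
  res <- tapply(sample_calls, pat, function(cl) {
    if (all(cl == "POOR")) "POOR" else if (all(cl == "GOOD")) "GOOD" else "MIXED"
  })
  stats::setNames(as.character(res), names(res))
}

#' Fit the two reference classifiers
#'
#' Gaussian naive Bayes and a radial-kernel support-vector machine with
#' cost 1000 (kernel width gamma defaults to 1/n_features), both from
#' \pkg{e1071}, fitted on the training samples restricted to the selected
#' features. Zero-variance features under naive Bayes have their class
#' standard deviation floored at 1e-9 with a warning.
#'
#' @param expr numeric matrix, samples x features.
#' @param training a `mir_training` object (or data.frame with `sample_id`,
#'   `class`).
#' @param features selected feature ids.
#' @param cost SVM cost parameter.
#' @param gamma SVM radial kernel width; default `1/length(features)`.
#' @return object of class `reference_classifiers` with elements `nb`, `svm`
#'   and `features`; use [predict_reference()] to classify new samples.
#' @export
fit_reference_classifiers <- function(expr, training, features,
                                      cost = 1000, gamma = NULL) {
  assert_expr(expr)
  train <- if (inherits(training, "mir_training")) training$train else training
  if (length(unique(train$class)) < 2)
    stop("both classes must be present in the training data")
  x <- expr[train$sample_id, features, drop = FALSE]
  y <- factor(train$class, levels = c("POOR", "GOOD"))
  if (is.null(gamma)) gamma <- 1 / length(features)

  nb <- e1071::naiveBayes(x, y)
  sds <- vapply(nb$tables, function(tb) tb[, 2], numeric(2))
  if (any(sds < 1e-9)) {
    warning("zero-variance feature(s) under naive Bayes: standard deviation floored at 1e-9")
    nb$tables <- lapply(nb$tables, function(tb) {
      tb[, 2] <- pmax(tb[, 2], 1e-9)
      tb
    })
  }
  # scale only non-constant columns (avoids the degenerate-scaling warning)
  scale_cols <- apply(x, 2, function(v) stats::sd(v) > 0)
  svm <- e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
                    scale = scale_cols)
  structure(list(nb = nb, svm = svm, features = features),
            class = "reference_classifiers")
}

#' Predict with the reference classifiers
#'
#' @param models a `reference_classifiers` object.
#' @param expr numeric matrix of samples to classify.
#' @param which `"nb"` or `"svm"`.
#' @return named character vector of `"POOR"`/`"GOOD"` calls.
#' @export
predict_reference <- function(models, expr, which = c("nb", "svm")) {
  which <- match.arg(which)
  x <- expr[, models$features, drop = FALSE]
  pred <- if (which == "nb") {
    predict(models$nb, x)
  } else {
    predict(models$svm, x)
  }
  stats::setNames(as.character(pred), rownames(expr))
}
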