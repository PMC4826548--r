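make_training <- function(expr, classes) {
  structure(list(
    train = data.frame(sample_id = rownames(expr), patient_id = rownames(expr),
                       class = classes, stringsAsFactors = FALSE),
    test_ids = character(0), restrict_to_pure = TRUE),
    class = "mir_training")
}

test_that("class centers are per-class training means", {
  expr <- rbind(p1 = c(1, 2), g1 = c(5, 6), g2 = c(7, 8))
  colnames(expr) <- c("f1", "f2")
  tr <- make_training(expr, c("POOR", "GOOD", "GOOD"))
  bm <- fit_biomarker(expr, tr, c("f1", "f2"))
  expect_equal(unname(bm$center_poor), c(1, 2))   # singleton mean
  expect_equal(unname(bm$center_good), c(6, 7))
  # duplicated training set: identical centers
  expr2 <- rbind(expr, expr)
  rownames(expr2) <- c(rownames(expr), paste0(rownames(expr), "b"))
  tr2 <- make_training(expr2, rep(c("POOR", "GOOD", "GOOD"), 2))
  bm2 <- fit_biomarker(expr2, tr2, c("f1", "f2"))
  expect_equal(bm2$center_poor, bm$center_poor)
  expect_equal(bm2$center_good, bm$center_good)
  # empty class errors
  expect_error(fit_biomarker(expr, make_training(expr, rep("GOOD", 3)),
                             c("f1", "f2")), "class")
})

test_that("planted markers sit lower in the poor center", {
  sim <- simulate_cohort(sim_config(n_patients = 60, n_features = 30,
                                    marker_effect = 2, noise_sd = 1, seed = 5))
  st <- sim$truth$sample_state[rownames(sim$expr)]
  tr <- make_training(sim$expr, ifelse(st == "POOR", "POOR", "GOOD"))
  bm <- fit_biomarker(sim$expr, tr, sim$truth$marker_ids)
  expect_true(all(bm$center_poor < bm$center_good))
})

test_that("samples go to the nearest center with ties to POOR", {
  bm <- structure(list(features = c("f1", "f2"),
                       center_poor = c(f1 = 0, f2 = 0),
                       center_good = c(f1 = 4, f2 = 0)),
                  class = "biomarker_model")
  x <- rbind(at_good = c(4, 0), midway = c(2, 1), near_poor = c(0.5, 0))
  colnames(x) <- c("f1", "f2")
  calls <- assign_samples(bm, x)
  expect_equal(unname(calls["at_good"]), "GOOD")
  expect_equal(unname(calls["midway"]), "POOR")   # equidistant -> POOR
  expect_equal(unname(calls["near_poor"]), "POOR")
  # missing feature is an error
  expect_error(assign_samples(bm, x[, "f1", drop = FALSE]), "f2")
})

test_that("assignment is invariant to adding a constant to centers and sample", {
  bm <- structure(list(features = c("f1", "f2"),
                       center_poor = c(f1 = 1, f2 = 2),
                       center_good = c(f1 = 5, f2 = 7)),
                  class = "biomarker_model")
  x <- matrix(c(2, 3), 1, 2, dimnames = list("s1", c("f1", "f2")))
  shift <- 11.5
  bm2 <- bm
  bm2$center_poor <- bm$center_poor + shift
  bm2$center_good <- bm$center_good + shift
  expect_identical(assign_samples(bm, x), assign_samples(bm2, x + shift))
})

test_that("patient calls are all/all/else-mixed and order-invariant", {
  s2p <- c(s1 = "pA", s2 = "pA", s3 = "pB", s4 = "pC", s5 = "pC", s6 = "pC")
  calls <- c(s1 = "POOR", s2 = "GOOD", s3 = "POOR",
             s4 = "GOOD", s5 = "GOOD", s6 = "GOOD")
  pc <- classify_patients(calls, s2p)
  expect_equal(unname(pc["pA"]), "MIXED")
  expect_equal(unname(pc["pB"]), "POOR")
  expect_equal(unname(pc["pC"]), "GOOD")
  perm <- c("s6", "s2", "s4", "s1", "s5", "s3")
  expect_identical(pc, classify_patients(calls[perm], s2p))
  expect_error(classify_patients(character(0), s2p), "no sample")
})

test_that("reference classifiers separate well-separated training data", {
  x <- make_blobs(n_per = 20, p = 5, sep = 10, sd = 1)
  tr <- make_training(x, rep(c("POOR", "GOOD"), each = 20))
  models <- fit_reference_classifiers(x, tr, colnames(x))
  nb_calls <- predict_reference(models, x, "nb")
  svm_calls <- predict_reference(models, x, "svm")
  truth <- stats::setNames(tr$train$class, tr$train$sample_id)
  expect_equal(mean(nb_calls == truth), 1)
  expect_equal(mean(svm_calls == truth), 1)
})

test_that("naive Bayes places the boundary at the midpoint for a symmetric problem", {
  # one feature, equal priors, equal class variances: boundary = mean midpoint
  x <- matrix(c(-3, -2, -1, 1, 2, 3), 6, 1,
              dimnames = list(paste0("s", 1:6), "f1"))
  tr <- make_training(x, rep(c("POOR", "GOOD"), each = 3))
  models <- fit_reference_classifiers(x, tr, "f1")
  eps <- 1e-3
  probe <- matrix(c(-eps, eps), 2, 1,
                  dimnames = list(c("below", "above"), "f1"))
  calls <- predict_reference(models, probe, "nb")
  expect_equal(unname(calls["below"]), "POOR")
  expect_equal(unname(calls["above"]), "GOOD")
})

test_that("zero-variance feature under naive Bayes is floored with a warning", {
  x <- cbind(f1 = c(rep(0, 5), rep(5, 5)), f2 = rep(1, 10))
  rownames(x) <- paste0("s", 1:10)
  tr <- make_training(x, rep(c("POOR", "GOOD"), each = 5))
  expect_warning(models <- fit_reference_classifiers(x, tr, c("f1", "f2")),
                 "floored")
  calls <- predict_reference(models, x, "nb")
  expect_equal(unname(calls), tr$train$class)
})

test_that("label-permuted training yields chance-level held-out accuracy", {
  set.seed(11)
  n <- 120
  x <- matrix(rnorm(2 * n * 4), 2 * n, 4,
              dimnames = list(sprintf("s%03d", 1:(2 * n)), paste0("f", 1:4)))
  y <- sample(rep(c("POOR", "GOOD"), each = n))
  tr <- make_training(x[1:n, ], y[1:n])
  models <- fit_reference_classifiers(x[1:n, ], tr, colnames(x))
  held <- predict_reference(models, x[(n + 1):(2 * n), ], "nb")
  acc <- mean(held == y[(n + 1):(2 * n)])
  maj <- max(mean(y[(n + 1):(2 * n)] == "POOR"),
             mean(y[(n + 1):(2 * n)] == "GOOD"))
  expect_lt(abs(acc - maj), 3 * sqrt(0.25 / n) + 0.1)
})

test_that("reference classifiers and nearest centers agree at high separation", {
  sim <- simulate_cohort(sim_config(n_patients = 50, n_features = 20,
                                    n_markers = 5, marker_effect = 6,
                                    noise_sd = 1, seed = 13))
  st <- sim$truth$sample_state[rownames(sim$expr)]
  tr <- make_training(sim$expr, ifelse(st == "POOR", "POOR", "GOOD"))
  feats <- sim$truth$marker_ids
  bm <- fit_biomarker(sim$expr, tr, feats)
  models <- fit_reference_classifiers(sim$expr, tr, feats)
  nc <- assign_samples(bm, sim$expr)
  nb <- predict_reference(models, sim$expr, "nb")
  sv <- predict_reference(models, sim$expr, "svm")
  expect_equal(mean(nc == nb), 1)
  expect_equal(mean(nc == sv), 1)
})
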