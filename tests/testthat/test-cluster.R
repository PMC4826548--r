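test_that("two planted blobs are recovered across seeds", {
  x <- make_blobs(n_per = 20, p = 10, sep = 10, sd = 1)
  truth <- rep(1:2, each = 20)
  for (s in 1:20) {
    fit <- fit_two_means(x, n_init = 5, seed = s)
    expect_equal(adjusted_rand_index(fit$cluster, truth), 1)
  }
})

test_that("identical samples give a degenerate fit with a warning", {
  x <- matrix(3, 5, 4, dimnames = list(paste0("s", 1:5), paste0("f", 1:4)))
  expect_warning(fit <- fit_two_means(x, seed = 1), "degenerate")
  expect_true(fit$degenerate)
  expect_equal(fit$centers[1, ], fit$centers[2, ])
})

test_that("duplicating every sample leaves the centroids unchanged", {
  x <- make_blobs(n_per = 10, p = 5, sep = 8)
  x2 <- rbind(x, x)
  rownames(x2) <- c(rownames(x), paste0(rownames(x), "_dup"))
  f1 <- fit_two_means(x, n_init = 5, seed = 1)
  f2 <- fit_two_means(x2, n_init = 5, seed = 1)
  # match centers up to label swap
  d_same <- sum((f1$centers - f2$centers)^2)
  d_swap <- sum((f1$centers - f2$centers[2:1, ])^2)
  expect_lt(min(d_same, d_swap), 1e-18)
})

test_that("returned fit has the best objective among its restarts", {
  x <- make_blobs(n_per = 15, p = 6, sep = 3, sd = 2)
  fit <- fit_two_means(x, n_init = 25, seed = 7)
  expect_true(all(fit$tot_withinss <= fit$all_withinss + 1e-9))
  expect_equal(fit$tot_withinss, min(fit$all_withinss))
})

test_that("orientation names the recurrence-enriched cluster as cluster 1", {
  x <- make_blobs(n_per = 20, p = 10, sep = 10, seed = 3)
  s2p <- stats::setNames(rownames(x), rownames(x))  # one sample per patient
  # blob 2 (rows 21..40) mostly recurrent
  rec <- stats::setNames(c(rep(FALSE, 18), rep(TRUE, 2),
                           rep(TRUE, 18), rep(FALSE, 2)), rownames(x))
  fit <- fit_two_means(x, n_init = 5, seed = 1)
  model <- orient_clusters(fit, x, s2p, rec)
  c1_samples <- names(model$assignment)[model$assignment == 1L]
  expect_setequal(c1_samples, rownames(x)[21:40])
  # M >= 0 exactly for cluster-1 samples, and |M| <= 2A everywhere
  expect_identical(model$assignment == 1L, model$M >= 0)
  expect_true(all(abs(model$M) <= 2 * model$A + 1e-12))
})

test_that("orientation tie-break picks the smaller cluster", {
  # 10 vs 30 samples, equal recurrent fractions (0.5 in both)
  set.seed(1)
  x <- rbind(matrix(rnorm(10 * 4), 10, 4), matrix(rnorm(30 * 4, 12), 30, 4))
  dimnames(x) <- list(paste0("s", 1:40), paste0("f", 1:4))
  s2p <- stats::setNames(rownames(x), rownames(x))
  rec <- stats::setNames(c(rep(c(TRUE, FALSE), 5), rep(c(TRUE, FALSE), 15)),
                         rownames(x))
  fit <- fit_two_means(x, n_init = 5, seed = 2)
  model <- orient_clusters(fit, x, s2p, rec)
  expect_equal(sum(model$assignment == 1L), 10)
  expect_match(model$orientation_meta$rule, "smaller")
})

test_that("a sample equidistant from both centers gets M = 0 and cluster 1", {
  centers <- rbind(c(0, 0), c(4, 0))
  x <- rbind(c(0.1, 0), c(3.9, 0), c(2, 3))  # third row equidistant
  dimnames(x) <- list(c("s1", "s2", "mid"), c("f1", "f2"))
  fit <- structure(list(centers = centers,
                        cluster = c(s1 = 1L, s2 = 2L, mid = 2L),
                        tot_withinss = 0, all_withinss = 0, degenerate = FALSE),
                   class = "mir_kmeans")
  s2p <- c(s1 = "p1", s2 = "p2", mid = "p3")
  rec <- c(p1 = TRUE, p2 = FALSE, p3 = FALSE)
  model <- orient_clusters(fit, x, s2p, rec)
  expect_equal(unname(model$M["mid"]), 0)
  expect_equal(unname(model$assignment["mid"]), 1L)
})

test_that("assignment equals brute-force nearest-center assignment", {
  sim <- simulate_cohort(sim_config(n_patients = 25, n_features = 12, seed = 4))
  d <- discover(sim, n_init = 10)
  brute <- apply(sim$expr[names(d$model$assignment), ], 1, function(row) {
    d1 <- sqrt(sum((row - d$model$centers[1, ])^2))
    d2 <- sqrt(sum((row - d$model$centers[2, ])^2))
    if (d1 <= d2) 1L else 2L
  })
  expect_identical(unname(d$model$assignment), unname(brute))
})

test_that("M and A follow their definitions exactly", {
  sim <- simulate_cohort(sim_config(n_patients = 15, n_features = 8, seed = 6))
  d <- discover(sim, n_init = 5)
  expect_equal(d$model$M, d$model$d2 - d$model$d1)
  expect_equal(d$model$A, (d$model$d1 + d$model$d2) / 2)
  ma <- ma_statistics(d$model, d$s2p)
  expect_equal(ma$M, unname(d$model$M[ma$sample_id]))
  # patient marks are consistent with the per-patient cluster sets
  for (p in unique(ma$patient_id)) {
    cl <- ma$cluster[ma$patient_id == p]
    mark <- unique(ma$patient_mark[ma$patient_id == p])
    expect_length(mark, 1)
    expected <- if (all(cl == 1)) "all-cluster-1"
      else if (all(cl == 2)) "all-cluster-2" else "mixed"
    expect_equal(mark, expected)
  }
})

test_that("PCA embedding handles rank deficiency and preserves 2-D geometry", {
  # rank-1 data: second coordinate ~ 0
  u <- seq(-2, 2, length.out = 10)
  x1 <- outer(u, c(1, 2, 3))
  dimnames(x1) <- list(paste0("s", 1:10), paste0("f", 1:3))
  e1 <- embed_2d(x1, method = "pca")
  expect_lt(max(abs(e1[, 2])), 1e-8)
  # 2-D input: pairwise distances reproduced up to rotation
  set.seed(2)
  x2 <- matrix(rnorm(40), 20, 2,
               dimnames = list(paste0("s", 1:20), c("f1", "f2")))
  e2 <- embed_2d(x2, method = "pca")
  expect_equal(as.vector(dist(e2)), as.vector(dist(x2)), tolerance = 1e-9)
})

test_that("t-SNE embedding is seed-deterministic", {
  x <- make_blobs(n_per = 10, p = 5, sep = 6)
  a <- embed_2d(x, method = "tsne", seed = 5, max_iter = 60)
  b <- embed_2d(x, method = "tsne", seed = 5, max_iter = 60)
  expect_identical(a, b)
  expect_equal(dim(a), c(20L, 2L))
})
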