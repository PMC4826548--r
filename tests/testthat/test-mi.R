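test_that("quartile breakpoints use linear-interpolation percentiles", {
  x <- matrix(1:8, 8, 1, dimnames = list(paste0("s", 1:8), "f1"))
  disc <- fit_discretization(x)
  expect_equal(unname(disc$breaks["f1", ]), c(1, 2.75, 4.5, 6.25, 8))
  expect_false(disc$degenerate[["f1"]])
  # monotone for arbitrary input
  set.seed(1)
  y <- matrix(rnorm(100), 20, 5,
              dimnames = list(paste0("s", 1:20), paste0("f", 1:5)))
  d2 <- fit_discretization(y)
  expect_true(all(apply(d2$breaks, 1, function(b) all(diff(b) >= 0))))
})

test_that("constant features are flagged degenerate and score 0", {
  x <- cbind(f1 = rep(2, 8), f2 = 1:8)
  rownames(x) <- paste0("s", 1:8)
  disc <- fit_discretization(x)
  expect_true(disc$degenerate[["f1"]])
  labs <- rep(c("POOR", "GOOD"), 4)
  sc <- mi_scores(x, labs, disc = disc)
  expect_equal(sc$mi[sc$feature_id == "f1"], 0)
})

test_that("discretization follows the half-open interval convention", {
  b <- c(0, 1, 2, 3, 4)  # min, Q1, Q2, Q3, max
  expect_equal(discretize(0, b), 1L)      # value = min
  expect_equal(discretize(0.99, b), 1L)
  expect_equal(discretize(1, b), 2L)      # Q1 starts interval 2
  expect_equal(discretize(2, b), 3L)      # exactly Q2 -> interval 3
  expect_equal(discretize(3, b), 4L)
  expect_equal(discretize(10, b), 4L)     # above training max clamps to 4
  expect_equal(discretize(-5, b), 1L)     # below training min clamps to 1
  expect_error(discretize(NaN, b), "non-finite")
})

test_that("mutual information matches its analytic values", {
  # X identically distributed in both classes: MI = 0
  x <- rep(c(1, 2, 3, 4), 2)
  y <- rep(c("POOR", "GOOD"), each = 4)
  expect_equal(mutual_information(x, y), 0)
  # X deterministic given class, equiprobable classes: MI = ln 2
  x2 <- rep(c(1, 4), each = 5)
  y2 <- rep(c("POOR", "GOOD"), each = 5)
  expect_equal(mutual_information(x2, y2), log(2), tolerance = 1e-12)
  expect_equal(mutual_information(x2, y2, unit = "bits"), 1, tolerance = 1e-12)
  # single class: 0 with warning
  expect_warning(m <- mutual_information(c(1, 2, 3), rep("POOR", 3)), "single class")
  expect_equal(m, 0)
})

test_that("mutual information agrees with the direct-summation oracle", {
  tab <- matrix(c(4, 1, 1, 4, 2, 2, 3, 3), 4, 2, byrow = TRUE)
  # build the raw vectors cell by cell
  x <- unlist(lapply(1:4, function(i) rep(i, sum(tab[i, ]))))
  y <- unlist(lapply(1:4, function(i)
    rep(c("POOR", "GOOD"), times = tab[i, ])))
  expect_equal(mutual_information(x, y), mi_oracle(tab), tolerance = 1e-12)
})

test_that("MI is symmetric, nonnegative and bounded by the marginal entropies", {
  set.seed(7)
  for (rep_i in 1:50) {
    tab <- matrix(rpois(8, 3), 4, 2)
    if (sum(tab) < 2 || any(colSums(tab) == 0)) next
    x <- unlist(lapply(1:4, function(i) rep(i, sum(tab[i, ]))))
    y <- unlist(lapply(1:4, function(i) rep(c("P", "G"), times = tab[i, ])))
    mi <- suppressWarnings(mutual_information(x, y))
    expect_gte(mi, 0)
    expect_lte(mi, entropy_oracle(rowSums(tab)) + 1e-12)
    expect_lte(mi, entropy_oracle(colSums(tab)) + 1e-12)
    # symmetry: swap roles of X and Y
    expect_equal(mi, suppressWarnings(mutual_information(y, x)), tolerance = 1e-12)
  }
})

test_that("ranking is invariant to the log base", {
  sim <- simulate_cohort(sim_config(n_patients = 30, n_features = 25, seed = 2))
  labs <- sim$truth$sample_state[rownames(sim$expr)]
  nats <- mi_scores(sim$expr, labs, unit = "nats")
  bits <- mi_scores(sim$expr, labs, unit = "bits")
  expect_identical(nats$feature_id, bits$feature_id)
  expect_equal(bits$mi, nats$mi / log(2), tolerance = 1e-12)
})

test_that("selection takes top-k with lexicographic tie-break and supports the gap rule", {
  sc <- data.frame(feature_id = c("a", "b", "c"), mi = c(0.5, 0.4, 0.01))
  expect_equal(rank_and_select(sc, k = 2), c("a", "b"))
  tie <- data.frame(feature_id = c("b", "a"), mi = c(0.3, 0.3))
  expect_equal(rank_and_select(tie, k = 1), "a")
  expect_error(rank_and_select(sc, k = 5), "exceeds")
  # gap rule: cut before the largest consecutive drop
  gap <- data.frame(feature_id = letters[1:5], mi = c(0.9, 0.85, 0.8, 0.1, 0.05))
  expect_equal(rank_and_select(gap, gap_rule = TRUE), c("a", "b", "c"))
})

test_that("label permutation drives marker MI down to the null level", {
  sim <- simulate_cohort(sim_config(n_patients = 60, n_features = 40,
                                    marker_effect = 3, seed = 8))
  labs <- sim$truth$sample_state[rownames(sim$expr)]
  sc <- mi_scores(sim$expr, labs)
  markers <- sim$truth$marker_ids
  mi_mark <- sc$mi[sc$feature_id %in% markers]
  mi_null <- sc$mi[!sc$feature_id %in% markers]
  expect_gt(min(mi_mark), max(mi_null))
  set.seed(3)
  perm <- sample(labs)
  names(perm) <- names(labs)
  scp <- mi_scores(sim$expr, perm)
  mi_mark_p <- scp$mi[scp$feature_id %in% markers]
  expect_lt(median(mi_mark_p), stats::quantile(mi_null, 0.99) + 0.05)
})
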