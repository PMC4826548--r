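#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Used throughout to compare recovered clusters with planted ground truth.
#'
#' @param a,b vectors of equal length; any label type.
#' @return numeric scalar; 1 for identical partitions (up to relabeling),
#'   approximately 0 for independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# Deterministic per-stage seed derived from one pipeline seed, so adding a
# stage never perturbs the random stream of earlier stages. Kept below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# shared validation helpers ---------------------------------------------------

assert_prob <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1] (got %s)",
                 name, paste(format(x), collapse = ", ")))
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d (got %s)",
                 name, min, paste(format(x), collapse = ", ")))
}

assert_expr <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression data must be a numeric matrix (samples x features)")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix must carry sample ids as rownames and feature ids as colnames")
  if (anyDuplicated(rownames(expr))) stop("duplicate sample ids in expression matrix")
  if (anyDuplicated(colnames(expr))) stop("duplicate feature ids in expression matrix")
  if (!all(is.finite(expr))) stop("expression matrix contains non-finite values")
  invisible(expr)
}

# named lookup with a hard error listing missing keys
lookup <- function(map, keys, what) {
  miss <- setdiff(keys, names(map))
  if (length(miss))
    stop(sprintf("no %s for: %s", what, paste(miss, collapse = ", ")))
  map[keys]
}
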