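# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use a different computational route than the package.

# Mutual information by direct summation over every cell of a joint count
# table (rows = intervals of X, cols = classes of Y); natural log.
mi_oracle <- function(tab) {
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pxy <- tab[i, j] / n
      if (pxy > 0) mi <- mi + pxy * log(pxy / (px[i] * py[j]))
    }
  }
  mi
}

entropy_oracle <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# Multi-group log-rank statistic by direct counting: tabulate observed and
# expected events and the hypergeometric covariance at each event time, then
# form the quadratic statistic on the first G-1 groups.
logrank_oracle <- function(times, events, groups) {
  groups <- as.factor(as.character(groups))
  G <- nlevels(groups)
  O <- E <- rep(0, G)
  V <- matrix(0, G, G)
  for (t in sort(unique(times[events]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    ng <- vapply(levels(groups), function(g) sum(at_risk & groups == g),
                 numeric(1))
    d <- sum(events & times == t)
    dg <- vapply(levels(groups), function(g)
      sum(events & times == t & groups == g), numeric(1))
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      for (a in seq_len(G)) for (b in seq_len(G)) {
        V[a, b] <- V[a, b] +
          d * (ng[a] / n) * ((a == b) - ng[b] / n) * (n - d) / (n - 1)
      }
    }
  }
  u <- (O - E)[-G]
  drop(t(u) %*% solve(V[-G, -G, drop = FALSE]) %*% u)
}

# Hand-coded Breslow partial log-likelihood for untied event times.
breslow_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (t in times[events]) {
    at_risk <- times >= t
    i <- which(times == t & events)
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# Small well-separated two-blob matrix for clustering tests.
make_blobs <- function(n_per = 20, p = 10, sep = 10, sd = 1, seed = 1) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per * p, 0, sd), n_per, p),
    matrix(rnorm(n_per * p, sep, sd), n_per, p))
  dimnames(x) <- list(sprintf("s%02d", seq_len(2 * n_per)),
                      sprintf("f%02d", seq_len(p)))
  x
}

# Tiny fully-specified cohort for label-rule tests: 6 patients covering every
# combination of purity and recurrence.
toy_label_cohort <- function() {
  assignment <- c(a1 = 1L, a2 = 1L,        # pA: recurrent, pure cluster 1
                  b1 = 2L, b2 = 2L,        # pB: non-recurrent, pure cluster 2
                  c1 = 1L, c2 = 2L,        # pC: recurrent, mixed
                  d1 = 1L,                 # pD: non-recurrent, cluster-1 sample
                  e1 = 2L,                 # pE: recurrent, pure cluster 2
                  f1 = 2L)                 # pF: non-recurrent, single focus
  s2p <- c(a1 = "pA", a2 = "pA", b1 = "pB", b2 = "pB", c1 = "pC", c2 = "pC",
           d1 = "pD", e1 = "pE", f1 = "pF")
  rec <- c(pA = TRUE, pB = FALSE, pC = TRUE, pD = FALSE, pE = TRUE, pF = FALSE)
  list(assignment = assignment, s2p = s2p, rec = rec)
}

# Run the standard discovery chain (cluster -> orient) on a simulated cohort.
discover <- function(sim, n_init = 25, seed = 1L) {
  s2p <- stats::setNames(sim$samples$patient_id, sim$samples$sample_id)
  rec <- stats::setNames(sim$patients$recurrence, sim$patients$patient_id)
  fit <- fit_two_means(sim$expr, n_init = n_init, seed = seed)
  model <- orient_clusters(fit, sim$expr, s2p, rec)
  list(model = model, s2p = s2p, rec = rec)
}

# Truth-derived cluster assignment (1 = poor state), used to isolate modules
# downstream of clustering.
truth_assignment <- function(sim) {
  st <- sim$truth$sample_state[rownames(sim$expr)]
  stats::setNames(ifelse(st == "POOR", 1L, 2L), names(st))
}
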