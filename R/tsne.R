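# Compact exact-gradient t-SNE (O(n^2) per iteration), sufficient for
# cohorts of a few hundred samples. Visualization plumbing only: seeded,
# deterministic, no Barnes-Hut approximation.

# Conditional Gaussian affinities with per-point precision tuned by binary
# search so each row's perplexity matches the target.
tsne_affinities <- function(D2, perplexity) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    betamin <- -Inf
    betamax <- Inf
    Di <- D2[i, -i]
    for (iter in 1:50) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP == 0) sumP <- .Machine$double.eps
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      if (abs(H - logU) < 1e-5) break
      if (H > logU) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- Pi / sumP
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

tsne_exact <- function(X, seed = 1L, perplexity = 30, max_iter = 300) {
  n <- nrow(X)
  perplexity <- min(perplexity, (n - 1) / 3)
  if (perplexity < 1) stop("too few samples for t-SNE")
  set.seed(seed)
  D2 <- as.matrix(stats::dist(X))^2
  P <- tsne_affinities(D2, perplexity)

  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  eta <- 100
  exaggeration <- 4
  for (iter in seq_len(max_iter)) {
    Pit <- if (iter <= 100) P * exaggeration else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (iter < 20) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y), "-")
  }
  Y
}
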