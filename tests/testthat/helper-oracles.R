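# Independent oracles, deliberately written as brute force / sampling
# code that shares no machinery with the implementation under test.

# All-pairs spring list by direct distance filtering.
oracle_spring_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= cutoff) out <- rbind(out, c(i, j, d))
  }
  out
}

# Connected components by breadth-first search over an adjacency rule.
oracle_components <- function(xyz, cutoff) {
  n <- nrow(xyz)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      for (u in seq_len(n)) {
        if (is.na(comp[u]) &&
            sqrt(sum((xyz[v, ] - xyz[u, ])^2)) <= cutoff)
          queue <- c(queue, u)
      }
    }
  }
  comp
}

# Precision/recall by explicit all-pairs counting with strict inequality.
oracle_precision_recall <- function(C, L, r_cutoff) {
  nc <- 0
  for (i in seq_len(nrow(C))) {
    dmin <- min(sqrt(rowSums(sweep(L, 2, C[i, ])^2)))
    if (dmin < r_cutoff) nc <- nc + 1
  }
  nl <- 0
  for (j in seq_len(nrow(L))) {
    dmin <- min(sqrt(rowSums(sweep(C, 2, L[j, ])^2)))
    if (dmin < r_cutoff) nl <- nl + 1
  }
  c(precision = nc / nrow(C), recall = nl / nrow(L))
}

# Monte-Carlo estimate of KL(N(0, M^-1) || N(0, Lam^-1)) in the shared
# r-dimensional internal subspace, by sampling from the perturbed
# Gaussian and averaging the log-density ratio. Returns the estimate and
# its standard error.
oracle_kl_mc <- function(lambda, M, n_samples = 2e5, seed = 99) {
  r <- length(lambda)
  eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
  stopifnot(all(eM$values > 0))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(seed)
  Z <- matrix(rnorm(n_samples * r), nrow = r)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  # x ~ N(0, M^-1): x = V diag(1/sqrt(mu)) z
  X <- eM$vectors %*% (Z / sqrt(eM$values))
  # log p'(x) - log p(x) = 1/2 [logdet M - logdet Lam - x'Mx + x'Lam x]
  qM <- colSums(X * (M %*% X))
  qL <- colSums(X * (lambda * X))
  ratio <- 0.5 * (sum(log(eM$values)) - sum(log(lambda)) - qM + qL)
  c(estimate = mean(ratio), se = stats::sd(ratio) / sqrt(n_samples))
}

# Perturbed quadratic form on the internal subspace, built from scratch:
# dense Hessian increment assembled directly from the attachment rule.
oracle_perturbed_core <- function(bundle, network, probe, gamma_s, r_int) {
  X <- as.matrix(network$nodes[, c("x", "y", "z")])
  n <- nrow(X)
  dH <- matrix(0, 3 * n, 3 * n)
  for (k in seq_len(n)) {
    d <- X[k, ] - probe
    dist <- sqrt(sum(d^2))
    if (dist <= r_int) {
      u <- d / dist
      b <- (3 * k - 2):(3 * k)
      dH[b, b] <- dH[b, b] + gamma_s * (u %o% u)
    }
  }
  Q <- bundle$basis
  M <- diag(bundle$eigenvalues) + t(Q) %*% dH %*% Q
  (M + t(M)) / 2
}
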