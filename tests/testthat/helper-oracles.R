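# independent brute-force oracles and tiny fixture builders

# per-pair block densities by an explicit double loop over unordered pairs
oracle_block_density <- function(m, sigma, weighted = FALSE, cmax = "pairs") {
  k <- max(sigma)
  n <- nrow(m)
  cnt <- matrix(0, k, k)
  tot <- matrix(0, k, k)
  for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    i <- sigma[u]; j <- sigma[v]
    val <- if (weighted) abs(m[u, v]) else (m[u, v] != 0) * 1
    cnt[i, j] <- cnt[i, j] + val
    if (i != j) cnt[j, i] <- cnt[j, i] + val
    tot[i, j] <- tot[i, j] + 1
    if (i != j) tot[j, i] <- tot[j, i] + 1
  }
  if (cmax == "literal") {
    omega <- tabulate(sigma, k)
    diag(tot) <- omega^2
  }
  w <- cnt / tot
  w[tot == 0] <- 0
  w
}

# Newman modularity by an explicit double loop over ordered pairs (incl. u = v)
oracle_modularity <- function(a, sigma, alpha = 1) {
  two_m <- sum(a)
  deg <- rowSums(a)
  q <- 0
  n <- nrow(a)
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (sigma[u] == sigma[v]) q <- q + a[u, v] - alpha * deg[u] * deg[v] / two_m
  }
  q / two_m
}

# random symmetric binary adjacency with zero diagonal
random_adjacency <- function(n, p = 0.3) {
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  a[ut] <- as.numeric(runif(sum(ut)) < p)
  a + t(a)
}

# random symmetric weight matrix in [-1, 1] with zero diagonal
random_weights <- function(n) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  w[ut] <- runif(sum(ut), -1, 1)
  w + t(w)
}

# small weighted connectome with two planted blocks and constant couplings
planted_weighted <- function(n = 8, within = 0.6, between = 0.1, k = 2) {
  sizes <- rep(n %/% k, k)
  sigma <- rep(seq_len(k), sizes)
  w <- matrix(between, n, n)
  for (i in seq_len(k)) w[sigma == i, sigma == i] <- within
  diag(w) <- 0
  list(fc = weighted_connectome(w), partition = node_partition(sigma))
}
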