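#' Block edge statistics for a graph under a fixed partition
#'
#' Accumulates, over unordered node pairs u < v, the k x k matrix of observed
#' within/between-community edge statistics: edge counts in binary mode, sums
#' of absolute weights in weighted mode (only coupling magnitude matters for
#' prominence, not sign). The capacity matrix `c_max` holds the maximum
#' possible number of pairs per block: `omega_i * omega_j` off-diagonal and,
#' under the default unordered-pair convention, `omega_i * (omega_i - 1) / 2`
#' on the diagonal (self-pairs excluded since diagonals are zero). The
#' `"literal"` convention keeps `omega_i^2` on the diagonal for sensitivity
#' checks.
#'
#' @param graph a [binary_connectome()] or [weighted_connectome()].
#' @param partition a [node_partition()] with matching node order.
#' @param cmax `"pairs"` (default) or `"literal"` diagonal convention.
#' @return An object of class `block_counts`: list with `c`, `c_max`, `omega`,
#'   `mode` and `n`.
#' @export
block_counts <- function(graph, partition, cmax = c("pairs", "literal")) {
  cmax <- match.arg(cmax)
  stopifnot(inherits(partition, "node_partition"))
  m <- conn_matrix(graph)
  n <- nrow(m)
  if (n != length(partition$sigma)) stopf("graph has %d nodes, partition %d", n, length(partition$sigma))
  mode <- if (inherits(graph, "binary_connectome")) "binary" else "weighted"
  x <- if (mode == "weighted") abs(m) else m
  k <- partition$k
  s <- matrix(0, n, k)
  s[cbind(seq_len(n), partition$sigma)] <- 1
  cfull <- crossprod(s, x) %*% s       # cfull[i,j] = sum_{u in i, v in j} x_uv
  cc <- cfull
  diag(cc) <- diag(cfull) / 2          # within-block pairs counted twice
  omega <- as.numeric(partition$omega)
  cm <- outer(omega, omega)
  diag(cm) <- if (cmax == "pairs") omega * (omega - 1) / 2 else omega^2
  structure(list(c = cc, c_max = cm, omega = partition$omega, mode = mode, n = n),
            class = "block_counts")
}

#' Infer stochastic block model parameters from block counts
#'
#' Law-of-large-numbers (plug-in maximum likelihood) inference with both the
#' graph and partition observed: `p = omega / n`, `W = c / c_max` entrywise
#' (0 where `c_max = 0`, i.e. singleton-community diagonals), expected-degree
#' matrix `Q = n W` (constant degree-regime scaling `s_t = 1`), and community
#' profile matrix `PQ = n P W`, whose entry (i, j) is the expected number of
#' community-j neighbours of a community-i node. In binary mode `W` is a
#' Bernoulli edge probability; in weighted mode it is the mean absolute
#' coupling per node pair, turning the SNR into a prominence measure.
#'
#' @param counts a [block_counts()] object.
#' @param n number of nodes; defaults to `counts$n`.
#' @return An object of class `sbm_params`: list with `p`, `P`, `W`, `Q`,
#'   `PQ`, `n`, `st = 1` and `mode`.
#' @export
infer_sbm <- function(counts, n = counts$n) {
  stopifnot(inherits(counts, "block_counts"))
  omega <- as.numeric(counts$omega)
  if (any(omega < 1) || sum(omega) != n) stopf("invalid community sizes for n = %d", n)
  p <- omega / n
  W <- counts$c / counts$c_max
  W[counts$c_max == 0] <- 0
  Q <- n * W
  PQ <- n * (p * W)   # diag(p) %*% W, row-scaled
  structure(list(p = p, P = diag(p, nrow = length(p)), W = W, Q = Q, PQ = PQ,
                 n = n, st = 1, mode = counts$mode),
            class = "sbm_params")
}

# Eigenvalues of diag(p) %*% q sorted by descending magnitude, computed via
# the symmetric similar matrix diag(sqrt(p)) q diag(sqrt(p)) for stability
# (guarantees a real spectrum when q is symmetric).
pq_eigenvalues <- function(p, q) {
  if (max(abs(q - t(q))) > 1e-8) stopf("block matrix is not symmetric; corrupted parameters")
  sp <- sqrt(p)
  sym <- (sp * t(sp * q))              # diag(sp) %*% q %*% diag(sp)
  sym <- (sym + t(sym)) / 2
  ev <- eigen(sym, symmetric = TRUE, only.values = TRUE)$values
  ev[order(abs(ev), decreasing = TRUE)]
}

#' Signal-to-noise ratio of inferred SBM parameters
#'
#' Computes `SNR = lambda2^2 / lambda1` where `lambda1`, `lambda2` are the
#' eigenvalues of the community profile matrix `PQ` sorted by descending
#' magnitude. `SNR > 1` is the Kesten-Stigum condition: weak recovery of the
#' partition (community detection better than chance) is efficiently
#' solvable. Degenerate inputs carry no mesoscopic signal and return 0:
#' a single community, an (almost) empty graph (`lambda1 <= 1e-12`), or a
#' rank-one profile (complete/constant graphs, `lambda2 = 0`).
#'
#' @param params an [infer_sbm()] result.
#' @return An object of class `snr_value`: list with `snr`, `lambda1`,
#'   `lambda2`.
#' @export
snr <- function(params) {
  stopifnot(inherits(params, "sbm_params"))
  snr_from_pq(params$p, params$n * params$W)
}

snr_from_pq <- function(p, q) {
  k <- length(p)
  if (k < 2L) {
    ev1 <- if (k == 1L) p[1L] * q[1L, 1L] else 0
    return(structure(list(snr = 0, lambda1 = ev1, lambda2 = 0), class = "snr_value"))
  }
  ev <- pq_eigenvalues(p, q)
  lambda1 <- ev[1L]
  lambda2 <- ev[2L]
  if (lambda1 < -1e-8) stopf("leading eigenvalue of PQ is negative (%.3g); corrupted parameters", lambda1)
  s <- if (lambda1 <= 1e-12) 0 else lambda2^2 / lambda1
  structure(list(snr = s, lambda1 = lambda1, lambda2 = lambda2), class = "snr_value")
}

#' @export
print.snr_value <- function(x, ...) {
  cat(sprintf("SNR = %.6g (lambda1 = %.6g, lambda2 = %.6g)%s\n", x$snr, x$lambda1, x$lambda2,
              if (x$snr > 1) " [weak recovery solvable]" else ""))
  invisible(x)
}

#' Closed-form SNR of a planted stochastic block model
#'
#' For model parameters given directly — community prior `p` and expected-
#' degree matrix `q` (`= nW` at degree-regime scaling `s_t = 1`) — returns the
#' SNR of `PQ = diag(p) q`. For the symmetric two-community model with
#' `p = (1/2, 1/2)` and `q = [[a, b], [b, a]]` this equals
#' `(a - b)^2 / (2 (a + b))`; the Kesten-Stigum boundary is SNR = 1.
#'
#' @param p probability vector (sums to 1).
#' @param q symmetric nonnegative k x k expected-degree matrix.
#' @return An `snr_value`.
#' @examples
#' analytic_snr(c(0.5, 0.5), matrix(c(6, 2, 2, 6), 2))$snr # exactly 1
#' @export
analytic_snr <- function(p, q) {
  p <- as.numeric(p)
  if (abs(sum(p) - 1) > 1e-12) stopf("p must sum to 1")
  if (any(p < 0)) stopf("p must be nonnegative")
  q <- as.matrix(q)
  if (any(q < 0)) stopf("q must be nonnegative")
  snr_from_pq(p, q)
}
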