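test_that("block counts follow the unordered-pair convention in both modes", {
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 1; a[1, 3] <- a[3, 1] <- 1; a[3, 4] <- a[4, 3] <- 1
  g <- binary_connectome(a)
  part <- node_partition(c(1, 1, 2, 2))
  bc <- block_counts(g, part)
  expect_equal(bc$c, matrix(c(1, 1, 1, 1), 2))
  expect_equal(bc$c_max, matrix(c(1, 4, 4, 1), 2))

  # empty graph
  empty <- binary_connectome(matrix(0, 4, 4))
  expect_true(all(block_counts(empty, part)$c == 0))

  # weighted mode sums absolute values
  w <- matrix(-0.5, 4, 4); diag(w) <- 0
  bcw <- block_counts(weighted_connectome(w), part)
  expect_equal(bcw$c, matrix(c(0.5, 2, 2, 0.5), 2))
  expect_equal(bcw$mode, "weighted")

  # literal capacity convention keeps omega_i^2 on the diagonal
  expect_equal(diag(block_counts(g, part, cmax = "literal")$c_max), c(4, 4))
})

test_that("SBM inference reproduces hand-computed parameters and conventions", {
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 1; a[1, 3] <- a[3, 1] <- 1; a[3, 4] <- a[4, 3] <- 1
  part <- node_partition(c(1, 1, 2, 2))
  sb <- infer_sbm(block_counts(binary_connectome(a), part))
  expect_equal(sb$p, c(0.5, 0.5))
  expect_equal(sb$W, matrix(c(1, 0.25, 0.25, 1), 2))
  expect_equal(sb$PQ, matrix(c(2, 0.5, 0.5, 2), 2))
  expect_equal(sb$st, 1)

  # complete graph: W is all ones for any 2-block partition
  comp <- binary_connectome(1 - diag(4))
  expect_equal(infer_sbm(block_counts(comp, part))$W, matrix(1, 2, 2))
  expect_equal(infer_sbm(block_counts(comp, node_partition(c(1, 2, 1, 2))))$W, matrix(1, 2, 2))

  # singleton community: 0/0 diagonal convention
  single <- node_partition(c(1, 2, 2, 2))
  sb2 <- infer_sbm(block_counts(binary_connectome(a), single))
  expect_equal(sb2$W[1, 1], 0)
})

test_that("SNR matches hand-derived eigenvalues on 2x2 profiles and degenerates to 0", {
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 1; a[1, 3] <- a[3, 1] <- 1; a[3, 4] <- a[4, 3] <- 1
  part <- node_partition(c(1, 1, 2, 2))
  v <- snr(infer_sbm(block_counts(binary_connectome(a), part)))
  expect_equal(v$lambda1, 2.5)
  expect_equal(v$lambda2, 1.5)
  expect_equal(v$snr, 0.9)

  # complete graph -> rank-1 PQ -> SNR 0 (too much noise)
  comp <- binary_connectome(1 - diag(4))
  expect_equal(snr(infer_sbm(block_counts(comp, part)))$snr, 0)
  # empty graph -> SNR 0 (too little signal)
  expect_equal(snr(infer_sbm(block_counts(binary_connectome(matrix(0, 4, 4)), part)))$snr, 0)
  # single community -> SNR 0
  expect_equal(snr(infer_sbm(block_counts(comp, node_partition(rep(1, 4)))))$snr, 0)
})

test_that("analytic SNR hits the Kesten-Stigum boundary and closed forms", {
  expect_equal(analytic_snr(c(0.5, 0.5), matrix(c(6, 2, 2, 6), 2))$snr, 1)
  v <- analytic_snr(c(0.5, 0.5), matrix(c(5, 1, 1, 5), 2))
  expect_equal(v$snr, 4 / 3)
  expect_equal(v$lambda1, 3)
  # symmetric 2-block closed form (a - b)^2 / (2 (a + b)) on a random case
  a <- 7.3; b <- 2.1
  expect_equal(analytic_snr(c(0.5, 0.5), matrix(c(a, b, b, a), 2))$snr,
               (a - b)^2 / (2 * (a + b)))
  # rank-1 q: SNR 0 for any p
  expect_equal(analytic_snr(c(0.3, 0.2, 0.5), matrix(4, 3, 3))$snr, 0)
  expect_error(analytic_snr(c(0.6, 0.6), diag(2)), "sum to 1")
})

test_that("inferred block densities equal the double-loop oracle and SNR is permutation invariant", {
  set.seed(101)
  for (case in 1:40) {
    n <- sample(5:30, 1)
    k <- sample(2:4, 1)
    sigma <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
    part <- node_partition(sigma)
    weighted <- case %% 2 == 0
    if (weighted) {
      m <- random_weights(n)
      g <- weighted_connectome(m)
    } else {
      m <- random_adjacency(n, runif(1, 0.1, 0.7))
      g <- binary_connectome(m)
    }
    sb <- infer_sbm(block_counts(g, part))
    expect_equal(sb$W, oracle_block_density(m, sigma, weighted), tolerance = 1e-12)

    # spectrum of PQ is real even via the generic eigensolver
    ev <- eigen(sb$PQ, only.values = TRUE)$values
    expect_lt(max(abs(Im(ev))), 1e-8)

    # simultaneous node permutation leaves the SNR unchanged
    perm <- sample.int(n)
    gp <- if (weighted) weighted_connectome(m[perm, perm]) else binary_connectome(m[perm, perm])
    expect_equal(snr(infer_sbm(block_counts(gp, node_partition(sigma[perm]))))$snr,
                 snr(sb)$snr, tolerance = 1e-10)
  }
})
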