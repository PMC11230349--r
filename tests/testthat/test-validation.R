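two_triangles <- function() {
  a <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
    a[e[1], e[2]] <- a[e[2], e[1]] <- 1
  binary_connectome(a)
}

test_that("modularity matches closed forms and the double-loop oracle", {
  g <- two_triangles()
  good <- node_partition(rep(1:2, each = 3))
  expect_equal(modularity_score(g, good), 0.5)
  # one community: Q = 0 at alpha = 1
  expect_equal(modularity_score(g, node_partition(rep(1, 6))), 0)
  # a partition crossing the triangles scores negative
  bad <- node_partition(rep(1:2, 3))
  expect_lt(modularity_score(g, bad), 0)
  expect_equal(modularity_score(g, bad), oracle_modularity(conn_matrix(g), bad$sigma))
  # edgeless graphs are rejected
  expect_error(modularity_score(binary_connectome(matrix(0, 3, 3)), node_partition(c(1, 1, 2))),
               "edgeless")

  # randomized agreement with the brute-force oracle, including alpha != 1,
  # plus an igraph cross-check
  set.seed(33)
  for (case in 1:30) {
    n <- sample(5:30, 1)
    a <- random_adjacency(n, runif(1, 0.2, 0.8))
    if (sum(a) == 0) next
    sigma <- sample.int(3, n, replace = TRUE)
    sigma[1:3] <- 1:3
    part <- node_partition(sigma)
    alpha <- sample(c(0.5, 1, 2), 1)
    q <- modularity_score(binary_connectome(a), part, alpha = alpha)
    expect_equal(q, oracle_modularity(a, part$sigma, alpha), tolerance = 1e-12)
    ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    expect_equal(q, igraph::modularity(ig, part$sigma, resolution = alpha), tolerance = 1e-12)
  }
})

test_that("modularity maximization recovers planted clique structure", {
  g <- two_triangles()
  best <- maximize_modularity(g, seed = 1)
  expect_equal(modularity_score(g, best), 0.5)
  expect_equal(ami(best, node_partition(rep(1:2, each = 3))), 1)

  # two 5-cliques joined by one edge
  a <- matrix(0, 10, 10)
  a[1:5, 1:5] <- 1; a[6:10, 6:10] <- 1; diag(a) <- 0
  a[5, 6] <- a[6, 5] <- 1
  best2 <- maximize_modularity(binary_connectome(a), seed = 1)
  expect_equal(best2$k, 2)
  expect_equal(ami(best2, node_partition(rep(1:2, each = 5))), 1)

  # complete graph: no structure, Q <= 0, degenerate output accepted
  comp <- binary_connectome(1 - diag(6))
  expect_lte(modularity_score(comp, maximize_modularity(comp, seed = 1)), 0)
  # found Q is at least the all-singletons baseline
  singletons <- node_partition(1:10)
  expect_gte(modularity_score(binary_connectome(a), best2),
             modularity_score(binary_connectome(a), singletons))
})

test_that("the Poisson SBM fit recovers planted blocks and improves its likelihood", {
  part <- make_planted_partition(60, 2)
  g <- sample_binary_sbm(part, matrix(c(0.5, 0.05, 0.05, 0.5), 2), seed = 2)
  fit <- poisson_sbm_fit(g, k = 2, seed = 4)
  expect_equal(ami(fit, part), 1)

  # weighted planted blocks (within mean 0.6, between 0.1)
  pl <- planted_weighted(n = 40, within = 0.6, between = 0.1)
  fitw <- poisson_sbm_fit(pl$fc, k = 2, seed = 4)
  expect_equal(ami(fitw, pl$partition), 1)

  # structureless Erdos-Renyi graph: agreement with any planted labels is near chance
  set.seed(9)
  er <- binary_connectome(random_adjacency(60, 0.2))
  fit_er <- poisson_sbm_fit(er, k = 2, seed = 4)
  expect_lt(abs(ami(fit_er, part)), 0.1)

  # greedy optimization does not decrease the profile likelihood from its start
  x <- conn_matrix(g)
  sig0 <- rep(1:2, 30)
  s0 <- matrix(0, 60, 2); s0[cbind(1:60, sig0)] <- 1
  c0 <- crossprod(s0, x) %*% s0; diag(c0) <- diag(c0) / 2
  ll0 <- snrthresh:::poisson_block_ll(c0, tabulate(sig0, 2))
  expect_gte(attr(fit, "loglik"), ll0)

  expect_error(poisson_sbm_fit(g, k = 61), "exceeds")
  expect_error(poisson_sbm_fit(g, k = 1), ">= 2")
})

test_that("adjusted mutual information matches an independent reference implementation", {
  # frozen oracle values from scikit-learn's adjusted_mutual_info_score
  p1 <- node_partition(c(1, 1, 2, 2, 3)); p2 <- node_partition(c(1, 2, 2, 3, 3))
  expect_equal(ami(p1, p2), -0.25, tolerance = 1e-12)
  x <- c(3, 2, 3, 3, 2, 3, 3, 1, 1, 1, 1, 3, 3, 1, 2, 3, 1, 3, 1, 2)
  y <- c(3, 1, 2, 1, 3, 1, 3, 2, 2, 2, 2, 2, 2, 3, 3, 3, 3, 2, 2, 3)
  expect_equal(ami(node_partition(x), node_partition(y)), 0.0947793592438894,
               tolerance = 1e-12)
  expect_equal(ami(node_partition(x), node_partition(y), method = "nmi"),
               0.2051082257000016, tolerance = 1e-12)

  # identity, label invariance, symmetry
  expect_equal(ami(p1, p1), 1)
  expect_equal(ami(node_partition(c("a", "a", "b")), node_partition(c(9, 9, 4))), 1)
  expect_equal(ami(p1, p2), ami(p2, p1))
  expect_error(ami(p1, node_partition(1:3)), "different node counts")

  # chance adjustment: independent partitions score ~0 on average
  set.seed(17)
  vals <- replicate(50, ami(node_partition(sample.int(4, 1000, TRUE)),
                            node_partition(sample.int(4, 1000, TRUE))))
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("agreement curves flag edgeless thresholds and align detector peaks with SNR", {
  sim <- simulate_fc_cohort(sim_config(n = 60, k = 4, gamma = 6, t_points = 300, seed = 21))
  ga <- group_average(sim$cohort)
  cur <- agreement_curves(ga, sim$partition, threshold_grid(0.1), seed = 2)
  expect_s3_class(cur, "agreement_curves")
  expect_true(any(cur$degenerate))               # tau beyond all |w|
  expect_true(all(cur$ami_q[cur$degenerate] == 0))
  expect_true(all(cur$ami_q <= 1 & cur$ami_sbm <= 1))
  ok <- !cur$degenerate
  expect_lte(abs(cur$tau[ok][which.max(cur$ami_q[ok])] - cur$tau[which.max(cur$snr_wei)]),
             0.1 + 1e-9)
})
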