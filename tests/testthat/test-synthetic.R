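test_that("planted partitions have contiguous blocks of the requested sizes", {
  p <- make_planted_partition(8, 2)
  expect_equal(p$sigma, rep(1:2, each = 4L))
  expect_equal(make_planted_partition(8, 2, sizes = c(3, 5))$omega, c(3L, 5L))
  expect_error(make_planted_partition(3, 5), "more communities")
  expect_error(make_planted_partition(8, 2, sizes = c(3, 4)), "summing")
})

test_that("binary SBM sampling respects edge probabilities and seeds", {
  p <- make_planted_partition(10, 2)
  expect_equal(sum(conn_matrix(sample_binary_sbm(p, matrix(1, 2, 2)))) / 2, 45)  # complete
  expect_equal(sum(conn_matrix(sample_binary_sbm(p, matrix(0, 2, 2)))), 0)       # empty
  g1 <- sample_binary_sbm(p, matrix(c(0.6, 0.2, 0.2, 0.6), 2), seed = 5)
  g2 <- sample_binary_sbm(p, matrix(c(0.6, 0.2, 0.2, 0.6), 2), seed = 5)
  expect_identical(conn_matrix(g1), conn_matrix(g2))
  expect_error(sample_binary_sbm(p, matrix(1.5, 2, 2)), "probabilities")
})

test_that("simulated cohorts are valid correlation connectomes and bit-reproducible", {
  cfg <- sim_config(n = 40, k = 4, gamma = 3, t_points = 100, seed = 12)
  s1 <- simulate_fc_cohort(cfg)
  s2 <- simulate_fc_cohort(cfg)
  expect_identical(lapply(s1$cohort$connectomes, `[[`, "weights"),
                   lapply(s2$cohort$connectomes, `[[`, "weights"))
  for (fc in s1$cohort$connectomes) {
    w <- fc$weights
    expect_true(all(abs(w) <= 1))
    expect_equal(w, t(w))
    expect_true(all(diag(w) == 0))
  }
  expect_equal(s1$partition$omega, rep(10L, 4))
  # infeasible factor correlation (rho_between close to rho_within at k > 2
  # stays PSD, but rho ordering violations are rejected up front)
  expect_error(sim_config(rho_within = 0.2, rho_between = 0.4), "rho_between < rho_within")
})

test_that("long scans calibrate block correlations to their targets", {
  s <- simulate_fc_cohort(sim_config(n = 60, k = 3, gamma = 1, t_points = 5000,
                                     fingerprint_sd = 0, coupling_sd = 0, seed = 3))
  w <- s$cohort$connectomes[[1]]$weights
  sig <- s$partition$sigma
  same <- outer(sig, sig, "==") & upper.tri(w)
  betw <- !outer(sig, sig, "==") & upper.tri(w)
  expect_lt(abs(mean(w[same]) - 0.45), 0.02)
  expect_lt(abs(mean(w[betw]) - 0.25), 0.02)
})

test_that("longer scans raise the group-average SNR", {
  lo <- simulate_fc_cohort(sim_config(n = 60, k = 4, gamma = 5, t_points = 100, seed = 2))
  hi <- simulate_fc_cohort(sim_config(n = 60, k = 4, gamma = 5, t_points = 1000, seed = 2))
  p_lo <- snr_profile(group_average(lo$cohort), lo$partition, mode = "weighted")
  p_hi <- snr_profile(group_average(hi$cohort), hi$partition, mode = "weighted")
  expect_gt(max(p_hi$snr), max(p_lo$snr))
})

test_that("parcellation refinement doubles communities node-for-node", {
  p <- make_planted_partition(100, 7)
  ref <- refine_parcellation(p, 2)
  expect_equal(length(ref$partition$sigma), 200)
  expect_equal(ref$partition$omega, 2L * p$omega)
  # children inherit the parent's community
  parent_of <- match(ref$mapping$parent, p$node_ids)
  expect_equal(ref$partition$sigma, p$sigma[parent_of])
  expect_error(refine_parcellation(p, 1), ">= 2")

  # the generator's split_factor mirrors the same structure
  s <- simulate_fc_cohort(sim_config(n = 30, k = 3, gamma = 2, t_points = 60,
                                     split_factor = 2, seed = 8))
  expect_equal(length(s$partition$sigma), 60)
  expect_equal(s$partition$omega, rep(20L, 3))
})

test_that("negative couplings are tolerated by the magnitude conventions", {
  s <- simulate_fc_cohort(sim_config(n = 40, k = 4, gamma = 2, t_points = 200,
                                     neg_fraction = 0.3, seed = 10))
  w <- s$cohort$connectomes[[1]]$weights
  expect_true(any(w < -0.1))
  prof <- snr_profile(group_average(s$cohort), s$partition, mode = "weighted")
  expect_true(all(is.finite(prof$snr)))
  expect_gt(max(prof$snr), 0)
})

test_that("planted detectability crosses the weak-recovery boundary as contrast grows", {
  p <- c(0.25, 0.25, 0.25, 0.25)
  q_of <- function(win, btw) {
    q <- matrix(200 * btw, 4, 4); diag(q) <- 200 * win; q
  }
  expect_lt(analytic_snr(p, q_of(0.08, 0.05))$snr, 1)   # sub-threshold regime
  expect_gt(analytic_snr(p, q_of(0.30, 0.05))$snr, 1)   # super-threshold regime
})
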