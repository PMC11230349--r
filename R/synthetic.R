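#' Configuration for synthetic connectome cohorts
#'
#' Describes a planted-partition cohort of correlation-type connectomes: `k`
#' assortative communities over `n` nodes, target within- and between-
#' community correlations, scan length `t_points` (time points entering the
#' sample Pearson correlation, hence controlling estimation noise), cohort
#' size `gamma`, and a subject "fingerprint" perturbation of the within-
#' community coupling strength. Defaults emulate a modest resting-state-like
#' cohort: 100 nodes in 7 communities, within-community correlation 0.5,
#' between 0.15, 200 time points, 20 subjects, fingerprint SD 0.05.
#'
#' @param n number of nodes.
#' @param k number of communities.
#' @param sizes community sizes (default: as equal as possible, summing to n).
#' @param rho_within target within-community node correlation, in
#'   `(rho_between, 1]`.
#' @param rho_between target between-community node correlation, in
#'   `[0, rho_within)`.
#' @param t_points scan length T (>= 4).
#' @param gamma cohort size.
#' @param fingerprint_sd SD of the per-subject, per-node perturbation of the
#'   within-community coupling (truncated to `(rho_between, 1)`).
#' @param coupling_sd SD of the cohort-level, node-specific baseline coupling
#'   heterogeneity: each node's coupling strength is drawn once per cohort as
#'   `N(rho_within, coupling_sd^2)` and shared by all subjects, emulating the
#'   stable regional differences in how strongly a parcel couples to its
#'   functional network. Subjects perturb this baseline by `fingerprint_sd`.
#' @param neg_fraction fraction of nodes whose factor loading sign is flipped,
#'   injecting negative couplings (exercises the `|w|` convention).
#' @param split_factor parcellation refinement: each of `n` parent nodes is
#'   represented by `split_factor` child nodes sharing the parent's community
#'   and latent loading (default 1, no refinement).
#' @param seed RNG seed (required; cohorts are bit-reproducible given the
#'   config).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n = 100, k = 7, sizes = NULL, rho_within = 0.45,
                       rho_between = 0.25, t_points = 600, gamma = 20,
                       fingerprint_sd = 0.1, coupling_sd = 0.1, neg_fraction = 0,
                       split_factor = 1, seed = 1) {
  if (is.null(sizes)) {
    sizes <- rep(n %/% k, k)
    extra <- n - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  }
  if (k > n) stopf("more communities (%d) than nodes (%d)", k, n)
  if (length(sizes) != k || sum(sizes) != n || any(sizes < 1))
    stopf("sizes must be %d positive integers summing to %d", k, n)
  if (!(rho_between >= 0 && rho_between < rho_within && rho_within <= 1))
    stopf("need 0 <= rho_between < rho_within <= 1")
  if (t_points < 4) stopf("t_points must be >= 4")
  if (gamma < 1) stopf("gamma must be >= 1")
  if (neg_fraction < 0 || neg_fraction > 1) stopf("neg_fraction must be in [0, 1]")
  if (coupling_sd < 0) stopf("coupling_sd must be nonnegative")
  if (split_factor < 1) stopf("split_factor must be >= 1")
  structure(list(n = as.integer(n), k = as.integer(k), sizes = as.integer(sizes),
                 rho_within = rho_within, rho_between = rho_between,
                 t_points = as.integer(t_points), gamma = as.integer(gamma),
                 fingerprint_sd = fingerprint_sd, coupling_sd = coupling_sd,
                 neg_fraction = neg_fraction,
                 split_factor = as.integer(split_factor), seed = as.integer(seed)),
            class = "sim_config")
}

#' Planted partition with contiguous community blocks
#'
#' @param n number of nodes.
#' @param k number of communities.
#' @param sizes community sizes summing to `n`; default as equal as possible.
#' @return A [node_partition()] with labels `"C1".."Ck"` in contiguous blocks.
#' @export
make_planted_partition <- function(n, k, sizes = NULL) {
  cfg <- sim_config(n = n, k = k, sizes = sizes)
  node_partition(rep(paste0("C", seq_len(k)), cfg$sizes))
}

#' Sample a binary graph from a stochastic block model
#'
#' Each unordered node pair `u < v` is an edge independently with probability
#' `w[sigma_u, sigma_v]`.
#'
#' @param partition a [node_partition()].
#' @param w symmetric k x k edge-probability matrix.
#' @param seed RNG seed.
#' @return A [binary_connectome()].
#' @export
sample_binary_sbm <- function(partition, w, seed = 1) {
  stopifnot(inherits(partition, "node_partition"))
  w <- as.matrix(w)
  if (any(w < 0 | w > 1)) stopf("edge probabilities must be in [0, 1]")
  if (max(abs(w - t(w))) > 0) stopf("edge-probability matrix must be symmetric")
  if (nrow(w) != partition$k) stopf("w must be k x k with k = %d", partition$k)
  n <- length(partition$sigma)
  probs <- w[partition$sigma, partition$sigma]
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  a[ut] <- with_seed(seed, as.numeric(runif(sum(ut)) < probs[ut]))
  a <- a + t(a)
  binary_connectome(a, partition$node_ids)
}

#' Simulate a cohort of correlation-type connectomes with planted communities
#'
#' A latent-factor emulator of Pearson functional connectomes. Per subject,
#' each community i has a factor signal `f_i(t)` over `t_points` time points;
#' the k factors are jointly Gaussian with pairwise correlation
#' `rho_between / rho_within` (so node-level between-community correlations
#' land near `rho_between`). Node signals are
#' `x_u(t) = sqrt(rho_u) f_sigma(u)(t) + sqrt(1 - rho_u) eps_u(t)` with
#' independent unit-variance noise; `rho_u` is a node-specific baseline
#' (`rho_within` plus a cohort-level `N(0, coupling_sd^2)` draw shared across
#' subjects) perturbed per subject by `N(0, fingerprint_sd^2)`, truncated to
#' `(rho_between, 1)`. The
#' connectome is the sample Pearson correlation matrix of the node signals
#' with a zeroed diagonal — bounded, noisy and assortative like empirical
#' functional connectomes, with estimation noise shrinking as `t_points`
#' grows. With `split_factor = m > 1` each parent node contributes `m` child
#' nodes that inherit its community and latent loading (parcellation
#' refinement), while factor series and loadings are drawn identically to the
#' unrefined cohort with the same seed.
#'
#' @param cfg a [sim_config()].
#' @return A list with `cohort` (an [fc_cohort()]), `partition` (ground-truth
#'   [node_partition()] at the — possibly refined — node resolution), and
#'   `config`.
#' @export
simulate_fc_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  k <- cfg$k
  m <- cfg$split_factor
  n_child <- cfg$n * m
  r <- cfg$rho_between / cfg$rho_within
  fac_cor <- matrix(r, k, k); diag(fac_cor) <- 1
  ch <- tryCatch(chol(fac_cor),
                 error = function(e) stopf("factor correlation matrix (off-diagonal %.3f) is not positive definite", r))
  parent_sigma <- rep(seq_len(k), cfg$sizes)
  child_sigma <- rep(parent_sigma, each = m)
  partition <- node_partition(paste0("C", child_sigma))

  conns <- with_seed(cfg$seed, {
    # cohort-level baseline coupling per parent node, shared by all subjects
    base_rho <- cfg$rho_within + rnorm(cfg$n, 0, cfg$coupling_sd)
    base_rho <- pmin(pmax(base_rho, cfg$rho_between + 1e-6), 1 - 1e-6)
    lapply(seq_len(cfg$gamma), function(g) {
      f <- matrix(rnorm(cfg$t_points * k), cfg$t_points, k) %*% ch
      rho <- base_rho + rnorm(cfg$n, 0, cfg$fingerprint_sd)
      rho <- pmin(pmax(rho, cfg$rho_between + 1e-6), 1 - 1e-6)
      sign_u <- rep(1, cfg$n)
      if (cfg$neg_fraction > 0) {
        flip <- sample.int(cfg$n, size = round(cfg$neg_fraction * cfg$n))
        sign_u[flip] <- -1
      }
      load_child <- rep(sign_u * sqrt(rho), each = m)
      noise_child <- rep(sqrt(1 - rho), each = m)
      x <- f[, child_sigma, drop = FALSE] * rep(load_child, each = cfg$t_points) +
        matrix(rnorm(cfg$t_points * n_child), cfg$t_points, n_child) *
          rep(noise_child, each = cfg$t_points)
      w <- cor(x)
      diag(w) <- 0
      weighted_connectome(w, partition$node_ids)
    })
  })
  list(cohort = fc_cohort(conns, condition = "synthetic"),
       partition = partition, config = cfg)
}

#' Refine a parcellation by splitting each node
#'
#' Every node is subdivided into `m` child nodes that inherit the parent's
#' community label (mirroring nested parcellation hierarchies where finer
#' parcels stay within the same functional network). Community sizes scale by
#' exactly `m`.
#'
#' @param partition a [node_partition()].
#' @param m split factor (>= 2).
#' @return A list with `partition` (refined, `m * n` nodes) and `mapping`
#'   (data frame `parent`, `child`). To re-simulate a cohort at the refined
#'   resolution with children sharing their parent's latent loading, set
#'   `split_factor = m` in [sim_config()] with the same seed.
#' @export
refine_parcellation <- function(partition, m) {
  stopifnot(inherits(partition, "node_partition"))
  if (m < 2) stopf("split factor m must be >= 2")
  n <- length(partition$sigma)
  child_labels <- rep(partition$labels[partition$sigma], each = m)
  child_ids <- paste0(rep(partition$node_ids, each = m), "_", rep(seq_len(m), n))
  list(partition = node_partition(child_labels, node_ids = child_ids),
       mapping = data.frame(parent = rep(partition$node_ids, each = m),
                            child = child_ids, row.names = NULL))
}

#' Write a simulated cohort to disk in the package's file formats
#'
#' Writes one matrix file per subject, the ground-truth partition, a YAML
#' manifest and a JSON provenance record of the full simulation config.
#'
#' @param sim a [simulate_fc_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_sim_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("subject_%03d.tsv", seq_along(sim$cohort$connectomes))
  for (i in seq_along(files)) write_connectome(sim$cohort$connectomes[[i]], file.path(dir, files[i]))
  write_partition(sim$partition, file.path(dir, "partition.tsv"))
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(condition = sim$cohort$condition, files = files,
                        subject_ids = sim$cohort$subject_ids), manifest)
  jsonlite::write_json(unclass(sim$config), file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
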