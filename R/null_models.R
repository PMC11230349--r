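#' Size-preserving random shuffle of a partition
#'
#' Applies a uniformly random permutation to the community-label vector, so
#' the community-size multiset (and hence the SBM prior `P`) is preserved
#' exactly while the alignment between communities and graph topology is
#' destroyed.
#'
#' @param partition a [node_partition()].
#' @param seed optional integer; when supplied the shuffle is deterministic
#'   and the caller's RNG state is untouched.
#' @return A shuffled [node_partition()] with the same `k` and `omega`.
#' @export
shuffle_partition <- function(partition, seed = NULL) {
  stopifnot(inherits(partition, "node_partition"))
  n <- length(partition$sigma)
  perm <- if (is.null(seed)) sample.int(n) else with_seed(seed, sample.int(n))
  sh <- partition$labels[partition$sigma[perm]]
  node_partition(sh, node_ids = partition$node_ids)
}

#' Partition-shuffle null distribution of SNR profiles
#'
#' Recomputes the SNR profile under repeated size-preserving shuffles of the
#' partition. For a partition that genuinely aligns with the graph's
#' mesoscopic structure, null profiles lie uniformly below the true-partition
#' profile and below the weak-recovery threshold SNR = 1.
#'
#' @inheritParams snr_profile
#' @param n_shuffles number of shuffles (default 100).
#' @param seed RNG seed; the ensemble is deterministic given the seed.
#' @return An object of class `null_ensemble`: list with `snr` (an
#'   `n_shuffles` x `length(grid)` matrix), `summary` (per-tau min / median /
#'   max data frame), `taus`, `mode`, `n_shuffles`, `seed`.
#' @export
null_snr_distribution <- function(fc, partition, grid = threshold_grid(),
                                  mode = c("binary", "weighted"),
                                  n_shuffles = 100, seed = 1,
                                  rule = c("magnitude", "positive"),
                                  cmax = c("pairs", "literal")) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  cmax <- match.arg(cmax)
  if (n_shuffles < 1) stopf("n_shuffles must be >= 1")
  taus <- as.numeric(grid)
  # thresholded graphs do not depend on the partition: compute them once
  graphs <- lapply(taus, function(tau) threshold_graph(fc, tau, mode = mode, rule = rule))
  snr_mat <- with_seed(seed, {
    t(vapply(seq_len(n_shuffles), function(i) {
      shp <- shuffle_partition(partition)
      vapply(graphs, function(g) snr(infer_sbm(block_counts(g, shp, cmax = cmax)))$snr,
             numeric(1))
    }, numeric(length(taus))))
  })
  summ <- data.frame(tau = taus,
                     min = apply(snr_mat, 2, min),
                     median = apply(snr_mat, 2, median),
                     max = apply(snr_mat, 2, max),
                     n_shuffles = n_shuffles, seed = seed)
  structure(list(snr = snr_mat, summary = summ, taus = taus, mode = mode,
                 n_shuffles = n_shuffles, seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("Partition-shuffle null ensemble: %d shuffles x %d thresholds (%s mode, seed %d)\n",
              x$n_shuffles, length(x$taus), x$mode, x$seed))
  cat(sprintf("  max null SNR over all shuffles and taus: %.4g%s\n", max(x$snr),
              if (max(x$snr) < 1) " (< 1: never weakly recoverable)" else ""))
  invisible(x)
}

#' Write a null-ensemble summary to CSV
#'
#' Columns: `tau`, `min`, `median`, `max`, `n_shuffles`, `seed`.
#'
#' @param x a [null_snr_distribution()] result.
#' @param path output path.
#' @export
write_null_summary <- function(x, path) {
  stopifnot(inherits(x, "null_ensemble"))
  utils::write.csv(x$summary, path, row.names = FALSE)
  invisible(path)
}

#' Ordering verdict across condition profiles and a null ensemble
#'
#' Checks the empirical prominence ordering `0 < SNR_null < SNR_task <
#' SNR_rest`: whether the maximum null SNR lies below each condition's SNR at
#' that condition's optimal threshold, and the pairwise ordering of the
#' conditions at their optima. Ties are reported, not errors.
#'
#' @param profiles named list of [snr_profile()] objects (e.g. `rest`,
#'   `task`), all on the same grid.
#' @param null_ensemble optional [null_snr_distribution()] on the same grid.
#' @return A list of class `snr_ordering` with per-condition optima
#'   (`tau_opt`, `max_snr`, `above_null`), the overall `max_null`, the
#'   condition `ordering` (names sorted by increasing max SNR) and `ties`.
#' @export
snr_ordering_report <- function(profiles, null_ensemble = NULL) {
  if (length(profiles) == 0L && is.null(null_ensemble)) stopf("nothing to compare")
  taus <- if (length(profiles)) profiles[[1L]]$tau else null_ensemble$taus
  for (p in profiles) if (!isTRUE(all.equal(p$tau, taus))) stopf("profiles are on different grids")
  if (!is.null(null_ensemble) && !isTRUE(all.equal(null_ensemble$taus, as.numeric(taus))))
    stopf("null ensemble is on a different grid")
  max_null <- if (is.null(null_ensemble)) NA_real_ else max(null_ensemble$snr)
  conds <- lapply(profiles, function(p) {
    tau_opt <- as.numeric(optimal_threshold(p))
    mx <- max(p$snr)
    list(tau_opt = tau_opt, max_snr = mx,
         above_null = if (is.na(max_null)) NA else mx > max_null)
  })
  mx <- vapply(conds, function(z) z$max_snr, 0)
  ord <- names(sort(mx))
  ties <- any(duplicated(mx))
  structure(list(conditions = conds, max_null = max_null, ordering = ord,
                 null_positive = if (is.na(max_null)) NA else max_null > 0,
                 ties = ties),
            class = "snr_ordering")
}

#' @export
print.snr_ordering <- function(x, ...) {
  if (!is.na(x$max_null))
    cat(sprintf("max null SNR: %.4g (positive: %s)\n", x$max_null, x$null_positive))
  for (nm in names(x$conditions)) {
    z <- x$conditions[[nm]]
    cat(sprintf("  %s: max SNR %.4g at tau_opt %.2f%s\n", nm, z$max_snr, z$tau_opt,
                if (isTRUE(z$above_null)) " (> null)" else ""))
  }
  if (length(x$ordering) > 1)
    cat("ordering by max SNR:", paste(x$ordering, collapse = " < "),
        if (x$ties) "(ties present)" else "", "\n")
  invisible(x)
}
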