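#' Threshold grid
#'
#' Discretized line-search grid over the threshold parameter tau in `[0, 1]`.
#'
#' @param step grid increment (default 0.05).
#' @param from,to grid limits within `[0, 1]`.
#' @return Numeric vector of strictly increasing thresholds, class
#'   `threshold_grid`.
#' @export
threshold_grid <- function(step = 0.05, from = 0, to = 1) {
  if (step <= 0 || from < 0 || to > 1 || from >= to) stopf("invalid grid specification")
  taus <- seq(from, to, by = step)
  if (taus[length(taus)] < to - 1e-12) taus <- c(taus, to)
  structure(round(taus, 10), class = "threshold_grid", step = step)
}

#' Group-average connectome of a cohort
#'
#' Entrywise arithmetic mean of the signed weights across subjects (no
#' Fisher-z transform); diagonal stays zero. Averaging damps subject-specific
#' fingerprints, so group-average entries are typically smaller in magnitude
#' than individual ones.
#'
#' @param cohort an [fc_cohort()].
#' @return A [weighted_connectome()].
#' @export
group_average <- function(cohort) {
  stopifnot(inherits(cohort, "fc_cohort"))
  g <- length(cohort$connectomes)
  m <- Reduce(`+`, lapply(cohort$connectomes, conn_matrix)) / g
  diag(m) <- 0
  weighted_connectome(m, cohort$node_ids,
                      correlation = cohort$connectomes[[1L]]$correlation %||% TRUE)
}

#' Threshold a weighted connectome
#'
#' Keeps node pairs whose coupling magnitude strictly exceeds tau
#' (`|w_uv| > tau`), so `tau = 0` keeps exactly the nonzero support and
#' `tau = 1` yields an empty graph. With `rule = "positive"` only `w_uv > tau`
#' survives (sensitivity analysis for signed couplings).
#'
#' @param fc a [weighted_connectome()].
#' @param tau threshold in `[0, 1]`.
#' @param mode `"binary"` returns the adjacency mask; `"weighted"` returns the
#'   retained signed weights (magnitudes are taken later, when accumulating
#'   block statistics).
#' @param rule `"magnitude"` (default) or `"positive"`.
#' @return A [binary_connectome()] or [weighted_connectome()].
#' @export
threshold_graph <- function(fc, tau, mode = c("binary", "weighted"),
                            rule = c("magnitude", "positive")) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  if (tau < 0 || tau > 1) stopf("tau must be in [0, 1]")
  w <- conn_matrix(fc)
  keep <- if (rule == "magnitude") abs(w) > tau else w > tau
  if (mode == "binary") {
    binary_connectome(keep * 1, fc$node_ids)
  } else {
    weighted_connectome(w * keep, fc$node_ids, correlation = FALSE)
  }
}

#' SNR profile across a threshold grid
#'
#' For each tau on the grid: threshold the connectome, accumulate block
#' statistics under the partition, infer the SBM parameters and compute the
#' SNR. Binary mode profiles `SNR(M_tau)` of the binarized graph (used for
#' weak-recoverability vetting); weighted mode profiles the prominence
#' `SNR(FC_tau)` computed from mean absolute couplings.
#'
#' @param fc a [weighted_connectome()].
#' @param partition a [node_partition()].
#' @param grid a [threshold_grid()].
#' @param mode `"binary"` or `"weighted"`.
#' @param source label recorded in the profile (e.g. `"group_average"` or a
#'   subject id).
#' @inheritParams block_counts
#' @inheritParams threshold_graph
#' @return A data frame of class `snr_profile` with columns `tau`, `snr`,
#'   `lambda1`, `lambda2` and attributes `mode` and `source`.
#' @export
snr_profile <- function(fc, partition, grid = threshold_grid(), mode = c("binary", "weighted"),
                        source = "group_average", rule = c("magnitude", "positive"),
                        cmax = c("pairs", "literal")) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  cmax <- match.arg(cmax)
  rows <- lapply(as.numeric(grid), function(tau) {
    g <- threshold_graph(fc, tau, mode = mode, rule = rule)
    v <- snr(infer_sbm(block_counts(g, partition, cmax = cmax)))
    c(tau = tau, snr = v$snr, lambda1 = v$lambda1, lambda2 = v$lambda2)
  })
  out <- as.data.frame(do.call(rbind, rows))
  structure(out, class = c("snr_profile", "data.frame"), mode = mode, source = source)
}

#' Weak-recoverability sub-interval of a binary SNR profile
#'
#' The sub-range `[a_w, b_w]` of the threshold grid over which the binarized
#' group-average graph satisfies the Kesten-Stigum condition SNR > 1:
#' `a_w` is the smallest and `b_w` the largest grid tau with SNR > 1. Returns
#' `NULL` when no grid point exceeds 1. If the super-threshold set is not
#' contiguous on the grid the interval is still reported as (min, max) with a
#' warning flag.
#'
#' @param profile a binary-mode [snr_profile()].
#' @return `NULL`, or a list with `a_w`, `b_w` and logical `contiguous`.
#' @export
weak_recoverability_interval <- function(profile) {
  stopifnot(inherits(profile, "snr_profile"))
  if (!identical(attr(profile, "mode"), "binary"))
    stopf("vetting uses the binarized graph; profile mode is '%s'", attr(profile, "mode"))
  above <- which(profile$snr > 1)
  if (length(above) == 0L) return(NULL)
  contiguous <- identical(above, seq(min(above), max(above)))
  if (!contiguous)
    warning("super-threshold set {tau: SNR > 1} is non-contiguous on the grid; reporting (min, max)")
  list(a_w = profile$tau[min(above)], b_w = profile$tau[max(above)], contiguous = contiguous)
}

#' SNR-maximizing threshold of a profile
#'
#' Argmax of SNR over the grid; ties break toward the smallest tau. An
#' all-zero profile is degenerate and returns the smallest grid point with
#' attribute `degenerate = TRUE`.
#'
#' @param profile an [snr_profile()].
#' @return The optimal tau (scalar, on the grid).
#' @export
optimal_threshold <- function(profile) {
  stopifnot(inherits(profile, "snr_profile"), nrow(profile) > 0)
  if (all(profile$snr == 0)) {
    return(structure(profile$tau[1L], degenerate = TRUE))
  }
  structure(profile$tau[which.max(profile$snr)], degenerate = FALSE)
}

#' Topology profile across a threshold grid
#'
#' Edge density (retained pairs over `n(n-1)/2`) and connected-component count
#' of the thresholded graph at each tau. Individual connectomes typically
#' fragment (components > 1) at smaller tau than the group average.
#'
#' @inheritParams snr_profile
#' @return Data frame with columns `tau`, `density`, `components`.
#' @export
topology_profile <- function(fc, grid = threshold_grid(), rule = c("magnitude", "positive")) {
  rule <- match.arg(rule)
  rows <- lapply(as.numeric(grid), function(tau) {
    a <- conn_matrix(threshold_graph(fc, tau, mode = "binary", rule = rule))
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(a, mode = "undirected"))$no
    c(tau = tau, density = graph_density(a), components = comp)
  })
  as.data.frame(do.call(rbind, rows))
}
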