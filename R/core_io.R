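#' Construct a weighted connectome
#'
#' A weighted connectome is a symmetric n x n matrix of functional couplings
#' (typically Pearson correlations between regional activity signals) with a
#' zero diagonal. Entries are dimensionless; when `correlation = TRUE` their
#' magnitudes must not exceed 1.
#'
#' @param weights numeric n x n matrix, symmetric within 1e-10.
#' @param node_ids character vector of n node identifiers; defaults to
#'   row names or `"1".."n"`.
#' @param correlation logical; enforce `|w| <= 1`.
#' @return An object of class `weighted_connectome` with fields `weights` and
#'   `node_ids`.
#' @seealso [read_connectome()], [binary_connectome()]
#' @export
weighted_connectome <- function(weights, node_ids = NULL, correlation = TRUE) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n < 2L || ncol(weights) != n) stopf("weights must be a square matrix with n >= 2")
  if (!is.numeric(weights) || anyNA(weights)) stopf("weights must be numeric with no missing values")
  if (max(abs(weights - t(weights))) > 1e-10) stopf("weights matrix is not symmetric (tolerance 1e-10)")
  if (correlation && max(abs(weights)) > 1 + 1e-12)
    stopf("correlation-type connectome has |entry| > 1 (max %.6g)", max(abs(weights)))
  diag(weights) <- 0
  node_ids <- as.character(node_ids %||% rownames(weights) %||% seq_len(n))
  if (length(node_ids) != n) stopf("node_ids length (%d) != n (%d)", length(node_ids), n)
  dimnames(weights) <- NULL
  structure(list(weights = weights, node_ids = node_ids, correlation = correlation),
            class = "weighted_connectome")
}

#' Construct a binary connectome
#'
#' @param adjacency n x n matrix with entries in `{0, 1}`, symmetric, zero
#'   diagonal (no self-loops).
#' @param node_ids character vector of node identifiers.
#' @return An object of class `binary_connectome` with fields `adjacency` and
#'   `node_ids`.
#' @export
binary_connectome <- function(adjacency, node_ids = NULL) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (n < 2L || ncol(adjacency) != n) stopf("adjacency must be a square matrix with n >= 2")
  if (!all(adjacency %in% c(0, 1))) stopf("binary connectome entries must be 0 or 1")
  storage.mode(adjacency) <- "double"
  if (max(abs(adjacency - t(adjacency))) > 0) stopf("adjacency is not symmetric")
  diag(adjacency) <- 0
  node_ids <- as.character(node_ids %||% rownames(adjacency) %||% seq_len(n))
  if (length(node_ids) != n) stopf("node_ids length (%d) != n (%d)", length(node_ids), n)
  dimnames(adjacency) <- NULL
  structure(list(adjacency = adjacency, node_ids = node_ids), class = "binary_connectome")
}

#' @export
print.weighted_connectome <- function(x, ...) {
  cat(sprintf("Weighted connectome: %d nodes, density %.3f, |w| in [%.3g, %.3g]\n",
              conn_n(x), graph_density(conn_matrix(x) != 0),
              min(abs(conn_matrix(x)[upper.tri(conn_matrix(x))])),
              max(abs(conn_matrix(x)))))
  invisible(x)
}

#' @export
print.binary_connectome <- function(x, ...) {
  cat(sprintf("Binary connectome: %d nodes, %d edges, density %.3f\n",
              conn_n(x), sum(conn_matrix(x)) / 2, graph_density(conn_matrix(x))))
  invisible(x)
}

#' Extract the numeric matrix of a connectome
#'
#' Accessor shared by both connectome flavours: the `weights` matrix of a
#' [weighted_connectome()] or the `adjacency` matrix of a
#' [binary_connectome()].
#'
#' @param x a connectome object.
#' @return The underlying n x n numeric matrix.
#' @export
conn_matrix <- function(x) {
  if (inherits(x, "weighted_connectome")) x$weights
  else if (inherits(x, "binary_connectome")) x$adjacency
  else stopf("not a connectome object")
}

conn_n <- function(x) length(x$node_ids)

graph_density <- function(a) {
  n <- nrow(a)
  sum(a[upper.tri(a)] != 0) / (n * (n - 1) / 2)
}

#' Construct a node partition
#'
#' Maps each of n nodes to one of k community labels. Internally labels are
#' re-encoded to integers `1..k` in order of first appearance; the original
#' label strings are retained in `labels`.
#'
#' @param sigma vector of community labels, one per node (any atomic type).
#' @param node_ids optional node identifiers (defaults to `"1".."n"`).
#' @return An object of class `node_partition` with fields `sigma` (integer
#'   codes 1..k), `k`, `omega` (community sizes), `labels` (original label per
#'   community) and `node_ids`.
#' @examples
#' p <- node_partition(c("VIS", "VIS", "DMN"))
#' p$omega # 2 1
#' @export
node_partition <- function(sigma, node_ids = NULL) {
  if (length(sigma) < 1L) stopf("empty partition")
  lev <- unique(as.character(sigma))
  code <- match(as.character(sigma), lev)
  k <- length(lev)
  omega <- as.integer(tabulate(code, nbins = k))
  stopifnot(all(omega >= 1L), sum(omega) == length(sigma))
  node_ids <- as.character(node_ids %||% seq_along(sigma))
  if (length(node_ids) != length(sigma)) stopf("node_ids length mismatch")
  structure(list(sigma = as.integer(code), k = k, omega = omega,
                 labels = lev, node_ids = node_ids),
            class = "node_partition")
}

#' @export
print.node_partition <- function(x, ...) {
  cat(sprintf("Partition: %d nodes in %d communities (sizes %s)\n",
              length(x$sigma), x$k, paste(x$omega, collapse = ", ")))
  invisible(x)
}

#' Construct a cohort of connectomes
#'
#' @param connectomes list of [weighted_connectome()] objects sharing node ids
#'   in identical order.
#' @param subject_ids optional subject labels (defaults to `"s1".."sG"`).
#' @param condition free-text tag (e.g. `"rest"`, `"task"`).
#' @return An object of class `fc_cohort`.
#' @export
fc_cohort <- function(connectomes, subject_ids = NULL, condition = "unspecified") {
  if (length(connectomes) < 1L) stopf("a cohort needs at least one connectome")
  if (!all(vapply(connectomes, inherits, TRUE, "weighted_connectome")))
    stopf("all cohort members must be weighted connectomes")
  ids <- connectomes[[1L]]$node_ids
  for (i in seq_along(connectomes)) {
    if (!identical(connectomes[[i]]$node_ids, ids))
      stopf("cohort member %d has mismatched node ids/order", i)
  }
  subject_ids <- as.character(subject_ids %||% paste0("s", seq_along(connectomes)))
  if (length(subject_ids) != length(connectomes)) stopf("subject_ids length mismatch")
  structure(list(connectomes = connectomes, subject_ids = subject_ids,
                 condition = condition, node_ids = ids),
            class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat(sprintf("Cohort '%s': %d subjects x %d nodes\n",
              x$condition, length(x$connectomes), length(x$node_ids)))
  invisible(x)
}

#' Read a connectome from a delimited matrix file
#'
#' Reads a square numeric matrix from a comma- or tab-delimited file
#' (delimiter auto-detected). An optional header row and leading id column
#' supply node identifiers. The matrix is symmetrized as `(A + t(A))/2` when
#' the maximum asymmetry is at most 1e-8 (an error otherwise) and the diagonal
#' is forced to zero.
#'
#' @param path file path.
#' @param kind `"weighted"` or `"binary"`.
#' @param correlation for `kind = "weighted"`: require `|entry| <= 1`.
#' @return A [weighted_connectome()] or [binary_connectome()].
#' @export
read_connectome <- function(path, kind = c("weighted", "binary"), correlation = TRUE) {
  kind <- match.arg(kind)
  sep <- detect_sep(path)
  first <- strsplit(readLines(path, n = 1L, warn = FALSE), sep, fixed = TRUE)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  df <- read.table(path, sep = sep, header = has_header, check.names = FALSE,
                   stringsAsFactors = FALSE, row.names = NULL)
  node_ids <- NULL
  # leading non-numeric column carries node ids
  if (ncol(df) > 0 && !is.numeric(df[[1L]]) &&
      anyNA(suppressWarnings(as.numeric(df[[1L]])))) {
    node_ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  if (has_header && is.null(node_ids)) node_ids <- colnames(df)
  m <- as.matrix(df)
  if (!is.numeric(m)) stopf("non-numeric cells in %s", path)
  if (nrow(m) != ncol(m)) stopf("matrix in %s is not square (%d x %d)", path, nrow(m), ncol(m))
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8) stopf("matrix in %s is asymmetric beyond tolerance (max |A - t(A)| = %.3g)", path, asym)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (kind == "binary") {
    if (!all(m %in% c(0, 1))) stopf("binary connectome %s has entries outside {0, 1}", path)
    binary_connectome(m, node_ids)
  } else {
    weighted_connectome(m, node_ids, correlation = correlation)
  }
}

#' Write a connectome to a delimited matrix file
#'
#' Numbers are written with 15 significant digits. A header row of node ids is
#' included only when the ids are not the default numeric sequence (numeric
#' headers would be indistinguishable from a data row). Reading the file back
#' reproduces the written values exactly.
#'
#' @param x a connectome object.
#' @param path output path; extension `.csv` selects comma, otherwise tab.
#' @export
write_connectome <- function(x, path) {
  m <- conn_matrix(x)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  lines <- vapply(seq_len(nrow(m)), function(i) paste(fmt_num(m[i, ]), collapse = sep), "")
  if (!identical(x$node_ids, as.character(seq_len(nrow(m)))) &&
      anyNA(suppressWarnings(as.numeric(x$node_ids))))
    lines <- c(paste(x$node_ids, collapse = sep), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read a node partition from a two-column file
#'
#' The file has two delimited columns: node id, community label. Every node in
#' `node_ids` must appear exactly once. Labels are re-encoded to `1..k` in
#' first-appearance order (by `node_ids` order).
#'
#' @param path file path (comma- or tab-delimited, auto-detected; optional
#'   header).
#' @param node_ids ordered node identifiers the partition must cover.
#' @return A [node_partition()].
#' @export
read_partition <- function(path, node_ids) {
  sep <- detect_sep(path)
  first <- strsplit(readLines(path, n = 1L, warn = FALSE), sep, fixed = TRUE)[[1L]]
  has_header <- identical(tolower(first[1L]), "node") || identical(tolower(first[1L]), "node_id")
  df <- read.table(path, sep = sep, header = has_header, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) != 2L) stopf("partition file %s must have exactly two columns", path)
  node_ids <- as.character(node_ids)
  if (anyDuplicated(df[[1L]])) stopf("duplicate node id in partition file: %s",
                                     df[[1L]][anyDuplicated(df[[1L]])])
  idx <- match(node_ids, df[[1L]])
  if (anyNA(idx)) stopf("partition file is missing node(s): %s",
                        paste(node_ids[is.na(idx)], collapse = ", "))
  if (nrow(df) != length(node_ids)) stopf("partition file lists unknown nodes")
  node_partition(df[[2L]][idx], node_ids = node_ids)
}

#' Write a node partition to a two-column tab-delimited file
#'
#' @param partition a [node_partition()].
#' @param path output path.
#' @export
write_partition <- function(partition, path) {
  writeLines(paste(partition$node_ids, partition$labels[partition$sigma], sep = "\t"), path)
  invisible(path)
}

#' Read a cohort from a manifest file
#'
#' The manifest is YAML or JSON with fields `condition`, `files` (connectome
#' matrix paths, relative paths resolved against the manifest directory) and
#' optional `subject_ids`.
#'
#' @param path manifest path (`.yaml`/`.yml`/`.json`).
#' @param correlation passed to [read_connectome()].
#' @return An [fc_cohort()].
#' @export
read_cohort <- function(path, correlation = TRUE) {
  man <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(man$files) || length(man$files) < 1L) stopf("manifest %s lists no files", path)
  base <- dirname(path)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$files), man$files, file.path(base, man$files))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stopf("manifest file(s) not found: %s", paste(missing, collapse = ", "))
  conns <- lapply(paths, read_connectome, kind = "weighted", correlation = correlation)
  fc_cohort(conns, subject_ids = man$subject_ids,
            condition = man$condition %||% "unspecified")
}

#' Validate a cohort against a partition
#'
#' Checks that every cohort member and the partition share the same node count
#' and node order, and summarizes the inputs.
#'
#' @param cohort an [fc_cohort()].
#' @param partition a [node_partition()].
#' @return Invisibly, a list report with `n`, `gamma`, `k`, `omega` and the
#'   range of edge densities across members. Errors on any mismatch.
#' @export
validate_cohort <- function(cohort, partition) {
  stopifnot(inherits(cohort, "fc_cohort"), inherits(partition, "node_partition"))
  if (!identical(cohort$node_ids, partition$node_ids))
    stopf("node ids/order differ between cohort and partition")
  dens <- vapply(cohort$connectomes, function(x) graph_density(conn_matrix(x) != 0), 0)
  report <- list(n = length(cohort$node_ids), gamma = length(cohort$connectomes),
                 k = partition$k, omega = partition$omega,
                 density_range = range(dens), condition = cohort$condition)
  invisible(report)
}
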