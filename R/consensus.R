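#' Co-assignment (consensus) matrix over clustering runs
#'
#' Entry `(i, j)` is the fraction of runs in which samples `i` and `j`
#' received the same cluster label.  The matrix is symmetric with a
#' unit diagonal.
#'
#' @param labelings List of integer label vectors of equal length (one
#'   per stochastic run), or a matrix with one run per column.
#' @return `n x n` numeric matrix with entries in `[0, 1]`.
#' @export
consensus_matrix <- function(labelings) {
  if (is.matrix(labelings))
    labelings <- lapply(seq_len(ncol(labelings)), function(j) labelings[, j])
  if (!is.list(labelings) || length(labelings) < 1L)
    stop("`labelings` must be a nonempty list of label vectors", call. = FALSE)
  n <- length(labelings[[1L]])
  lens <- lengths(labelings)
  if (any(lens != n))
    stop("all labelings must have the same length", call. = FALSE)
  C <- matrix(0, n, n)
  for (lab in labelings)
    C <- C + outer(lab, lab, `==`)
  C <- C / length(labelings)
  nm <- names(labelings[[1L]])
  if (!is.null(nm)) dimnames(C) <- list(nm, nm)
  C
}

#' Final consensus labels from a co-assignment matrix
#'
#' Cuts an average-linkage hierarchical clustering of the dissimilarity
#' `1 - C` into `k` groups (the extraction used throughout the
#' consensus-clustering literature on expression subtyping; the
#' co-clustering model itself does not prescribe one).
#'
#' @param C Consensus matrix from [consensus_matrix()].
#' @param k Number of final clusters, `1 <= k <= nrow(C)`.
#' @return Integer vector of cluster labels in `1..k`.
#' @export
consensus_labels <- function(C, k) {
  C <- .as_expr_matrix(C, "C")
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8)
    stop("`C` must be a symmetric square consensus matrix", call. = FALSE)
  k <- .check_count(k, "k")
  if (k > nrow(C)) stop("`k` must not exceed nrow(C)", call. = FALSE)
  if (k == nrow(C)) return(seq_len(nrow(C)))
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  unname(stats::cutree(hc, k = k))
}

#' Consensus of repeated MBI co-clustering runs
#'
#' Runs [mbi_cocluster()] `n_runs` times from independent random
#' starts, aggregates the column (sample) labelings into a
#' co-assignment matrix, and extracts `k` final sample clusters.  Two
#' samples of the same subtype are expected to travel together across
#' runs, so their co-assignment frequency approaches 1.
#'
#' @param A Numeric matrix (typically the sparse foreground `Y`).
#' @param k1,k2 MBI row / column group counts.
#' @param n_runs Number of independent MBI runs (default 10).
#' @param k Number of final consensus clusters (default `k2`).
#' @param seed Optional integer seed.
#' @param restarts Restarts within each run (default 1, so runs are
#'   genuinely independent stochastic replicates).
#' @param stability_threshold Clusters with mean within-cluster
#'   co-assignment at or above this value are flagged consistent
#'   (default 0.8).
#' @return An object of class `"consensus_result"`: `coassignment`,
#'   `final_labels`, `n_runs`, overall `stability` (mean within-cluster
#'   co-assignment over off-diagonal pairs), per-cluster
#'   `cluster_stability`, `consistent` flags, the per-run `runs`
#'   (all `"cocluster"` objects) and `run_labelings`.
#' @export
mbi_consensus <- function(A, k1, k2, n_runs = 10L, k = k2, seed = NULL,
                          restarts = 1L, stability_threshold = 0.8) {
  A <- .as_expr_matrix(A, "A")
  n_runs <- .check_count(n_runs, "n_runs")
  if (!is.null(seed)) set.seed(seed)
  runs <- lapply(seq_len(n_runs), function(r)
    mbi_cocluster(A, k1, k2, restarts = restarts, seed = NULL))
  labelings <- lapply(runs, `[[`, "col_labels")
  C <- consensus_matrix(labelings)
  dimnames(C) <- list(colnames(A), colnames(A))
  final <- consensus_labels(C, k)
  stab <- .cluster_stability(C, final, k)
  structure(list(
    coassignment = C, final_labels = final, n_runs = n_runs,
    stability = stab$overall, cluster_stability = stab$per_cluster,
    consistent = stab$per_cluster >= stability_threshold,
    stability_threshold = stability_threshold,
    runs = runs, run_labelings = labelings,
    sample_ids = colnames(A)
  ), class = "consensus_result")
}

# mean within-cluster coassignment over off-diagonal pairs; singleton
# clusters are perfectly stable by convention
.cluster_stability <- function(C, labels, k) {
  per <- vapply(seq_len(k), function(g) {
    idx <- which(labels == g)
    if (length(idx) < 2L) return(1)
    B <- C[idx, idx, drop = FALSE]
    (sum(B) - length(idx)) / (length(idx)^2 - length(idx))
  }, numeric(1))
  pair_counts <- vapply(seq_len(k), function(g) {
    s <- sum(labels == g); s * (s - 1)
  }, numeric(1))
  overall <- if (sum(pair_counts) == 0) 1 else
    sum(per * pair_counts) / sum(pair_counts)
  list(overall = overall, per_cluster = per)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus over %d MBI runs: %d samples, %d final clusters\n",
              x$n_runs, length(x$final_labels),
              length(unique(x$final_labels))))
  cat(sprintf("  overall stability: %.3f; cluster sizes: %s\n",
              x$stability,
              paste(tabulate(x$final_labels), collapse = ", ")))
  cat(sprintf("  consistent clusters (stability >= %.2f): %d of %d\n",
              x$stability_threshold, sum(x$consistent), length(x$consistent)))
  invisible(x)
}
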