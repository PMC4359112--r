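#' Full subtype-discovery pipeline: decompose, co-cluster, consensus
#'
#' Runs the two-stage framework end to end on a genes-by-samples
#' matrix: (1) common-background / sparse-foreground decomposition by
#' ADMM at noise budget `delta`; (2) `n_runs` stochastic MBI
#' checkerboard co-clusterings of the foreground; (3) consensus
#' aggregation of the sample labelings into final clusters.
#'
#' @param M Numeric genes-by-samples matrix.
#' @param k1,k2 Row (gene) and column (sample) group counts for MBI.
#' @param delta Noise budget of the decomposition (default 0).
#' @param n_runs Number of MBI runs entering the consensus
#'   (default 10).
#' @param seed Optional integer seed for the stochastic runs.
#' @param gamma,tol,max_iter Passed to [decompose_common_vector()].
#' @param ... Further arguments to [mbi_consensus()].
#' @return An object of class `"sparcoc_fit"`: the `csd` decomposition,
#'   the `consensus` result, the best single run (`best_run`), and the
#'   final `row_labels` (from the best run) and `col_labels` (consensus).
#' @examples
#' toy <- generate_fig1_toy(seed = 1)
#' fit <- sparcoc_cluster(toy$M, k1 = 2, k2 = 2, seed = 1, tol = 1e-9)
#' fit$col_labels
#' @export
sparcoc_cluster <- function(M, k1, k2, delta = 0, n_runs = 10L,
                            seed = NULL, gamma = NULL, tol = 1e-7,
                            max_iter = 5000L, ...) {
  csd <- decompose_common_vector(M, delta = delta, gamma = gamma,
                                 tol = tol, max_iter = max_iter)
  cons <- mbi_consensus(csd$Y, k1 = k1, k2 = k2, n_runs = n_runs,
                        seed = seed, ...)
  best <- cons$runs[[which.min(vapply(cons$runs, `[[`, numeric(1),
                                      "objective"))]]
  structure(list(csd = csd, consensus = cons, best_run = best,
                 row_labels = best$row_labels,
                 col_labels = cons$final_labels,
                 k1 = k1, k2 = k2),
            class = "sparcoc_fit")
}

#' @export
print.sparcoc_fit <- function(x, ...) {
  cat("Two-stage decomposition + co-clustering fit\n")
  print(x$csd)
  print(x$consensus)
  invisible(x)
}
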