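#' The 20 x 20 worked example: rank-one background plus one 5 x 5 block
#'
#' Regenerates the package's canonical toy instance: a 20 x 20
#' rank-one background whose columns all equal a per-gene baseline
#' vector spanning exactly \[1, 100\], plus a foreground that is zero
#' everywhere except a 5 x 5 co-cluster (rows 10-14, columns 10-14,
#' 1-based inclusive) of constant value 10.  No noise is added, so
#' `M = background + foreground` exactly and `M` has rank 2.
#'
#' The background is the outer product of the seeded baseline vector
#' with the all-one row vector -- i.e. every sample shares the same
#' per-gene background, which is precisely the structure the
#' common-vector decomposition model posits and removes.  At
#' `delta = 0` the decomposition recovers both planted components
#' exactly (the optimal background entry of each gene is its row
#' median, which the 5-of-20 planted block cannot move).
#'
#' @param seed Integer seed; any seed yields an instance with the same
#'   structural properties.
#' @return A `"planted_instance"`: `M` (with gene/sample ids),
#'   `background`, `foreground`, `noise_sd = 0`, `row_truth`,
#'   `col_truth` (group 1 = the planted block), and `seed`.
#' @examples
#' toy <- generate_fig1_toy(seed = 7)
#' qr(toy$M)$rank
#' @export
generate_fig1_toy <- function(seed = 1L) {
  seed <- as.integer(seed)
  set.seed(seed)
  u <- stats::runif(20)
  x <- 1 + 99 * (u - min(u)) / (max(u) - min(u))   # spans [1, 100] exactly
  background <- x %o% rep(1, 20)
  foreground <- matrix(0, 20, 20)
  foreground[10:14, 10:14] <- 10
  M <- expression_matrix(background + foreground)
  dimnames(background) <- dimnames(foreground) <- dimnames(M)
  row_truth <- ifelse(seq_len(20) %in% 10:14, 1L, 2L)
  col_truth <- ifelse(seq_len(20) %in% 10:14, 1L, 2L)
  structure(list(M = M, background = background, foreground = foreground,
                 noise_sd = 0, row_truth = row_truth, col_truth = col_truth,
                 seed = seed),
            class = "planted_instance")
}

#' General planted background + checkerboard generator
#'
#' Simulates a genes-by-samples matrix as the sum of a low-rank
#' background, a blockwise-constant foreground on a balanced random
#' row/column partition, and i.i.d. Gaussian noise.  Ground-truth
#' labels are returned for recovery scoring.
#'
#' The rank-one component of the background is a shared per-gene
#' baseline drawn uniformly on \[1, 100\] (times the all-one row
#' vector), matching the common-vector decomposition model; additional
#' rank components (when `background_rank > 1`) are standard-normal
#' outer products.
#'
#' @param m,n Number of genes (rows) and samples (columns).
#' @param k1,k2 Number of planted row / column groups (`k1 <= m`,
#'   `k2 <= n`); rows and columns are partitioned into balanced groups
#'   uniformly at random.
#' @param block_effects `k1 x k2` matrix; entry `(g, h)` is the
#'   constant foreground value added on block `(g, h)` (0 = no
#'   signal).  A scalar is accepted when `k1 = k2 = 1`.
#' @param background_rank Rank of the background (default 1).
#' @param noise_sd Standard deviation of the Gaussian noise
#'   (default 0).
#' @param seed Integer seed.
#' @return A `"planted_instance"` (see [generate_fig1_toy()]).
#' @export
generate_planted <- function(m, n, k1, k2, block_effects,
                             background_rank = 1L, noise_sd = 0,
                             seed = 1L) {
  m <- .check_count(m, "m"); n <- .check_count(n, "n")
  k1 <- .check_count(k1, "k1"); k2 <- .check_count(k2, "k2")
  if (k1 > m || k2 > n)
    stop("`k1`/`k2` must not exceed the matrix dimensions", call. = FALSE)
  background_rank <- .check_count(background_rank, "background_rank")
  .check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  block_effects <- matrix(as.numeric(block_effects), k1, k2)
  seed <- as.integer(seed)
  set.seed(seed)

  row_truth <- sample(rep_len(seq_len(k1), m))
  col_truth <- sample(rep_len(seq_len(k2), n))
  background <- stats::runif(m, 1, 100) %o% rep(1, n)
  if (background_rank > 1L)
    for (l in seq_len(background_rank - 1L))
      background <- background + stats::rnorm(m) %o% stats::rnorm(n)
  foreground <- matrix(block_effects[cbind(rep(row_truth, n),
                                           rep(col_truth, each = m))], m, n)
  noise <- if (noise_sd > 0) matrix(stats::rnorm(m * n, 0, noise_sd), m, n)
           else matrix(0, m, n)
  M <- expression_matrix(background + foreground + noise)
  dimnames(background) <- dimnames(foreground) <- dimnames(M)
  structure(list(M = M, background = background, foreground = foreground,
                 noise_sd = noise_sd, row_truth = row_truth,
                 col_truth = col_truth, seed = seed),
            class = "planted_instance")
}

#' @export
print.planted_instance <- function(x, ...) {
  cat(sprintf("Planted instance: %d x %d, %d row / %d column groups, noise sd %g (seed %d)\n",
              nrow(x$M), ncol(x$M), length(unique(x$row_truth)),
              length(unique(x$col_truth)), x$noise_sd, x$seed))
  invisible(x)
}
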