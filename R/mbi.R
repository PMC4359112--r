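#' Block centroids of a checkerboard co-clustering
#'
#' Given row groups `1..k1` and column groups `1..k2`, returns the
#' `k1 x k2` matrix of block means (the "core" of the checkerboard
#' model).  Empty blocks get centroid 0.
#'
#' @param A Numeric matrix.
#' @param row_labels Integer vector, one label in `1..k1` per row.
#' @param col_labels Integer vector, one label in `1..k2` per column.
#' @param k1,k2 Number of row / column groups.
#' @return `k1 x k2` numeric matrix of block centroids.
#' @export
compute_block_centroids <- function(A, row_labels, col_labels, k1, k2) {
  A <- .as_expr_matrix(A, "A")
  .check_labels(row_labels, nrow(A), k1, "row_labels")
  .check_labels(col_labels, ncol(A), k2, "col_labels")
  # group sums via rowsum in each direction, then fill absent groups
  rs <- rowsum(A, row_labels)                       # present row groups x n
  R <- matrix(0, k1, ncol(A))
  R[as.integer(rownames(rs)), ] <- rs
  cs <- t(rowsum(t(R), col_labels))                 # k1 x present col groups
  S <- matrix(0, k1, k2)
  S[, as.integer(colnames(cs))] <- cs
  cnt <- tabulate(row_labels, k1) %o% tabulate(col_labels, k2)
  core <- S
  core[cnt > 0] <- S[cnt > 0] / cnt[cnt > 0]
  core
}

#' Squared-error objective of a co-clustering
#'
#' Sum over all matrix entries of the squared deviation from the
#' centroid of the assigned (row group, column group) block.  Zero if
#' and only if `A` is exactly blockwise constant under the labels.
#'
#' @param A Numeric matrix.
#' @param clustering A `"cocluster"` object (see [mbi_cocluster()]), or
#'   any list with `row_labels`, `col_labels`, `core`, `k1`, `k2`.
#' @return Nonnegative scalar.
#' @export
cocluster_objective <- function(A, clustering) {
  A <- .as_expr_matrix(A, "A")
  rl <- clustering$row_labels
  cl <- clustering$col_labels
  .check_labels(rl, nrow(A), clustering$k1, "row_labels")
  .check_labels(cl, ncol(A), clustering$k2, "col_labels")
  .block_sse(A, rl, cl, clustering$core)
}

.block_sse <- function(A, rl, cl, core) {
  sum((A - core[rl, cl, drop = FALSE])^2)
}

.check_labels <- function(lab, len, k, name) {
  if (length(lab) != len)
    stop(sprintf("`%s` must have length %d", name, len), call. = FALSE)
  if (anyNA(lab) || any(lab < 1L) || any(lab > k) || any(lab != round(lab)))
    stop(sprintf("`%s` must contain integers in 1..%d", name, k),
         call. = FALSE)
  invisible(as.integer(lab))
}

#' Checkerboard co-clustering by Maximum Block Improvement
#'
#' Partitions the rows of `A` into `k1` groups and the columns into
#' `k2` groups so that `A` is approximated by a `k1 x k2` grid of
#' constant blocks, minimizing the squared-error objective of
#' [cocluster_objective()].  The exact block model attains objective 0
#' whenever perfect co-clusters exist.
#'
#' The Maximum Block Improvement (MBI) search treats the row labels,
#' the column labels and the core (block centroids) as blocks of
#' variables.  At each step it evaluates the objective decrease from
#' re-optimizing candidate blocks -- all row labels with columns and
#' core fixed (rows are separable given the rest), all column labels
#' likewise, the core alone by block means, and two joint moves that
#' refit one side's labels together with the core (equivalent to a
#' weighted k-means on the block-compressed matrix; these escape the
#' partial optima where labels and a stale core lock each other in) --
#' and commits only the block update with the maximum improvement.
#' The committed objective sequence is therefore monotonically
#' nonincreasing; the search stops when no block improves by more than
#' `1e-12` or at `max_iter`.
#'
#' Initialization is uniform random labels; `restarts` independent
#' starts are run and the best objective kept.  Ties in a label's best
#' group go to the lowest group index.  If a label update would empty a
#' group, the worst-fit row (or column) is reassigned to it so the
#' group counts stay honest; such a repaired candidate is only
#' committed if it still improves the objective.
#'
#' @param A Numeric matrix (typically a sparse foreground `Y` from
#'   [decompose_common_vector()]).
#' @param k1 Number of row (gene) groups, `1 <= k1 <= nrow(A)`.
#' @param k2 Number of column (sample) groups, `1 <= k2 <= ncol(A)`.
#' @param restarts Number of random restarts (default 10); the best
#'   objective is returned.
#' @param seed Optional integer seed for reproducible restarts.
#' @param max_iter Cap on committed updates per restart (default 500).
#' @return An object of class `"cocluster"`: `row_labels`,
#'   `col_labels`, `core`, `objective`, `k1`, `k2`,
#'   `proximity = "squared_error"`, the per-restart objectives
#'   (`restart_objectives`) and the committed-objective `trace` of the
#'   winning restart.
#' @examples
#' toy <- generate_fig1_toy(seed = 1)
#' fit <- decompose_common_vector(toy$M, delta = 0, tol = 1e-9)
#' cc <- mbi_cocluster(fit$Y, k1 = 2, k2 = 2, seed = 1)
#' table(cc$row_labels)
#' @export
mbi_cocluster <- function(A, k1, k2, restarts = 10L, seed = NULL,
                          max_iter = 500L) {
  A <- .as_expr_matrix(A, "A")
  m <- nrow(A); n <- ncol(A)
  k1 <- .check_count(k1, "k1"); k2 <- .check_count(k2, "k2")
  if (k1 > m) stop("`k1` must not exceed nrow(A)", call. = FALSE)
  if (k2 > n) stop("`k2` must not exceed ncol(A)", call. = FALSE)
  restarts <- .check_count(restarts, "restarts")
  max_iter <- .check_count(max_iter, "max_iter")
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  restart_obj <- numeric(restarts)
  for (r in seq_len(restarts)) {
    run <- .mbi_single(A, k1, k2, max_iter)
    restart_obj[r] <- run$objective
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  structure(list(
    row_labels = best$row_labels, col_labels = best$col_labels,
    core = best$core, objective = best$objective,
    k1 = k1, k2 = k2, proximity = "squared_error",
    trace = best$trace, restart_objectives = restart_obj,
    gene_ids = rownames(A), sample_ids = colnames(A)
  ), class = "cocluster")
}

# one MBI run from a random start
.mbi_single <- function(A, k1, k2, max_iter) {
  m <- nrow(A); n <- ncol(A)
  rl <- sample.int(k1, m, replace = TRUE)
  cl <- sample.int(k2, n, replace = TRUE)
  core <- compute_block_centroids(A, rl, cl, k1, k2)
  obj <- .block_sse(A, rl, cl, core)
  trace <- obj
  eps <- 1e-12

  for (it in seq_len(max_iter)) {
    # exact single-block moves
    rows <- .best_labels(A, core[, cl, drop = FALSE], k1, by_row = TRUE)
    cols <- .best_labels(A, core[rl, , drop = FALSE], k2, by_row = FALSE)
    core_new <- compute_block_centroids(A, rl, cl, k1, k2)
    obj_core <- .block_sse(A, rl, cl, core_new)
    # joint (labels, core) moves: refit one side's labels together with
    # the core, via weighted k-means on the block-compressed matrix
    rl_j <- .refit_side(A, cl, k1, k2)
    core_rj <- compute_block_centroids(A, rl_j, cl, k1, k2)
    obj_rj <- .block_sse(A, rl_j, cl, core_rj)
    cl_j <- .refit_side(t(A), rl, k2, k1)
    core_cj <- compute_block_centroids(A, rl, cl_j, k1, k2)
    obj_cj <- .block_sse(A, rl, cl_j, core_cj)

    gains <- obj - c(rows$objective, cols$objective, obj_core,
                     obj_rj, obj_cj)
    pick <- which.max(gains)
    if (gains[pick] <= eps) break
    if (pick == 1L) {
      rl <- rows$labels; obj <- rows$objective
    } else if (pick == 2L) {
      cl <- cols$labels; obj <- cols$objective
    } else if (pick == 3L) {
      core <- core_new; obj <- obj_core
    } else if (pick == 4L) {
      rl <- rl_j; core <- core_rj; obj <- obj_rj
    } else {
      cl <- cl_j; core <- core_cj; obj <- obj_cj
    }
    trace <- c(trace, obj)
  }
  list(row_labels = rl, col_labels = cl, core = core,
       objective = obj, trace = trace)
}

# Jointly re-optimize the row labels and the core for fixed column
# labels `cl`.  Collapsing columns to per-group means turns the block
# model into k-means on the m x k2 matrix of row block-means with
# column weights sqrt(n_h) (n_h = column-group sizes): the co-cluster
# squared error differs from that k-means criterion only by a constant.
# k-means is itself solved heuristically (multiple starts), so the move
# is a candidate like any other -- it is only committed if it improves.
.refit_side <- function(A, cl, k_fit, k_other) {
  n_h <- tabulate(cl, k_other)
  S <- t(rowsum(t(A), cl))
  Sfull <- matrix(0, nrow(A), k_other)
  Sfull[, as.integer(colnames(S))] <- S
  feat <- sweep(Sfull, 2, pmax(n_h, 1), "/")
  W <- sweep(feat, 2, sqrt(n_h), "*")
  k_eff <- min(k_fit, nrow(unique(W)))
  tryCatch(
    suppressWarnings(stats::kmeans(W, centers = k_eff, nstart = 5L)$cluster),
    error = function(e) sample.int(k_fit, nrow(A), replace = TRUE)
  )
}

# Optimal group per row (or column) of A against fixed expanded centroids.
# `centers` is k x n for rows (row g = centroid profile across columns)
# or m x k for columns.  Empty groups are repaired by moving the single
# worst-fit item into each.
.best_labels <- function(A, centers, k, by_row) {
  if (by_row) {
    cost <- vapply(seq_len(k), function(g)
      rowSums((A - matrix(centers[g, ], nrow(A), ncol(A), byrow = TRUE))^2),
      numeric(nrow(A)))
  } else {
    cost <- vapply(seq_len(k), function(g)
      colSums((A - matrix(centers[, g], nrow(A), ncol(A)))^2),
      numeric(ncol(A)))
  }
  cost <- matrix(cost, ncol = k)
  lab <- max.col(-cost, ties.method = "first")   # ties -> lowest index
  # empty-group repair: donate the worst-fit item to each empty group,
  # never emptying the donor's group in the process
  empty <- which(tabulate(lab, k) == 0L)
  for (g in empty) {
    fit <- cost[cbind(seq_along(lab), lab)]
    ord <- order(fit, decreasing = TRUE)
    for (i in ord) {
      if (sum(lab == lab[i]) > 1L) { lab[i] <- g; break }
    }
  }
  objective <- sum(cost[cbind(seq_along(lab), lab)])
  list(labels = lab, objective = objective)
}

#' @export
print.cocluster <- function(x, ...) {
  cat(sprintf("MBI checkerboard co-clustering: %d row groups x %d column groups\n",
              x$k1, x$k2))
  cat(sprintf("  objective (squared error): %g after %d committed updates\n",
              x$objective, length(x$trace) - 1L))
  cat(sprintf("  row group sizes: %s\n",
              paste(tabulate(x$row_labels, x$k1), collapse = ", ")))
  cat(sprintf("  column group sizes: %s\n",
              paste(tabulate(x$col_labels, x$k2), collapse = ", ")))
  invisible(x)
}

#' Local search over the number of row and column groups
#'
#' Neither the checkerboard model nor the data fix `(k1, k2)`; this
#' helper hill-climbs over the grid `k1_range x k2_range`, scoring each
#' candidate by the best MBI objective over `restarts` plus a
#' complexity penalty `log(m*n) * k1 * k2` (a BIC-style charge per
#' block; the package's own choice, since the block model gives no
#' criterion).  Moves go to the best-scoring neighbour that changes
#' each of `k1`, `k2` by at most 1 (including diagonal moves, which are
#' needed when single-coordinate splits yield no gain, e.g. on a
#' symmetric 2 x 2 checkerboard with flat marginal means).
#'
#' @param A Numeric matrix.
#' @param k1_range,k2_range Candidate ranges (integer vectors).
#' @param restarts Restarts per candidate (default 10).
#' @param seed Optional seed; candidate runs derive deterministic
#'   per-candidate seeds from it.
#' @return List with the selected `k1`, `k2`, the winning
#'   `clustering`, its penalized `score` and the `visited` score table.
#' @export
local_search_dims <- function(A, k1_range, k2_range, restarts = 10L,
                              seed = NULL) {
  A <- .as_expr_matrix(A, "A")
  k1_range <- sort(unique(as.integer(k1_range)))
  k2_range <- sort(unique(as.integer(k2_range)))
  if (!length(k1_range) || !length(k2_range))
    stop("`k1_range` and `k2_range` must be nonempty", call. = FALSE)
  pen <- log(nrow(A) * ncol(A))
  cache <- new.env(parent = emptyenv())

  score_of <- function(k1, k2) {
    key <- paste(k1, k2)
    if (!is.null(cache[[key]])) return(cache[[key]])
    s <- if (is.null(seed)) NULL else seed + 131L * k1 + 17L * k2
    cc <- mbi_cocluster(A, k1, k2, restarts = restarts, seed = s)
    out <- list(score = cc$objective + pen * k1 * k2, clustering = cc)
    cache[[key]] <- out
    out
  }

  cur <- c(min(k1_range), min(k2_range))
  cur_sc <- score_of(cur[1], cur[2])
  repeat {
    nb <- expand.grid(k1 = cur[1] + (-1):1, k2 = cur[2] + (-1):1)
    nb <- nb[nb$k1 %in% k1_range & nb$k2 %in% k2_range &
               !(nb$k1 == cur[1] & nb$k2 == cur[2]), , drop = FALSE]
    if (!nrow(nb)) break
    scs <- lapply(seq_len(nrow(nb)), function(i) score_of(nb$k1[i], nb$k2[i]))
    vals <- vapply(scs, `[[`, numeric(1), "score")
    j <- which.min(vals)
    if (vals[j] >= cur_sc$score - 1e-12) break
    cur <- c(nb$k1[j], nb$k2[j])
    cur_sc <- scs[[j]]
  }
  visited <- do.call(rbind, lapply(ls(cache), function(key) {
    kk <- as.integer(strsplit(key, " ")[[1]])
    data.frame(k1 = kk[1], k2 = kk[2], score = cache[[key]]$score)
  }))
  list(k1 = cur[1], k2 = cur[2], clustering = cur_sc$clustering,
       score = cur_sc$score, visited = visited)
}
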