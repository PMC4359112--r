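#' Differentially expressed genes between two sample groups
#'
#' Runs a per-gene Welch two-sample t-test between the two sample
#' groups and keeps genes with `p < alpha` (raw p-values; no
#' multiple-testing correction is applied -- the signature-selection
#' step deliberately uses the raw cutoff, and this is documented rather
#' than adjusted).  Genes with zero variance in both groups carry no
#' test information and are excluded; their count is reported via a
#' message and the `n_excluded` field.
#'
#' @param M Numeric genes-by-samples matrix.
#' @param labels Sample group labels with exactly two levels (any type;
#'   coerced to factor), each level with at least two samples.
#' @param alpha Significance cutoff (default 0.01).
#' @return An object of class `"gene_signature"`: `gene_ids`,
#'   `t_stats`, `p_values` (all aligned, only genes passing the
#'   cutoff), plus `alpha`, `n_tested`, `n_excluded` and a provenance
#'   string in `source_labelings`.
#' @examples
#' M <- expression_matrix(matrix(rnorm(200), 20, 10))
#' sig <- differential_genes(M, rep(1:2, each = 5), alpha = 0.05)
#' length(sig$gene_ids)
#' @export
differential_genes <- function(M, labels, alpha = 0.01) {
  M <- .as_expr_matrix(M, "M")
  if (is.null(rownames(M))) rownames(M) <- paste0("gene_", seq_len(nrow(M)))
  labels <- as.factor(labels)
  if (length(labels) != ncol(M))
    stop("`labels` must have one entry per sample (column)", call. = FALSE)
  if (nlevels(labels) != 2L)
    stop("`labels` must define exactly two groups", call. = FALSE)
  .check_scalar(alpha, "alpha", positive = TRUE)
  g1 <- which(labels == levels(labels)[1L])
  g2 <- which(labels == levels(labels)[2L])
  if (length(g1) < 2L || length(g2) < 2L)
    stop("each group needs at least two samples", call. = FALSE)

  v1 <- apply(M[, g1, drop = FALSE], 1L, stats::var)
  v2 <- apply(M[, g2, drop = FALSE], 1L, stats::var)
  degenerate <- v1 == 0 & v2 == 0
  if (any(degenerate))
    message(sum(degenerate),
            " gene(s) with zero variance in both groups excluded")
  testable <- which(!degenerate)
  tt <- vapply(testable, function(i) {
    ht <- stats::t.test(M[i, g1], M[i, g2], var.equal = FALSE)
    c(ht$statistic, ht$p.value)
  }, numeric(2))
  keep <- tt[2L, ] < alpha
  structure(list(
    gene_ids = rownames(M)[testable[keep]],
    t_stats = unname(tt[1L, keep]),
    p_values = unname(tt[2L, keep]),
    alpha = alpha,
    n_tested = length(testable),
    n_excluded = sum(degenerate),
    source_labelings = paste0("two-group labels (", length(g1), " vs ",
                              length(g2), " samples)")
  ), class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("Gene signature: %d genes at p < %g (Welch t-test, %d tested, %d degenerate excluded)\n",
              length(x$gene_ids), x$alpha, x$n_tested, x$n_excluded))
  if (length(x$gene_ids))
    cat("  top genes:", paste(utils::head(x$gene_ids, 5), collapse = ", "),
        "\n")
  invisible(x)
}

#' Genes common to several signatures
#'
#' Returns the gene identifiers present in every signature, preserving
#' the order of the first.  This is the cross-dataset intersection step
#' used to call a signature replicated in independent cohorts.
#'
#' @param sigs List of two or more `"gene_signature"` objects or
#'   character vectors of gene ids.
#' @return Character vector of common gene ids.
#' @export
intersect_signatures <- function(sigs) {
  if (!is.list(sigs) || length(sigs) < 2L)
    stop("`sigs` must be a list of at least two signatures", call. = FALSE)
  ids <- lapply(sigs, function(s)
    if (inherits(s, "gene_signature")) s$gene_ids else as.character(s))
  Reduce(intersect, ids)
}

#' Filter a signature by an external gene list
#'
#' Keeps only genes present in a user-supplied identifier list (for
#' example a curated cancer-gene catalogue).  No database ships with
#' the package; the list is the caller's.
#'
#' @param sig A `"gene_signature"` or character vector of gene ids.
#' @param keep_ids Character vector of identifiers to retain.
#' @return The filtered object (same type as the input).
#' @export
filter_signature <- function(sig, keep_ids) {
  keep_ids <- as.character(keep_ids)
  if (inherits(sig, "gene_signature")) {
    keep <- sig$gene_ids %in% keep_ids
    sig$gene_ids <- sig$gene_ids[keep]
    sig$t_stats <- sig$t_stats[keep]
    sig$p_values <- sig$p_values[keep]
    sig
  } else {
    as.character(sig)[as.character(sig) %in% keep_ids]
  }
}

#' Least-squares (nearest-centroid) sample classification
#'
#' Scores each test sample against the per-gene mean profile (centroid)
#' of every training class and assigns the class minimizing the sum of
#' squared per-gene differences.  Ties go to the lowest class index.
#' This is the cross-cohort sample-prediction step used to transfer
#' cluster assignments onto an independent dataset.
#'
#' @param train Numeric genes-by-samples training matrix.
#' @param train_labels Class labels, one per training sample.
#' @param test Numeric genes-by-samples test matrix with the same genes
#'   in the same order as `train` (checked via row names when present).
#' @return Integer vector of predicted class indices (positions in
#'   `sort(unique(train_labels))`), named by test sample when test has
#'   column names, with the class levels in attribute `"levels"`.
#' @export
least_squares_classify <- function(train, train_labels, test) {
  train <- .as_expr_matrix(train, "train")
  test <- .as_expr_matrix(test, "test")
  if (nrow(train) != nrow(test))
    stop("train and test must share the same genes (row count differs)",
         call. = FALSE)
  if (!is.null(rownames(train)) && !is.null(rownames(test)) &&
      !identical(rownames(train), rownames(test)))
    stop("train and test gene identifiers differ or are reordered",
         call. = FALSE)
  if (length(train_labels) != ncol(train))
    stop("`train_labels` must have one entry per training sample",
         call. = FALSE)
  classes <- sort(unique(train_labels))
  centroids <- vapply(classes, function(cl)
    rowMeans(train[, train_labels == cl, drop = FALSE]),
    numeric(nrow(train)))
  sse <- vapply(seq_along(classes), function(j)
    colSums((test - centroids[, j])^2), numeric(ncol(test)))
  sse <- matrix(sse, ncol = length(classes))
  pred <- max.col(-sse, ties.method = "first")
  names(pred) <- colnames(test)
  attr(pred, "levels") <- classes
  pred
}
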