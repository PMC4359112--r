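#' Construct a validated genes-by-samples expression matrix
#'
#' The package's working container is a plain numeric matrix with gene
#' identifiers as row names and sample identifiers as column names
#' (genes = rows, samples = columns, always).  `expression_matrix()`
#' attaches identifiers and enforces the invariants every downstream
#' function assumes: finite entries, at least one row and column, and
#' unique, non-empty identifiers.
#'
#' @param values Numeric matrix, genes in rows and samples in columns.
#' @param gene_ids Character vector of unique gene identifiers, one per
#'   row.  Defaults to existing row names, or `gene_1 ... gene_m`.
#' @param sample_ids Character vector of unique sample identifiers, one
#'   per column.  Defaults to existing column names, or `sample_1 ...`.
#'
#' @return A numeric matrix with validated `dimnames`.
#' @examples
#' M <- expression_matrix(matrix(rnorm(12), 3, 4))
#' dim(M)
#' @export
expression_matrix <- function(values, gene_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("expression matrix must have at least one row and one column",
         call. = FALSE)
  if (!all(is.finite(values)))
    stop("expression matrix entries must all be finite", call. = FALSE)
  if (is.null(gene_ids))
    gene_ids <- rownames(values) %||% paste0("gene_", seq_len(nrow(values)))
  if (is.null(sample_ids))
    sample_ids <- colnames(values) %||% paste0("sample_", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("`gene_ids` length does not match the number of rows", call. = FALSE)
  if (length(sample_ids) != ncol(values))
    stop("`sample_ids` length does not match the number of columns",
         call. = FALSE)
  .check_ids(gene_ids, "gene")
  .check_ids(sample_ids, "sample")
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_ids <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids)))
    stop(sprintf("%s identifiers must be non-empty strings", what),
         call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate %s identifier(s): %s", what,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  invisible(ids)
}

# internal: validate an arbitrary numeric matrix argument (ids optional)
.as_expr_matrix <- function(M, arg = "M") {
  M <- as.matrix(M)
  storage.mode(M) <- "double"
  if (!all(is.finite(M)))
    stop(sprintf("`%s` must be a finite numeric matrix", arg), call. = FALSE)
  M
}
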