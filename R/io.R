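#' Read / write genes-by-samples matrices as CSV
#'
#' The on-disk format is a plain comma-separated file: header row of
#' sample identifiers, first column of gene identifiers (header cell
#' `gene_id`), numeric cells with a locale-independent decimal point
#' and no quoting.  `write_matrix()` followed by `read_matrix()` is an
#' identity for finite matrices.
#'
#' @param path File path.
#' @param M Numeric matrix with gene/sample identifiers (see
#'   [expression_matrix()]).
#' @return `read_matrix()` returns a validated expression matrix;
#'   `write_matrix()` returns `path` invisibly.
#' @export
read_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    stop("matrix CSV needs a gene-id column plus at least one sample column",
         call. = FALSE)
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  raw <- as.matrix(df[-1L])
  vals <- suppressWarnings(array(as.numeric(raw), dim(raw)))
  bad <- which(is.na(vals) & !(raw %in% c("NA", "NaN")))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(raw)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(raw)) + 1L
    stop(sprintf("non-numeric cell at gene '%s', sample '%s': \"%s\"",
                 gene_ids[i], sample_ids[j], raw[bad[1L]]), call. = FALSE)
  }
  expression_matrix(vals, gene_ids = gene_ids, sample_ids = sample_ids)
}

#' @rdname read_matrix
#' @export
write_matrix <- function(M, path) {
  M <- expression_matrix(M)
  if (any(grepl("[,\"]", c(rownames(M), colnames(M)))))
    stop("identifiers must not contain commas or quotes", call. = FALSE)
  df <- data.frame(gene_id = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a clinical survival CSV
#'
#' Expects columns `sample_id`, `time` (nonnegative, months) and
#' `event` (0 = censored, 1 = event); extra columns are ignored.
#'
#' @param path File path.
#' @return A validated `"survival_table"`.
#' @export
read_survival <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("survival CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  survival_table(df$sample_id, df$time, df$event)
}

#' @rdname read_survival
#' @param table A `"survival_table"`.
#' @export
write_survival <- function(table, path) {
  table <- .validate_survival(table)
  utils::write.csv(table[c("sample_id", "time", "event")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a decomposition as X.csv / Y.csv / Z.csv
#'
#' Mirrors the worked example's file layout: the rank-one background
#' expanded to a full matrix in `X.csv`, the sparse foreground in
#' `Y.csv` and the noise term in `Z.csv`, all in the
#' [write_matrix()] CSV format.
#'
#' @param fit A `"csd"` object from [decompose_common_vector()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_decomposition <- function(fit, dir) {
  stopifnot(inherits(fit, "csd"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix(csd_background(fit), file.path(dir, "X.csv"))
  write_matrix(fit$Y, file.path(dir, "Y.csv"))
  write_matrix(fit$Z, file.path(dir, "Z.csv"))
  invisible(dir)
}
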