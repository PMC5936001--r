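#' Construct an expression dataset
#'
#' A light container for a samples x genes expression matrix with unique
#' sample and gene identifiers and a transform state (`"raw_fpkm"` or
#' `"log"`).  Raw FPKM values must be finite and non-negative.
#'
#' @param values numeric matrix, samples in rows.
#' @param sample_ids,gene_ids unique identifier vectors matching the matrix.
#' @param transform `"raw_fpkm"` (default) or `"log"`.
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, sample_ids = rownames(values),
                               gene_ids = colnames(values),
                               transform = c("raw_fpkm", "log")) {
  transform <- match.arg(transform)
  values <- as.matrix(values)
  if (is.null(sample_ids) || is.null(gene_ids)) {
    stop("sample_ids and gene_ids are required")
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  if (anyDuplicated(gene_ids)) stop("duplicate gene IDs")
  if (nrow(values) != length(sample_ids) || ncol(values) != length(gene_ids)) {
    stop("values dimensions do not match the identifier vectors")
  }
  if (any(!is.finite(values))) stop("expression values must be finite (no missing values)")
  if (transform == "raw_fpkm" && any(values < 0)) {
    stop("raw FPKM values must be non-negative")
  }
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 gene_ids = gene_ids, transform = transform),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d samples x %d genes (%s)\n",
              length(x$sample_ids), length(x$gene_ids), x$transform))
  invisible(x)
}

#' @export
as.matrix.expression_dataset <- function(x, ...) x$values

#' Load an expression matrix from delimited text
#'
#' Reads a TSV/CSV file with one header row and one leading identifier
#' column, in either orientation, and returns a dataset in samples x genes
#' orientation preserving the file's identifier order.  Non-numeric or
#' missing cells are rejected with an error naming the offending row and
#' column; duplicate identifiers error.
#'
#' @param path file path; `.csv` is comma-separated, anything else
#'   tab-separated (override with `sep`).
#' @param orientation `"samples_by_genes"` (rows are samples) or
#'   `"genes_by_samples"`.
#' @param sep optional field separator.
#' @return an [expression_dataset()].
#' @export
load_expression <- function(path,
                            orientation = c("samples_by_genes",
                                            "genes_by_samples"),
                            sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  row_ids <- raw[[1]]
  col_ids <- colnames(raw)[-1]
  if (anyDuplicated(row_ids)) {
    stop("duplicate row IDs in ", path, ": ",
         row_ids[duplicated(row_ids)][1])
  }
  if (anyDuplicated(col_ids)) {
    stop("duplicate column IDs in ", path, ": ",
         col_ids[duplicated(col_ids)][1])
  }
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  bad <- which(is.na(num) | body == "", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric or missing cell in %s at row '%s', column '%s'",
                 path, row_ids[bad[1, 1]], col_ids[bad[1, 2]]))
  }
  if (orientation == "genes_by_samples") {
    expression_dataset(t(num), sample_ids = col_ids, gene_ids = row_ids)
  } else {
    expression_dataset(num, sample_ids = row_ids, gene_ids = col_ids)
  }
}

#' Log-transform FPKM expression values
#'
#' Applies `log2(x + offset)` entrywise.  The default offset of 1 keeps
#' zeros at zero, the standard choice for FPKM-normalized data.  Applying the
#' transform twice is an error.
#'
#' @param ds an [expression_dataset()] in `raw_fpkm` state.
#' @param offset non-negative pseudo-count (default 1).
#' @return the transformed dataset (`transform = "log"`).
#' @export
log_transform <- function(ds, offset = 1) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$transform != "raw_fpkm") {
    stop("dataset is already log-transformed")
  }
  if (offset < 0) stop("offset must be >= 0")
  expression_dataset(log2(ds$values + offset), ds$sample_ids, ds$gene_ids,
                     transform = "log")
}
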