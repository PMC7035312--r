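#' Barcodes-by-genes UMI count container
#'
#' A light wrapper around a sparse integer matrix of UMI counts with rows as
#' cell barcodes and columns as genes, plus a logical mitochondrial-gene mask
#' and a sample identifier. This is the substrate of the QC cascade and the
#' differential-expression stage; everything computed from it is returned as
#' a tibble.
#'
#' @param counts A non-negative integer matrix (base or \pkg{Matrix} sparse),
#'   barcodes in rows, genes in columns. Must carry unique row names
#'   (barcodes) and column names (gene identifiers).
#' @param mito_mask Logical vector, one entry per gene, `TRUE` for
#'   mitochondrial genes. Defaults to all `FALSE`.
#' @param sample_id Single string naming the sample.
#'
#' @return An object of class `gene_barcode_matrix`: a list with elements
#'   `counts` (a `dgCMatrix`), `mito_mask` (named logical) and `sample_id`.
#' @export
#'
#' @examples
#' m <- matrix(c(3, 0, 2, 0, 1, 5), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("AAAC", "AAAG"), c("PRM1", "PRM2", "MT-ND1")))
#' gbm <- gene_barcode_matrix(m, mito_mask = c(FALSE, FALSE, TRUE), sample_id = "S1")
#' gbm
gene_barcode_matrix <- function(counts, mito_mask = NULL, sample_id = "sample") {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  # a zero-extent margin (every cell or gene filtered away) carries NULL
  # dimnames in Matrix; only non-empty margins must be named
  if ((is.null(rownames(counts)) && nrow(counts) > 0) ||
      (is.null(colnames(counts)) && ncol(counts) > 0)) {
    abort("`counts` must have barcode row names and gene column names.")
  }
  if (anyDuplicated(rownames(counts))) {
    abort("Barcodes (row names) must be unique within a sample.")
  }
  if (anyDuplicated(colnames(counts))) {
    abort("Gene identifiers (column names) must be unique.")
  }
  if (any(counts@x < 0)) abort("UMI counts must be non-negative.")
  if (is.null(mito_mask)) mito_mask <- rep(FALSE, ncol(counts))
  if (length(mito_mask) != ncol(counts)) {
    abort(sprintf("`mito_mask` has length %d but there are %d genes.",
                  length(mito_mask), ncol(counts)))
  }
  mito_mask <- as.logical(mito_mask)
  names(mito_mask) <- colnames(counts)
  structure(
    list(counts = counts, mito_mask = mito_mask,
         sample_id = as.character(sample_id)[1]),
    class = "gene_barcode_matrix"
  )
}

#' @export
print.gene_barcode_matrix <- function(x, ...) {
  cat(sprintf(
    "<gene_barcode_matrix> sample '%s': %d barcodes x %d genes (%d mitochondrial), %.0f UMI total\n",
    x$sample_id, nrow(x$counts), ncol(x$counts), sum(x$mito_mask), sum(x$counts)))
  invisible(x)
}

#' @export
dim.gene_barcode_matrix <- function(x) dim(x$counts)

#' @rdname gene_barcode_matrix
#' @param x Object to test or coerce.
#' @export
is_gene_barcode_matrix <- function(x) inherits(x, "gene_barcode_matrix")

barcodes_of <- function(x) rownames(x$counts) %||% character()
genes_of <- function(x) colnames(x$counts) %||% character()

stopifnot_gbm <- function(x) {
  if (!is_gene_barcode_matrix(x)) {
    abort("Expected a `gene_barcode_matrix`; see `gene_barcode_matrix()`.")
  }
  invisible(x)
}
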