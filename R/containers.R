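# S3 containers for UMI count data and its normalized form.

#' Construct a count dataset
#'
#' Light container for a sparse UMI count matrix (genes x cells) with cell
#' metadata. Mirrors the content of a 10x-style triplet directory.
#'
#' @param counts sparse or dense nonnegative integer matrix, genes in rows,
#'   cells in columns. Coerced to `dgCMatrix`.
#' @param gene_ids character vector of gene identifiers (rownames). If
#'   `NULL`, taken from `rownames(counts)`.
#' @param gene_names character vector of display symbols; defaults to
#'   `gene_ids`.
#' @param barcodes character vector of cell barcodes; defaults to
#'   `colnames(counts)` or generated.
#' @param cell_meta data.frame with one row per cell. A `timepoint` column
#'   is used by time-course summaries; a `sample` column by per-sample QC.
#' @param mito_genes optional character vector naming mitochondrial genes;
#'   by default genes whose name starts with `"mt-"` (mouse convention).
#' @return An object of class `count_dataset`: a list with elements
#'   `counts`, `gene_ids`, `gene_names`, `barcodes`, `cell_meta`,
#'   `mito_mask`.
#' @export
count_dataset <- function(counts, gene_ids = NULL, gene_names = NULL,
                          barcodes = NULL, cell_meta = NULL,
                          mito_genes = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be nonnegative")
  if (any(counts@x != round(counts@x))) stop("counts must be integers")
  if (is.null(gene_ids)) gene_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%05d", seq_len(nrow(counts)))
  if (is.null(gene_names)) gene_names <- gene_ids
  if (is.null(barcodes)) barcodes <- colnames(counts)
  if (is.null(barcodes)) barcodes <- sprintf("cell_%06d", seq_len(ncol(counts)))
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length does not match number of rows")
  if (length(barcodes) != ncol(counts))
    stop("barcodes length does not match number of columns")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(barcode = barcodes, stringsAsFactors = FALSE)
  }
  if (nrow(cell_meta) != ncol(counts))
    stop("cell_meta rows must match number of cells")
  rownames(counts) <- gene_ids
  colnames(counts) <- barcodes
  rownames(cell_meta) <- NULL
  if (is.null(mito_genes)) {
    mito_mask <- startsWith(gene_names, "mt-")
  } else {
    mito_mask <- gene_names %in% mito_genes | gene_ids %in% mito_genes
  }
  structure(list(counts = counts, gene_ids = gene_ids,
                 gene_names = gene_names, barcodes = barcodes,
                 cell_meta = cell_meta, mito_mask = mito_mask),
            class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("count_dataset: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  if ("timepoint" %in% names(x$cell_meta) && ncol(x$counts) > 0) {
    tab <- table(x$cell_meta$timepoint)
    cat("  timepoints:",
        paste(sprintf("%s (%d)", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.count_dataset <- function(x) dim(x$counts)

#' Subset cells of a dataset
#'
#' Subsets cells by index or logical vector, keeping counts, normalized
#' matrices and cell metadata aligned.
#'
#' @param x a `count_dataset` or `normalized_dataset`.
#' @param idx integer or logical cell selector.
#' @return Object of the same class with the selected cells.
#' @export
subset_cells <- function(x, idx) UseMethod("subset_cells")

#' @export
subset_cells.count_dataset <- function(x, idx) {
  out <- x
  out$counts <- x$counts[, idx, drop = FALSE]
  out$barcodes <- colnames(out$counts)
  out$cell_meta <- x$cell_meta[idx, , drop = FALSE]
  rownames(out$cell_meta) <- NULL
  out
}

#' @export
subset_cells.normalized_dataset <- function(x, idx) {
  out <- x
  out$data <- subset_cells(x$data, idx)
  out$lognorm <- x$lognorm[, idx, drop = FALSE]
  out$scaled <- x$scaled[, idx, drop = FALSE]
  out
}

# Resolve gene symbols to row indices; errors name any missing gene.
gene_index <- function(data, genes) {
  nm <- data$gene_names
  idx <- match(genes, nm)
  if (anyNA(idx)) {
    idx2 <- match(genes, data$gene_ids)
    idx[is.na(idx)] <- idx2[is.na(idx)]
  }
  if (anyNA(idx))
    stop("gene(s) not found in dataset: ",
         paste(genes[is.na(idx)], collapse = ", "))
  idx
}

#' @export
print.normalized_dataset <- function(x, ...) {
  cat(sprintf("normalized_dataset: %d genes x %d cells (log-normalized + scaled)\n",
              nrow(x$lognorm), ncol(x$lognorm)))
  invisible(x)
}
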