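# Readers and writers for the standard interchange formats: 10x-style MTX
# triplet directories and GMT gene-set files.

first_existing <- function(dir, names) {
  for (n in names) {
    p <- file.path(dir, n)
    if (file.exists(p)) return(p)
  }
  stop("missing file in ", dir, ": expected one of ",
       paste(names, collapse = ", "))
}

#' Read a 10x-style MTX triplet directory
#'
#' Expects `matrix.mtx`, `features.tsv` (or `genes.tsv`) and
#' `barcodes.tsv`, plain or gzipped. Duplicate gene names are
#' deduplicated by suffixing and reported. If a `cell_meta.csv` is
#' present it is attached as cell metadata.
#'
#' @param dir directory path.
#' @return A [count_dataset()].
#' @export
read_10x_mtx <- function(dir) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  mtx <- first_existing(dir, c("matrix.mtx", "matrix.mtx.gz"))
  feat <- first_existing(dir, c("features.tsv", "features.tsv.gz",
                                "genes.tsv", "genes.tsv.gz"))
  bc <- first_existing(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  counts <- Matrix::readMM(mtx)
  features <- utils::read.delim(feat, header = FALSE,
                                stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(bc, header = FALSE,
                                stringsAsFactors = FALSE)[, 1]
  if (nrow(features) != nrow(counts))
    stop("dimension mismatch: ", nrow(features), " features vs ",
         nrow(counts), " matrix rows")
  if (length(barcodes) != ncol(counts))
    stop("dimension mismatch: ", length(barcodes), " barcodes vs ",
         ncol(counts), " matrix columns")
  gene_ids <- features[, 1]
  gene_names <- if (ncol(features) >= 2) features[, 2] else gene_ids
  dup <- duplicated(gene_names)
  if (any(dup)) {
    message(sum(dup), " duplicated gene name(s) deduplicated by suffixing")
    gene_names <- make.unique(gene_names)
  }
  if (anyDuplicated(gene_ids)) gene_ids <- make.unique(gene_ids)
  meta_path <- file.path(dir, "cell_meta.csv")
  meta <- if (file.exists(meta_path)) {
    utils::read.csv(meta_path, stringsAsFactors = FALSE)
  } else NULL
  count_dataset(counts, gene_ids = gene_ids, gene_names = gene_names,
                barcodes = barcodes, cell_meta = meta)
}

#' Write a count dataset as a 10x-style MTX triplet
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv` and
#' `cell_meta.csv` into `dir` (created if needed).
#'
#' @param data a [count_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_10x_mtx <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(data$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(data$gene_ids, data$gene_names),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(data$barcodes, file.path(dir, "barcodes.tsv"))
  utils::write.csv(data$cell_meta, file.path(dir, "cell_meta.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (term, description, genes... per tab-separated
#'   line).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Write gene sets as a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(length(names(sets)) == length(sets))
  lines <- vapply(names(sets), function(n)
    paste(c(n, n, sets[[n]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
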