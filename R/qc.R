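# Cell QC and normalization: gene-count floor, mitochondrial cap,
# per-sample percentile trimming, log-normalization and per-gene scaling.

qc_metrics <- function(data) {
  counts <- data$counts
  n_umi <- Matrix::colSums(counts)
  n_genes <- Matrix::colSums(counts > 0)
  mito <- if (any(data$mito_mask)) {
    Matrix::colSums(counts[data$mito_mask, , drop = FALSE])
  } else rep(0, ncol(counts))
  mito_frac <- ifelse(n_umi > 0, mito / n_umi, 0)
  data.frame(barcode = data$barcodes, n_umi = as.numeric(n_umi),
             n_genes = as.numeric(n_genes), mito_fraction = mito_frac,
             stringsAsFactors = FALSE)
}

#' Filter cells on gene count, mitochondrial content and depth percentiles
#'
#' Retains cells that (i) express at least `min_genes` genes, (ii) have a
#' mitochondrial UMI fraction of at most `max_mito`, and (iii) fall inside
#' the per-sample percentile band for both total UMI and detected genes:
#' between the `lower_pct` and `1 - upper_pct` sample quantiles (band
#' boundaries inclusive, so ties at the boundary are kept). The two
#' percentile filters are applied independently; a cell is excluded if it
#' violates either. Percentile bands are computed per `sample` column of
#' the cell metadata (falling back to one band for the whole dataset).
#'
#' @param data a [count_dataset()].
#' @param min_genes minimum number of detected genes (default 200).
#' @param max_mito maximum mitochondrial UMI fraction (default 0.10).
#' @param upper_pct upper tail fraction trimmed (default 0.05).
#' @param lower_pct lower tail fraction trimmed (default 0.01).
#' @return Filtered `count_dataset` with a `qc_report` attribute: one row
#'   per input cell with its metrics, pass flag and comma-separated
#'   exclusion reasons (`min_genes`, `mito`, `umi_low`, `umi_high`,
#'   `genes_low`, `genes_high`).
#' @export
filter_cells <- function(data, min_genes = 200, max_mito = 0.10,
                         upper_pct = 0.05, lower_pct = 0.01) {
  stopifnot(min_genes >= 0, max_mito >= 0, max_mito <= 1,
            upper_pct >= 0, upper_pct < 1, lower_pct >= 0, lower_pct < 1)
  if (ncol(data$counts) == 0) stop("empty dataset: no cells to filter")
  qc <- qc_metrics(data)
  sample_id <- if ("sample" %in% names(data$cell_meta)) {
    as.character(data$cell_meta$sample)
  } else rep("all", nrow(qc))

  reasons <- vector("list", nrow(qc))
  add_reason <- function(mask, tag) {
    for (i in which(mask)) reasons[[i]] <<- c(reasons[[i]], tag)
  }
  add_reason(qc$n_genes < min_genes, "min_genes")
  add_reason(qc$mito_fraction > max_mito, "mito")
  for (s in unique(sample_id)) {
    in_s <- sample_id == s
    qu <- stats::quantile(qc$n_umi[in_s], c(lower_pct, 1 - upper_pct))
    qg <- stats::quantile(qc$n_genes[in_s], c(lower_pct, 1 - upper_pct))
    add_reason(in_s & qc$n_umi < qu[1], "umi_low")
    add_reason(in_s & qc$n_umi > qu[2], "umi_high")
    add_reason(in_s & qc$n_genes < qg[1], "genes_low")
    add_reason(in_s & qc$n_genes > qg[2], "genes_high")
  }
  qc$pass <- lengths(reasons) == 0
  qc$reason <- vapply(reasons, function(r)
    if (length(r)) paste(r, collapse = ",") else "", character(1))
  if (!any(qc$pass)) warning("all cells removed by QC filters")
  out <- subset_cells(data, qc$pass)
  attr(out, "qc_report") <- qc
  out
}

#' Log-normalize and scale a count matrix
#'
#' Per cell, counts are depth-normalized to `scale_factor` total and
#' log-transformed: `ln(1 + count / cell_total * scale_factor)`. The scaled
#' matrix is the per-gene z-score of the log-normalized values over cells,
#' clipped at `clip`; genes constant across cells scale to 0. Cells with
#' zero total get all-zero values and are flagged in the report.
#'
#' @param data a [count_dataset()].
#' @param scale_factor target per-cell total (default 1e4).
#' @param clip symmetric bound on scaled z-scores (default 10).
#' @return Object of class `normalized_dataset`: list with `data` (the
#'   input), `lognorm` (sparse), `scaled` (dense), `qc_report`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_cells_per_timepoint = 40, seed = 1))
#' norm <- lognormalize(sim$dataset)
#' range(norm$scaled)
lognormalize <- function(data, scale_factor = 1e4, clip = 10) {
  counts <- data$counts
  if (ncol(counts) == 0) stop("empty dataset: no cells to normalize")
  totals <- Matrix::colSums(counts)
  if (all(totals == 0)) stop("no cell with nonzero total")
  denom <- ifelse(totals > 0, totals, 1)
  ln <- counts
  ln@x <- log1p(counts@x / rep.int(denom, diff(counts@p)) * scale_factor)
  dense <- as.matrix(ln)
  mu <- rowMeans(dense)
  sdv <- apply(dense, 1, stats::sd)
  scaled <- (dense - mu) / ifelse(sdv > 0, sdv, 1)
  scaled[sdv == 0, ] <- 0
  scaled[scaled > clip] <- clip
  scaled[scaled < -clip] <- -clip
  qc <- data.frame(barcode = data$barcodes, total_umi = as.numeric(totals),
                   zero_total = totals == 0, stringsAsFactors = FALSE)
  structure(list(data = data, lognorm = ln, scaled = scaled,
                 qc_report = qc),
            class = "normalized_dataset")
}
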