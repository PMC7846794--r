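# Cell-cycle module scoring (bin-matched control genes), phase assignment,
# and the phases x timepoints independence test with continuity correction.

#' Module score for a gene set with expression-matched controls
#'
#' Genes of the whole universe are binned into `n_bins` equal-frequency
#' bins by mean log-normalized expression; for every member of `gene_set`,
#' `n_ctrl` control genes are sampled (seeded, with replacement) from that
#' member's bin. The per-cell score is the mean log-normalized expression
#' of the gene set minus that of the pooled control multiset, so a score
#' near 0 means "no enrichment beyond expression-matched background".
#'
#' @param norm a `normalized_dataset`.
#' @param gene_set character vector; members absent from the dataset are
#'   dropped (an error if none remain).
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl control genes drawn per member gene (default 100).
#' @param seed integer seed for control sampling.
#' @param ctrl_genes optional explicit control gene set, bypassing the
#'   bin-matched sampling.
#' @param ctrl_exclude genes barred from the control pools (beyond any
#'   bin structure). On genome-scale data the gene set is a negligible
#'   fraction of every bin; on compact gene universes excluding the
#'   scored program (e.g. both cell-cycle lists) keeps the controls a
#'   genuine background.
#' @return Numeric score per cell.
#' @export
score_gene_set <- function(norm, gene_set, n_bins = 24, n_ctrl = 100,
                           seed = 1L, ctrl_genes = NULL,
                           ctrl_exclude = NULL) {
  stopifnot(inherits(norm, "normalized_dataset"))
  present <- intersect(gene_set, norm$data$gene_names)
  missing <- setdiff(gene_set, present)
  if (length(present) == 0)
    stop("no gene of the set is present in the dataset; missing: ",
         paste(missing, collapse = ", "))
  ln <- norm$lognorm
  set_idx <- gene_index(norm$data, present)
  if (is.null(ctrl_genes)) {
    avg <- Matrix::rowMeans(ln)
    n_bins_eff <- min(n_bins, nrow(ln))
    bin <- as.integer(cut(rank(avg, ties.method = "first"),
                          breaks = n_bins_eff))
    excluded <- rep(FALSE, nrow(ln))
    if (!is.null(ctrl_exclude)) {
      hit <- match(intersect(ctrl_exclude, norm$data$gene_names),
                   norm$data$gene_names)
      excluded[hit] <- TRUE
    }
    set.seed(seed)
    ctrl_idx <- unlist(lapply(set_idx, function(i) {
      pool <- which(bin == bin[i] & !excluded)
      if (length(pool) == 0) pool <- which(bin == bin[i])
      pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
    }))
  } else {
    ctrl_idx <- gene_index(norm$data, ctrl_genes)
  }
  set_mean <- Matrix::colMeans(ln[set_idx, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(ln[ctrl_idx, , drop = FALSE])
  as.numeric(set_mean - ctrl_mean)
}

#' Assign a cell-cycle phase from S and G2/M module scores
#'
#' `S` iff the S score exceeds both the G2/M score and 0; `G2M` iff the
#' G2/M score is at least the S score and positive; otherwise `G1`.
#'
#' @param s_score,g2m_score numeric vectors of per-cell module scores.
#' @return Character vector in `{"G1", "S", "G2M"}`.
#' @export
assign_phase <- function(s_score, g2m_score) {
  stopifnot(length(s_score) == length(g2m_score),
            all(is.finite(s_score)), all(is.finite(g2m_score)))
  ifelse(s_score > g2m_score & s_score > 0, "S",
         ifelse(g2m_score >= s_score & g2m_score > 0, "G2M", "G1"))
}

#' Score and assign cell-cycle phases
#'
#' Convenience wrapper: S and G2/M module scores via [score_gene_set()]
#' (default mouse phase gene lists) followed by [assign_phase()].
#'
#' @param norm a `normalized_dataset`.
#' @param s_genes,g2m_genes phase gene sets; defaults from
#'   [default_cell_cycle_genes()].
#' @param n_bins,n_ctrl,seed passed to [score_gene_set()].
#' @return data.frame: `barcode`, `s_score`, `g2m_score`, `phase`.
#' @export
score_cell_cycle <- function(norm, s_genes = NULL, g2m_genes = NULL,
                             n_bins = 24, n_ctrl = 100, seed = 1L) {
  cc <- default_cell_cycle_genes()
  if (is.null(s_genes)) s_genes <- cc$s
  if (is.null(g2m_genes)) g2m_genes <- cc$g2m
  excl <- union(s_genes, g2m_genes)
  s <- score_gene_set(norm, s_genes, n_bins, n_ctrl, seed,
                      ctrl_exclude = excl)
  g2m <- score_gene_set(norm, g2m_genes, n_bins, n_ctrl, seed + 1L,
                        ctrl_exclude = excl)
  data.frame(barcode = norm$data$barcodes, s_score = s, g2m_score = g2m,
             phase = assign_phase(s, g2m), stringsAsFactors = FALSE)
}

#' Chi-squared independence test with continuity correction
#'
#' Tests independence of rows and columns of a contingency table (e.g.
#' cell-cycle phases x timepoints) with the Yates continuity correction
#' applied cell-wise: `sum(max(|O - E| - 0.5, 0)^2 / E)`, df =
#' `(r - 1)(c - 1)`, upper-tail p. For 2x2 tables this is the classical
#' Yates-corrected test; the cell-wise correction extends to larger
#' tables and can be disabled.
#'
#' @param tab matrix of nonnegative counts, at least 2x2.
#' @param correct apply the continuity correction (default `TRUE`).
#' @return List (class `htest_simple`): `statistic`, `df`, `p.value`,
#'   `expected`.
#' @export
#' @examples
#' phase_independence_test(matrix(c(20, 10, 10, 20), 2))
phase_independence_test <- function(tab, correct = TRUE) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need a table with at least 2 rows and 2 columns")
  if (any(tab < 0)) stop("counts must be nonnegative")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("zero marginal in the contingency table")
  expected <- outer(rs, cs) / sum(tab)
  dev <- abs(tab - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 expected = expected),
            class = "htest_simple")
}

#' @export
print.htest_simple <- function(x, ...) {
  cat(sprintf("chi-squared = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}
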