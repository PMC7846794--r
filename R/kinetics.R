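# Marker-gated endothelial / EndMA classification and time-course
# summaries: expressing fractions, marker-set z-score kinetics,
# fold-change to homeostasis, and strong-expression quadrant analysis.

# Accept either a count_dataset or a normalized_dataset.
as_count_data <- function(x) {
  if (inherits(x, "normalized_dataset")) x$data
  else if (inherits(x, "count_dataset")) x
  else stop("expected a count_dataset or normalized_dataset")
}

cell_groups <- function(x, group_by) {
  meta <- as_count_data(x)$cell_meta
  if (!group_by %in% names(meta))
    stop("grouping column not found in cell metadata: ", group_by)
  g <- meta[[group_by]]
  if (anyNA(g)) stop("empty (NA) group label in column ", group_by)
  as.character(g)
}

#' Subset to endothelial cells by co-expression gating
#'
#' Retains cells with raw UMI > 0 for every gate gene (default the
#' endothelial identity pair `Cdh5` and `Pecam1`).
#'
#' @param data a `count_dataset` or `normalized_dataset`.
#' @param genes gate genes, all required at UMI >= 1.
#' @return Same class as the input, cells subset.
#' @export
subset_ec <- function(data, genes = c("Cdh5", "Pecam1")) {
  cd <- as_count_data(data)
  gi <- gene_index(cd, genes)
  if (ncol(cd$counts) == 0) return(data)
  keep <- Matrix::colSums(cd$counts[gi, , drop = FALSE] > 0) == length(gi)
  subset_cells(data, as.logical(keep))
}

#' Classify endothelial cells as EndMA-positive or -negative
#'
#' A cell (assumed already endothelial-gated) is `EndMA+` iff it has raw
#' UMI >= 1 for every positive marker (default `Serpine1` and `Fn1`),
#' otherwise `EndMA-`.
#'
#' @param ec_data endothelial-subset `count_dataset` or
#'   `normalized_dataset`.
#' @param pos_markers mesenchymal gate genes.
#' @return Character vector per cell: `"EndMA+"` / `"EndMA-"`.
#' @export
classify_endma <- function(ec_data, pos_markers = c("Serpine1", "Fn1")) {
  cd <- as_count_data(ec_data)
  gi <- gene_index(cd, pos_markers)
  pos <- Matrix::colSums(cd$counts[gi, , drop = FALSE] >= 1) ==
    length(gi)
  ifelse(as.logical(pos), "EndMA+", "EndMA-")
}

#' Fraction of cells expressing genes, per group
#'
#' Per group, the fraction of cells with raw UMI >= 1 for all (or any) of
#' the listed genes.
#'
#' @param data `count_dataset` or `normalized_dataset`.
#' @param genes gene names.
#' @param combination `"all"` (default) or `"any"`.
#' @param group_by metadata column to group by (default `"timepoint"`).
#' @return data.frame: `group`, `n_cells`, `fraction`.
#' @export
fraction_expressing <- function(data, genes, combination = c("all", "any"),
                                group_by = "timepoint") {
  combination <- match.arg(combination)
  cd <- as_count_data(data)
  gi <- gene_index(cd, genes)
  grp <- cell_groups(data, group_by)
  if (length(grp) == 0) stop("no cells to summarize")
  hits <- cd$counts[gi, , drop = FALSE] >= 1
  ok <- if (combination == "all") {
    Matrix::colSums(hits) == length(gi)
  } else Matrix::colSums(hits) > 0
  ok <- as.logical(ok)
  groups <- unique(grp)
  data.frame(group = groups,
             n_cells = vapply(groups, function(g) sum(grp == g), numeric(1)),
             fraction = vapply(groups, function(g) mean(ok[grp == g]),
                               numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Marker-set z-score kinetics
#'
#' Per gene, the per-group mean log-normalized expression is z-scored
#' across groups (sample SD; genes constant across groups score 0), then
#' averaged over the gene set per group — the "mean z-score of the marker
#' panel per timepoint" summary.
#'
#' @param norm a `normalized_dataset`.
#' @param gene_set character vector of genes.
#' @param group_by metadata column (default `"timepoint"`).
#' @return data.frame `group`, `mean_z`; per-gene z matrix in attribute
#'   `"per_gene"`.
#' @export
zscore_kinetics <- function(norm, gene_set, group_by = "timepoint") {
  stopifnot(inherits(norm, "normalized_dataset"))
  gi <- gene_index(norm$data, gene_set)
  grp <- cell_groups(norm, group_by)
  groups <- unique(grp)
  if (length(groups) < 2) stop("need at least two groups for z-scores")
  means <- vapply(groups, function(g)
    Matrix::rowMeans(norm$lognorm[gi, grp == g, drop = FALSE]),
    numeric(length(gi)))
  means <- matrix(means, nrow = length(gi),
                  dimnames = list(gene_set, groups))
  z <- t(apply(means, 1, function(m) {
    s <- stats::sd(m)
    if (is.na(s) || s == 0) rep(0, length(m)) else (m - mean(m)) / s
  }))
  dimnames(z) <- dimnames(means)
  out <- data.frame(group = groups, mean_z = colMeans(z),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "per_gene") <- z
  out
}

#' Fold-change of mean expression relative to a baseline group
#'
#' `FC(t, g) = (mean_t(g) + pc) / (mean_baseline(g) + pc)` on
#' log-normalized means by default (`use = "counts"` switches to raw
#' means), summarized per group as mean and SD over the gene set.
#'
#' @param norm a `normalized_dataset`.
#' @param genes gene set.
#' @param baseline baseline group label (default `"Hom"`).
#' @param pseudocount numerical guard (default 1e-9).
#' @param use `"lognorm"` or `"counts"`.
#' @param group_by metadata column (default `"timepoint"`).
#' @return data.frame `group`, `mean_fc`, `sd_fc`; per-gene fold-change
#'   matrix in attribute `"per_gene"`.
#' @export
foldchange_to_baseline <- function(norm, genes, baseline = "Hom",
                                   pseudocount = 1e-9,
                                   use = c("lognorm", "counts"),
                                   group_by = "timepoint") {
  use <- match.arg(use)
  cd <- as_count_data(norm)
  gi <- gene_index(cd, genes)
  grp <- cell_groups(norm, group_by)
  if (!baseline %in% grp) stop("baseline group not present: ", baseline)
  mat <- if (use == "lognorm") {
    stopifnot(inherits(norm, "normalized_dataset"))
    norm$lognorm
  } else cd$counts
  groups <- unique(grp)
  means <- vapply(groups, function(g)
    Matrix::rowMeans(mat[gi, grp == g, drop = FALSE]),
    numeric(length(gi)))
  means <- matrix(means, nrow = length(gi),
                  dimnames = list(genes, groups))
  fc <- (means + pseudocount) / (means[, baseline] + pseudocount)
  out <- data.frame(group = groups, mean_fc = colMeans(fc),
                    sd_fc = apply(fc, 2, stats::sd),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "per_gene") <- fc
  out
}

#' Strong-expression quadrant analysis of two markers
#'
#' A cell expresses a marker "strongly" if its log-normalized value
#' exceeds the median of that marker's nonzero values pooled over all
#' groups (the top 50% of nonzero values; one fixed box across
#' timepoints). Per group, cells are partitioned into the four boxes
#' x-strong-only, y-strong-only, both, neither, reported as percentages.
#'
#' @param norm a `normalized_dataset`.
#' @param marker_x,marker_y marker genes.
#' @param group_by metadata column (default `"timepoint"`).
#' @return data.frame `group`, `box` (`x_only`, `y_only`, `both`,
#'   `neither`), `percent`; thresholds in attribute `"thresholds"`.
#' @export
quadrant_analysis <- function(norm, marker_x, marker_y,
                              group_by = "timepoint") {
  stopifnot(inherits(norm, "normalized_dataset"))
  gi <- gene_index(norm$data, c(marker_x, marker_y))
  x <- as.numeric(norm$lognorm[gi[1], ])
  y <- as.numeric(norm$lognorm[gi[2], ])
  if (!any(x > 0)) stop("marker has no nonzero values: ", marker_x)
  if (!any(y > 0)) stop("marker has no nonzero values: ", marker_y)
  tx <- stats::median(x[x > 0])
  ty <- stats::median(y[y > 0])
  strong_x <- x > tx
  strong_y <- y > ty
  box <- ifelse(strong_x & strong_y, "both",
         ifelse(strong_x, "x_only",
         ifelse(strong_y, "y_only", "neither")))
  grp <- cell_groups(norm, group_by)
  groups <- unique(grp)
  boxes <- c("x_only", "y_only", "both", "neither")
  out <- do.call(rbind, lapply(groups, function(g) {
    b <- factor(box[grp == g], levels = boxes)
    data.frame(group = g, box = boxes,
               percent = 100 * as.numeric(table(b)) / sum(grp == g),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "thresholds") <- c(x = tx, y = ty)
  out
}
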