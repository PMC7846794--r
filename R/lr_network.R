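# Four-layer ligand-receptor communication network: source cell type ->
# ligand -> receptor -> target cell type, with product-path aggregation
# and permutation significance of source-target connections.

#' Per-cell-type expression profiles and fold-changes
#'
#' Computes the mean log-normalized expression of every gene per cell
#' type, plus a fold-change per gene and type: either versus all other
#' cell types (`"vs_rest"`) or versus a baseline condition within the
#' same cell type (`"vs_baseline"`, e.g. injury versus homeostasis).
#'
#' @param norm a `normalized_dataset`.
#' @param cell_type character vector per cell.
#' @param fc_mode `"vs_rest"` or `"vs_baseline"`.
#' @param baseline_mask logical per cell marking baseline cells (required
#'   for `"vs_baseline"`).
#' @param pseudocount guard for ratios (default 1e-9).
#' @return List: `mean` and `fc`, both genes x cell types matrices.
#' @export
celltype_profiles <- function(norm, cell_type,
                              fc_mode = c("vs_rest", "vs_baseline"),
                              baseline_mask = NULL, pseudocount = 1e-9) {
  fc_mode <- match.arg(fc_mode)
  stopifnot(inherits(norm, "normalized_dataset"),
            length(cell_type) == ncol(norm$lognorm))
  types <- unique(cell_type)
  ln <- norm$lognorm
  mean_expr <- vapply(types, function(t)
    Matrix::rowMeans(ln[, cell_type == t, drop = FALSE]),
    numeric(nrow(ln)))
  dimnames(mean_expr) <- list(norm$data$gene_names, types)
  if (fc_mode == "vs_rest") {
    fc <- vapply(types, function(t) {
      rest <- Matrix::rowMeans(ln[, cell_type != t, drop = FALSE])
      (mean_expr[, t] + pseudocount) / (rest + pseudocount)
    }, numeric(nrow(ln)))
  } else {
    if (is.null(baseline_mask))
      stop("baseline_mask required for fc_mode = 'vs_baseline'")
    fc <- vapply(types, function(t) {
      sel <- cell_type == t
      base <- Matrix::rowMeans(ln[, sel & baseline_mask, drop = FALSE])
      post <- Matrix::rowMeans(ln[, sel & !baseline_mask, drop = FALSE])
      (post + pseudocount) / (base + pseudocount)
    }, numeric(nrow(ln)))
  }
  dimnames(fc) <- list(norm$data$gene_names, types)
  list(mean = mean_expr, fc = fc)
}

#' Build the four-layer ligand-receptor graph
#'
#' Layers: source cell types -> ligands -> receptors -> target cell types.
#' A source->ligand edge exists iff the ligand's mean expression in the
#' source reaches `min_expr`, weighted by the ligand's fold-change there;
#' receptor->target edges symmetrically; ligand->receptor edges carry the
#' catalog association score. A path's weight is the product of its three
#' edge weights, and the aggregate weight of a source-target connection
#' is the sum of path weights over all catalog pairs linking them.
#'
#' @param mean_expr genes x cell-types matrix of mean expression.
#' @param fold_change genes x cell-types matrix of fold-changes (>= 0).
#' @param catalog data.frame `ligand`, `receptor`, `score` (scores in
#'   (0, 1]).
#' @param min_expr expression floor for an edge to exist (default 0.1).
#' @return Object of class `lr_graph`: `aggregate` (source x target
#'   matrix), `edges` (long data.frame of the three edge layers), and the
#'   internal pair-profile matrices reused by
#'   [permutation_significance()].
#' @export
build_lr_graph <- function(mean_expr, fold_change, catalog,
                           min_expr = 0.1) {
  stopifnot(is.matrix(mean_expr), is.matrix(fold_change),
            identical(dim(mean_expr), dim(fold_change)),
            all(c("ligand", "receptor", "score") %in% names(catalog)))
  if (any(fold_change < 0)) stop("fold-changes must be nonnegative")
  if (nrow(catalog) > 0 && any(catalog$score <= 0))
    stop("association scores must be positive")
  types <- colnames(mean_expr)
  if (is.null(types)) stop("cell types (column names) are required")
  missing <- setdiff(unique(c(catalog$ligand, catalog$receptor)),
                     rownames(mean_expr))
  if (length(missing) > 0)
    stop("catalog genes absent from the expression profiles: ",
         paste(utils::head(missing, 5), collapse = ", "))
  masked <- fold_change * (mean_expr >= min_expr)
  Lw <- masked[catalog$ligand, , drop = FALSE]
  Rw <- masked[catalog$receptor, , drop = FALSE]
  w <- catalog$score
  agg <- crossprod(Lw * w, Rw)
  dimnames(agg) <- list(types, types)

  edge_rows <- function(mat, genes, from_type) {
    idx <- which(mat > 0, arr.ind = TRUE)
    if (nrow(idx) == 0)
      return(data.frame(from = character(), to = character(),
                        layer = character(), weight = numeric()))
    if (from_type) {
      data.frame(from = types[idx[, 2]], to = genes[idx[, 1]],
                 layer = "source_ligand", weight = mat[idx])
    } else {
      data.frame(from = genes[idx[, 1]], to = types[idx[, 2]],
                 layer = "receptor_target", weight = mat[idx])
    }
  }
  edges <- rbind(
    unique(edge_rows(Lw, catalog$ligand, TRUE)),
    data.frame(from = catalog$ligand, to = catalog$receptor,
               layer = "ligand_receptor", weight = w),
    unique(edge_rows(Rw, catalog$receptor, FALSE)))
  rownames(edges) <- NULL
  structure(list(aggregate = agg, edges = edges, Lw = Lw, Rw = Rw,
                 score = w, catalog = catalog, types = types,
                 min_expr = min_expr),
            class = "lr_graph")
}

#' @export
print.lr_graph <- function(x, ...) {
  cat(sprintf("lr_graph: %d pairs, %d cell types\n", length(x$score),
              length(x$types)))
  print(round(x$aggregate, 3))
  if (!is.null(x$significance)) {
    cat(sprintf("%d / %d source-target connections significant\n",
                sum(x$significance$significant), nrow(x$significance)))
  }
  invisible(x)
}

#' Permutation significance of source-target connections
#'
#' Each permutation re-pairs ligands with receptors uniformly at random
#' (randomized network connections; association scores stay attached to
#' their pair slot, so the weight marginals are preserved) and recomputes
#' every source-target aggregate. Empirical p-values use the add-one
#' estimator `p = (1 + #[perm >= observed]) / (n_perm + 1)`, are BH
#' adjusted across all source-target pairs, and flagged at
#' `adjusted p < alpha`.
#'
#' @param graph an [build_lr_graph()] result.
#' @param n_perm number of permutations (>= 100; 1e5 emulates the full
#'   analysis, smaller values are for testing).
#' @param alpha significance level on adjusted p (default 0.01).
#' @param seed integer seed.
#' @return The graph with a `significance` data.frame: `source`,
#'   `target`, `aggregate`, `p`, `p_adj`, `significant`.
#' @export
permutation_significance <- function(graph, n_perm = 1e5, alpha = 0.01,
                                     seed = 1L) {
  stopifnot(inherits(graph, "lr_graph"))
  if (n_perm < 100) stop("n_perm must be at least 100")
  n_pairs <- length(graph$score)
  obs <- graph$aggregate
  Lww <- graph$Lw * graph$score
  ge <- matrix(0L, nrow(obs), ncol(obs))
  set.seed(seed)
  for (i in seq_len(n_perm)) {
    perm <- sample.int(n_pairs)
    aggp <- crossprod(Lww, graph$Rw[perm, , drop = FALSE])
    ge <- ge + (aggp >= obs)
  }
  p <- (1 + ge) / (n_perm + 1)
  p_adj <- matrix(stats::p.adjust(p, method = "BH"), nrow(p))
  sig <- data.frame(
    source = rep(graph$types, times = length(graph$types)),
    target = rep(graph$types, each = length(graph$types)),
    aggregate = as.vector(obs), p = as.vector(p),
    p_adj = as.vector(p_adj),
    significant = as.vector(p_adj) < alpha,
    stringsAsFactors = FALSE)
  graph$significance <- sig
  graph$alpha <- alpha
  graph$n_perm <- n_perm
  graph
}
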