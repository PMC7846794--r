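# Zero-inflated bimodal likelihood-ratio differential expression, fold
# changes on de-logged means, and an exact Fisher test via hypergeometric
# summation.

bimod_loglik <- function(n0, pos, pi, mu, s2, use_normal) {
  ll <- 0
  if (n0 > 0) ll <- ll + n0 * log(1 - pi)
  if (length(pos) > 0) {
    ll <- ll + length(pos) * log(pi)
    if (use_normal)
      ll <- ll + sum(stats::dnorm(pos, mu, sqrt(s2), log = TRUE))
  }
  ll
}

#' Zero-inflated bimodal likelihood-ratio test
#'
#' Models each group's expression as a point mass at zero (probability
#' `1 - pi`) plus a normal component on the nonzero values, and tests the
#' null of shared `(pi, mu)` against group-specific values with a common
#' variance, by a likelihood-ratio statistic `2(l1 - l0)` referred to a
#' chi-squared with 2 degrees of freedom (one for the detection rate, one
#' for the positive-component mean). Suitable for zero-inflated
#' log-normalized single-cell data.
#'
#' Degenerate inputs follow the contract: a group that is entirely zero
#' contributes through the detection component alone; if fewer than two
#' nonzero values exist in total, or all nonzero values are identical, the
#' normal component cancels between the nested models and the test reduces
#' to its detection part; two all-zero groups give statistic 0, p 1.
#'
#' @param x,y numeric vectors of (log-normalized) expression per group;
#'   both non-empty.
#' @return List: `statistic`, `p.value`, `df`.
#' @export
#' @examples
#' bimod_lrt(c(0, 0, 0, 0, 2, 2, 2, 2), c(0, 2, 2, 2, 2, 2, 2, 2))
bimod_lrt <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  px <- x[x != 0]; py <- y[y != 0]
  n0x <- sum(x == 0); n0y <- sum(y == 0)
  pos <- c(px, py)
  if (length(pos) == 0)
    return(list(statistic = 0, p.value = 1, df = 2))
  mu0 <- mean(pos)
  s2_null <- sum((pos - mu0)^2) / length(pos)
  mux <- if (length(px)) mean(px) else NA_real_
  muy <- if (length(py)) mean(py) else NA_real_
  rss_alt <- sum((px - if (length(px)) mux else 0)^2) +
    sum((py - if (length(py)) muy else 0)^2)
  s2_alt <- rss_alt / length(pos)
  # When the pooled nonzero values are constant, the normal component is
  # degenerate under both models and cancels; otherwise floor the
  # alternative variance to keep the statistic finite.
  use_normal <- length(pos) >= 2 && s2_null > 0
  s2_alt <- max(s2_alt, 1e-12)
  pix <- length(px) / length(x)
  piy <- length(py) / length(y)
  pi0 <- length(pos) / (length(x) + length(y))
  ll1 <- bimod_loglik(n0x, px, pix, mux, s2_alt, use_normal) +
    bimod_loglik(n0y, py, piy, muy, s2_alt, use_normal)
  ll0 <- bimod_loglik(n0x, px, pi0, mu0, s2_null, use_normal) +
    bimod_loglik(n0y, py, pi0, mu0, s2_null, use_normal)
  stat <- max(0, 2 * (ll1 - ll0))
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 2, lower.tail = FALSE), df = 2)
}

#' Log fold change on de-logged means
#'
#' Means are taken after inverting the log1p transform
#' (`mean(expm1(values))`), a pseudocount is added to both, and the
#' natural log of their ratio is returned; positive when the first group
#' is higher.
#'
#' @param x,y numeric vectors of log-normalized expression.
#' @param pseudocount added to both de-logged means (default 1).
#' @return Natural-log fold change (scalar).
#' @export
log_fold_change <- function(x, y, pseudocount = 1) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  log((mean(expm1(x)) + pseudocount) / (mean(expm1(y)) + pseudocount))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Sums hypergeometric probabilities over all tables with the observed
#' margins whose probability does not exceed the observed table's (with
#' the conventional `1 + 1e-7` relative tolerance for floating-point
#' ties).
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact(matrix(c(1, 11, 9, 3), 2))
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(dim(tab) == c(2, 2))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must hold nonnegative integers")
  if (sum(tab) == 0) stop("table has zero grand total")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- probs[support == tab[1, 1]]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Differential expression between two cell groups
#'
#' Applies [bimod_lrt()] gene-wise between two groups of cells, with
#' de-logged [log_fold_change()], expressing fractions, and Bonferroni
#' correction over the tested genes.
#'
#' @param norm a `normalized_dataset`.
#' @param group1_mask logical per cell: `TRUE` for group 1 (e.g. EndMA+),
#'   `FALSE` for group 2.
#' @param genes genes to test; default all genes detected in at least one
#'   cell of either group.
#' @return data.frame (class `de_result`): `gene`, `log_fc`, `pct_1`,
#'   `pct_2`, `statistic`, `p`, `p_bonferroni`, sorted by `p`.
#' @export
de_bimod <- function(norm, group1_mask, genes = NULL) {
  stopifnot(inherits(norm, "normalized_dataset"),
            is.logical(group1_mask),
            length(group1_mask) == ncol(norm$lognorm))
  if (!any(group1_mask) || all(group1_mask))
    stop("both groups must be non-empty")
  m1 <- as.matrix(norm$lognorm[, group1_mask, drop = FALSE])
  m2 <- as.matrix(norm$lognorm[, !group1_mask, drop = FALSE])
  if (is.null(genes)) {
    detected <- rowSums(m1) + rowSums(m2) > 0
    genes <- norm$data$gene_names[detected]
  }
  gi <- gene_index(norm$data, genes)
  res <- lapply(seq_along(gi), function(j) {
    x <- m1[gi[j], ]; y <- m2[gi[j], ]
    t <- bimod_lrt(x, y)
    data.frame(gene = genes[j], log_fc = log_fold_change(x, y),
               pct_1 = mean(x > 0), pct_2 = mean(y > 0),
               statistic = t$statistic, p = t$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out <- out[order(out$p, -abs(out$log_fc)), ]
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}
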