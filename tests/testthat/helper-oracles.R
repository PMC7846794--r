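# Shared fixtures and independent oracles used across the suite.

# Tiny count_dataset from a dense matrix (genes x cells).
toy_dataset <- function(mat, gene_names = NULL, timepoint = NULL,
                        sample = NULL) {
  if (is.null(gene_names))
    gene_names <- sprintf("gene%03d", seq_len(nrow(mat)))
  rownames(mat) <- gene_names
  meta <- data.frame(barcode = sprintf("c%04d", seq_len(ncol(mat))))
  if (!is.null(timepoint)) meta$timepoint <- timepoint
  meta$sample <- if (is.null(sample)) "s1" else sample
  count_dataset(Matrix::Matrix(mat, sparse = TRUE),
                gene_ids = gene_names, cell_meta = meta)
}

# Normalized dataset with prescribed lognorm values (for summaries that
# consume normalized expression directly).
toy_norm <- function(lognorm, gene_names = NULL, timepoint = NULL) {
  if (is.null(gene_names))
    gene_names <- sprintf("gene%03d", seq_len(nrow(lognorm)))
  counts <- round(expm1(lognorm))
  ds <- toy_dataset(counts, gene_names, timepoint = timepoint)
  structure(list(data = ds,
                 lognorm = Matrix::Matrix(lognorm, sparse = TRUE,
                                          dimnames = list(gene_names,
                                                          ds$barcodes)),
                 scaled = lognorm, qc_report = NULL),
            class = "normalized_dataset")
}

# All-endothelial simulation config used by recovery experiments.
ec_only_config <- function(n_per_tp, seed, ...) {
  tps <- c("Hom", "d1", "d3", "d5", "d7", "d14", "d28")
  ctp <- matrix(rep(c(1, 0, 0, 0), each = 7), nrow = 7,
                dimnames = list(tps, c("EC", "Fb", "Mono", "SMC")))
  sim_config(n_cells_per_timepoint = n_per_tp,
             cell_type_proportions = ctp, seed = seed, ...)
}

# Grid-search maximum-likelihood oracle for the zero-inflated bimodal LRT:
# maximizes the same two-component likelihood over (pi, mu, sigma) grids
# with iterative refinement (separate grids per parameter and model),
# never using the closed-form estimates.
bimod_grid_oracle <- function(x, y, n_grid = 31, n_iter = 7) {
  stats_of <- function(v) {
    pos <- v[v != 0]
    list(n0 = sum(v == 0), np = length(pos),
         xb = if (length(pos)) mean(pos) else 0,
         S = if (length(pos)) sum((pos - mean(pos))^2) else 0)
  }
  gx <- stats_of(x); gy <- stats_of(y)
  pool <- c(x[x != 0], y[y != 0])
  if (length(pool) < 2) stop("oracle needs >= 2 nonzero values")
  g0 <- list(n0 = gx$n0 + gy$n0, np = length(pool), xb = mean(pool),
             S = sum((pool - mean(pool))^2))

  bin_part <- function(g, p) {
    out <- g$np * log(p)
    if (g$n0 > 0) out <- out + g$n0 * log(1 - p)
    out
  }
  norm_part <- function(g, mu, sigma) {
    -g$np * log(sigma) - g$np * 0.5 * log(2 * pi) -
      (g$S + g$np * (mu - g$xb)^2) / (2 * sigma^2)
  }

  # Maximize sum over groups of bin + normal log likelihood, common sigma,
  # each parameter on its own iteratively refined grid.
  max_model <- function(groups) {
    k <- length(groups)
    pr <- replicate(k, c(1e-5, 1 - 1e-5), simplify = FALSE)
    mr <- replicate(k, range(pool) + c(-2, 2), simplify = FALSE)
    sr <- c(max(1e-4, stats::sd(pool) * 0.02), stats::sd(pool) * 3 + 1)
    best <- -Inf
    for (it in seq_len(n_iter)) {
      sis <- seq(sr[1], sr[2], length.out = n_grid)
      # best pi per group is sigma-independent
      pi_best <- lapply(seq_len(k), function(i) {
        grid <- seq(pr[[i]][1], pr[[i]][2], length.out = n_grid)
        grid[which.max(bin_part(groups[[i]], grid))]
      })
      mu_at <- function(i, sigma) {
        grid <- seq(mr[[i]][1], mr[[i]][2], length.out = n_grid)
        grid[which.max(norm_part(groups[[i]], grid, sigma))]
      }
      tot <- vapply(sis, function(s) {
        sum(vapply(seq_len(k), function(i)
          bin_part(groups[[i]], pi_best[[i]]) +
            norm_part(groups[[i]], mu_at(i, s), s), numeric(1)))
      }, numeric(1))
      s_best <- sis[which.max(tot)]
      best <- max(tot)
      # shrink each grid around its current argmax
      shrink <- function(rng, arg) {
        step <- (rng[2] - rng[1]) / (n_grid - 1)
        c(max(rng[1], arg - 2 * step), min(rng[2], arg + 2 * step))
      }
      pr <- lapply(seq_len(k), function(i) shrink(pr[[i]], pi_best[[i]]))
      mr <- lapply(seq_len(k), function(i)
        shrink(mr[[i]], mu_at(i, s_best)))
      sr <- shrink(sr, s_best)
      sr[1] <- max(sr[1], 1e-5)
    }
    best
  }
  l1 <- max_model(list(gx, gy))
  l0 <- max_model(list(g0))
  max(0, 2 * (l1 - l0))
}

# Exhaustive Fisher oracle: enumerate all tables with the observed
# margins, probabilities from log-factorials (no dhyper).
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2]); n <- r1 + r2
  lfac <- lgamma(seq_len(n + 1))  # lfac[k+1] = log(k!)
  lf <- function(k) lfac[k + 1]
  const <- lf(r1) + lf(r2) + lf(c1) + lf(c2) - lf(n)
  lp <- function(a) const - lf(a) - lf(r1 - a) - lf(c1 - a) -
    lf(r2 - c1 + a)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(vapply(support, lp, numeric(1)))
  p_obs <- probs[support == tab[1, 1]]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Direct application of the clonal 2-SD rule, written independently of
# flag_clonal_areas (plain loops over the long table).
clonal_rule_oracle <- function(tab) {
  key <- paste(tab$group, tab$animal, tab$image, tab$area)
  out <- rep(FALSE, length(unique(key)))
  names(out) <- unique(key)
  for (an in unique(paste(tab$group, tab$animal))) {
    sel <- paste(tab$group, tab$animal) == an
    for (fl in unique(tab$fluorophore)) {
      rows <- sel & tab$fluorophore == fl
      thr <- mean(tab$count[rows]) + 2 * stats::sd(tab$count[rows])
      hit <- rows & tab$count > thr
      out[unique(key[hit])] <- TRUE
    }
  }
  out
}
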