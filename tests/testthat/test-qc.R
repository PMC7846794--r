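make_qc_toy <- function() {
  # 60 cells x 260 genes incl. 10 mitochondrial; cell 1 detects only 150
  # genes, cell 2 has 12% mitochondrial UMI, the rest are identical.
  genes <- c(sprintf("g%03d", 1:250), sprintf("mt-%d", 1:10))
  mat <- matrix(0, 260, 60)
  mat[1:220, ] <- 1          # 220 detected genes everywhere
  mat[1:250, 1] <- 0
  mat[1:150, 1] <- 1          # cell 1: 150 genes
  mat[251:260, ] <- 1         # a little mito signal for everyone
  mat[251:260, 2] <- 4        # cell 2: 40 mito of 260 total UMI ~ 15%
  toy_dataset(mat, genes)
}

test_that("cells violating the gene floor or mitochondrial cap are excluded", {
  data <- make_qc_toy()
  out <- filter_cells(data, min_genes = 200, max_mito = 0.10,
                      upper_pct = 0, lower_pct = 0)
  qc <- attr(out, "qc_report")
  expect_false(qc$pass[1])
  expect_match(qc$reason[1], "min_genes")
  expect_false(qc$pass[2])
  expect_match(qc$reason[2], "mito")
  expect_true(all(qc$pass[-(1:2)]))
  expect_equal(ncol(out$counts), 58)
})

test_that("identical cells are all retained when the band collapses", {
  mat <- matrix(1, 250, 100)
  data <- toy_dataset(mat)
  out <- filter_cells(data, min_genes = 200, max_mito = 0.10)
  expect_equal(ncol(out$counts), 100)
})

test_that("permissive thresholds make filtering the identity", {
  sim <- simulate_dataset(sim_config(n_cells_per_timepoint = 80, seed = 5))
  out <- filter_cells(sim$dataset, min_genes = 0, max_mito = 1,
                      upper_pct = 0, lower_pct = 0)
  expect_equal(ncol(out$counts), ncol(sim$dataset$counts))
  expect_error(filter_cells(subset_cells(sim$dataset, logical(0))),
               "empty")
})

test_that("percentile trimming matches a direct per-sample recomputation", {
  sim <- simulate_dataset(sim_config(n_cells_per_timepoint = 400, seed = 6))
  data <- sim$dataset
  out <- filter_cells(data)
  qc <- attr(out, "qc_report")
  # independent recomputation of all four rules
  n_umi <- Matrix::colSums(data$counts)
  n_genes <- Matrix::colSums(data$counts > 0)
  mito <- Matrix::colSums(data$counts[data$mito_mask, ]) / pmax(n_umi, 1)
  keep <- n_genes >= 200 & mito <= 0.10
  for (s in unique(data$cell_meta$sample)) {
    i <- data$cell_meta$sample == s
    qu <- quantile(n_umi[i], c(0.01, 0.95))
    qg <- quantile(n_genes[i], c(0.01, 0.95))
    keep[i] <- keep[i] & n_umi[i] >= qu[1] & n_umi[i] <= qu[2] &
      n_genes[i] >= qg[1] & n_genes[i] <= qg[2]
  }
  expect_identical(qc$pass, unname(keep))
})

test_that("log-normalization follows the depth-scaled log1p formula", {
  mat <- matrix(0, 2, 2)
  mat[, 1] <- c(10, 9990)   # total exactly 10,000
  mat[, 2] <- c(5, 5)
  norm <- lognormalize(toy_dataset(mat))
  expect_equal(norm$lognorm[1, 1], log(11), tolerance = 1e-12)
  # doubling all counts of a cell leaves its lognorm column unchanged
  mat2 <- mat
  mat2[, 2] <- mat[, 2] * 2
  norm2 <- lognormalize(toy_dataset(mat2))
  expect_equal(as.numeric(norm2$lognorm[, 2]),
               as.numeric(norm$lognorm[, 2]), tolerance = 1e-12)
})

test_that("scaling yields centered unit-variance genes, constants map to 0", {
  sim <- simulate_dataset(sim_config(n_cells_per_timepoint = 60, seed = 7))
  norm <- lognormalize(sim$dataset)
  variable <- apply(as.matrix(norm$lognorm), 1, sd) > 0
  # exact unit z-scores wherever the +/-10 clip did not engage
  clipped <- apply(abs(norm$scaled), 1, max) >= 10
  exact <- variable & !clipped
  rm <- rowMeans(norm$scaled[exact, ])
  expect_lt(max(abs(rm)), 1e-6)
  sds <- apply(norm$scaled[exact, ], 1, sd)
  expect_equal(unname(sds), rep(1, sum(exact)), tolerance = 1e-6)
  expect_true(all(norm$scaled[!variable, ] == 0))
  expect_true(all(abs(norm$scaled) <= 10))
})

test_that("zero-total cells are flagged and produce zero values", {
  mat <- matrix(c(3, 1, 0, 0), 2, 2)
  norm <- lognormalize(toy_dataset(mat))
  expect_true(norm$qc_report$zero_total[2])
  expect_true(all(norm$lognorm[, 2] == 0))
})
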