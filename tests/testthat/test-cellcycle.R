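test_that("module score is zero against itself and matches hand arithmetic", {
  ln <- matrix(c(1, 2, 3, 0, 1, 2,
                 2, 1, 0, 1, 1, 1), 6, 2)
  norm <- toy_norm(ln, sprintf("g%d", 1:6))
  set <- c("g1", "g2", "g3")
  expect_equal(score_gene_set(norm, set, ctrl_genes = set), c(0, 0))
  # n_bins = 1 with explicit whole-universe controls: direct difference
  sc <- score_gene_set(norm, set, ctrl_genes = sprintf("g%d", 1:6))
  manual <- colMeans(ln[1:3, ]) - colMeans(ln)
  expect_equal(sc, unname(manual), tolerance = 1e-12)
  expect_error(score_gene_set(norm, c("nope1", "nope2")), "nope")
})

test_that("module scores are invariant to cell order and seeded", {
  sim <- simulate_dataset(sim_config(n_cells_per_timepoint = 60, seed = 19))
  norm <- lognormalize(sim$dataset)
  cc <- default_cell_cycle_genes()
  a <- score_gene_set(norm, cc$s, seed = 3)
  expect_identical(a, score_gene_set(norm, cc$s, seed = 3))
  perm <- sample(ncol(norm$lognorm))
  b <- score_gene_set(subset_cells(norm, perm), cc$s, seed = 3)
  expect_equal(a[perm], b, tolerance = 1e-12)
})

test_that("expression-matched random sets score zero on average", {
  set.seed(77)
  ln <- matrix(rpois(400 * 200, 2) * 0.5, 400, 200)
  norm <- toy_norm(ln)
  means <- replicate(30, {
    set <- sample(norm$data$gene_names, 20)
    mean(score_gene_set(norm, set, seed = sample.int(1e6, 1)))
  })
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se)
})

test_that("phase assignment follows the score-sign rule", {
  expect_equal(assign_phase(0.5, 0.2), "S")
  expect_equal(assign_phase(-0.1, -0.3), "G1")
  expect_equal(assign_phase(0.2, 0.5), "G2M")
  expect_equal(assign_phase(0.3, 0.3), "G2M")  # tie goes to G2M
  expect_equal(assign_phase(-0.2, 0.1), "G2M")
  expect_equal(assign_phase(0, 0), "G1")
})

test_that("phases are recovered on synthetic data with active cycling", {
  cfg <- ec_only_config(400, seed = 23, cycling_fraction_schedule = 0.3)
  sim <- simulate_dataset(cfg)
  ec <- subset_ec(lognormalize(sim$dataset))
  truth <- sim$truth[match(ec$data$barcodes, sim$truth$barcode), ]
  sc <- score_cell_cycle(ec, seed = 5)
  expect_gte(mean(sc$phase == truth$cycle_phase), 0.8)
  # per-timepoint phase proportions partition the cells
  tab <- table(sc$phase, truth$timepoint)
  expect_equal(unname(colSums(prop.table(tab, 2))), rep(1, ncol(tab)))
})

test_that("continuity-corrected independence test matches the formula", {
  t0 <- phase_independence_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p.value, 1)
  t1 <- phase_independence_test(matrix(c(20, 10, 10, 20), 2))
  expect_equal(t1$statistic, 5.4, tolerance = 1e-12)
  expect_equal(t1$p.value, 0.02013675, tolerance = 1e-6)
  # cross-check against the reference implementation for 2x2
  ref <- suppressWarnings(chisq.test(matrix(c(20, 10, 10, 20), 2),
                                     correct = TRUE))
  expect_equal(t1$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(t1$p.value, ref$p.value, tolerance = 1e-12)
  expect_error(phase_independence_test(matrix(c(0, 0, 5, 5), 2)),
               "marginal")
})

test_that("the correction vanishes for large deviations", {
  tab <- matrix(c(2000, 1000, 1000, 2000), 2)
  a <- phase_independence_test(tab, correct = TRUE)$statistic
  b <- phase_independence_test(tab, correct = FALSE)$statistic
  expect_lt(abs(a - b) / b, 0.01)
  # and applies cell-wise to larger tables
  tab3 <- matrix(c(30, 12, 9, 8, 25, 11, 12, 7, 26), 3)
  t3 <- phase_independence_test(tab3)
  expect_equal(t3$df, 4)
  expect_gte(t3$statistic, 0)
})
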