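test_that("endothelial gating keeps cells with UMI > 0 for both markers", {
  mat <- matrix(0, 4, 3)
  rownames(mat) <- c("Cdh5", "Pecam1", "Serpine1", "Fn1")
  mat[, 1] <- c(2, 1, 1, 3)   # kept, EndMA+
  mat[, 2] <- c(0, 5, 0, 4)   # dropped (Cdh5 = 0)
  mat[, 3] <- c(1, 1, 0, 4)   # kept, EndMA- (Serpine1 = 0)
  data <- toy_dataset(mat, rownames(mat))
  ec <- subset_ec(data)
  expect_equal(ec$barcodes, data$barcodes[c(1, 3)])
  expect_equal(classify_endma(ec), c("EndMA+", "EndMA-"))
  expect_error(subset_ec(data, c("Cdh5", "Nope1")), "Nope1")
  expect_error(classify_endma(ec, c("Serpine1", "Missing9")), "Missing9")
  empty <- subset_cells(data, logical(0))
  expect_equal(ncol(subset_ec(empty)$counts), 0)
})

test_that("expressing fractions match a brute-force cell loop", {
  mat <- matrix(c(rep(1, 3), rep(0, 7)), 1, 10)
  d <- toy_dataset(mat, "gA", timepoint = rep("t1", 10))
  expect_equal(fraction_expressing(d, "gA")$fraction, 0.3)

  set.seed(21)
  mat <- matrix(rpois(50 * 20, 0.7), 50, 20)
  tp <- sample(c("t1", "t2", "t3"), 20, replace = TRUE)
  d <- toy_dataset(mat, timepoint = tp)
  genes <- sprintf("gene%03d", c(4, 17, 33))
  for (comb in c("all", "any")) {
    res <- fraction_expressing(d, genes, combination = comb)
    for (g in unique(tp)) {
      manual <- 0
      for (cell in which(tp == g)) {
        hit <- mat[c(4, 17, 33), cell] >= 1
        manual <- manual + if (comb == "all") all(hit) else any(hit)
      }
      expect_equal(res$fraction[res$group == g], manual / sum(tp == g))
    }
  }
})

test_that("adding genes under 'all' never increases the fraction", {
  set.seed(31)
  mat <- matrix(rpois(30 * 40, 1), 30, 40)
  d <- toy_dataset(mat, timepoint = rep(c("a", "b"), 20))
  picks <- sprintf("gene%03d", c(1, 5, 9, 13))
  prev <- rep(1, 2)
  for (k in seq_along(picks)) {
    fr <- fraction_expressing(d, picks[seq_len(k)])$fraction
    expect_true(all(fr <= prev + 1e-12))
    prev <- fr
  }
})

test_that("z-score kinetics standardize per-timepoint means", {
  ln <- rbind(c(0, 0, 2, 2),      # means 0 and 2 -> z = -/+ 1/sqrt(2)
              c(1, 1, 1, 1))      # constant -> z = 0
  norm <- toy_norm(ln, c("gA", "gB"), timepoint = c("t1", "t1", "t2", "t2"))
  res <- zscore_kinetics(norm, c("gA", "gB"))
  z <- attr(res, "per_gene")
  expect_equal(unname(z["gA", ]), c(-0.7071068, 0.7071068),
               tolerance = 1e-6)
  expect_equal(unname(z["gB", ]), c(0, 0))
  # mean over a single-gene set equals that gene's z-scores
  solo <- zscore_kinetics(norm, "gA")
  expect_equal(solo$mean_z, unname(z["gA", ]))
  expect_equal(res$mean_z, unname(colMeans(z)))
})

test_that("fold-changes to baseline follow the ratio-of-means definition", {
  ln <- rbind(c(log1p(1), log1p(1), log1p(3), log1p(3)),
              c(0, 0, 0, 0))
  norm <- toy_norm(ln, c("gA", "gB"), timepoint = c("Hom", "Hom", "d3", "d3"))
  res <- foldchange_to_baseline(norm, c("gA", "gB"), baseline = "Hom",
                                pseudocount = 1e-12)
  fc <- attr(res, "per_gene")
  expect_equal(unname(fc["gA", "Hom"]), 1)
  expect_equal(unname(fc["gA", "d3"]), log1p(3) / log1p(1),
               tolerance = 1e-9)
  expect_equal(unname(fc["gB", "d3"]), 1)   # 0/0 -> pc/pc = 1
  expect_error(foldchange_to_baseline(norm, "gA", baseline = "d99"),
               "d99")
})

test_that("quadrant thresholds use the pooled nonzero median", {
  ln <- rbind(c(0, 1, 2, 3, 4, 0), c(4, 3, 0, 0, 1, 2))
  norm <- toy_norm(ln, c("mx", "my"),
                  timepoint = c("t1", "t1", "t1", "t2", "t2", "t2"))
  res <- quadrant_analysis(norm, "mx", "my")
  thr <- attr(res, "thresholds")
  expect_equal(unname(thr), c(2.5, 2.5))   # median of {1,2,3,4}
  # cells at 3 and 4 are strong; per timepoint percentages sum to 100
  sums <- tapply(res$percent, res$group, sum)
  expect_equal(as.numeric(sums), c(100, 100))
  t1 <- res[res$group == "t1", ]
  expect_equal(t1$percent[t1$box == "y_only"], 200 / 3)  # my = 4 and 3
  expect_equal(t1$percent[t1$box == "x_only"], 0)
  zero <- toy_norm(rbind(rep(0, 4), rep(1, 4)), c("mx", "my"),
                   timepoint = rep("t1", 4))
  expect_error(quadrant_analysis(zero, "mx", "my"), "no nonzero")
})

test_that("kinetics summaries are invariant to cell order", {
  set.seed(13)
  sim <- simulate_dataset(sim_config(n_cells_per_timepoint = 80, seed = 13))
  norm <- lognormalize(sim$dataset)
  perm <- sample(ncol(norm$lognorm))
  norm2 <- subset_cells(norm, perm)
  panels <- default_marker_panels()
  a <- zscore_kinetics(norm, panels$endothelial)
  b <- zscore_kinetics(norm2, panels$endothelial)
  b <- b[match(a$group, b$group), ]
  expect_equal(a$mean_z, b$mean_z, tolerance = 1e-12)
  fa <- fraction_expressing(norm, c("Serpine1", "Fn1"))
  fb <- fraction_expressing(norm2, c("Serpine1", "Fn1"))
  expect_equal(fa$fraction, fb$fraction[match(fa$group, fb$group)])
})

test_that("EndMA classification recovers the planted transient schedule", {
  sched <- c(Hom = 0, d1 = 0.1, d3 = 0.5, d5 = 0.5, d7 = 0.4,
             d14 = 0.05, d28 = 0)
  cfg <- ec_only_config(500, seed = 17, endma_fraction_schedule = sched)
  sim <- simulate_dataset(cfg)
  ec <- subset_ec(sim$dataset)
  lab <- classify_endma(ec)
  tp <- ec$cell_meta$timepoint
  rec <- vapply(names(sched), function(t)
    mean(lab[tp == t] == "EndMA+"), numeric(1))
  expect_true(all(abs(rec - sched) <= 0.05))
  # transient shape: peak in d3-d7, reversion by d14
  expect_gt(max(rec[c("d3", "d5", "d7")]), 0.35)
  expect_lt(rec["d14"], 0.1)
  expect_lt(rec["Hom"], 0.05)
})
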