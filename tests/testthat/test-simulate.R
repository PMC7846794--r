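test_that("simulation is deterministic and validates its configuration", {
  cfg <- sim_config(n_cells_per_timepoint = 60, seed = 11)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.matrix(a$dataset$counts), as.matrix(b$dataset$counts))
  expect_identical(a$truth, b$truth)

  bad <- sim_config(n_cells_per_timepoint = 10)
  bad$cell_type_proportions[1, 1] <- 0.9
  expect_error(simulate_dataset(bad), "sum to 1")
  expect_error(sim_config(endma_fraction_schedule = c(nonsense = 0.5)),
               "unknown timepoint")
  expect_error(sim_config(endma_fraction_schedule = c(Hom = 1.2)),
               "\\[0, 1\\]")
})

test_that("an all-zero cell budget yields an empty dataset and truth", {
  sim <- simulate_dataset(sim_config(n_cells_per_timepoint = 0, seed = 1))
  expect_equal(ncol(sim$dataset$counts), 0)
  expect_equal(nrow(sim$truth), 0)
  expect_gt(nrow(sim$gene_params), 0)
})

test_that("ground-truth label frequencies realize the configured schedules", {
  cfg <- sim_config(n_cells_per_timepoint = 500, seed = 2)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth
  for (tp in cfg$timepoints) {
    ec <- tr[tr$timepoint == tp & tr$cell_type == "EC", ]
    expect_lt(abs(mean(ec$endma_flag) -
                    cfg$endma_fraction_schedule[[tp]]), 0.01)
    expect_lt(abs(mean(ec$cycle_phase != "G1") -
                    cfg$cycling_fraction_schedule[[tp]]), 0.01)
    expect_lt(abs(mean(ec$reporter_labeled) -
                    cfg$reporter_labeling_rate), 0.01)
  }
  # program flags only where the module defines them
  expect_true(all(!tr$endma_flag[tr$cell_type != "EC"]))
  expect_true(all(tr$cycle_phase %in% c("G1", "S", "G2M")))
})

test_that("per-gene count marginals match the configured NB means", {
  cfg <- sim_config(n_cells_per_timepoint = c(Hom = 5000),
                    timepoints = "Hom",
                    cell_type_proportions = matrix(
                      c(0, 1, 0, 0), 1,
                      dimnames = list("Hom", c("EC", "Fb", "Mono", "SMC"))),
                    library_sigma = 0, seed = 8)
  sim <- simulate_dataset(cfg)
  gp <- sim$gene_params
  hk <- grepl("^Hk", gp$gene)
  obs <- Matrix::rowMeans(sim$dataset$counts)[hk]
  mu <- gp$baseline_mean[hk]
  se <- sqrt((mu + mu^2 / gp$nb_size[hk]) / ncol(sim$dataset$counts))
  z <- (obs - mu) / se
  expect_gt(mean(abs(z) <= 3), 0.99)
})

test_that("reporter expression is bimodal at intermediate labeling rates", {
  cfg <- ec_only_config(800, seed = 4, reporter_labeling_rate = 0.5)
  sim <- simulate_dataset(cfg)
  norm <- lognormalize(sim$dataset)
  egfp <- as.numeric(norm$lognorm[match("EGFP", sim$dataset$gene_names), ])
  km <- stats::kmeans(egfp, centers = c(min(egfp), max(egfp)))
  expect_gt(abs(diff(km$centers)), 2)
  expect_gt(min(km$size) / length(egfp), 0.05)  # both modes populated
})

test_that("ligand-receptor catalog fixtures obey their contract", {
  expect_equal(nrow(simulate_lr_catalog(0)), 0)
  expect_error(simulate_lr_catalog(-1), ">= 0")
  a <- simulate_lr_catalog(50, seed = 9)
  b <- simulate_lr_catalog(50, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$score > 0 & a$score <= 1))
  expect_false(any(duplicated(a[c("ligand", "receptor")])))
  expect_true(all(c(a$ligand, a$receptor) %in%
                    endmakit:::gene_universe()))
})

test_that("clone-count tables have the image x area layout and null rate", {
  tab <- simulate_clone_counts(4, clonal_effect = 0, seed = 3)
  per_animal <- table(paste(tab$group, tab$animal))
  expect_true(all(per_animal == 5 * 6 * 3))   # 30 areas x 3 fluorophores
  expect_identical(tab, simulate_clone_counts(4, clonal_effect = 0,
                                              seed = 3))
  # flag rate under the null matches a Monte-Carlo estimate of the
  # 2-SD rule on fresh Poisson draws
  rate_sim <- mean(sapply(1:40, function(s) {
    mean(flag_clonal_areas(simulate_clone_counts(4, 0, seed = s))$clonal)
  }))
  set.seed(99)
  rate_mc <- mean(replicate(4000, {
    counts <- matrix(rpois(90, 8), 30, 3)
    hit <- sapply(1:3, function(j)
      counts[, j] > mean(counts[, j]) + 2 * sd(counts[, j]))
    mean(rowSums(hit) > 0)
  }))
  expect_lt(abs(rate_sim - rate_mc), 0.02)
})
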