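lr_toy <- function() {
  types <- c("A", "B", "C")
  genes <- c("L1", "R1", "L2", "R2", "x1", "x2")
  me <- matrix(0, 6, 3, dimnames = list(genes, types))
  fc <- matrix(0, 6, 3, dimnames = list(genes, types))
  me["L1", "A"] <- 1; fc["L1", "A"] <- 2.0
  me["R1", "B"] <- 1; fc["R1", "B"] <- 3.0
  list(me = me, fc = fc,
       catalog = data.frame(ligand = "L1", receptor = "R1", score = 0.9))
}

test_that("a single expressed path aggregates to the weight product", {
  toy <- lr_toy()
  g <- build_lr_graph(toy$me, toy$fc, toy$catalog)
  expect_equal(g$aggregate["A", "B"], 2.0 * 0.9 * 3.0)
  expect_equal(sum(g$aggregate), 5.4)
  expect_equal(sort(unique(g$edges$layer)),
               c("ligand_receptor", "receptor_target", "source_ligand"))
})

test_that("unexpressed ligands produce no edges and empty aggregates", {
  toy <- lr_toy()
  toy$me["L1", "A"] <- 0   # below min_expr everywhere
  g <- build_lr_graph(toy$me, toy$fc, toy$catalog)
  expect_equal(sum(g$aggregate), 0)
  expect_false(any(g$edges$layer == "source_ligand"))
  expect_error(build_lr_graph(toy$me, toy$fc,
                              data.frame(ligand = "Zz", receptor = "R1",
                                         score = 0.5)),
               "absent")
})

test_that("aggregates equal a brute-force triple loop", {
  set.seed(41)
  types <- c("A", "B", "C")
  genes <- sprintf("g%d", 1:12)
  me <- matrix(runif(36, 0, 0.4), 12, 3, dimnames = list(genes, types))
  fc <- matrix(rlnorm(36, 0, 0.5), 12, 3, dimnames = list(genes, types))
  cat5 <- data.frame(ligand = genes[1:5], receptor = genes[6:10],
                     score = runif(5, 0.2, 1))
  g <- build_lr_graph(me, fc, cat5, min_expr = 0.1)
  manual <- matrix(0, 3, 3, dimnames = list(types, types))
  for (p in 1:5) for (s in types) for (t in types) {
    lw <- if (me[cat5$ligand[p], s] >= 0.1) fc[cat5$ligand[p], s] else 0
    rw <- if (me[cat5$receptor[p], t] >= 0.1) fc[cat5$receptor[p], t] else 0
    manual[s, t] <- manual[s, t] + lw * cat5$score[p] * rw
  }
  expect_equal(unclass(g$aggregate), manual, tolerance = 1e-12)
  # linear in association scores
  cat2 <- cat5; cat2$score <- cat5$score * 2
  g2 <- build_lr_graph(me, fc, cat2, min_expr = 0.1)
  expect_equal(unclass(g2$aggregate), 2 * manual, tolerance = 1e-12)
})

test_that("permutation p-values hit the add-one floor for dominant signals", {
  set.seed(47)
  types <- c("A", "B", "C", "D")
  genes <- sprintf("g%03d", 1:60)
  me <- matrix(1, 60, 4, dimnames = list(genes, types))
  fc <- matrix(exp(rnorm(240, 0, 0.05)), 60, 4,
               dimnames = list(genes, types))
  cat8 <- simulate_lr_catalog(30, seed = 3, genes = genes)
  cat8$score[1:8] <- 0.95
  for (i in 1:8) {
    fc[cat8$ligand[i], "A"] <- 6
    fc[cat8$receptor[i], "B"] <- 6
  }
  g <- permutation_significance(build_lr_graph(me, fc, cat8),
                                n_perm = 199, alpha = 0.05, seed = 11)
  s <- g$significance
  expect_equal(s$p[s$source == "A" & s$target == "B"], 1 / 200)
  # determinism of flags and p-values
  g2 <- permutation_significance(build_lr_graph(me, fc, cat8),
                                 n_perm = 199, alpha = 0.05, seed = 11)
  expect_identical(g$significance, g2$significance)
  expect_error(permutation_significance(build_lr_graph(me, fc, cat8),
                                        n_perm = 50), "at least 100")
})

test_that("BH adjustment is monotone and flags shrink with alpha", {
  set.seed(53)
  types <- c("A", "B", "C", "D")
  genes <- sprintf("g%03d", 1:50)
  me <- matrix(1, 50, 4, dimnames = list(genes, types))
  fc <- matrix(exp(rnorm(200, 0, 0.4)), 50, 4,
               dimnames = list(genes, types))
  catn <- simulate_lr_catalog(25, seed = 5, genes = genes)
  g <- permutation_significance(build_lr_graph(me, fc, catn),
                                n_perm = 300, alpha = 0.2, seed = 2)
  s <- g$significance
  o <- order(s$p)
  expect_true(all(diff(s$p_adj[o]) >= -1e-12))
  expect_equal(s$p_adj, p.adjust(s$p, "BH"))
  loose <- sum(s$p_adj < 0.2)
  tight <- sum(s$p_adj < 0.05)
  expect_lte(tight, loose)
})
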