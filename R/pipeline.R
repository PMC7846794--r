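# End-to-end pipeline driver: QC -> reporter calling -> EC subset ->
# EndMA classification -> kinetics -> cell cycle -> DE -> enrichment ->
# ligand-receptor network, with per-stage CSV outputs.

#' Pipeline configuration
#'
#' Collects every module parameter with the analysis defaults (minimum
#' 200 genes, mitochondrial cap 0.10, 5%/1% depth percentile bands,
#' UMI >= 1 marker gating, 100,000 network permutations at adjusted
#' alpha 0.01) plus input/output paths. With `counts_dir = NULL` the
#' pipeline runs on a dataset simulated from `sim` (and then also writes
#' ground truth).
#'
#' @param out_dir output directory.
#' @param counts_dir optional 10x-style input directory.
#' @param sim a [sim_config()] used when no counts are supplied.
#' @param min_genes,max_mito,upper_pct,lower_pct QC thresholds.
#' @param reporter_gene transgene for reporter calling (default
#'   `"EGFP"`).
#' @param ec_gate,endma_markers marker gates.
#' @param n_perm,alpha ligand-receptor permutation settings.
#' @param n_lr_pairs catalog size simulated when none is given.
#' @param lr_catalog optional data.frame (`ligand`, `receptor`, `score`).
#' @param seed integer master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, counts_dir = NULL, sim = NULL,
                            min_genes = 200, max_mito = 0.10,
                            upper_pct = 0.05, lower_pct = 0.01,
                            reporter_gene = "EGFP",
                            ec_gate = c("Cdh5", "Pecam1"),
                            endma_markers = c("Serpine1", "Fn1"),
                            n_perm = 1e5, alpha = 0.01,
                            n_lr_pairs = 60, lr_catalog = NULL,
                            seed = 1L) {
  if (missing(out_dir) || is.null(out_dir))
    stop("pipeline_config: out_dir is required")
  if (is.null(counts_dir) && is.null(sim))
    sim <- sim_config(seed = seed)
  structure(list(out_dir = out_dir, counts_dir = counts_dir, sim = sim,
                 min_genes = min_genes, max_mito = max_mito,
                 upper_pct = upper_pct, lower_pct = lower_pct,
                 reporter_gene = reporter_gene, ec_gate = ec_gate,
                 endma_markers = endma_markers, n_perm = n_perm,
                 alpha = alpha, n_lr_pairs = n_lr_pairs,
                 lr_catalog = lr_catalog, seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

write_out <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes QC, normalization, reporter calling (when the transgene is
#' present), endothelial subsetting, EndMA classification, marker
#' kinetics, cell-cycle scoring with the phase-independence test,
#' EndMA+ versus EndMA- differential expression, term enrichment of the
#' upregulated genes against the built-in marker panels, and the
#' ligand-receptor permutation network. Every stage writes a tidy CSV to
#' `config$out_dir`; outputs are a pure function of (inputs, config,
#' seed).
#'
#' @param config a [pipeline_config()].
#' @return Invisible list of the stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_lines <- utils::capture.output(utils::str(unclass(
    config[setdiff(names(config), c("sim", "lr_catalog"))])))
  writeLines(c(cfg_lines,
               sprintf("endmakit version: %s",
                       as.character(utils::packageVersion("endmakit")))),
             file.path(config$out_dir, "resolved_config.txt"))

  truth <- NULL
  data <- run_stage("load", {
    if (!is.null(config$counts_dir)) {
      read_10x_mtx(config$counts_dir)
    } else {
      sim <- simulate_dataset(config$sim)
      truth <- sim$truth
      write_out(truth, config$out_dir, "ground_truth.csv")
      sim$dataset
    }
  })

  filtered <- run_stage("qc", {
    f <- filter_cells(data, config$min_genes, config$max_mito,
                      config$upper_pct, config$lower_pct)
    write_out(attr(f, "qc_report"), config$out_dir, "qc_report.csv")
    f
  })
  norm <- run_stage("normalize", lognormalize(filtered))

  reporter <- NULL
  if (config$reporter_gene %in% filtered$gene_names &&
      sum(filtered$counts[match(config$reporter_gene,
                                filtered$gene_names), ]) > 0) {
    reporter <- run_stage("reporter", {
      r <- call_reporter_by_sample(norm, gene = config$reporter_gene)
      write_out(r, config$out_dir, "reporter_calls.csv")
      r
    })
  }

  ec <- run_stage("ec_subset", subset_ec(norm, config$ec_gate))
  endma <- run_stage("endma", {
    lab <- classify_endma(ec, config$endma_markers)
    tp <- ec$data$cell_meta$timepoint
    kin <- data.frame(timepoint = unique(tp),
                      n_ec = as.numeric(table(tp)[unique(tp)]),
                      endma_fraction = vapply(unique(tp), function(t)
                        mean(lab[tp == t] == "EndMA+"), numeric(1)))
    write_out(kin, config$out_dir, "endma_kinetics.csv")
    list(labels = lab, kinetics = kin)
  })

  panels <- default_marker_panels()
  kinetics <- run_stage("kinetics", {
    fr <- fraction_expressing(ec, config$endma_markers,
                              combination = "all")
    zs <- zscore_kinetics(ec, panels$endothelial)
    fc <- foldchange_to_baseline(ec, panels$mesenchymal,
                                 baseline = ec$data$cell_meta$timepoint[1])
    qd <- quadrant_analysis(ec, "Pecam1", "Fn1")
    write_out(fr, config$out_dir, "fraction_expressing.csv")
    write_out(zs, config$out_dir, "zscore_kinetics.csv")
    write_out(fc, config$out_dir, "foldchange.csv")
    write_out(qd, config$out_dir, "quadrants.csv")
    list(fraction = fr, zscore = zs, foldchange = fc, quadrants = qd)
  })

  cycle <- run_stage("cell_cycle", {
    sc <- score_cell_cycle(ec, seed = config$seed + 10L)
    sc$timepoint <- ec$data$cell_meta$timepoint
    tab <- table(sc$phase, sc$timepoint)
    test <- if (nrow(tab) >= 2 && ncol(tab) >= 2) {
      phase_independence_test(tab)
    } else list(statistic = NA_real_, df = NA_integer_,
                p.value = NA_real_)
    write_out(sc, config$out_dir, "cell_cycle.csv")
    write_out(data.frame(statistic = test$statistic, df = test$df,
                         p = test$p.value),
              config$out_dir, "cell_cycle_test.csv")
    list(scores = sc, test = test)
  })

  de <- run_stage("de", {
    mask <- endma$labels == "EndMA+"
    if (any(mask) && !all(mask)) {
      d <- de_bimod(ec, mask)
      write_out(d, config$out_dir, "de_endma.csv")
      d
    } else NULL
  })

  enrichment <- run_stage("enrich", {
    if (!is.null(de)) {
      up <- de$gene[de$p_bonferroni < 0.05 & de$log_fc > 0]
      if (length(up) >= 2) {
        lib <- panels[c("mesenchymal", "endothelial_extended", "immune",
                        "glycolysis", "tca", "fa_signaling", "ppp",
                        "glutamine", "stress")]
        detected <- ec$data$gene_names[
          Matrix::rowSums(ec$data$counts) > 0]
        e <- enrich_terms(up, lib, background = detected,
                          seed = config$seed + 20L)
        write_out(e, config$out_dir, "enrichment.csv")
        e
      } else NULL
    } else NULL
  })

  lr <- run_stage("lr_network", {
    ct <- if (!is.null(truth)) {
      truth$cell_type[match(norm$data$barcodes, truth$barcode)]
    } else if ("cell_type" %in% names(norm$data$cell_meta)) {
      norm$data$cell_meta$cell_type
    } else NULL
    if (!is.null(ct) && length(unique(ct)) >= 2) {
      catalog <- if (!is.null(config$lr_catalog)) config$lr_catalog
        else simulate_lr_catalog(config$n_lr_pairs,
                                 seed = config$seed + 30L,
                                 genes = norm$data$gene_names)
      prof <- celltype_profiles(norm, ct)
      g <- build_lr_graph(prof$mean, prof$fc, catalog)
      g <- permutation_significance(g, n_perm = config$n_perm,
                                    alpha = config$alpha,
                                    seed = config$seed + 40L)
      write_out(g$significance, config$out_dir, "lr_significance.csv")
      g
    } else NULL
  })

  summary_df <- data.frame(
    stage = c("cells_in", "cells_pass_qc", "ec_cells", "endma_positive",
              "reporter_positive", "de_genes_tested",
              "lr_significant"),
    value = c(ncol(data$counts), ncol(filtered$counts),
              ncol(as_count_data(ec)$counts),
              sum(endma$labels == "EndMA+"),
              if (is.null(reporter)) NA else sum(reporter$positive),
              if (is.null(de)) NA else nrow(de),
              if (is.null(lr)) NA else sum(lr$significance$significant)))
  write_out(summary_df, config$out_dir, "summary.csv")
  writeLines(c("endmakit pipeline run",
               sprintf("seed: %d", config$seed),
               sprintf("version: %s",
                       as.character(utils::packageVersion("endmakit"))),
               sprintf("R: %s", paste(R.version$major, R.version$minor,
                                      sep = "."))),
             file.path(config$out_dir, "run_log.txt"))
  invisible(list(data = data, truth = truth, filtered = filtered,
                 norm = norm, reporter = reporter, ec = ec,
                 endma = endma, kinetics = kinetics, cycle = cycle,
                 de = de, enrichment = enrichment, lr = lr,
                 summary = summary_df))
}
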