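# Seeded synthetic-data generator: multi-timepoint UMI counts with ground
# truth, ligand-receptor catalog fixtures, and Confetti clone-count tables.

# The simulated gene universe: identity markers for the four cell types,
# stress and metabolic panels, cell-cycle genes, mitochondrial genes,
# unnamed housekeeping filler, and the two transgenes appended last.
gene_universe <- function(n_housekeeping = 800) {
  p <- default_marker_panels()
  cc <- default_cell_cycle_genes()
  hk <- sprintf("Hk%04d", seq_len(n_housekeeping))
  unique(c(p$endothelial_extended, p$mesenchymal, p$immune, p$smc,
           p$stress, p$glycolysis, p$tca, p$fa_signaling, p$ppp,
           p$glutamine, cc$s, cc$g2m, mito_gene_symbols(), hk,
           "EGFP", "tdTomato"))
}

# Split n into integer counts proportional to p (largest-remainder rule),
# so configured fractions are realized exactly.
apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

default_type_proportions <- function(timepoints) {
  std <- rbind(
    Hom = c(EC = 0.35, Fb = 0.40, Mono = 0.15, SMC = 0.10),
    d1  = c(0.20, 0.25, 0.45, 0.10),
    d3  = c(0.15, 0.25, 0.50, 0.10),
    d5  = c(0.20, 0.30, 0.40, 0.10),
    d7  = c(0.25, 0.35, 0.30, 0.10),
    d14 = c(0.30, 0.40, 0.20, 0.10),
    d28 = c(0.35, 0.40, 0.15, 0.10))
  colnames(std) <- c("EC", "Fb", "Mono", "SMC")
  if (all(timepoints %in% rownames(std))) return(std[timepoints, , drop = FALSE])
  m <- matrix(rep(c(0.35, 0.35, 0.20, 0.10), each = length(timepoints)),
              nrow = length(timepoints),
              dimnames = list(timepoints, c("EC", "Fb", "Mono", "SMC")))
  m
}

named_schedule <- function(x, timepoints, what) {
  if (any(x < 0 | x > 1)) stop(what, " values must lie in [0, 1]")
  if (is.null(names(x))) {
    if (length(x) == 1L) x <- rep(x, length(timepoints))
    if (length(x) != length(timepoints))
      stop(what, " must have one value per timepoint")
    names(x) <- timepoints
  }
  if (!all(names(x) %in% timepoints))
    stop("unknown timepoint label in ", what, ": ",
         paste(setdiff(names(x), timepoints), collapse = ", "))
  out <- x[timepoints]
  names(out) <- timepoints
  if (anyNA(out)) stop(what, " missing value for some timepoints")
  if (any(out < 0 | out > 1)) stop(what, " values must lie in [0, 1]")
  out
}

#' Simulation configuration
#'
#' Defines the study conditions emulated by [simulate_dataset()]: a
#' seven-timepoint post-infarction time course (`Hom`, `d1`, `d3`, `d5`,
#' `d7`, `d14`, `d28`) of non-cardiomyocyte cells (endothelial, fibroblast,
#' monocyte, smooth muscle), with a transient mesenchymal program in
#' endothelial cells peaking at days 3-7 and reverting by day 14, a bimodal
#' EGFP lineage-tracing reporter, and cell-cycle activity peaking at day 3.
#'
#' Counts are negative binomial per gene and program; library-size
#' variation is a lognormal per-cell factor so that percentile-based QC has
#' something to trim. Configured fractions are realized exactly (largest
#' remainder / exact subset sizes), so ground-truth label frequencies match
#' the schedules up to rounding.
#'
#' @param n_cells_per_timepoint integer, scalar or named by timepoint.
#' @param timepoints ordered character vector of timepoint labels.
#' @param cell_type_proportions matrix (timepoints x EC/Fb/Mono/SMC) of
#'   composition simplexes; rows must sum to 1 within 1e-9.
#' @param endma_fraction_schedule per-timepoint fraction of endothelial
#'   cells carrying the mesenchymal (EndMA) program, in `[0, 1]`.
#' @param cycling_fraction_schedule per-timepoint fraction of endothelial
#'   cells in S or G2/M phase.
#' @param reporter_labeling_rate fraction of endothelial cells carrying the
#'   recombined reporter (EGFP high, tdTomato off).
#' @param ambient_reporter_rate fraction of unlabeled cells with spurious
#'   low EGFP counts (ambient contamination).
#' @param nb_size negative-binomial size (inverse dispersion); list with
#'   `baseline` (housekeeping/marker genes) and `program` (induced program
#'   genes, less dispersed).
#' @param expr named list of mean expression levels per gene program (UMI
#'   scale): `marker` (identity markers), `marker_core` (Cdh5/Pecam1 in
#'   endothelial cells and the strongest markers of other types),
#'   `marker_low` (off-type leak), `endma` (mesenchymal genes in activated
#'   cells), `endma_ec_atten` (attenuation of non-core endothelial genes in
#'   activated cells), `reporter` (EGFP in labeled cells), `ambient`,
#'   `tdtomato`, `cycle_base`, `cycle_boost`, `mito`, `stress`, and the
#'   housekeeping gamma parameters `hk_shape`, `hk_rate`.
#' @param library_sigma sd (log scale) of the lognormal per-cell depth
#'   factor.
#' @param n_housekeeping number of filler housekeeping genes.
#' @param seed integer; single global seed for all substreams.
#' @return Object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_cells_per_timepoint = 1000,
                       timepoints = c("Hom", "d1", "d3", "d5", "d7",
                                      "d14", "d28"),
                       cell_type_proportions = NULL,
                       endma_fraction_schedule = c(Hom = 0.02, d1 = 0.15,
                                                   d3 = 0.45, d5 = 0.45,
                                                   d7 = 0.35, d14 = 0.05,
                                                   d28 = 0.02),
                       cycling_fraction_schedule = c(Hom = 0.05, d1 = 0.10,
                                                     d3 = 0.30, d5 = 0.25,
                                                     d7 = 0.15, d14 = 0.05,
                                                     d28 = 0.05),
                       reporter_labeling_rate = 0.8,
                       ambient_reporter_rate = 0.05,
                       nb_size = list(baseline = 2, program = 3),
                       expr = list(),
                       library_sigma = 0.3,
                       n_housekeeping = 800,
                       seed = 1L) {
  stopifnot(length(timepoints) >= 1, !anyDuplicated(timepoints))
  n <- n_cells_per_timepoint
  if (is.null(names(n))) {
    if (length(n) == 1L) n <- rep(n, length(timepoints))
    names(n) <- timepoints
  }
  if (!all(names(n) %in% timepoints))
    stop("unknown timepoint label in n_cells_per_timepoint: ",
         paste(setdiff(names(n), timepoints), collapse = ", "))
  n <- n[timepoints]
  names(n) <- timepoints
  if (anyNA(n) || any(n < 0) || any(n != round(n)))
    stop("n_cells_per_timepoint must be nonnegative integers")
  if (is.null(cell_type_proportions))
    cell_type_proportions <- default_type_proportions(timepoints)
  ctp <- as.matrix(cell_type_proportions)
  if (!all(rownames(ctp) %in% timepoints) || nrow(ctp) != length(timepoints))
    stop("cell_type_proportions rows must match the timepoints")
  ctp <- ctp[timepoints, , drop = FALSE]
  if (any(abs(rowSums(ctp) - 1) > 1e-9))
    stop("cell_type_proportions rows must sum to 1 (within 1e-9)")
  if (any(ctp < 0)) stop("cell_type_proportions must be nonnegative")
  # default schedules adapt to a reduced timepoint grid
  if (missing(endma_fraction_schedule))
    endma_fraction_schedule <-
      endma_fraction_schedule[names(endma_fraction_schedule) %in% timepoints]
  if (missing(cycling_fraction_schedule))
    cycling_fraction_schedule <-
      cycling_fraction_schedule[names(cycling_fraction_schedule) %in%
                                  timepoints]
  endma <- named_schedule(endma_fraction_schedule, timepoints,
                          "endma_fraction_schedule")
  cyc <- named_schedule(cycling_fraction_schedule, timepoints,
                        "cycling_fraction_schedule")
  stopifnot(reporter_labeling_rate >= 0, reporter_labeling_rate <= 1,
            ambient_reporter_rate >= 0, ambient_reporter_rate <= 1,
            library_sigma >= 0, n_housekeeping >= 0)
  expr_def <- list(marker = 3, marker_core = 10, marker_low = 0.02,
                   endma = 15, endma_ec_atten = 0.6, reporter = 20,
                   ambient = 0.5, tdtomato = 10, cycle_base = 0.05,
                   cycle_boost = 80, mito = 2, stress = 0.5,
                   hk_shape = 0.8, hk_rate = 0.8)
  expr_def[names(expr)] <- expr
  structure(list(n_cells_per_timepoint = n, timepoints = timepoints,
                 cell_type_proportions = ctp,
                 endma_fraction_schedule = endma,
                 cycling_fraction_schedule = cyc,
                 reporter_labeling_rate = reporter_labeling_rate,
                 ambient_reporter_rate = ambient_reporter_rate,
                 nb_size = nb_size, expr = expr_def,
                 library_sigma = library_sigma,
                 n_housekeeping = n_housekeeping,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multi-timepoint single-cell UMI dataset with ground truth
#'
#' Draws a sparse genes x cells UMI matrix under the configured study
#' conditions and returns it together with the per-cell ground truth
#' (cell type, EndMA flag, reporter label, cycle phase, trajectory-state
#' emulation label, depth factor) that fully determines the generative
#' parameters of every cell.
#'
#' Program structure: endothelial cells express `Cdh5`/`Pecam1` at the core
#' level and other endothelial genes at marker level; EndMA-flagged
#' endothelial cells additionally draw mesenchymal genes (`Col1a1`,
#' `Col3a1`, `Serpine1`, `Fn1`, ...) from the elevated `endma` mean and
#' attenuate their non-core endothelial genes; reporter-labeled cells get
#' high-mode EGFP and lose tdTomato; ambient cells a low EGFP mode; cycling
#' cells elevated S or G2/M gene counts.
#'
#' @param config a [sim_config()] object.
#' @return List with `dataset` (a [count_dataset()]), `truth` (data.frame,
#'   one row per cell) and `gene_params` (per-gene baseline NB mean and
#'   size, so that truth labels plus gene parameters fully determine every
#'   cell's generative distribution). Deterministic given `config$seed`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_cells_per_timepoint = 50, seed = 7))
#' sim$dataset
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  # re-validate: config lists can be edited after construction
  if (any(abs(rowSums(config$cell_type_proportions) - 1) > 1e-9))
    stop("cell_type_proportions rows must sum to 1 (within 1e-9)")
  for (sched in c("endma_fraction_schedule", "cycling_fraction_schedule"))
    named_schedule(config[[sched]], config$timepoints, sched)
  set.seed(config$seed)
  p <- default_marker_panels()
  cc <- default_cell_cycle_genes()
  genes <- gene_universe(config$n_housekeeping)
  nG <- length(genes)
  gi <- function(g) match(intersect(g, genes), genes)
  idx <- list(
    endo_core = gi(c("Cdh5", "Pecam1")),
    endo_rest = gi(setdiff(p$endothelial_extended, c("Cdh5", "Pecam1"))),
    mesench = gi(p$mesenchymal),
    immune = gi(p$immune),
    smc = gi(unique(c(p$smc, "Acta2", "Tagln", "Cnn1"))),
    stress = gi(p$stress),
    s_genes = gi(cc$s),
    g2m_genes = gi(cc$g2m),
    mito = gi(mito_gene_symbols()),
    hk = grep("^Hk\\d", genes),
    egfp = match("EGFP", genes),
    tdtom = match("tdTomato", genes))
  ex <- config$expr

  # Baseline means shared by all cells; markers leak at marker_low off-type.
  baseline <- rep(ex$marker_low, nG)
  # Housekeeping background: gamma bulk plus a low-expression block so
  # every expression stratum (in particular the one the cell-cycle genes
  # occupy) is densely populated for bin-matched control sampling.
  n_hk <- length(idx$hk)
  n_low <- round(0.3 * n_hk)
  baseline[idx$hk] <- c(stats::runif(n_low, 0.03, 0.3),
                        pmax(stats::rgamma(n_hk - n_low,
                                           shape = ex$hk_shape,
                                           rate = ex$hk_rate), 0.01))
  baseline[idx$mito] <- ex$mito
  baseline[idx$stress] <- ex$stress
  baseline[c(idx$s_genes, idx$g2m_genes)] <- ex$cycle_base
  baseline[c(idx$egfp, idx$tdtom)] <- 0

  # Per-gene NB size: induced-program genes are less dispersed.
  size_gene <- rep(config$nb_size$baseline, nG)
  size_gene[c(idx$mesench, idx$endo_core, idx$s_genes, idx$g2m_genes,
              idx$egfp, idx$tdtom)] <- config$nb_size$program

  tps <- config$timepoints
  n_per <- config$n_cells_per_timepoint
  total <- sum(n_per)
  types <- c("EC", "Fb", "Mono", "SMC")

  truth_list <- vector("list", length(tps))
  M <- matrix(0, nG, total)
  col0 <- 0L
  for (ti in seq_along(tps)) {
    tp <- tps[ti]
    n <- n_per[[tp]]
    if (n == 0L) { truth_list[[ti]] <- NULL; next }
    ct_counts <- apportion(n, config$cell_type_proportions[tp, types])
    cell_type <- rep(types, ct_counts)
    cell_type <- cell_type[sample.int(n)]
    ec <- which(cell_type == "EC")
    n_ec <- length(ec)

    endma <- logical(n)
    if (n_ec > 0) {
      k <- round(config$endma_fraction_schedule[[tp]] * n_ec)
      if (k > 0) endma[ec[sample.int(n_ec, k)]] <- TRUE
    }
    phase <- rep("G1", n)
    if (n_ec > 0) {
      k <- round(config$cycling_fraction_schedule[[tp]] * n_ec)
      if (k > 0) {
        cyc_cells <- ec[sample.int(n_ec, k)]
        half <- seq_len(k) <= ceiling(k / 2)
        phase[cyc_cells[half]] <- "S"
        phase[cyc_cells[!half]] <- "G2M"
      }
    }
    labeled <- logical(n)
    if (n_ec > 0) {
      k <- round(config$reporter_labeling_rate * n_ec)
      if (k > 0) labeled[ec[sample.int(n_ec, k)]] <- TRUE
    }
    ambient <- logical(n)
    unl <- which(!labeled)
    k <- round(config$ambient_reporter_rate * length(unl))
    if (k > 0) ambient[unl[sample.int(length(unl), k)]] <- TRUE

    # Trajectory-state emulation labels (EC only): mesenchymal program ->
    # state 4, cycling -> state 5, remainder spread over quiescent /
    # inflammatory states 1-3. Assigned, never inferred.
    state <- rep(NA_integer_, n)
    if (n_ec > 0) {
      state[ec] <- sample(1:3, n_ec, replace = TRUE,
                          prob = if (tp %in% c("d1", "d3")) c(.3, .2, .5)
                                 else c(.5, .3, .2))
      state[ec][phase[ec] != "G1"] <- 5L
      state[endma] <- 4L
    }

    # Mean matrix for this block.
    Mb <- matrix(baseline, nG, n)
    set_rows <- function(Mb, rows, cols, value) {
      if (length(rows) && length(cols)) Mb[rows, cols] <- value
      Mb
    }
    fb <- which(cell_type == "Fb"); mono <- which(cell_type == "Mono")
    smc <- which(cell_type == "SMC")
    Mb <- set_rows(Mb, idx$endo_core, ec, ex$marker_core)
    Mb <- set_rows(Mb, idx$endo_rest, ec, ex$marker)
    Mb <- set_rows(Mb, idx$mesench, fb, ex$marker)
    Mb <- set_rows(Mb, idx$immune, mono, ex$marker)
    Mb <- set_rows(Mb, idx$smc, smc, ex$marker)
    # EndMA program: mesenchymal genes up, non-core endothelial genes down.
    w <- which(endma)
    Mb <- set_rows(Mb, idx$mesench, w, ex$endma)
    Mb <- set_rows(Mb, idx$endo_rest, w, ex$marker * ex$endma_ec_atten)
    # Cell cycle.
    Mb <- set_rows(Mb, idx$s_genes, which(phase == "S"),
                   ex$cycle_base * ex$cycle_boost)
    Mb <- set_rows(Mb, idx$g2m_genes, which(phase == "G2M"),
                   ex$cycle_base * ex$cycle_boost)
    # Reporter transgenes.
    Mb[idx$egfp, labeled] <- ex$reporter
    Mb[idx$egfp, ambient] <- ex$ambient
    Mb[idx$tdtom, !labeled] <- ex$tdtomato

    sf <- exp(stats::rnorm(n, 0, config$library_sigma))
    Mb <- sweep(Mb, 2, sf, `*`)
    M[, col0 + seq_len(n)] <- Mb
    truth_list[[ti]] <- data.frame(
      timepoint = tp, cell_type = cell_type, endma_flag = endma,
      reporter_labeled = labeled, ambient_reporter = ambient,
      cycle_phase = phase, trajectory_state = state, size_factor = sf,
      stringsAsFactors = FALSE)
    col0 <- col0 + n
  }

  gene_params <- data.frame(gene = genes, baseline_mean = baseline,
                            nb_size = size_gene, stringsAsFactors = FALSE)
  truth <- do.call(rbind, truth_list)
  if (is.null(truth)) {
    truth <- data.frame(barcode = character(), timepoint = character(),
                        cell_type = character(), endma_flag = logical(),
                        reporter_labeled = logical(),
                        ambient_reporter = logical(),
                        cycle_phase = character(),
                        trajectory_state = integer(),
                        size_factor = numeric(), stringsAsFactors = FALSE)
    counts <- Matrix::Matrix(0, nG, 0, sparse = TRUE,
                             dimnames = list(genes, NULL))
    ds <- count_dataset(counts, gene_ids = genes,
                        cell_meta = data.frame(barcode = character(),
                                               timepoint = character(),
                                               sample = character(),
                                               stringsAsFactors = FALSE))
    return(list(dataset = ds, truth = truth, gene_params = gene_params))
  }

  counts <- matrix(stats::rnbinom(nG * total,
                                  size = rep(size_gene, total),
                                  mu = as.vector(M)),
                   nG, total)
  barcodes <- sprintf("%s_cell%05d", truth$timepoint,
                      stats::ave(seq_len(total), truth$timepoint,
                                 FUN = seq_along))
  truth <- cbind(barcode = barcodes, truth, stringsAsFactors = FALSE)
  meta <- data.frame(barcode = barcodes, timepoint = truth$timepoint,
                     sample = truth$timepoint, stringsAsFactors = FALSE)
  dimnames(counts) <- list(genes, barcodes)
  ds <- count_dataset(Matrix::Matrix(counts, sparse = TRUE),
                      gene_ids = genes, cell_meta = meta)
  list(dataset = ds, truth = truth, gene_params = gene_params)
}

#' Simulate a ligand-receptor pair catalog
#'
#' Fixture generator for the ligand-receptor network: random ligand ->
#' receptor pairs over genes of the simulated universe, with association
#' scores in (0, 1].
#'
#' @param n_pairs number of pairs (>= 0).
#' @param seed integer seed.
#' @param genes gene universe to draw from; defaults to the simulated one.
#' @return data.frame with columns `ligand`, `receptor`, `score`.
#' @export
simulate_lr_catalog <- function(n_pairs, seed = 1L, genes = NULL) {
  if (n_pairs < 0) stop("n_pairs must be >= 0")
  if (is.null(genes)) genes <- setdiff(gene_universe(), c("EGFP", "tdTomato"))
  if (n_pairs == 0)
    return(data.frame(ligand = character(), receptor = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  set.seed(seed)
  pairs <- unique(data.frame(
    ligand = sample(genes, 4 * n_pairs, replace = TRUE),
    receptor = sample(genes, 4 * n_pairs, replace = TRUE),
    stringsAsFactors = FALSE))
  pairs <- pairs[pairs$ligand != pairs$receptor, , drop = FALSE]
  if (nrow(pairs) < n_pairs) stop("gene universe too small for n_pairs")
  pairs <- pairs[seq_len(n_pairs), ]
  pairs$score <- 1 - stats::runif(n_pairs) * (1 - 1e-6)
  rownames(pairs) <- NULL
  pairs
}

#' Simulate Confetti clone-count area tables
#'
#' Emulates per-animal border-zone image quantification: 5 images per
#' animal, each split into 6 equal areas, with counts of RFP/YFP/GFP
#' labeled cells per area. Two groups are generated (`control`, `treated`);
#' `clonal_effect > 0` inflates one fluorophore in a random subset of
#' control-group areas, emulating clonal expansion.
#'
#' @param n_animals_per_group integer >= 1.
#' @param clonal_effect nonnegative multiplier increment: inflated areas
#'   draw from `base_rate * (1 + clonal_effect)`.
#' @param seed integer seed.
#' @param base_rate Poisson mean count per area and fluorophore.
#' @param inflate_fraction fraction of control areas carrying the effect.
#' @param n_images,n_areas layout of the quantification grid.
#' @return data.frame: `group`, `animal`, `image`, `area`, `fluorophore`,
#'   `count`, and the generative flag `inflated`.
#' @export
simulate_clone_counts <- function(n_animals_per_group, clonal_effect = 0,
                                  seed = 1L, base_rate = 8,
                                  inflate_fraction = 0.15,
                                  n_images = 5, n_areas = 6) {
  if (n_animals_per_group < 1) stop("n_animals_per_group must be >= 1")
  if (clonal_effect < 0) stop("clonal_effect must be nonnegative")
  set.seed(seed)
  fluors <- c("RFP", "YFP", "GFP")
  grid <- expand.grid(fluorophore = fluors, area = seq_len(n_areas),
                      image = seq_len(n_images),
                      animal = seq_len(n_animals_per_group),
                      group = c("control", "treated"),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("group", "animal", "image", "area", "fluorophore")]
  grid$animal <- paste0(substr(grid$group, 1, 1), grid$animal)
  mu <- rep(base_rate, nrow(grid))
  grid$inflated <- FALSE
  if (clonal_effect > 0) {
    ctrl_areas <- unique(grid[grid$group == "control",
                              c("group", "animal", "image", "area")])
    k <- round(inflate_fraction * nrow(ctrl_areas))
    if (k > 0) {
      sel <- ctrl_areas[sample.int(nrow(ctrl_areas), k), ]
      sel$fluorophore <- sample(fluors, k, replace = TRUE)
      key <- do.call(paste, c(grid[c("group", "animal", "image", "area",
                                     "fluorophore")], sep = "|"))
      selkey <- do.call(paste, c(sel, sep = "|"))
      hit <- key %in% selkey
      mu[hit] <- base_rate * (1 + clonal_effect)
      grid$inflated <- hit
    }
  }
  grid$count <- stats::rpois(nrow(grid), mu)
  rownames(grid) <- NULL
  grid
}
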