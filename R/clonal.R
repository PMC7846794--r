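# Confetti clonal-expansion statistics: per-animal 2-SD area flagging and
# Fisher group comparison.

#' Flag areas with clonally expanding cells
#'
#' For each animal and fluorophore, the mean and sample SD of counts over
#' that animal's areas are computed; an area is flagged clonal if, for any
#' fluorophore, its count exceeds `mean + 2 * SD` (strict inequality, so
#' constant counts flag nothing). The alternative literal reading of the
#' rule (`count > 2 * SD`) is selectable.
#'
#' @param table data.frame with columns `group`, `animal`, `image`,
#'   `area`, `fluorophore`, `count` (as produced by
#'   [simulate_clone_counts()]).
#' @param rule `"mean_plus_2sd"` (default) or `"two_sd"`.
#' @return data.frame with one row per (group, animal, image, area) and a
#'   logical `clonal` flag.
#' @export
flag_clonal_areas <- function(table, rule = c("mean_plus_2sd", "two_sd")) {
  rule <- match.arg(rule)
  need <- c("group", "animal", "image", "area", "fluorophore", "count")
  stopifnot(all(need %in% names(table)))
  if (any(table$count < 0) || any(table$count != round(table$count)))
    stop("counts must be nonnegative integers")
  key <- paste(table$group, table$animal)
  flagged <- logical(nrow(table))
  for (a in unique(key)) {
    rows <- which(key == a)
    for (f in unique(table$fluorophore[rows])) {
      fr <- rows[table$fluorophore[rows] == f]
      if (length(fr) < 2)
        stop("animal ", a, " has fewer than 2 areas for ", f,
             " (SD undefined)")
      counts <- table$count[fr]
      thr <- if (rule == "mean_plus_2sd") {
        mean(counts) + 2 * stats::sd(counts)
      } else 2 * stats::sd(counts)
      flagged[fr] <- counts > thr
    }
  }
  area_key <- paste(table$group, table$animal, table$image, table$area)
  agg <- tapply(flagged, area_key, any)
  first <- !duplicated(area_key)
  out <- data.frame(group = table$group[first],
                    animal = table$animal[first],
                    image = table$image[first], area = table$area[first],
                    clonal = as.logical(agg[area_key[first]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compare clonal-area incidence between two groups
#'
#' Builds the 2x2 table of flagged versus unflagged areas by group and
#' tests it with [fisher_exact()]. The percent reduction in flagged-area
#' incidence of the second group relative to the first is reported with a
#' bootstrap SD over animals.
#'
#' @param flags output of [flag_clonal_areas()]; must contain exactly two
#'   groups.
#' @param reference group treated as the reference incidence (default the
#'   first group encountered).
#' @param n_boot bootstrap resamples of animals (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return List: `table` (2x2), `odds_ratio`, `p.value`,
#'   `percent_reduction`, `reduction_sd`.
#' @export
compare_groups <- function(flags, reference = NULL, n_boot = 1000,
                           seed = 1L) {
  stopifnot(all(c("group", "animal", "clonal") %in% names(flags)))
  groups <- unique(flags$group)
  if (length(groups) != 2) stop("need exactly two groups")
  if (is.null(reference)) reference <- groups[1]
  other <- setdiff(groups, reference)
  if (any(tapply(flags$clonal, flags$group, length) < 1))
    stop("each group needs at least one area")
  tab <- rbind(
    c(sum(flags$clonal[flags$group == reference]),
      sum(!flags$clonal[flags$group == reference])),
    c(sum(flags$clonal[flags$group == other]),
      sum(!flags$clonal[flags$group == other])))
  dimnames(tab) <- list(c(reference, other), c("clonal", "not_clonal"))
  p <- fisher_exact(tab)
  or <- (tab[1, 1] * tab[2, 2]) / max(1, tab[1, 2] * tab[2, 1])
  rate <- function(g, data) mean(data$clonal[data$group == g])
  r_ref <- rate(reference, flags); r_oth <- rate(other, flags)
  reduction <- if (r_ref > 0) 100 * (r_ref - r_oth) / r_ref else 0
  set.seed(seed)
  boots <- replicate(n_boot, {
    res <- lapply(c(reference, other), function(g) {
      an <- unique(flags$animal[flags$group == g])
      pick <- an[sample.int(length(an), length(an), replace = TRUE)]
      do.call(rbind, lapply(pick, function(a)
        flags[flags$group == g & flags$animal == a, ]))
    })
    bs <- do.call(rbind, res)
    rr <- rate(reference, bs); ro <- rate(other, bs)
    if (rr > 0) 100 * (rr - ro) / rr else NA_real_
  })
  list(table = tab, odds_ratio = or, p.value = p,
       percent_reduction = reduction,
       reduction_sd = stats::sd(boots, na.rm = TRUE))
}
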