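# Term enrichment with a combined score: Fisher exact overlap p-value
# times the z-score of the term's rank deviation from its resampled
# expected rank.

#' Term enrichment with combined score
#'
#' Per term, the overlap of the query with the term's gene set is tested
#' by [fisher_exact()] against the background universe. The term's rank
#' (by ascending p) is compared with its expected rank, estimated together
#' with its SD from `n_null` seeded random queries of the same size;
#' `z = (rank - expected_rank) / SD` and the combined score is
#' `ln(p) * z` (positive when a term is both significant and
#' better-ranked than expected). Terms are returned ranked by combined
#' score.
#'
#' @param query_genes character vector of query genes (non-empty).
#' @param library named list of character vectors (term -> gene set).
#' @param background background gene universe: a character vector, or an
#'   integer size (the library union padded with inert genes to that
#'   size).
#' @param n_null number of random same-size queries for rank calibration
#'   (default 100).
#' @param seed integer seed for the null queries.
#' @return data.frame: `term`, `overlap`, `term_size`, `p`, `z`,
#'   `combined_score`, ordered by decreasing combined score.
#' @export
enrich_terms <- function(query_genes, library, background, n_null = 100,
                         seed = 1L) {
  if (length(query_genes) == 0) stop("query must be non-empty")
  if (length(library) == 0) stop("library must be non-empty")
  if (is.null(names(library)) || any(names(library) == ""))
    stop("library must be a named list of gene sets")
  if (is.numeric(background)) {
    universe <- unique(unlist(library))
    if (background < length(universe))
      stop("background size smaller than the library union")
    pad <- background - length(universe)
    if (pad > 0) universe <- c(universe, sprintf("bg%06d", seq_len(pad)))
  } else {
    universe <- unique(as.character(background))
  }
  query <- unique(intersect(query_genes, universe))
  if (length(query) == 0) stop("query is disjoint from the background")
  sets <- lapply(library, function(g) unique(intersect(g, universe)))
  N <- length(universe)
  nq <- length(query)

  term_p <- function(q) {
    vapply(sets, function(s) {
      k <- length(intersect(q, s))
      fisher_exact(matrix(c(k, length(s) - k, length(q) - k,
                            N - length(s) - length(q) + k), 2))
    }, numeric(1))
  }
  p_obs <- term_p(query)
  rank_obs <- rank(p_obs, ties.method = "average")

  set.seed(seed)
  null_ranks <- matrix(NA_real_, n_null, length(sets))
  for (b in seq_len(n_null)) {
    q0 <- universe[sample.int(N, nq)]
    null_ranks[b, ] <- rank(term_p(q0), ties.method = "average")
  }
  exp_rank <- colMeans(null_ranks)
  sd_rank <- apply(null_ranks, 2, stats::sd)
  z <- ifelse(is.na(sd_rank) | sd_rank == 0, 0,
              (rank_obs - exp_rank) / sd_rank)
  out <- data.frame(term = names(sets),
                    overlap = vapply(sets, function(s)
                      length(intersect(query, s)), numeric(1)),
                    term_size = lengths(sets),
                    p = p_obs, z = z,
                    combined_score = log(p_obs) * z,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$combined_score, out$p), ]
}
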