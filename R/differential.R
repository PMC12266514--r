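# Differential analysis across single-time-point networks: term
# uniqueness per time point and centrality rank change.

#' Terms unique to each time point
#'
#' For each time point, the significant terms of its enrichment result
#' that are not significant at any other time point.  The returned sets
#' are pairwise disjoint by construction.
#'
#' @param results Named list (by time point) of `enrichment_result`
#'   objects built with the same network creation strategy.
#' @return Named list of character vectors of unique terms.
#' @export
differential_terms <- function(results) {
  stop_if_not(length(results) >= 2, "need at least 2 time points")
  sig <- lapply(results, significant_terms)
  out <- lapply(seq_along(sig), function(i)
    setdiff(sig[[i]], unique(unlist(sig[-i]))))
  stats::setNames(out, names(results))
}

#' Mean absolute centrality rank change across time points
#'
#' Over the genes shared by all compared networks, dense descending
#' ranks of the chosen centrality are recomputed within the shared set
#' per time point; for each gene the absolute rank difference is taken
#' for every unordered time-point pair and averaged.
#'
#' @param tables Named list (by time point) of `centrality_table`
#'   objects.
#' @param metric `"degree"`, `"betweenness"` or `"closeness"`.
#' @return Named numeric vector gene -> mean absolute rank change, with
#'   the metric stored as an attribute.
#' @export
centrality_rank_change <- function(tables,
                                   metric = c("degree", "betweenness",
                                              "closeness")) {
  metric <- match.arg(metric)
  stop_if_not(length(tables) >= 2, "need at least 2 time points")
  shared <- sort(Reduce(intersect, lapply(tables, `[[`, "gene")))
  if (length(shared) < 5)
    stop("fewer than 5 genes shared across time points", call. = FALSE)
  ranks <- vapply(tables, function(tab) {
    v <- tab[[metric]][match(shared, tab$gene)]
    dense_rank_desc(v)
  }, numeric(length(shared)))
  pairs <- utils::combn(ncol(ranks), 2)
  changes <- rowMeans(vapply(seq_len(ncol(pairs)), function(j)
    abs(ranks[, pairs[1, j]] - ranks[, pairs[2, j]]),
    numeric(length(shared))))
  structure(stats::setNames(changes, shared), metric = metric)
}

#' GSEA on differential centrality rank changes
#'
#' Genes are ranked by mean absolute rank change (descending) and
#' preranked GSEA is applied; terms in the positive-ES tail are the
#' "differentially central" terms, so significance requires both
#' q < 0.05 and ES > 0.  A degenerate ranking (all changes equal)
#' is flagged with a warning and yields no significant terms.
#'
#' @param changes Output of [centrality_rank_change()].
#' @param sets A [gene_set_collection()].
#' @param n_perm,seed,min_overlap Passed to [preranked_gsea()].
#' @param provenance Optional provenance fields.
#' @return An `enrichment_result`.
#' @export
differential_centrality_gsea <- function(changes, sets, n_perm = 1000,
                                         seed = 1, min_overlap = 3,
                                         provenance = list()) {
  ranking <- ranked_gene_list(names(changes), as.numeric(changes))
  if (max(changes) == min(changes)) {
    warning("degenerate ranking: all rank changes equal")
    res <- preranked_gsea(ranking, sets, n_perm = n_perm, seed = seed,
                          min_overlap = min_overlap,
                          provenance = provenance)
    res$p <- rep(1, nrow(res)); res$q <- rep(1, nrow(res))
    res$significant <- rep(FALSE, nrow(res))
    return(res)
  }
  res <- preranked_gsea(ranking, sets, n_perm = n_perm, seed = seed,
                        min_overlap = min_overlap, provenance = provenance)
  res$significant <- res$significant & res$es > 0
  res
}
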