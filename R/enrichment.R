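# Enrichment machinery: GMT gene-set collections, preranked GSEA with a
# permutation null, hypergeometric over-representation, and BH control.

#' Gene-set collection
#'
#' @param sets Named list of character vectors (term id -> gene ids);
#'   duplicate genes within a set are removed.
#' @param name Collection name.
#' @param descriptions Optional term descriptions (recycled to `""`).
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, name = "collection",
                                descriptions = NULL) {
  stop_if_not(!anyDuplicated(names(sets)), "term ids must be unique")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  stop_if_not(all(lengths(sets) > 0), "every set must be non-empty")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(list(name = name, sets = sets,
                 descriptions = stats::setNames(descriptions, names(sets))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection '%s': %d sets, sizes %s\n", x$name,
              length(x$sets),
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-")
              else "-"))
  invisible(x)
}

#' Read a GMT file
#'
#' Standard dialect: tab-separated, field 1 term id, field 2
#' description, fields 3+ gene ids.
#'
#' @param path GMT file path.
#' @return A [gene_set_collection()]; an empty file gives an empty
#'   collection with a warning.
#' @export
read_gmt <- function(path) {
  stop_if_not(file.exists(path), "file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(name = basename(path), sets = list(),
                          descriptions = character()),
                     class = "gene_set_collection"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop(sprintf("GMT parse error: line %d has fewer than 3 fields",
                 short[1]), call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  gene_set_collection(sets, name = basename(path),
                      descriptions = vapply(fields, `[[`, character(1), 2))
}

#' Write a gene-set collection as GMT
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id)
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, mapped back to
#' input positions.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  stop_if_not(all(!is.na(pvalues)) && all(pvalues >= 0 & pvalues <= 1),
              "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

enrichment_result <- function(df, provenance = list()) {
  attr(df, "provenance") <- provenance
  class(df) <- c("enrichment_result", "data.frame")
  df
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: %d terms, %d significant (q < 0.05)\n",
              nrow(x), sum(x$significant)))
  if (nrow(x)) print.data.frame(utils::head(x[order(x$p), ], 5))
  invisible(x)
}

#' Significant terms of an enrichment result
#' @param result An `enrichment_result`.
#' @return Character vector of term ids flagged significant.
#' @export
significant_terms <- function(result) {
  result$term[result$significant]
}

#' Build a ranked gene list
#'
#' Orders genes by score descending with ties broken by gene id.
#'
#' @param genes Gene ids (unique).
#' @param scores Numeric scores, one per gene.
#' @return Data frame with columns `gene`, `score`, ordered.
#' @export
ranked_gene_list <- function(genes, scores) {
  stop_if_not(!anyDuplicated(genes), "gene ids must be unique")
  stop_if_not(length(genes) == length(scores), "one score per gene")
  ord <- order(-scores, genes)
  data.frame(gene = as.character(genes)[ord], score = scores[ord],
             stringsAsFactors = FALSE)
}

# weighted Kolmogorov-Smirnov enrichment score (weight exponent 1 on
# |score|) for hit positions in a score-ranked list; signed maximum
# deviation of the running sum
gsea_es <- function(scores, hit_idx) {
  N <- length(scores)
  nh <- length(hit_idx)
  w <- abs(scores[hit_idx])
  wsum <- sum(w)
  inc <- numeric(N)
  if (wsum > 0) inc[hit_idx] <- w / wsum
  else inc[hit_idx] <- 1 / nh          # all-zero scores: unweighted KS
  dec <- rep(1 / (N - nh), N)
  dec[hit_idx] <- 0
  run <- cumsum(inc - dec)
  run[which.max(abs(run))]
}

#' Preranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov enrichment score (weight exponent 1) per
#' set, with a permutation p-value from `n_perm` gene-label shuffles
#' (two-sided on |ES|, with the +1 correction) and BH adjustment across
#' tested terms.  Sets overlapping the ranking universe in fewer than
#' `min_overlap` genes are skipped.
#'
#' @param ranking A ranked gene list from [ranked_gene_list()] (>= 10
#'   genes).
#' @param sets A [gene_set_collection()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param min_overlap Minimum overlap with the ranking universe
#'   (default 3).
#' @param provenance Optional provenance fields.
#' @return An `enrichment_result` with columns `term`, `es`, `size`,
#'   `p`, `q`, `significant` (q < 0.05).
#' @export
preranked_gsea <- function(ranking, sets, n_perm = 1000, seed = 1,
                           min_overlap = 3, provenance = list()) {
  stop_if_not(nrow(ranking) >= 10, "ranking must cover at least 10 genes")
  scores <- ranking$score
  N <- length(scores)
  universe <- ranking$gene
  overlaps <- lapply(sets$sets, function(s) which(universe %in% s))
  keep <- lengths(overlaps) >= min_overlap
  if (!any(keep)) {
    warning("no gene set overlaps the ranking universe sufficiently")
    return(enrichment_result(data.frame(term = character(), es = numeric(),
                                        size = integer(), p = numeric(),
                                        q = numeric(),
                                        significant = logical()),
                             provenance))
  }
  overlaps <- overlaps[keep]
  es <- vapply(overlaps, function(ix) gsea_es(scores, ix), numeric(1))
  sizes <- lengths(overlaps)
  # one permutation null per distinct set size, reused across sets
  p <- with_seed(seed, {
    nulls <- new.env()
    vapply(seq_along(overlaps), function(i) {
      key <- as.character(sizes[i])
      if (is.null(nulls[[key]]))
        nulls[[key]] <- vapply(seq_len(n_perm), function(b)
          gsea_es(scores, sample.int(N, sizes[i])), numeric(1))
      (1 + sum(abs(nulls[[key]]) >= abs(es[i]))) / (n_perm + 1)
    }, numeric(1))
  })
  q <- bh_adjust(p)
  enrichment_result(data.frame(term = names(overlaps), es = es,
                               size = as.integer(sizes), p = p, q = q,
                               significant = q < 0.05,
                               stringsAsFactors = FALSE, row.names = NULL),
                    provenance)
}

#' Hypergeometric over-representation analysis
#'
#' Per term with gene set S, the upper-tail probability
#' \eqn{P[X \ge |hits \cap S|]} for X hypergeometric with population
#' `background`, successes \eqn{S \cap background}, and draws `hits`;
#' BH adjustment across terms.
#'
#' @param hits Character vector of hit genes (subset of `background`).
#' @param background Character vector: the gene universe.
#' @param sets A [gene_set_collection()].
#' @param provenance Optional provenance fields.
#' @return An `enrichment_result` with columns `term`, `overlap`, `size`,
#'   `p`, `q`, `significant`.
#' @export
hypergeometric_ora <- function(hits, background, sets, provenance = list()) {
  hits <- unique(as.character(hits))
  background <- unique(as.character(background))
  stop_if_not(all(hits %in% background), "hits must be a subset of background")
  N <- length(background); n <- length(hits)
  rows <- lapply(names(sets$sets), function(id) {
    S <- intersect(sets$sets[[id]], background)
    K <- length(S)
    k <- length(intersect(hits, S))
    p <- if (n == 0 || K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = id, overlap = k, size = K, p = p,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows) %||%
    data.frame(term = character(), overlap = integer(), size = integer(),
               p = numeric())
  df$q <- if (nrow(df)) bh_adjust(df$p) else numeric()
  df$significant <- df$q < 0.05
  enrichment_result(df, provenance)
}

#' Write an enrichment result as TSV
#' @param result An `enrichment_result`.
#' @param path Output path.
#' @export
write_enrichment <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
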