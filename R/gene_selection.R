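# Gene selection: reduce the gene universe to the top-k genes after
# pseudo-bulk creation, by variance, per-time-point expression, or
# differential expression between time points.

gene_selection <- function(strategy, k, genes) {
  structure(list(strategy = strategy, k = as.integer(k),
                 genes = as.character(genes)), class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("gene_selection: strategy=%s k=%d -> %d genes\n",
              x$strategy, x$k, length(x$genes)))
  invisible(x)
}

#' Select the most variable genes across pseudobulks
#'
#' Genes are ranked by sample variance across all pseudobulks
#' (descending) and the top `k` kept; ties are broken by gene id.
#'
#' @param pb A [pseudobulk_matrix()].
#' @param k Number of genes to keep.
#' @return A `gene_selection` with `strategy = "var"`.
#' @export
select_top_variable <- function(pb, k) {
  stop_if_not(k > 0, "k must be positive")
  stop_if_not(nrow(pb$matrix) >= 2, "need at least 2 pseudobulks")
  v <- apply(pb$matrix, 2, stats::var)
  ord <- order(-v, pb$gene_ids)
  gene_selection("var", k, pb$gene_ids[ord][seq_len(min(k, length(v)))])
}

#' Select the union of the top expressed genes per time point
#'
#' Per time point, genes are ranked by summed expression over that time
#' point's pseudobulks and the top `k` taken; the union over time points
#' is returned (so more than `k` genes are possible).
#'
#' @inheritParams select_top_variable
#' @return A `gene_selection` with `strategy = "sum"`.
#' @export
select_top_expressed_union <- function(pb, k) {
  stop_if_not(k > 0, "k must be positive")
  labs <- sort(unique(pb$time_labels))
  sel <- lapply(labs, function(t) {
    s <- colSums(pb$matrix[pb$time_labels == t, , drop = FALSE])
    pb$gene_ids[order(-s, pb$gene_ids)][seq_len(min(k, length(s)))]
  })
  gene_selection("sum", k, sort(unique(unlist(sel))))
}

#' Select the most differentially expressed genes between time points
#'
#' For every pair of time-point groups of pseudobulks, a two-sided
#' Wilcoxon rank-sum test is run per gene and Benjamini-Hochberg
#' adjusted within the pair.  Genes are ranked by the sum of their
#' adjusted p-values over all pairs (ascending; smaller = more
#' differential) and the top `k` kept; ties broken by gene id.
#'
#' @inheritParams select_top_variable
#' @return A `gene_selection` with `strategy = "deg"`.
#' @export
select_top_differential <- function(pb, k) {
  stop_if_not(k > 0, "k must be positive")
  labs <- sort(unique(pb$time_labels))
  stop_if_not(length(labs) >= 2, "need at least 2 distinct time labels")
  for (t in labs)
    if (sum(pb$time_labels == t) < 2)
      stop(sprintf("time label '%s' has fewer than 2 pseudobulks", t),
           call. = FALSE)
  psum <- numeric(ncol(pb$matrix))
  pairs <- utils::combn(labs, 2)
  for (j in seq_len(ncol(pairs))) {
    a <- pb$matrix[pb$time_labels == pairs[1, j], , drop = FALSE]
    b <- pb$matrix[pb$time_labels == pairs[2, j], , drop = FALSE]
    p <- vapply(seq_len(ncol(a)), function(i)
      suppressWarnings(stats::wilcox.test(a[, i], b[, i],
                                          exact = FALSE)$p.value),
      numeric(1))
    p[is.na(p)] <- 1          # constant gene in both groups
    psum <- psum + stats::p.adjust(p, method = "BH")
  }
  ord <- order(psum, pb$gene_ids)
  gene_selection("deg", k, pb$gene_ids[ord][seq_len(min(k, ncol(pb$matrix)))])
}

#' Write a gene selection as one gene id per line
#' @param sel A `gene_selection`.
#' @param path Output file.
#' @export
write_gene_selection <- function(sel, path) {
  writeLines(sel$genes, path)
  invisible(path)
}
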