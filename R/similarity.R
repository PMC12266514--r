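# Pairwise gene-gene similarity: Pearson, Spearman, or mutual
# information with equal-frequency binning.

#' Compute a pairwise gene similarity matrix
#'
#' Pearson and Spearman correlations use [stats::cor()]; mutual
#' information uses a plug-in estimate over equal-frequency bins with
#' `B = max(2, floor(sqrt(n_samples)))` bins per gene, in bits (log2).
#' Pairs involving a constant gene get similarity 0 (with a warning).
#'
#' @param pb A [pseudobulk_matrix()] (or any samples-by-genes matrix
#'   wrapped in one).
#' @param genes A `gene_selection` or character vector of gene ids;
#'   `NULL` uses all genes.
#' @param metric `"pearson"`, `"spearman"` or `"mi"`.
#' @return A `similarity_matrix`; for `metric = "mi"` the binned data
#'   are retained so permutation nulls (ARACNE) can be computed.
#' @export
compute_similarity <- function(pb, genes = NULL,
                               metric = c("pearson", "spearman", "mi")) {
  metric <- match.arg(metric)
  if (inherits(genes, "gene_selection")) genes <- genes$genes
  x <- pb$matrix
  if (!is.null(genes)) {
    stop_if_not(all(genes %in% colnames(x)), "unknown gene in selection")
    x <- x[, genes, drop = FALSE]
  }
  stop_if_not(nrow(x) >= 3, "need at least 3 pseudobulks")
  bins <- NULL
  if (metric %in% c("pearson", "spearman")) {
    v <- suppressWarnings(stats::cor(x, method = metric))
    if (anyNA(v)) {
      warning("constant gene(s): similarity set to 0 for their pairs")
      v[is.na(v)] <- 0
    }
  } else {
    bins <- equal_frequency_bins(x)
    v <- mi_matrix(bins)
  }
  diag(v) <- 0
  structure(list(genes = colnames(x), values = v, metric = metric,
                 data = x, bins = bins), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix: %d genes, metric=%s\n",
              length(x$genes), x$metric))
  invisible(x)
}

# equal-frequency discretization: bin by average ranks so the result is
# deterministic and invariant to sample order, even under heavy ties
equal_frequency_bins <- function(x, n_bins = NULL) {
  n <- nrow(x)
  B <- n_bins %||% max(2L, floor(sqrt(n)))
  b <- apply(x, 2, function(col) {
    r <- rank(col, ties.method = "average")
    pmin(pmax(ceiling(B * r / n), 1L), B)
  })
  storage.mode(b) <- "integer"
  attr(b, "n_bins") <- B
  b
}

# plug-in MI (bits) for all gene pairs from a binned matrix, vectorized
# as B^2 cross-products of bin indicator matrices
mi_matrix <- function(bins) {
  n <- nrow(bins); g <- ncol(bins)
  B <- attr(bins, "n_bins")
  ind <- lapply(seq_len(B), function(b) (bins == b) * 1)
  marg <- vapply(ind, colSums, numeric(g)) / n    # g x B marginals
  mi <- matrix(0, g, g)
  for (a in seq_len(B)) {
    for (b in seq_len(B)) {
      joint <- crossprod(ind[[a]], ind[[b]]) / n  # P[X in a, Y in b]
      denom <- outer(marg[, a], marg[, b])
      term <- joint * log2(joint / denom)
      term[joint == 0] <- 0
      mi <- mi + term
    }
  }
  mi[mi < 0] <- 0   # guard tiny negatives from floating point
  dimnames(mi) <- list(colnames(bins), colnames(bins))
  (mi + t(mi)) / 2
}

# MI (bits) of one binned vector against every column of a binned matrix
mi_vector <- function(bvec, bins, B = attr(bins, "n_bins")) {
  n <- length(bvec)
  g <- ncol(bins)
  out <- numeric(g)
  marg_x <- tabulate(bvec, nbins = B) / n
  marg_y <- vapply(seq_len(B), function(b) colSums(bins == b), numeric(g)) / n
  for (a in seq_len(B)) {
    sel <- bvec == a
    if (!any(sel)) next
    for (b in seq_len(B)) {
      joint <- colSums(bins[sel, , drop = FALSE] == b) / n
      term <- joint * log2(joint / (marg_x[a] * marg_y[, b]))
      term[joint == 0] <- 0
      out <- out + term
    }
  }
  out
}
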