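# Pseudo-bulk creation: collapse single cells into aggregate profiles so
# network algorithms developed for bulk data can be applied.

#' Pseudo-bulk matrix container
#'
#' @param matrix pseudobulks-by-genes numeric matrix.
#' @param pseudobulk_ids,gene_ids Unique identifiers.
#' @param time_labels One time label per pseudobulk.
#' @param method Creation method: `"leiden"`, `"time"`, `"SEACell"` or
#'   `"none"`.
#' @param zero_mode `"ignore_zeros"`, `"with_zeros"` or `"n/a"`.
#' @return A `pseudobulk_matrix` object.
#' @export
pseudobulk_matrix <- function(matrix, pseudobulk_ids, gene_ids, time_labels,
                              method = c("leiden", "time", "SEACell", "none"),
                              zero_mode = c("ignore_zeros", "with_zeros", "n/a")) {
  method <- match.arg(method)
  zero_mode <- match.arg(zero_mode)
  matrix <- as.matrix(matrix)
  stop_if_not(nrow(matrix) == length(pseudobulk_ids) &&
              ncol(matrix) == length(gene_ids), "dimension mismatch")
  stop_if_not(length(time_labels) == nrow(matrix),
              "one time label per pseudobulk required")
  dimnames(matrix) <- list(pseudobulk_ids, gene_ids)
  structure(list(matrix = matrix,
                 pseudobulk_ids = as.character(pseudobulk_ids),
                 gene_ids = as.character(gene_ids),
                 time_labels = as.character(time_labels),
                 method = method, zero_mode = zero_mode),
            class = "pseudobulk_matrix")
}

#' @export
print.pseudobulk_matrix <- function(x, ...) {
  cat(sprintf("pseudobulk_matrix: %d pseudobulks x %d genes (method=%s, zero_mode=%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$method, x$zero_mode))
  print(table(time = x$time_labels))
  invisible(x)
}

# majority time label of a group of cells; ties broken by earliest label
# in sorted order, so labeling is deterministic and order-invariant
majority_label <- function(labels) {
  tab <- table(labels)
  names(tab)[which.max(tab)]   # table() is sorted by label; which.max -> first
}

pb_assignment <- function(groups, labels, method) {
  stop_if_not(length(groups) == length(labels), "one label per group")
  stop_if_not(all(lengths(groups) >= 1), "empty pseudobulk group")
  structure(list(groups = groups, labels = as.character(labels),
                 method = method), class = "pb_assignment")
}

#' Cluster cells into pseudo-bulk groups by graph-based clustering
#'
#' Cells are embedded with PCA, connected by a k-nearest-neighbour graph
#' and partitioned by Leiden clustering with the modularity objective.
#' Each cluster is labeled by its most frequent time point.
#'
#' @param study An [expression_study()].
#' @param resolution Leiden resolution (default 1).
#' @param k Neighbours in the kNN graph (default 15).
#' @param n_pcs Principal components retained (default 30).
#' @param seed Integer seed; the partition is deterministic given it.
#' @return A `pb_assignment` (groups of cell indices with time labels).
#' @export
pseudobulk_by_clustering <- function(study, resolution = 1, k = 15,
                                     n_pcs = 30, seed = 1) {
  n <- nrow(study$matrix)
  stop_if_not(n >= 2, "need at least 2 cells")
  if (n <= k) stop("fewer cells than kNN k", call. = FALSE)
  pcs <- study_pcs(study$matrix, n_pcs)
  d <- as.matrix(stats::dist(pcs))
  nn <- t(apply(d, 1, function(row) order(row)[2:(k + 1)]))
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  memb <- with_seed(seed,
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = resolution)))
  groups <- split(seq_len(n), memb)
  labels <- vapply(groups, function(ix) majority_label(study$time_labels[ix]),
                   character(1))
  pb_assignment(unname(groups), unname(labels), "leiden")
}

# PCA embedding used by the clustering- and metacell-based methods
study_pcs <- function(x, n_pcs) {
  rank <- min(n_pcs, nrow(x) - 1L, ncol(x))
  p <- stats::prcomp(x, rank. = rank, center = TRUE, scale. = FALSE)
  p$x
}

#' Sample pseudo-bulk groups per time point
#'
#' For each time point, `n_clusters` groups of `cluster_size` cells are
#' sampled; cells may belong to several groups.  Within one group,
#' sampling is without replacement when the time point has at least
#' `cluster_size` cells, otherwise with replacement.
#'
#' @param study An [expression_study()].
#' @param n_clusters Groups per time point (default 10).
#' @param cluster_size Cells per group (default 100).
#' @param seed Integer seed; sub-seeds are split per time point so the
#'   assignment for one time point is reproducible in isolation.
#' @return A `pb_assignment`.
#' @export
pseudobulk_by_time_sampling <- function(study, n_clusters = 10,
                                        cluster_size = 100, seed = 1) {
  labs <- sort(unique(study$time_labels))
  counts <- table(factor(study$time_labels, levels = labs))
  if (any(counts == 0)) stop("empty time point", call. = FALSE)
  sub_seeds <- split_seed(seed, length(labs))
  groups <- list(); labels <- character()
  for (i in seq_along(labs)) {
    cells_t <- which(study$time_labels == labs[i])
    replace <- length(cells_t) < cluster_size
    gs <- with_seed(sub_seeds[i], lapply(seq_len(n_clusters), function(j)
      sample(cells_t, cluster_size, replace = replace)))
    groups <- c(groups, gs)
    labels <- c(labels, rep(labs[i], n_clusters))
  }
  pb_assignment(groups, labels, "time")
}

#' Metacell-style pseudo-bulk aggregation
#'
#' Groups cells by k-means on the top principal components with
#' `n_metacells` centers and aggregates each group by the per-gene mean.
#' Each metacell is labeled by its most frequent time point.
#'
#' @param study An [expression_study()].
#' @param n_metacells Number of metacells (must be below the cell count).
#' @param n_pcs Principal components used for the embedding (default 30).
#' @param seed Integer seed.
#' @return A [pseudobulk_matrix()] with `zero_mode = "n/a"`.
#' @export
pseudobulk_metacell <- function(study, n_metacells, n_pcs = 30, seed = 1) {
  stop_if_not(n_metacells >= 1, "n_metacells must be positive")
  n <- nrow(study$matrix)
  stop_if_not(n_metacells < n, "n_metacells must be below the cell count")
  groups <- if (n_metacells == 1) list(seq_len(n)) else {
    pcs <- study_pcs(study$matrix, n_pcs)
    km <- with_seed(seed, stats::kmeans(pcs, centers = n_metacells,
                                        nstart = 5, iter.max = 50))
    unname(split(seq_len(n), km$cluster))
  }
  m <- t(vapply(groups, function(ix)
    colMeans(study$matrix[ix, , drop = FALSE]), numeric(ncol(study$matrix))))
  labels <- vapply(groups, function(ix) majority_label(study$time_labels[ix]),
                   character(1))
  pseudobulk_matrix(m, sprintf("SEACell_%03d", seq_along(groups)),
                    study$gene_ids, labels, method = "SEACell",
                    zero_mode = "n/a")
}

#' Collapse assigned cell groups to median pseudo-bulk profiles
#'
#' Per pseudobulk and gene, the median over member cells.  Under
#' `ignore_zeros` the zero entries are dropped before the median (all
#' zeros give 0); under `with_zeros` they are kept.  Networks built from
#' `with_zeros` pseudobulks are conventionally tagged "w0".
#'
#' @param study An [expression_study()].
#' @param assignment A `pb_assignment` from one of the grouping methods.
#' @param zero_mode `"ignore_zeros"` or `"with_zeros"`.
#' @return A [pseudobulk_matrix()].
#' @export
collapse_median <- function(study, assignment,
                            zero_mode = c("ignore_zeros", "with_zeros")) {
  zero_mode <- match.arg(zero_mode)
  stop_if_not(inherits(assignment, "pb_assignment"), "pb_assignment required")
  rows <- lapply(assignment$groups, function(ix) {
    sub <- study$matrix[ix, , drop = FALSE]
    if (zero_mode == "ignore_zeros") {
      sub[sub == 0] <- NA_real_
      med <- apply(sub, 2, stats::median, na.rm = TRUE)
      med[is.na(med)] <- 0
      med
    } else {
      apply(sub, 2, stats::median)
    }
  })
  m <- do.call(rbind, rows)
  prefix <- assignment$method
  pseudobulk_matrix(m, sprintf("%s_%03d", prefix, seq_along(rows)),
                    study$gene_ids, assignment$labels,
                    method = if (prefix %in% c("leiden", "time")) prefix else "none",
                    zero_mode = zero_mode)
}
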