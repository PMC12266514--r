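# Node-level and graph-level analysis of co-expression networks.

#' Node centralities of a co-expression network
#'
#' Unweighted degree, shortest-path betweenness normalized by the number
#' of vertex pairs excluding the node, and closeness computed on each
#' node's reachable set with component-size scaling
#' (\eqn{(r/(n-1)) \cdot (r/\sum d)} for r reachable others at total
#' distance \eqn{\sum d}).  Centralities are computed on the unweighted
#' topology; edge weights are creation metadata only.  Dense descending
#' ranks are attached per metric.
#'
#' @param net A [coexpression_network()] with >= 2 genes.
#' @return A `centrality_table` data frame with one row per gene.
#' @export
node_centralities <- function(net) {
  stop_if_not(length(net$genes) >= 2, "need at least 2 nodes")
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  if (nrow(net$edges) == 0) {
    bet <- stats::setNames(numeric(n), net$genes)
    clo <- bet
  } else {
    bet <- igraph::betweenness(g, weights = NA, normalized = TRUE)
    d <- igraph::distances(g, weights = NA)
    clo <- apply(d, 1, function(row) {
      fin <- row[is.finite(row) & row > 0]
      r <- length(fin)
      if (r == 0) 0 else (r / (n - 1)) * (r / sum(fin))
    })
  }
  out <- data.frame(gene = net$genes,
                    degree = as.numeric(deg[net$genes]),
                    betweenness = as.numeric(bet[net$genes]),
                    closeness = as.numeric(clo[net$genes]),
                    stringsAsFactors = FALSE)
  out$degree_rank <- dense_rank_desc(out$degree)
  out$betweenness_rank <- dense_rank_desc(out$betweenness)
  out$closeness_rank <- dense_rank_desc(out$closeness)
  attr(out, "provenance") <- net$provenance
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Graph-size metrics of a network
#'
#' Density \eqn{d = 2m / (n (n - 1))}, the average local clustering
#' coefficient (nodes of degree < 2 contribute 0), and transitivity
#' \eqn{T = 3 \cdot \#triangles / \#triads} where a triad is a path of
#' length two.
#'
#' @param net A [coexpression_network()] with >= 2 genes.
#' @return A `network_size_metrics` list with fields `n`, `m`,
#'   `density`, `avg_clustering`, `transitivity`, `n_triangles`,
#'   `n_triads`.
#' @export
network_size_metrics <- function(net) {
  stop_if_not(length(net$genes) >= 2, "need at least 2 nodes")
  g <- as_igraph(net)
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  deg <- igraph::degree(g)
  n_tri <- sum(igraph::count_triangles(g)) / 3
  n_triads <- sum(choose(deg, 2))
  avg_c <- if (m == 0) 0 else
    mean(igraph::transitivity(g, type = "localundirected", isolates = "zero"))
  trans <- if (n_triads == 0) 0 else 3 * n_tri / n_triads
  structure(list(n = n, m = m, density = 2 * m / (n * (n - 1)),
                 avg_clustering = avg_c, transitivity = trans,
                 n_triangles = n_tri, n_triads = n_triads),
            class = "network_size_metrics")
}

#' @export
print.network_size_metrics <- function(x, ...) {
  cat(sprintf("n=%d m=%d density=%.4f avg_clustering=%.4f transitivity=%.4f\n",
              x$n, x$m, x$density, x$avg_clustering, x$transitivity))
  invisible(x)
}

#' Detect communities by weighted modularity optimization
#'
#' Louvain-family partition of the network using edge weights, at the
#' given resolution; deterministic given the seed.  An edgeless network
#' yields singleton communities with a warning.
#'
#' @param net A [coexpression_network()].
#' @param resolution Louvain resolution (default 1).
#' @param seed Integer seed.
#' @return A `community_partition` data frame mapping every network gene
#'   to exactly one community id.
#' @export
detect_communities <- function(net, resolution = 1, seed = 1) {
  if (nrow(net$edges) == 0) {
    warning("edgeless network: every gene is its own community")
    memb <- seq_along(net$genes)
  } else {
    g <- as_igraph(net)
    cl <- with_seed(seed, igraph::cluster_louvain(
      g, weights = igraph::E(g)$weight, resolution = resolution))
    memb <- as.integer(igraph::membership(cl)[net$genes])
  }
  out <- data.frame(gene = net$genes, community = as.integer(memb),
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- net$provenance
  attr(out, "resolution") <- resolution
  attr(out, "seed") <- seed
  class(out) <- c("community_partition", "data.frame")
  out
}

#' Genes of each community at or above a minimum size
#'
#' Communities below `min_size` genes are skipped (with a message), the
#' convention used before community-level enrichment.
#'
#' @param partition A `community_partition`.
#' @param min_size Minimum community size (default 5).
#' @return Named list of gene-id character vectors.
#' @export
community_gene_sets <- function(partition, min_size = 5) {
  sets <- split(partition$gene, partition$community)
  small <- lengths(sets) < min_size
  if (any(small))
    message(sprintf("skipping %d communities below %d genes",
                    sum(small), min_size))
  sets[!small]
}
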