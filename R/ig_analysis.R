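# Intermediate-gene (IG) analysis: collect non-seed genes on shortest
# paths between seed genes in a prior PPI network and enrich them.

#' Prior PPI network container
#'
#' @param edges Data frame with character columns `from`, `to`
#'   (undirected; self-loops and duplicates are removed).
#' @param nodes Optional full node universe (isolated proteins kept).
#' @param truth Optional planted-path table (synthetic fixtures).
#' @return A `ppi_network`.
#' @export
ppi_network <- function(edges, nodes = NULL, truth = NULL) {
  edges <- as.data.frame(edges)
  stop_if_not(all(nzchar(edges$from)) && all(nzchar(edges$to)),
              "ids must be non-empty strings")
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  keys <- edge_key(edges$from, edges$to)
  edges <- edges[!duplicated(keys), , drop = FALSE]
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  rownames(edges) <- NULL
  structure(list(edges = edges, nodes = nodes, truth = truth),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges%s\n", length(x$nodes),
              nrow(x$edges),
              if (is.null(x$truth)) "" else
                sprintf(" (%d planted paths)", nrow(x$truth))))
  invisible(x)
}

#' Read a PPI network from a two-column TSV edge list
#' @param path TSV path (columns `from`, `to`; header optional when the
#'   first line parses as two ids).
#' @return A [ppi_network()].
#' @export
read_ppi_network <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  names(df)[1:2] <- c("from", "to")
  ppi_network(df[, 1:2])
}

#' Write a PPI network as a two-column TSV edge list
#' @param ppi A [ppi_network()].
#' @param path Output path.
#' @export
write_ppi_network <- function(ppi, path) {
  utils::write.table(ppi$edges[, c("from", "to")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Intermediate genes on shortest paths between seeds
#'
#' For every unordered seed pair at shortest-path distance between 2 and
#' `max_len`, all shortest paths are enumerated and every non-seed
#' interior node is counted once per pair in which it appears on any
#' shortest path.  Adjacent seed pairs contribute nothing; pairs in
#' different components are skipped (and counted in `skipped_pairs`).
#'
#' @param ppi A [ppi_network()].
#' @param seeds Character vector of seed genes (>= 2 must map into the
#'   PPI).
#' @param max_len Maximum seed-pair distance considered (default 3).
#' @return An `intermediate_gene_result` with fields `seeds`,
#'   `frequency` (named integer vector) and `skipped_pairs`.
#' @export
shortest_path_intermediates <- function(ppi, seeds, max_len = 3) {
  stop_if_not(max_len >= 2, "max_len must be >= 2")
  seeds <- sort(unique(as.character(seeds)))
  mapped <- intersect(seeds, ppi$nodes)
  if (length(mapped) < 2)
    stop("fewer than 2 seeds mappable to the PPI", call. = FALSE)
  g <- igraph::graph_from_data_frame(ppi$edges, directed = FALSE,
                                     vertices = data.frame(name = ppi$nodes))
  d <- igraph::distances(g, v = mapped, to = mapped, weights = NA)
  freq <- integer(0)
  skipped <- 0L
  for (i in seq_along(mapped)) {
    for (j in seq_along(mapped)) {
      if (j <= i) next
      dij <- d[i, j]
      if (!is.finite(dij)) { skipped <- skipped + 1L; next }
      if (dij < 2 || dij > max_len) next
      paths <- igraph::all_shortest_paths(g, from = mapped[i],
                                          to = mapped[j], weights = NA)$vpaths
      interior <- unique(unlist(lapply(paths, function(p) {
        nm <- igraph::as_ids(p)
        nm[-c(1, length(nm))]
      })))
      interior <- setdiff(interior, seeds)
      for (node in interior)
        freq[node] <- (if (node %in% names(freq)) freq[[node]] else 0L) + 1L
    }
  }
  if (length(freq)) freq <- freq[order(names(freq))]
  structure(list(seeds = mapped,
                 frequency = freq,
                 skipped_pairs = skipped),
            class = "intermediate_gene_result")
}

#' @export
print.intermediate_gene_result <- function(x, ...) {
  cat(sprintf("intermediate_gene_result: %d seeds, %d intermediates, %d pairs skipped\n",
              length(x$seeds), length(x$frequency), x$skipped_pairs))
  invisible(x)
}

#' Enrich the intermediate gene set
#'
#' Hypergeometric over-representation of the intermediates (optionally
#' filtered to frequency >= `min_freq`) against the PPI gene universe.
#'
#' @param result An `intermediate_gene_result`.
#' @param background Character vector: the PPI gene universe.
#' @param sets A [gene_set_collection()].
#' @param min_freq Minimum seed-pair frequency (default 1).
#' @param provenance Optional provenance fields.
#' @return An `enrichment_result`; empty intermediates give an empty
#'   result with a warning.
#' @export
ig_enrich <- function(result, background, sets, min_freq = 1,
                      provenance = list()) {
  ints <- names(result$frequency)[result$frequency >= min_freq]
  if (!length(ints)) {
    warning("no intermediate genes at the requested frequency")
    return(enrichment_result(data.frame(term = character(),
                                        overlap = integer(),
                                        size = integer(), p = numeric(),
                                        q = numeric(),
                                        significant = logical()),
                             provenance))
  }
  hypergeometric_ora(ints, background, sets,
                     provenance = utils::modifyList(list(analysis = "ig"),
                                                    provenance))
}
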