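# Network inference: build weighted undirected gene-gene co-expression
# networks (GGCNs) from similarity matrices by ARACNE-style mutual
# information pruning, CLR background z-scoring, or WGCNA-style soft
# thresholding, plus a consensus across inferred networks.

default_provenance <- function() {
  list(dataset = "n/a", modeling = "n/a", pseudobulk = "n/a",
       zero_mode = "n/a", selection = "n/a", k = "n/a",
       algorithm = "n/a", metric = "n/a")
}

#' Co-expression network container
#'
#' A simple undirected weighted graph over a fixed gene universe,
#' carrying the full parameter tuple (provenance) that produced it.
#'
#' @param genes Character vector: the gene universe (includes isolated
#'   genes).
#' @param edges Data frame with columns `from`, `to`, `weight`.
#' @param provenance Named list describing the creation parameters;
#'   missing entries are filled with `"n/a"`.
#' @return A `coexpression_network`.
#' @export
coexpression_network <- function(genes, edges, provenance = list()) {
  genes <- as.character(genes)
  stop_if_not(!anyDuplicated(genes), "duplicate gene ids")
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    stop_if_not(all(c(edges$from, edges$to) %in% genes),
                "edge endpoint not in gene universe")
    stop_if_not(all(edges$from != edges$to), "self-loop")
    stop_if_not(all(is.finite(edges$weight)), "non-finite edge weight")
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    stop_if_not(!anyDuplicated(paste(edges$from, edges$to)), "duplicate edge")
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  }
  prov <- utils::modifyList(default_provenance(), provenance)
  structure(list(genes = genes, edges = edges, provenance = prov),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("coexpression_network: %d genes, %d edges (algorithm=%s, metric=%s, modeling=%s)\n",
              length(x$genes), nrow(x$edges), p$algorithm, p$metric,
              p$modeling))
  invisible(x)
}

# internal: igraph view of a network, keeping isolated genes as vertices
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$genes))
  g
}

#' Split a pseudobulk matrix into network-inference inputs
#'
#' `"combined"` modeling yields one input holding all pseudobulks;
#' `"single"` yields one input per time label.  Single-time-point labels
#' with fewer than 3 pseudobulks are skipped with a warning.
#'
#' @param pb A [pseudobulk_matrix()].
#' @param modeling `"combined"` or `"single"`.
#' @return A named list of [pseudobulk_matrix()] objects.
#' @export
assemble_time_point_inputs <- function(pb, modeling = c("combined", "single")) {
  modeling <- match.arg(modeling)
  if (modeling == "combined") return(list(combined = pb))
  labs <- sort(unique(pb$time_labels))
  out <- list()
  for (t in labs) {
    sel <- pb$time_labels == t
    if (sum(sel) < 3) {
      warning(sprintf("time point '%s' has fewer than 3 pseudobulks; skipped", t))
      next
    }
    out[[t]] <- pseudobulk_matrix(pb$matrix[sel, , drop = FALSE],
                                  pb$pseudobulk_ids[sel], pb$gene_ids,
                                  pb$time_labels[sel], method = pb$method,
                                  zero_mode = pb$zero_mode)
  }
  out
}

# DPI triplet scan on a fixed edge set: for every connected triplet of
# the pre-DPI graph, mark the weakest edge for removal when
# w_min < (1 - eps) * min(other two).  All marks are taken on the same
# input graph, so removal order cannot matter.
dpi_prune <- function(genes, edges, eps = 0) {
  if (nrow(edges) < 3) return(edges)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = genes))
  tri <- matrix(as.integer(igraph::triangles(g)), nrow = 3)
  if (ncol(tri) == 0) return(edges)
  w <- edges$weight
  names(w) <- edge_key(edges$from, edges$to)
  drop <- character()
  for (t in seq_len(ncol(tri))) {
    ks <- c(edge_key(genes[tri[1, t]], genes[tri[2, t]]),
            edge_key(genes[tri[1, t]], genes[tri[3, t]]),
            edge_key(genes[tri[2, t]], genes[tri[3, t]]))
    ws <- w[ks]
    i_min <- which.min(ws)
    if (ws[i_min] < (1 - eps) * min(ws[-i_min]))
      drop <- c(drop, ks[i_min])
  }
  edges[!(edge_key(edges$from, edges$to) %in% drop), , drop = FALSE]
}

#' ARACNE-style network: MI threshold plus data-processing-inequality
#'
#' Edges whose mutual information exceeds a permutation-null threshold
#' at level `alpha` are kept; then, for every connected triplet, the
#' weakest edge is removed when its MI is below `(1 - dpi_tolerance)`
#' times the smaller of the other two (the data processing inequality
#' \eqn{I(n1,n3) \le \min[I(n1,n2); I(n2,n3)]}).  The triplet scan reads
#' the pre-DPI edge set only, so the result does not depend on removal
#' order and a second application removes nothing.
#'
#' @param sim A `similarity_matrix` with `metric = "mi"`.
#' @param alpha Null-quantile level for the MI threshold (default 0.05).
#' @param dpi_tolerance DPI tolerance epsilon >= 0 (default 0).
#' @param n_null Number of one-column permutations pooled into the null
#'   (default 100).
#' @param seed Integer seed for the permutations.
#' @param threshold Optional explicit MI threshold overriding the
#'   permutation null (used by tests and tiny fixtures).
#' @param provenance Optional provenance fields.
#' @return A [coexpression_network()] weighted by MI.
#' @export
aracne_network <- function(sim, alpha = 0.05, dpi_tolerance = 0,
                           n_null = 100, seed = 1, threshold = NULL,
                           provenance = list()) {
  stop_if_not(inherits(sim, "similarity_matrix"), "similarity_matrix required")
  if (sim$metric != "mi") stop("ARACNE requires an MI similarity", call. = FALSE)
  v <- sim$values
  thr <- threshold %||% aracne_null_threshold(sim, alpha, n_null, seed)
  idx <- which(upper.tri(v) & v > thr, arr.ind = TRUE)
  edges <- data.frame(from = sim$genes[idx[, 1]], to = sim$genes[idx[, 2]],
                      weight = v[idx], stringsAsFactors = FALSE)
  edges <- dpi_prune(sim$genes, edges, eps = dpi_tolerance)
  coexpression_network(sim$genes, edges,
                       utils::modifyList(list(algorithm = "aracne",
                                              metric = "mi"), provenance))
}

# pooled permutation null: each draw permutes one gene's binned values
# and recomputes its MI against every other gene
aracne_null_threshold <- function(sim, alpha, n_null, seed) {
  bins <- sim$bins
  stop_if_not(!is.null(bins), "MI similarity lacks binned data")
  g <- ncol(bins)
  with_seed(seed, {
    pool <- lapply(seq_len(n_null), function(i) {
      j <- sample.int(g, 1)
      perm <- sample(bins[, j])
      mi_vector(perm, bins[, -j, drop = FALSE], B = attr(bins, "n_bins"))
    })
    stats::quantile(unlist(pool), 1 - alpha, names = FALSE)
  })
}

#' CLR network: background z-scored mutual information
#'
#' For gene i, \eqn{z_i(j) = (I_{ij} - mean_i) / sd_i} over row i
#' excluding the diagonal (genes with zero row sd get z = 0).  The
#' combined score \eqn{c_{ij} = \sqrt{\max(0, z_i(j))^2 + \max(0,
#' z_j(i))^2}} is the edge weight; edges with score at or above
#' `z_cutoff` are kept.
#'
#' @param sim A `similarity_matrix` with `metric = "mi"` and >= 3 genes.
#' @param z_cutoff Score threshold (default 2).
#' @param provenance Optional provenance fields.
#' @return A [coexpression_network()] weighted by the combined z-score.
#' @export
clr_network <- function(sim, z_cutoff = 2, provenance = list()) {
  stop_if_not(inherits(sim, "similarity_matrix"), "similarity_matrix required")
  if (sim$metric != "mi") stop("CLR requires an MI similarity", call. = FALSE)
  g <- length(sim$genes)
  stop_if_not(g >= 3, "need at least 3 genes")
  v <- sim$values
  z <- clr_scores(v)
  idx <- which(upper.tri(z) & z >= z_cutoff, arr.ind = TRUE)
  edges <- data.frame(from = sim$genes[idx[, 1]], to = sim$genes[idx[, 2]],
                      weight = z[idx], stringsAsFactors = FALSE)
  coexpression_network(sim$genes, edges,
                       utils::modifyList(list(algorithm = "clr",
                                              metric = "mi"), provenance))
}

# combined CLR score matrix from an MI matrix (diagonal excluded)
clr_scores <- function(v) {
  g <- nrow(v)
  zrow <- matrix(0, g, g)
  for (i in seq_len(g)) {
    row <- v[i, -i]
    s <- stats::sd(row)
    zrow[i, -i] <- if (s > 0) (row - mean(row)) / s else 0
  }
  zp <- pmax(zrow, 0)
  sqrt(zp^2 + t(zp)^2)
}

#' WGCNA-style network: soft-thresholded adjacency with quantile pruning
#'
#' Unsigned adjacency \eqn{a_{ij} = |s_{ij}|^\beta} (MI similarities are
#' first rescaled to `[0, 1]` by their maximum).  With `beta = "auto"`
#' the smallest power in 1..20 whose degree distribution gives a
#' scale-free fit \eqn{R^2 \ge 0.8} is chosen (default 6 when none
#' does).  Edges with adjacency strictly above the `edge_quantile`
#' quantile of off-diagonal adjacency values are kept.
#'
#' @param sim A `similarity_matrix` (any metric).
#' @param beta Soft-thresholding power or `"auto"`.
#' @param edge_quantile Pruning quantile in (0, 1) (default 0.95); 0 is
#'   accepted and keeps every nonzero-adjacency pair.
#' @param provenance Optional provenance fields.
#' @return A [coexpression_network()] weighted by adjacency.
#' @export
wgcna_network <- function(sim, beta = "auto", edge_quantile = 0.95,
                          provenance = list()) {
  stop_if_not(inherits(sim, "similarity_matrix"), "similarity_matrix required")
  s <- abs(sim$values)
  if (sim$metric == "mi" && max(s) > 0) s <- s / max(s)
  diag(s) <- 0
  if (max(s) == 0) {
    warning("all similarities are 0; returning an empty network")
    return(coexpression_network(sim$genes,
                                data.frame(from = character(),
                                           to = character(),
                                           weight = numeric()),
                                utils::modifyList(list(algorithm = "wgcna",
                                                       metric = sim$metric),
                                                  provenance)))
  }
  if (identical(beta, "auto")) beta <- pick_soft_power(s)
  a <- s^beta
  off <- a[upper.tri(a)]
  thr <- if (edge_quantile <= 0) 0 else
    stats::quantile(off, edge_quantile, names = FALSE)
  idx <- which(upper.tri(a) & a > thr, arr.ind = TRUE)
  edges <- data.frame(from = sim$genes[idx[, 1]], to = sim$genes[idx[, 2]],
                      weight = a[idx], stringsAsFactors = FALSE)
  coexpression_network(sim$genes, edges,
                       utils::modifyList(list(algorithm = "wgcna",
                                              metric = sim$metric),
                                         provenance))
}

# scale-free fit: regress log10 degree-bin frequency on log10 mean
# connectivity over 10 bins; return smallest power with R^2 >= 0.8
pick_soft_power <- function(s, powers = 1:20, target_r2 = 0.8,
                            default = 6L) {
  for (b in powers) {
    a <- s^b
    k <- rowSums(a)
    r2 <- scale_free_r2(k)
    if (!is.na(r2) && r2 >= target_r2) return(b)
  }
  default
}

scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins || max(k) - min(k) < 1e-12) return(NA_real_)
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  cut_k <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tabulate(cut_k, nbins = n_bins)
  mids <- vapply(split(k, cut_k), function(v)
    if (length(v)) mean(v) else NA_real_, numeric(1))
  keep <- freq > 0 & !is.na(mids) & mids > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(freq[keep]) ~ log10(mids[keep]))
  summary(fit)$r.squared
}

#' Consensus network across inferred networks
#'
#' An edge is retained iff it is present in more than `min_fraction` of
#' the input networks; its weight is the mean over the networks where it
#' is present.
#'
#' @param networks List of [coexpression_network()] objects over the
#'   same gene universe.
#' @param min_fraction Strict presence-fraction threshold (default 0.5).
#' @param provenance Optional provenance fields.
#' @return A [coexpression_network()] with `algorithm = "consensus"`.
#' @export
consensus_network <- function(networks, min_fraction = 0.5,
                              provenance = list()) {
  stop_if_not(length(networks) >= 2, "need at least 2 networks")
  genes <- networks[[1]]$genes
  for (net in networks)
    if (!identical(sort(net$genes), sort(genes)))
      stop("networks have mismatched gene universes", call. = FALSE)
  keys <- lapply(networks, function(net)
    paste(net$edges$from, net$edges$to, sep = "|"))
  all_keys <- unique(unlist(keys))
  count <- rowSums(vapply(keys, function(k) all_keys %in% k,
                          logical(length(all_keys))))
  wsum <- numeric(length(all_keys)); names(wsum) <- all_keys
  for (i in seq_along(networks)) {
    wsum[keys[[i]]] <- wsum[keys[[i]]] + networks[[i]]$edges$weight
  }
  keep <- count / length(networks) > min_fraction
  parts <- do.call(rbind, strsplit(all_keys[keep], "|", fixed = TRUE))
  edges <- if (any(keep))
    data.frame(from = parts[, 1], to = parts[, 2],
               weight = wsum[keep] / count[keep], stringsAsFactors = FALSE)
  else data.frame(from = character(), to = character(), weight = numeric())
  coexpression_network(genes, edges,
                       utils::modifyList(list(algorithm = "consensus",
                                              metric = "n/a"), provenance))
}

#' Write a network as a 3-column TSV edge list with provenance sidecar
#' @param net A [coexpression_network()].
#' @param path Output TSV path; `<path>.provenance.json` is written next
#'   to it and the gene universe is stored in the sidecar.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(provenance = net$provenance, genes = net$genes),
                       paste0(path, ".provenance.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a network written by [write_network()]
#' @param path TSV path.
#' @return A [coexpression_network()].
#' @export
read_network <- function(path) {
  edges <- utils::read.delim(path, colClasses = c("character", "character",
                                                  "numeric"))
  side <- jsonlite::read_json(paste0(path, ".provenance.json"),
                              simplifyVector = TRUE)
  coexpression_network(side$genes, edges, as.list(side$provenance))
}
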