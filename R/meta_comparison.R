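# Meta-comparison: cluster result objects by the similarity of their
# significant term sets, test creation parameters for cluster
# over-representation, and score results against injected literature
# counts.

ASSIGNMENT_CATEGORIES <- c("dataset", "modeling", "pseudobulk", "zero_mode",
                           "selection", "k", "algorithm", "metric",
                           "analysis")

#' Term assignment of one result object
#'
#' The atom of meta-comparison: one (network, analysis strategy) result,
#' annotated with its complete parameter tuple and its set of
#' significant terms.
#'
#' @param id Result-object identifier.
#' @param params Named list over the parameter categories (`dataset`,
#'   `modeling`, `pseudobulk`, `zero_mode`, `selection`, `k`,
#'   `algorithm`, `metric`, `analysis`); missing or inapplicable entries
#'   are recorded as `"n/a"`.
#' @param terms Character vector of significant terms.
#' @return A `term_assignment`.
#' @export
term_assignment <- function(id, params, terms) {
  full <- stats::setNames(as.list(rep("n/a", length(ASSIGNMENT_CATEGORIES))),
                          ASSIGNMENT_CATEGORIES)
  for (nm in intersect(names(params), ASSIGNMENT_CATEGORIES))
    if (!is.null(params[[nm]])) full[[nm]] <- as.character(params[[nm]])
  structure(list(id = as.character(id), params = full,
                 terms = sort(unique(as.character(terms)))),
            class = "term_assignment")
}

#' Jaccard distance matrix between term assignments
#'
#' \eqn{D_{ij} = 1 - |S_i \cap S_j| / |S_i \cup S_j|}; two empty sets
#' have distance 0 by convention (logged as a message).
#'
#' @param assignments List of [term_assignment()] objects (>= 2).
#' @return Symmetric distance matrix with assignment ids as dimnames.
#' @export
jaccard_distance_matrix <- function(assignments) {
  stop_if_not(length(assignments) >= 2, "need at least 2 assignments")
  ids <- vapply(assignments, `[[`, character(1), "id")
  sets <- lapply(assignments, `[[`, "terms")
  n <- length(sets)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  both_empty <- FALSE
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      u <- length(union(sets[[i]], sets[[j]]))
      if (u == 0) { both_empty <- TRUE; d <- 0 }
      else d <- 1 - length(intersect(sets[[i]], sets[[j]])) / u
      D[i, j] <- D[j, i] <- d
    }
  }
  if (both_empty)
    message("empty term-set pair(s): distance 0 by convention")
  D
}

#' Louvain clustering of the term-set similarity graph
#'
#' The complete weighted graph with weights `1 - D` (weights below
#' `weight_floor` pruned) is partitioned by Louvain clustering;
#' deterministic given the seed.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param resolution Louvain resolution (default 1).
#' @param seed Integer seed.
#' @param weight_floor Minimum similarity kept as an edge (default
#'   0.05).
#' @return Named integer vector of cluster labels.
#' @export
cluster_similarity_graph <- function(D, resolution = 1, seed = 1,
                                     weight_floor = 0.05) {
  stop_if_not(is.matrix(D) && nrow(D) == ncol(D), "square matrix required")
  if (max(abs(D - t(D))) > 1e-8) stop("asymmetric distance matrix",
                                      call. = FALSE)
  stop_if_not(all(abs(diag(D)) < 1e-8), "diagonal must be zero")
  W <- 1 - D
  diag(W) <- 0
  W[W < weight_floor] <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- if (igraph::ecount(g) == 0)
    seq_len(nrow(D))
  else with_seed(seed, as.integer(igraph::membership(
    igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                            resolution = resolution))))
  stats::setNames(as.integer(memb), rownames(D))
}

#' Parameter over-representation within result clusters
#'
#' For each cluster and each (category, value) pair, the hypergeometric
#' upper-tail probability of the observed value count in the cluster
#' (population: all result objects).  BH adjustment is applied within
#' each category across all of its cluster-value tests.  Categories with
#' a single observed value are skipped with a message.
#'
#' @param labels Named cluster labels from [cluster_similarity_graph()].
#' @param assignments The list of [term_assignment()] objects the labels
#'   cover.
#' @return A `cluster_enrichment` data frame with columns `cluster`,
#'   `category`, `value`, `k`, `K`, `n`, `N`, `p`, `q`, `significant`.
#' @export
parameter_overrepresentation <- function(labels, assignments) {
  ids <- vapply(assignments, `[[`, character(1), "id")
  stop_if_not(all(ids %in% names(labels)), "labels must cover all assignments")
  lab <- labels[ids]
  N <- length(assignments)
  params <- do.call(rbind, lapply(assignments, function(a)
    as.data.frame(a$params, stringsAsFactors = FALSE)))
  rows <- list()
  for (cat in ASSIGNMENT_CATEGORIES) {
    vals <- unique(params[[cat]])
    if (length(vals) < 2) {
      message(sprintf("category '%s' has a single value; skipped", cat))
      next
    }
    for (cl in sort(unique(lab))) {
      in_cl <- lab == cl
      n <- sum(in_cl)
      for (v in vals) {
        has_v <- params[[cat]] == v
        K <- sum(has_v)
        k <- sum(has_v & in_cl)
        p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        rows[[length(rows) + 1L]] <-
          data.frame(cluster = cl, category = cat, value = v, k = k, K = K,
                     n = n, N = N, p = p, stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows) %||%
    data.frame(cluster = integer(), category = character(),
               value = character(), k = integer(), K = integer(),
               n = integer(), N = integer(), p = numeric())
  df$q <- NA_real_
  for (cat in unique(df$category))
    df$q[df$category == cat] <- bh_adjust(df$p[df$category == cat])
  df$significant <- !is.na(df$q) & df$q < 0.05
  class(df) <- c("cluster_enrichment", "data.frame")
  df
}

#' Read a term -> literature-count table
#' @param path TSV with columns term and count (header required).
#' @return Named numeric vector.
#' @export
read_literature_counts <- function(path) {
  df <- utils::read.delim(path)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Literature-support test of one result object
#'
#' One-sided Welch t-test on `log10(count + 1)` comparing the
#' significant terms of the assignment against the non-significant terms
#' of the tested universe; higher counts among significant terms give a
#' small p.  Requires counts for at least 3 terms on each side; constant
#' counts make the result untestable.
#'
#' @param assignment A [term_assignment()].
#' @param all_terms Character vector: all terms tested for this result
#'   object.
#' @param counts Named numeric vector term -> literature count.
#' @return List with `statistic`, `p`, `n_sig`, `n_nonsig`, `testable`.
#' @export
literature_score_test <- function(assignment, all_terms, counts) {
  sig <- intersect(assignment$terms, names(counts))
  nonsig <- intersect(setdiff(all_terms, assignment$terms), names(counts))
  untestable <- list(statistic = NA_real_, p = NA_real_,
                     n_sig = length(sig), n_nonsig = length(nonsig),
                     testable = FALSE)
  if (length(sig) < 3 || length(nonsig) < 3) return(untestable)
  x <- log10(counts[sig] + 1)
  y <- log10(counts[nonsig] + 1)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    # both groups constant: no sampling variance; the comparison is
    # degenerate but directionally unambiguous when the means differ
    if (mean(x) == mean(y)) return(untestable)
    return(list(statistic = sign(mean(x) - mean(y)) * Inf,
                p = if (mean(x) > mean(y)) 0 else 1,
                n_sig = length(sig), n_nonsig = length(nonsig),
                testable = TRUE))
  }
  tt <- stats::t.test(x, y, alternative = "greater", var.equal = FALSE)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       n_sig = length(sig), n_nonsig = length(nonsig), testable = TRUE)
}

#' Cluster result objects by their literature-test scores
#'
#' Result objects are embedded as (t, p) pairs, a Euclidean distance is
#' rescaled to `[0, 1]` by its maximum, and the similarity graph is
#' clustered as in [cluster_similarity_graph()].  The "expected" cluster
#' is the one with the largest mean t statistic.
#'
#' @param scores Data frame with columns `id`, `statistic`, `p`
#'   (untestable rows dropped).
#' @param resolution,seed,weight_floor As in
#'   [cluster_similarity_graph()].
#' @return List with `labels` (named integer vector) and
#'   `expected_cluster`.
#' @export
cluster_literature_scores <- function(scores, resolution = 1, seed = 1,
                                      weight_floor = 0.05) {
  scores <- scores[is.finite(scores$statistic), , drop = FALSE]
  stop_if_not(nrow(scores) >= 2, "need at least 2 testable results")
  m <- scale(as.matrix(scores[, c("statistic", "p")]))
  m[is.nan(m)] <- 0
  D <- as.matrix(stats::dist(m))
  if (max(D) > 0) D <- D / max(D)
  dimnames(D) <- list(scores$id, scores$id)
  labels <- cluster_similarity_graph(D, resolution = resolution,
                                     seed = seed,
                                     weight_floor = weight_floor)
  mean_t <- tapply(scores$statistic, labels, mean)
  list(labels = labels,
       expected_cluster = as.integer(names(which.max(mean_t))))
}

#' Write term assignments as JSON lines
#' @param assignments List of [term_assignment()] objects.
#' @param path Output path (one JSON object per line).
#' @export
write_term_assignments <- function(assignments, path) {
  lines <- vapply(assignments, function(a)
    jsonlite::toJSON(list(id = a$id, params = a$params, terms = a$terms),
                     auto_unbox = TRUE), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read term assignments written by [write_term_assignments()]
#' @param path JSON-lines path.
#' @return List of [term_assignment()] objects.
#' @export
read_term_assignments <- function(path) {
  lapply(readLines(path), function(line) {
    obj <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    term_assignment(obj$id, as.list(obj$params),
                    unlist(obj$terms) %||% character())
  })
}
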