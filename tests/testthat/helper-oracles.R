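# Independent brute-force oracles used to validate the implementation.
# These deliberately avoid igraph and the package's own code paths.

# random simple undirected graph as a 0/1 adjacency matrix
random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.integer(runif(length(up)) < p)
  a + t(a)
}

adjacency_to_network <- function(a, prefix = "v") {
  n <- nrow(a)
  genes <- sprintf("%s%02d", prefix, seq_len(n))
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  coexpression_network(genes,
                       data.frame(from = genes[idx[, 1]],
                                  to = genes[idx[, 2]],
                                  weight = rep(1, nrow(idx))))
}

# BFS distances from one source on an adjacency matrix
bfs_dist <- function(a, src) {
  n <- nrow(a)
  d <- rep(Inf, n); d[src] <- 0
  frontier <- src
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      nb <- which(a[v, ] > 0)
      new <- nb[d[nb] == Inf]
      d[new] <- d[v] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  d
}

# enumerate every shortest path between s and t by recursive predecessor
# expansion over BFS distances
enumerate_shortest_paths <- function(a, s, t) {
  d <- bfs_dist(a, s)
  if (!is.finite(d[t])) return(list())
  expand <- function(v) {
    if (v == s) return(list(s))
    preds <- which(a[v, ] > 0 & d == d[v] - 1)
    out <- list()
    for (p in preds)
      for (path in expand(p))
        out[[length(out) + 1L]] <- c(path, v)
    out
  }
  expand(t)
}

# betweenness by full shortest-path enumeration, normalized by pair count
bf_betweenness <- function(a) {
  n <- nrow(a)
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- enumerate_shortest_paths(a, s, t)
      if (!length(paths)) next
      through <- numeric(n)
      for (path in paths) {
        interior <- setdiff(path, c(s, t))
        through[interior] <- through[interior] + 1
      }
      b <- b + through / length(paths)
    }
  }
  b / choose(n - 1, 2)
}

# closeness on each node's reachable set with component-size scaling
bf_closeness <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(v) {
    d <- bfs_dist(a, v)
    fin <- d[is.finite(d) & d > 0]
    r <- length(fin)
    if (r == 0) 0 else (r / (n - 1)) * (r / sum(fin))
  }, numeric(1))
}

# triangle and triad counting by direct triple loops
bf_graph_metrics <- function(a) {
  n <- nrow(a)
  m <- sum(a) / 2
  tri <- 0
  for (i in seq_len(n - 2))
    for (j in (i + 1):(n - 1))
      for (k in (j + 1):n)
        if (a[i, j] && a[i, k] && a[j, k]) tri <- tri + 1
  deg <- rowSums(a)
  triads <- sum(choose(deg, 2))
  local <- vapply(seq_len(n), function(v) {
    nb <- which(a[v, ] > 0)
    if (length(nb) < 2) return(0)
    links <- sum(a[nb, nb]) / 2
    links / choose(length(nb), 2)
  }, numeric(1))
  list(density = 2 * m / (n * (n - 1)),
       transitivity = if (triads == 0) 0 else 3 * tri / triads,
       avg_clustering = mean(local),
       n_triangles = tri)
}

# O(n^3) triplet-scan oracle for DPI pruning of a thresholded MI matrix:
# returns the surviving adjacency (0/1)
bf_dpi <- function(mi, thr, eps = 0) {
  n <- nrow(mi)
  adj <- (mi > thr) & upper.tri(mi)
  adj <- adj | t(adj)
  drop <- matrix(FALSE, n, n)
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        if (!(adj[i, j] && adj[i, k] && adj[j, k])) next
        w <- c(mi[i, j], mi[i, k], mi[j, k])
        mn <- which.min(w)
        if (w[mn] < (1 - eps) * min(w[-mn])) {
          if (mn == 1) drop[i, j] <- drop[j, i] <- TRUE
          if (mn == 2) drop[i, k] <- drop[k, i] <- TRUE
          if (mn == 3) drop[j, k] <- drop[k, j] <- TRUE
        }
      }
    }
  }
  adj & !drop
}

# direct per-row mean/sd recomputation of CLR combined scores
bf_clr <- function(mi) {
  n <- nrow(mi)
  z <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- mi[i, -i]
    s <- sd(row)
    if (s > 0) z[i, -i] <- (mi[i, -i] - mean(row)) / s
  }
  zp <- pmax(z, 0)
  sqrt(zp^2 + t(zp)^2)
}

# exact hypergeometric upper tail by combinatorial enumeration
bf_hyper_upper <- function(k, K, N, n) {
  js <- max(k, 0):min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# intermediate-gene frequencies by exhaustive shortest-path enumeration
bf_intermediates <- function(a, node_names, seeds, max_len) {
  sidx <- match(seeds, node_names)
  freq <- integer(0)
  for (x in seq_along(sidx)) {
    for (y in seq_along(sidx)) {
      if (y <= x) next
      paths <- enumerate_shortest_paths(a, sidx[x], sidx[y])
      if (!length(paths)) next
      len <- length(paths[[1]]) - 1
      if (len < 2 || len > max_len) next
      interior <- unique(unlist(lapply(paths, function(p)
        p[-c(1, length(p))])))
      interior <- setdiff(node_names[interior], seeds)
      for (nm in interior)
        freq[nm] <- (if (nm %in% names(freq)) freq[[nm]] else 0L) + 1L
    }
  }
  freq[order(names(freq))]
}

# mutual information of two binned vectors by direct table counting
bf_mi <- function(bx, by) {
  tab <- table(bx, by)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  total <- 0
  for (i in seq_len(nrow(p)))
    for (j in seq_len(ncol(p)))
      if (p[i, j] > 0)
        total <- total + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  unname(total)
}
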