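test_that("similarity metrics behave on known relationships", {
  set.seed(4)
  x <- rnorm(30)
  m <- cbind(gA = x, gB = 2 * x + 1, gC = exp(x))
  pb <- pb_from_matrix(m - min(m))
  pe <- compute_similarity(pb, metric = "pearson")
  expect_equal(pe$values["gA", "gB"], 1, tolerance = 1e-12)
  sp <- compute_similarity(pb, metric = "spearman")
  expect_equal(sp$values["gA", "gC"], 1, tolerance = 1e-12)
  expect_lt(pe$values["gA", "gC"], 1)
  # constant gene: flagged, similarity 0
  m2 <- cbind(m - min(m), gD = rep(2, 30))
  expect_warning(pc <- compute_similarity(pb_from_matrix(m2),
                                          metric = "pearson"), "constant")
  expect_equal(pc$values["gD", "gA"], 0)
})

test_that("mutual information matches direct table counting and the binary case", {
  # identical balanced binary vectors with 2 bins carry exactly 1 bit
  b <- rep(c(0, 5), each = 10)
  pb <- pb_from_matrix(cbind(gX = b, gY = b, gZ = rev(b)))
  sim <- compute_similarity(pb, metric = "mi")
  bins <- coexcompare:::equal_frequency_bins(pb$matrix, n_bins = 2)
  expect_equal(sim$values["gX", "gY"], 1)
  # oracle: plug-in MI by direct contingency-table counting
  set.seed(12)
  m <- matrix(rgamma(25 * 8, 2), 25, 8,
              dimnames = list(NULL, sprintf("g%d", 1:8)))
  sim2 <- compute_similarity(pb_from_matrix(m), metric = "mi")
  bins2 <- coexcompare:::equal_frequency_bins(m)
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(sim2$values[i, j], bf_mi(bins2[, i], bins2[, j]),
                 tolerance = 1e-12)
  expect_true(all(sim2$values >= 0))
})

test_that("time-point input assembly follows the modeling mode", {
  pb <- small_pb()                       # 12 pseudobulks over 3 labels
  combined <- assemble_time_point_inputs(pb, "combined")
  expect_length(combined, 1)
  expect_equal(nrow(combined$combined$matrix), 12)
  single <- assemble_time_point_inputs(pb, "single")
  expect_length(single, 3)
  expect_true(all(vapply(single, function(s) nrow(s$matrix), numeric(1)) == 4))
  # a label below the minimum is skipped with a warning
  keep <- c(which(pb$time_labels != "t3"), which(pb$time_labels == "t3")[1:2])
  pb2 <- pseudobulk_matrix(pb$matrix[keep, ], pb$pseudobulk_ids[keep],
                           pb$gene_ids, pb$time_labels[keep],
                           method = "time", zero_mode = pb$zero_mode)
  expect_warning(res <- assemble_time_point_inputs(pb2, "single"), "t3")
  expect_length(res, 2)
})

test_that("ARACNE applies the printed DPI inequality on a triangle", {
  v <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  v["a", "b"] <- v["b", "a"] <- 0.5
  v["b", "c"] <- v["c", "b"] <- 0.3
  v["a", "c"] <- v["c", "a"] <- 0.2
  net <- aracne_network(sim_from_matrix(v), threshold = 0.1)
  expect_equal(nrow(net$edges), 2)
  expect_false(any(net$edges$from == "a" & net$edges$to == "c"))
  # chain without the third edge above threshold: no triplet, no removal
  net2 <- aracne_network(sim_from_matrix(v), threshold = 0.25)
  expect_equal(nrow(net2$edges), 2)
  expect_error(aracne_network(sim_from_matrix(v, metric = "pearson")),
               "MI")
})

test_that("DPI equals the triplet-scan oracle and is idempotent", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 20
    v <- matrix(0, n, n)
    v[upper.tri(v)] <- runif(n * (n - 1) / 2)
    v <- v + t(v)
    dimnames(v) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
    thr <- 0.4
    net <- aracne_network(sim_from_matrix(v), threshold = thr)
    oracle <- bf_dpi(v, thr)
    got <- matrix(FALSE, n, n, dimnames = dimnames(v))
    for (r in seq_len(nrow(net$edges)))
      got[net$edges$from[r], net$edges$to[r]] <-
        got[net$edges$to[r], net$edges$from[r]] <- TRUE
    expect_identical(got, oracle)
    # idempotence: the scan removes nothing from its own output
    again <- coexcompare:::dpi_prune(net$genes, net$edges, eps = 0)
    expect_identical(again, net$edges)
  }
})

test_that("the ARACNE permutation threshold suppresses null edges", {
  set.seed(5)
  m <- matrix(rnorm(40 * 30), 40, 30,
              dimnames = list(NULL, sprintf("g%02d", 1:30)))
  sim <- compute_similarity(pb_from_matrix(m - min(m)), metric = "mi")
  net <- aracne_network(sim, alpha = 0.05, n_null = 60, seed = 2)
  # independent genes: only a small fraction of pairs may survive
  expect_lt(nrow(net$edges) / choose(30, 2), 0.1)
  net2 <- aracne_network(sim, alpha = 0.05, n_null = 60, seed = 2)
  expect_identical(net$edges, net2$edges)
})

test_that("CLR scores equal independent row-statistics recomputation", {
  set.seed(9)
  n <- 15
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- rgamma(n * (n - 1) / 2, 2)
  v <- v + t(v)
  dimnames(v) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  z <- coexcompare:::clr_scores(v)
  expect_equal(z, unname(bf_clr(v)), tolerance = 1e-12)
  net <- clr_network(sim_from_matrix(v), z_cutoff = 1)
  for (r in seq_len(nrow(net$edges))) {
    i <- match(net$edges$from[r], rownames(v))
    j <- match(net$edges$to[r], rownames(v))
    expect_equal(net$edges$weight[r], bf_clr(v)[i, j], tolerance = 1e-12)
  }
  # a pair exactly on both row means scores 0 and is dropped
  flat <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(flat) <- 0
  expect_equal(nrow(clr_network(sim_from_matrix(flat),
                                z_cutoff = 0.1)$edges), 0)
})

test_that("WGCNA soft threshold and quantile pruning match brute force", {
  set.seed(13)
  n <- 25
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- runif(n * (n - 1) / 2, -1, 1)
  v <- v + t(v)
  dimnames(v) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  sim <- sim_from_matrix(v, metric = "pearson")
  net <- wgcna_network(sim, beta = 3, edge_quantile = 0.9)
  a <- abs(v)^3
  off <- a[upper.tri(a)]
  thr <- quantile(off, 0.9, names = FALSE)
  expect_equal(nrow(net$edges), sum(off > thr))
  # beta = 1, quantile 0: every nonzero pair is an edge
  net0 <- wgcna_network(sim, beta = 1, edge_quantile = 0)
  expect_equal(nrow(net0$edges), sum(abs(v[upper.tri(v)]) > 0))
  # adjacency is monotone decreasing in beta for |s| < 1
  net_b2 <- wgcna_network(sim, beta = 2, edge_quantile = 0)
  net_b8 <- wgcna_network(sim, beta = 8, edge_quantile = 0)
  expect_true(all(net_b8$edges$weight <= net_b2$edges$weight + 1e-15))
  # all-zero similarity: empty network with warning
  zero <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(e <- wgcna_network(sim_from_matrix(zero, "pearson")),
                 "empty")
  expect_equal(nrow(e$edges), 0)
})

test_that("consensus retains edges by strict majority and averages weights", {
  mk <- function(pairs, w) {
    coexpression_network(letters[1:4],
                         data.frame(from = pairs[, 1], to = pairs[, 2],
                                    weight = w))
  }
  n1 <- mk(rbind(c("a", "b"), c("b", "c")), c(1, 1))
  n2 <- mk(rbind(c("a", "b"), c("c", "d")), c(3, 1))
  n3 <- mk(rbind(c("a", "b"), c("b", "c")), c(5, 2))
  cons <- consensus_network(list(n1, n2, n3))
  expect_setequal(paste(cons$edges$from, cons$edges$to),
                  c("a b", "b c"))                  # 3/3 and 2/3 kept, 1/3 dropped
  expect_equal(cons$edges$weight[cons$edges$from == "a"], 3)   # mean(1,3,5)
  expect_equal(cons$edges$weight[cons$edges$from == "b"], 1.5) # mean(1,2)
  bad <- mk(rbind(c("a", "b")), 1)
  bad$genes <- c("a", "b", "c", "x")
  expect_error(consensus_network(list(n1, bad)), "mismatched")
})

test_that("inference is invariant to gene ordering", {
  set.seed(31)
  n <- 12
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- rgamma(n * (n - 1) / 2, 2)
  v <- v + t(v)
  genes <- sprintf("g%02d", 1:n)
  dimnames(v) <- list(genes, genes)
  perm <- sample(n)
  vp <- v[perm, perm]
  for (build in list(function(s) clr_network(s, z_cutoff = 1),
                     function(s) wgcna_network(s, beta = 2,
                                               edge_quantile = 0.8))) {
    e1 <- build(sim_from_matrix(v))$edges
    e2 <- build(sim_from_matrix(vp))$edges
    e2 <- e2[order(e2$from, e2$to), ]
    rownames(e2) <- NULL
    expect_equal(e1, e2)
  }
})

test_that("network edge lists round-trip through TSV with provenance", {
  net <- clr_network(sim_from_matrix({
    set.seed(2); n <- 8
    v <- matrix(0, n, n); v[upper.tri(v)] <- rgamma(28, 2); v <- v + t(v)
    dimnames(v) <- list(sprintf("g%d", 1:n), sprintf("g%d", 1:n)); v
  }), z_cutoff = 0.5, provenance = list(modeling = "combined",
                                        selection = "var"))
  path <- tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$edges, net$edges, tolerance = 1e-12)
  expect_identical(back$provenance, net$provenance)
  expect_identical(back$genes, net$genes)
})
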