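asg <- function(id, terms, ...) {
  term_assignment(id, list(...), terms)
}

test_that("jaccard distances follow the set formula and metric properties", {
  a <- asg("a", c("A", "B")); b <- asg("b", c("B", "C"))
  c_ <- asg("c", c("A", "B")); d <- asg("d", c("X", "Y"))
  D <- jaccard_distance_matrix(list(a, b, c_, d))
  expect_equal(D["a", "b"], 2 / 3)
  expect_equal(D["a", "c"], 0)
  expect_equal(D["a", "d"], 1)
  expect_equal(diag(D), setNames(rep(0, 4), c("a", "b", "c", "d")))
  # empty pair convention
  expect_message(D0 <- jaccard_distance_matrix(list(asg("e", character()),
                                                    asg("f", character()))),
                 "convention")
  expect_equal(D0["e", "f"], 0)
  # metric properties spot-checked on random triples
  set.seed(3)
  pool <- sprintf("T%02d", 1:15)
  for (i in 1:20) {
    tri <- lapply(1:3, function(j) asg(paste0("x", j),
                                       sample(pool, sample(1:10, 1))))
    D3 <- jaccard_distance_matrix(tri)
    expect_true(all(D3 >= 0 & D3 <= 1))
    expect_equal(D3, t(D3))
    for (p in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3)))
      expect_lte(D3[p[1], p[2]], D3[p[1], p[3]] + D3[p[3], p[2]] + 1e-12)
  }
})

test_that("similarity-graph clustering separates disjoint blocks", {
  block1 <- lapply(1:4, function(i) asg(paste0("p", i), c("A", "B", "C")))
  block2 <- lapply(1:4, function(i) asg(paste0("q", i), c("X", "Y", "Z")))
  D <- jaccard_distance_matrix(c(block1, block2))
  labels <- cluster_similarity_graph(D, seed = 1)
  expect_length(unique(labels), 2)
  expect_length(unique(labels[paste0("p", 1:4)]), 1)
  expect_length(unique(labels[paste0("q", 1:4)]), 1)
  # identical sets: one cluster
  same <- lapply(1:5, function(i) asg(paste0("s", i), c("A", "B")))
  Ds <- jaccard_distance_matrix(same)
  expect_length(unique(cluster_similarity_graph(Ds, seed = 1)), 1)
  # determinism
  expect_identical(cluster_similarity_graph(D, seed = 7),
                   cluster_similarity_graph(D, seed = 7))
  # asymmetric input rejected
  Dbad <- D; Dbad[1, 2] <- Dbad[1, 2] + 0.5
  expect_error(cluster_similarity_graph(Dbad), "asymmetric")
})

test_that("parameter over-representation matches the exact hypergeometric", {
  # 12 result objects; algorithm drives membership of cluster 1
  assignments <- lapply(1:12, function(i)
    asg(sprintf("r%02d", i), sprintf("T%d", i),
        algorithm = if (i <= 4) "aracne" else "clr",
        metric = c("mi", "pearson")[i %% 2 + 1]))
  labels <- setNames(c(rep(1L, 4), rep(2L, 8)),
                     sprintf("r%02d", 1:12))
  enr <- suppressMessages(parameter_overrepresentation(labels, assignments))
  row <- enr[enr$cluster == 1 & enr$category == "algorithm" &
             enr$value == "aracne", ]
  # k = K = n = 4, N = 12: exact enumeration oracle
  expect_equal(row$p, bf_hyper_upper(4, 4, 12, 4), tolerance = 1e-12)
  expect_true(row$significant)
  # proportionally spread value: p near 1
  rows_m <- enr[enr$category == "metric", ]
  expect_true(all(rows_m$p > 0.2))
  # every (cluster, category, value) p matches the oracle
  for (r in seq_len(nrow(enr)))
    expect_equal(enr$p[r],
                 bf_hyper_upper(enr$k[r], enr$K[r], enr$N[r], enr$n[r]),
                 tolerance = 1e-12)
  # single-valued categories are skipped
  expect_false("dataset" %in% enr$category)
})

test_that("a planted driver parameter is flagged in its cluster", {
  flagged <- vapply(1:25, function(s) {
    set.seed(s)
    pool <- sprintf("T%03d", 1:100)
    assignments <- lapply(1:24, function(i) {
      alg <- c("aracne", "clr", "wgcna")[(i - 1) %% 3 + 1]
      asg(sprintf("r%02d", i),
          if (alg == "aracne") pool[1:10] else sample(pool[11:100], 10),
          algorithm = alg, metric = sample(c("pearson", "mi"), 1),
          selection = sample(c("var", "sum", "deg"), 1))
    })
    D <- jaccard_distance_matrix(assignments)
    labels <- cluster_similarity_graph(D, seed = s)
    enr <- suppressMessages(parameter_overrepresentation(labels, assignments))
    ar <- sprintf("r%02d", seq(1, 24, 3))
    cl <- as.integer(names(which.max(table(labels[ar]))))
    row <- enr[enr$cluster == cl & enr$category == "algorithm" &
               enr$value == "aracne", ]
    nrow(row) == 1 && row$significant
  }, logical(1))
  expect_gte(mean(flagged), 0.9)
})

test_that("the literature t-test behaves on planted and degenerate counts", {
  terms <- sprintf("T%02d", 1:20)
  counts <- setNames(c(rep(1e4, 10), rep(1, 10)), terms)
  a <- asg("a", terms[1:10])
  res <- literature_score_test(a, terms, counts)
  expect_true(res$testable)
  expect_gt(res$statistic, 0)
  expect_lt(res$p, 0.01)
  # oracle: direct Welch computation on counts with sampling variation
  set.seed(4)
  varied <- setNames(c(rpois(10, 1e4), rpois(10, 3)), terms)
  res_v <- literature_score_test(a, terms, varied)
  tt <- t.test(log10(varied[1:10] + 1), log10(varied[11:20] + 1),
               alternative = "greater")
  expect_equal(res_v$statistic, unname(tt$statistic))
  expect_equal(res_v$p, tt$p.value)
  # identical distributions: t near 0 on average
  set.seed(8)
  stats <- replicate(40, {
    cnt <- setNames(rpois(20, 50), terms)
    literature_score_test(asg("x", sample(terms, 10)), terms,
                          cnt)$statistic
  })
  expect_lt(abs(mean(stats)), 0.5)
  # constant counts are untestable
  flat <- setNames(rep(7, 20), terms)
  expect_false(literature_score_test(a, terms, flat)$testable)
  # too few terms on either side
  expect_false(literature_score_test(asg("y", terms[1:2]), terms,
                                     counts)$testable)
})

test_that("literature score clustering identifies the high-t cluster", {
  scores <- data.frame(id = sprintf("r%02d", 1:10),
                       statistic = c(rep(5, 5), rep(-1, 5)),
                       p = c(rep(0.001, 5), rep(0.8, 5)))
  out <- cluster_literature_scores(scores, seed = 2)
  expect_length(unique(out$labels[1:5]), 1)
  expect_equal(out$expected_cluster, unname(out$labels[1]))
})

test_that("term assignments round-trip through JSON lines", {
  a1 <- asg("a", c("T1", "T2"), algorithm = "clr", metric = "mi")
  a2 <- asg("b", character(), algorithm = "wgcna")
  p <- tempfile(fileext = ".jsonl")
  write_term_assignments(list(a1, a2), p)
  back <- read_term_assignments(p)
  expect_identical(back[[1]]$terms, a1$terms)
  expect_identical(back[[1]]$params, a1$params)
  expect_identical(back[[2]]$terms, character())
  expect_identical(back[[2]]$params$algorithm, "wgcna")
})
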