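test_that("GMT parsing follows the standard dialect", {
  p <- tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\tA\tB", "T2\tother\tA\tA\tC"), p)
  gs <- read_gmt(p)
  expect_length(gs$sets, 2)
  expect_setequal(gs$sets$T1, c("A", "B"))
  expect_length(gs$sets$T2, 2)          # duplicate counted once
  writeLines(c("T1\tdesc\tA", "T2\tonly-two-fields"), p)
  expect_error(read_gmt(p), "line 2")
  writeLines(character(), p)
  expect_warning(empty <- read_gmt(p), "empty")
  expect_length(empty$sets, 0)
  # round trip
  writeLines(c("T1\tdesc\tA\tB", "T2\tother\tA\tC"), p)
  gs2 <- read_gmt(p)
  p2 <- tempfile(fileext = ".gmt")
  write_gmt(gs2, p2)
  expect_identical(readLines(p2), readLines(p))
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone: raising every p cannot create more rejections
  set.seed(2)
  p <- runif(40)
  expect_lte(sum(bh_adjust(pmin(p + 0.1, 1)) < 0.05),
             sum(bh_adjust(p) < 0.05))
})

test_that("ranked gene lists sort by score then id", {
  rk <- ranked_gene_list(c("b", "a", "c"), c(1, 1, 5))
  expect_identical(rk$gene, c("c", "a", "b"))
  expect_error(ranked_gene_list(c("a", "a"), 1:2), "unique")
})

test_that("the enrichment score is maximal for the top of the ranking", {
  set.seed(6)
  scores <- sort(runif(100, 0.1, 1), decreasing = TRUE)
  es_top <- coexcompare:::gsea_es(scores, 1:3)
  # the top-3 set beats every random 3-gene set
  for (i in 1:200) {
    idx <- sort(sample(100, 3))
    expect_lte(coexcompare:::gsea_es(scores, idx), es_top)
  }
  expect_gt(es_top, 0)
  expect_lte(es_top, 1)
})

test_that("with flat scores the enrichment score is the unweighted KS statistic", {
  scores <- rep(1, 50)
  for (idx in list(c(1, 2, 3), c(10, 25, 40), c(48, 49, 50))) {
    nh <- length(idx)
    # closed-form unweighted KS over positions
    run <- cumsum(ifelse(seq_len(50) %in% idx, 1 / nh, -1 / (50 - nh)))
    expect_equal(coexcompare:::gsea_es(scores, idx),
                 run[which.max(abs(run))], tolerance = 1e-12)
  }
})

test_that("preranked GSEA flags a planted top set and respects the overlap rule", {
  set.seed(10)
  genes <- sprintf("g%03d", 1:100)
  scores <- sort(rexp(100), decreasing = TRUE)
  rk <- ranked_gene_list(genes, scores)
  gs <- gene_set_collection(list(top = genes[1:8],
                                 tiny = genes[1],        # overlap < 3
                                 spread = genes[seq(5, 95, 10)]))
  res <- preranked_gsea(rk, gs, n_perm = 500, seed = 3)
  expect_false("tiny" %in% res$term)    # skipped by the min-overlap rule
  expect_true(res$significant[res$term == "top"])
  expect_gt(res$es[res$term == "top"], 0)
  # determinism
  res2 <- preranked_gsea(rk, gs, n_perm = 500, seed = 3)
  expect_identical(res, res2)
  # no usable set
  expect_warning(e <- preranked_gsea(rk,
    gene_set_collection(list(out = c("x1", "x2", "x3")))), "overlap")
  expect_equal(nrow(e), 0)
})

test_that("GSEA enrichment scores agree with fgsea's statistic", {
  skip_if_not_installed("fgsea")
  set.seed(22)
  genes <- sprintf("g%03d", 1:60)
  scores <- sort(rnorm(60, 1, 1), decreasing = TRUE)
  for (i in 1:10) {
    idx <- sort(sample(60, 6))
    mine <- coexcompare:::gsea_es(scores, idx)
    ref <- fgsea::calcGseaStat(scores, idx, gseaParam = 1,
                               scoreType = "std")
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("hypergeometric ORA matches exact combinatorial enumeration", {
  bg <- sprintf("G%02d", 1:10)
  gs <- gene_set_collection(list(S = bg[1:5]))
  res <- hypergeometric_ora(bg[1:5], bg, gs)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)  # 1/252
  # exhaustive oracle across configurations with N <= 12
  set.seed(17)
  for (i in 1:25) {
    N <- sample(5:12, 1)
    bgN <- sprintf("G%02d", seq_len(N))
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    S <- sample(bgN, K)
    hits <- sample(bgN, n)
    res <- hypergeometric_ora(hits, bgN, gene_set_collection(list(S = S)))
    k <- length(intersect(hits, S))
    expect_equal(res$p, bf_hyper_upper(k, K, N, n), tolerance = 1e-12)
  }
  # zero overlap and term == background both give p = 1
  res0 <- hypergeometric_ora(bg[6:10], bg,
                             gene_set_collection(list(S = bg[1:5])))
  expect_equal(res0$p, 1)
  resN <- hypergeometric_ora(bg[1:3], bg, gene_set_collection(list(S = bg)))
  expect_equal(resN$p, 1)
  # empty hits
  resE <- hypergeometric_ora(character(), bg,
                             gene_set_collection(list(S = bg[1:5])))
  expect_equal(resE$p, 1)
  expect_error(hypergeometric_ora(c("Z9"), bg,
                                  gene_set_collection(list(S = bg[1:5]))),
               "subset")
})
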