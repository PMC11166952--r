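test_that("fisher_overlap builds the right table and matches the hypergeometric tail", {
  uni <- sprintf("g%02d", 1:10)
  res <- fisher_overlap(uni[1:3], uni[4:6], uni)
  expect_identical(res$a, 0L)
  expect_gte(res$p_value, 0.5)

  # identical five-gene sets in a universe of 100
  uni2 <- sprintf("g%03d", 1:100)
  res2 <- fisher_overlap(uni2[1:5], uni2[1:5], uni2)
  expect_equal(res2$p_value, hyper_tail_oracle(5, 5, 100, 5), tolerance = 1e-12)
  expect_equal(res2$p_value, 1 / choose(100, 5), tolerance = 1e-12)

  # universe exactly covered by A union B: d = 0 still defined
  res3 <- fisher_overlap(uni[1:6], uni[5:10], uni)
  expect_identical(res3$d, 0L)
  expect_true(is.finite(res3$p_value))

  expect_error(fisher_overlap(uni[1:3], uni[4:6], character(0)), "empty universe")
  expect_error(fisher_overlap(c(uni[1], "zzz"), uni[4:6], uni), "subset")
})

test_that("fisher_overlap equals brute-force enumeration on random small instances", {
  set.seed(71)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    uni <- sprintf("u%02d", seq_len(n))
    a <- sample(uni, sample(1:n, 1))
    b <- sample(uni, sample(1:n, 1))
    res <- fisher_overlap(a, b, uni)
    expect_equal(res$p_value,
                 hyper_tail_oracle(res$a, length(b), n, length(a)),
                 tolerance = 1e-10)
  }
})

test_that("bh_adjust applies the step-up rule and is permutation-equivariant", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(5)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) >= p) && all(bh_adjust(p) <= 1))
  # non-decreasing when the input is sorted
  expect_false(is.unsorted(bh_adjust(sort(p))))
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
})

test_that("ranking metrics follow their definitions", {
  expect_equal(rank_metric(2, 0.01, "signed_logp"), 2)
  expect_equal(rank_metric(2, 1, "signed_logp"), 0)
  expect_equal(rank_metric(-0.5, 1, "lfc_times_logp"), 0)
  expect_equal(rank_metric(-0.5, 0.01, "lfc_times_logp"), -1)
  expect_equal(rank_metric(NULL, NULL, "stat", stat = c(3, -1)), c(3, -1))
  expect_warning(out <- rank_metric(1, 0, "signed_logp"), "clamped")
  expect_true(is.finite(out) && out > 300)
})

test_that("ranked_gene_list orders by score with lexicographic tie-break", {
  out <- ranked_gene_list(c("b", "a", "c"), c(1, 1, 5))
  expect_identical(out$gene, c("c", "a", "b"))
  expect_error(ranked_gene_list(c("a", "a"), c(1, 2)), "unique")
})

test_that("a set at the top of the ranking gets a positive, significant ES", {
  genes <- sprintf("g%03d", 1:100)
  rnk <- ranked_gene_list(genes, seq(100, 1))
  out <- preranked_gsea(rnk, list(top = genes[1:5]), n_perm = 1000, seed = 1)
  expect_gt(out$ES, 0)
  expect_lt(out$p_value, 0.05)
  expect_identical(sign(out$NES), sign(out$ES))
  expect_gte(out$padj, out$p_value)
})

test_that("exact GSEA p equals full enumeration of all same-size subsets", {
  genes <- letters[1:8]
  scores <- c(4, 3, 2.5, 1, 0.5, -1, -2, -3)
  rnk <- ranked_gene_list(genes, scores)
  set <- c("a", "c", "f")
  out <- preranked_gsea(rnk, list(s = set), exact = TRUE, seed = 1)

  # oracle: all C(8,3) = 56 subset scores via an independent running sum
  combs <- combn(8, 3)
  es_all <- apply(combs, 2, function(idx) {
    in_set <- seq_len(8) %in% idx
    es_oracle(scores, in_set)
  })
  es_obs <- es_oracle(scores, genes %in% set)
  expect_equal(out$ES, es_obs, tolerance = 1e-12)
  p_exact <- if (es_obs >= 0) {
    sum(es_all >= es_obs) / sum(es_all >= 0)
  } else {
    sum(es_all <= es_obs) / sum(es_all < 0)
  }
  expect_equal(out$p_value, p_exact, tolerance = 1e-12)

  # sampled permutations converge to the enumeration value
  out_perm <- preranked_gsea(rnk, list(s = set), n_perm = 20000, seed = 2)
  expect_lt(abs(out_perm$p_value - p_exact), 0.02)
})

test_that("reversing the ranking negates every enrichment score", {
  set.seed(9)
  genes <- sprintf("g%02d", 1:30)
  scores <- sort(rnorm(30), decreasing = TRUE)
  rnk <- ranked_gene_list(genes, scores)
  rev_rnk <- ranked_gene_list(genes, -scores)
  for (i in 1:10) {
    set <- sample(genes, sample(3:8, 1))
    expect_equal(gsea_es(rev_rnk, set), -gsea_es(rnk, set), tolerance = 1e-12)
  }
})

test_that("random gene sets center their NES near zero", {
  set.seed(13)
  genes <- sprintf("g%03d", 1:120)
  rnk <- ranked_gene_list(genes, rnorm(120))
  sets <- lapply(1:30, function(i) sample(genes, 10))
  names(sets) <- sprintf("s%02d", 1:30)
  out <- preranked_gsea(rnk, sets, n_perm = 500, seed = 13)
  expect_lt(abs(mean(out$NES, na.rm = TRUE)), 0.35)
  expect_gt(min(out$p_value), 0.001)
})

test_that("gsea agrees with fgsea on direction and magnitude", {
  skip_if_not_installed("fgsea")
  set.seed(33)
  genes <- sprintf("g%03d", 1:150)
  stats <- sort(rnorm(150, sd = 2), decreasing = TRUE)
  names(stats) <- genes
  sets <- list(top = genes[3:20], mid = genes[70:95], bottom = genes[130:150])
  mine <- preranked_gsea(ranked_gene_list(genes, stats), sets,
                         n_perm = 2000, seed = 3)
  ref <- suppressWarnings(fgsea::fgsea(sets, stats, nPermSimple = 2000))
  ref <- ref[match(mine$pathway, ref$pathway), ]
  expect_equal(mine$ES, ref$ES, tolerance = 1e-6)
  expect_equal(sign(mine$NES), sign(ref$NES))
})

test_that("degenerate sets are dropped with a warning and n_perm is validated", {
  genes <- letters[1:10]
  rnk <- ranked_gene_list(genes, 10:1)
  expect_warning(out <- preranked_gsea(rnk, list(all = genes, ok = genes[1:3]),
                                       n_perm = 200, seed = 1),
                 "entire ranking")
  expect_identical(out$pathway, "ok")
  expect_warning(out2 <- preranked_gsea(rnk, list(gone = c("zz", "yy")),
                                        n_perm = 200, seed = 1),
                 "no ranked genes")
  expect_identical(nrow(out2), 0L)
  expect_error(preranked_gsea(rnk, list(ok = genes[1:3]), n_perm = 50),
               "n_perm")
})

test_that("pathway scores and their cross-study correlation behave", {
  expect_equal(pathway_score(0.01, -1.3), -2)
  expect_equal(pathway_score(1, 2.1), 0)
  expect_equal(pathway_score(0.001, 0.2), 3)
  expect_error(pathway_score(0, 1), "padj")

  a <- c(p1 = 1, p2 = 2, p3 = 3, p4 = 4)
  expect_equal(score_correlation(a, a)$pearson_r, 1)
  expect_equal(score_correlation(a, a)$slope, 1)
  doubled <- score_correlation(a, 2 * a)
  expect_equal(doubled$pearson_r, 1)
  expect_equal(doubled$slope, 2)
  expect_error(score_correlation(a[1:2], a[1:2]), "fewer than 3")

  # independent scores are usually weakly correlated
  set.seed(15)
  hits <- sum(replicate(100, {
    x <- rnorm(200); y <- rnorm(200)
    names(x) <- names(y) <- sprintf("p%03d", 1:200)
    abs(score_correlation(x, y)$pearson_r) < 0.2
  }))
  expect_gte(hits, 95)
})

test_that("ora matches enumeration and ranks perfect overlap first", {
  uni <- sprintf("g%02d", 1:20)
  query <- uni[1:5]
  sets <- list(same = query, disjoint = uni[10:13],
               partial = c(uni[1:3], uni[15]))
  out <- ora(query, sets, uni)
  expect_identical(out$set[1], "same")
  expect_equal(out$p_value[out$set == "partial"],
               hyper_tail_oracle(3, 4, 20, 5), tolerance = 1e-12)
  expect_gt(out$p_value[out$set == "disjoint"], 0.5)
  expect_error(ora(character(0), sets, uni), "empty query")
  expect_error(ora(c("nope"), sets, uni), "subset")
})

test_that("overlap percentage is the directional recovery fraction", {
  expect_equal(overlap_percentage(letters[1:4], letters), 100)
  expect_equal(overlap_percentage(letters[1:4], LETTERS), 0)
  expect_equal(overlap_percentage(sprintf("g%d", 1:10), sprintf("g%d", 8:20)), 30)
  expect_error(overlap_percentage(character(0), letters), "empty reference")
})
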