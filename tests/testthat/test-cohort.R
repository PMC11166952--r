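test_that("identical configs generate bit-identical cohorts", {
  cfg <- cohort_config(cell_types = c("CD14_Mono", "NK"), n_genes = 30,
                       n_microbes_per_rank = c("bacteria:species" = 15),
                       n_planted = 5, seed = 1)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- generate_cohort(cohort_config(cell_types = c("CD14_Mono", "NK"),
                                      n_genes = 30,
                                      n_microbes_per_rank = c("bacteria:species" = 15),
                                      n_planted = 5, seed = 2))
  expect_false(identical(a$expression$NK, c2$expression$NK))
})

test_that("n_planted = 0 yields an empty truth and planted ids always exist", {
  co0 <- generate_cohort(cohort_config(n_genes = 20, n_planted = 0,
                                       n_microbes_per_rank = c("bacteria:genus" = 10),
                                       cell_types = "B", planted_cell_type = "B",
                                       planted_rank = "bacteria:genus"))
  expect_identical(nrow(co0$truth$planted_pairs), 0L)

  co <- small_planted_cohort(seed = 7)
  tp <- co$truth$planted_pairs
  expect_true(all(tp$gene %in% rownames(co$expression$CD14_Mono)))
  expect_true(all(tp$microbe %in% rownames(co$microbes[["bacteria:species"]])))
  expect_true(all(tp$cell_type %in% names(co$expression)))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(n_crew = 1), "n_crew")
  expect_error(cohort_config(zero_inflation = 1), "zero_inflation")
  expect_error(cohort_config(n_genes = 10,
                             n_microbes_per_rank = c("bacteria:genus" = 3),
                             n_planted = 31), "n_planted")
  expect_error(cohort_config(n_microbes_per_rank = c(5)), "n_microbes_per_rank")
})

test_that("microbial counts are non-negative integers with the configured zero fraction", {
  co <- generate_cohort(cohort_config(cell_types = "B", n_genes = 10,
                                      n_microbes_per_rank = c("bacteria:species" = 200),
                                      n_planted = 0, zero_inflation = 0.3, seed = 5))
  m <- co$microbes[["bacteria:species"]]
  expect_true(all(m >= 0))
  expect_equal(m, round(m))
  # zero_inflation forces zeros on top of the occasional rounded-to-zero draw
  expect_gt(mean(m == 0), 0.28)
  expect_lt(mean(m == 0), 0.38)
})

test_that("non-planted gene expression matches the configured marginal moments", {
  crew_sd <- 0.5; noise_sd <- 1
  co <- generate_cohort(cohort_config(cell_types = "B", n_genes = 1500,
                                      n_microbes_per_rank = c("bacteria:genus" = 5),
                                      n_planted = 0, frac_extra_degs = 0,
                                      crew_sd = crew_sd, noise_sd = noise_sd,
                                      baseline_range = c(4, 8), seed = 9))
  e <- co$expression$B
  # centered per gene, the SD pools crew and residual variance
  sds <- apply(e, 1, sd)
  expect_equal(mean(sds), sqrt(crew_sd^2 + noise_sd^2), tolerance = 0.05)
  expect_equal(mean(rowMeans(e)), 6, tolerance = 0.1)
})

test_that("planted recovery is monotone in effect size", {
  power_at <- function(effect) {
    hits <- 0L; total <- 0L
    for (seed in 1:6) {
      co <- small_planted_cohort(seed, effect_size = effect, noise_sd = 1,
                                 cell_types = "CD14_Mono")
      degs <- list(CD14_Mono = rownames(co$expression$CD14_Mono))
      out <- run_two_stage(co, degs, seed = seed,
                           cfg = screen_config("fixed", fixed_lambda = 0.05,
                                               seed = seed))
      rec <- truth_recovery(co$truth, out$candidates, out$results)
      hits <- hits + rec$n_recovered[rec$quantity == "planted_pairs_nominal"]
      total <- total + rec$n_planted[1]
    }
    hits / total
  }
  expect_gte(power_at(1.0), power_at(0.25))
})

test_that("DEG table follows the fold-change and significance rules", {
  vals <- rbind(flat = rep(5, 12),
                doubled = rep(rep(c(2, 4), each = 3), 2), # pre = c, post = 2c
                noisy = rnorm(12, 10))
  colnames(vals) <- sprintf("crew%d_T%d", rep(1:2, each = 6), rep(1:6, 2))
  expr <- expression_matrix(vals, "B")
  tab <- generate_deg_table(expr)
  expect_equal(tab$log2FC[tab$gene == "flat"], 0)
  expect_false(tab$is_deg[tab$gene == "flat"])
  expect_equal(tab$log2FC[tab$gene == "doubled"], 1)
  expect_error(generate_deg_table(expr, design = rep(c("pre", "post"), c(1, 11))),
               "degenerate design")
})

test_that("DEG p-values are calibrated under the two-group null", {
  set.seed(31)
  vals <- matrix(rnorm(2000 * 12), nrow = 2000)
  colnames(vals) <- sprintf("crew%d_T%d", rep(1:2, each = 6), rep(1:6, 2))
  rownames(vals) <- sprintf("g%04d", 1:2000)
  tab <- generate_deg_table(expression_matrix(vals, "B"))
  expect_gt(mean(tab$p < 0.05), 0.04)
  expect_lt(mean(tab$p < 0.05), 0.06)
})

test_that("interactome generator plants DEG-enriched compounds reproducibly", {
  genes <- sprintf("g%03d", 1:200)
  degs <- genes[1:30]
  a <- generate_interactome(50, genes, density = 0.05, n_planted = 4,
                            deg_genes = degs, seed = 3)
  b <- generate_interactome(50, genes, density = 0.05, n_planted = 4,
                            deg_genes = degs, seed = 3)
  expect_identical(a, b)
  expect_length(a$interactome, 50)
  expect_length(a$planted_compounds, 4)
  for (cmp in a$planted_compounds) {
    frac_in <- mean(a$interactome[[cmp]] %in% degs)
    expect_gt(frac_in, 0.5)
  }
  expect_error(generate_interactome(10, genes, density = 1.2), "density")
})

test_that("pathway generator respects bounds and plants concordant sets", {
  genes <- sprintf("g%03d", 1:100)
  ranking <- ranked_gene_list(genes, rev(seq_along(genes)))
  pw <- generate_pathways(12, set_size = c(5, 15), genes = genes,
                          n_planted = 3, ranking = ranking, seed = 2)
  expect_length(pw$pathways, 12)
  for (id in pw$planted_pathways) {
    expect_gt(gsea_es(ranking, pw$pathways[[id]]), 0)
  }
  expect_identical(generate_pathways(0, genes = genes)$pathways,
                   structure(list(), names = character(0)))
  expect_error(generate_pathways(3, set_size = c(10, 300), genes = genes),
               "set_size")
})
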