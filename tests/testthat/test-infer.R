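test_that("the fast mixed-model path reproduces a stock lmer REML fit", {
  ctrl <- lme4::lmerControl(calc.derivs = FALSE, check.conv.singular = "ignore")
  set.seed(17)
  crew <- factor(rep(1:4, each = 6))
  for (i in 1:10) {
    x <- rnorm(24)
    y <- 0.4 * x + rep(rnorm(4, 0, 0.6), each = 6) + rnorm(24, 0, 0.8)
    fit <- suppressWarnings(fit_lmm(y, x, crew))
    m <- suppressMessages(lme4::lmer(y ~ x + (1 | crew), REML = TRUE, control = ctrl))
    cs <- coef(summary(m))
    vc <- as.data.frame(lme4::VarCorr(m))
    if (fit$method == "lmm") {
      expect_equal(fit$slope, cs["x", "Estimate"], tolerance = 1e-8)
      expect_equal(fit$slope_se, cs["x", "Std. Error"], tolerance = 1e-8)
      expect_equal(fit$crew_variance, vc$vcov[1], tolerance = 1e-6)
    } else {
      # fallback triggers exactly when the REML crew variance hits zero
      expect_lt(vc$vcov[1], 1e-8)
    }
  }
})

test_that("fit_lmm recovers a planted slope and flags its inputs", {
  set.seed(23)
  crew <- rep(1:4, each = 6)
  x <- rnorm(24)
  y <- 1.0 * x + rep(rnorm(4, 0, 0.5), each = 6) + rnorm(24, 0, 0.1)
  fit <- fit_lmm(y, x, crew)
  expect_lt(abs(fit$slope - 1.0), 3 * fit$slope_se)
  expect_lt(fit$p_value, 1e-6)
  expect_error(fit_lmm(y, rep(2, 24), crew), "degenerate predictor")
  expect_warning(fit_lmm(y, x, rep(1, 24)), "single crew group")
})

test_that("bonferroni_threshold is alpha over the family size", {
  sch <- bonferroni_scheme(0.05, c("bacteria:species" = 50), c(CD14_Mono = 200))
  expect_equal(bonferroni_threshold(sch, "CD14_Mono", "bacteria", "species"), 5e-6)
  sch2 <- bonferroni_scheme(0.2, c("virus:genus" = 1), c(NK = 1))
  expect_equal(bonferroni_threshold(sch2, "NK", "virus", "genus"), 0.2)
  sch3 <- bonferroni_scheme(0.05, c("bacteria:genus" = 10), c(B = 10))
  expect_equal(bonferroni_threshold(sch3, "B", "bacteria", "genus"), 5e-4)
  expect_error(bonferroni_threshold(sch, "CD14_Mono", "virus", "genus"),
               "configuration error")
})

test_that("classification sets nested flags at the three stringency levels", {
  sch <- bonferroni_scheme(0.05, c("bacteria:species" = 50), c(CD14_Mono = 200))
  res <- data.frame(cell_type = "CD14_Mono", gene = c("g1", "g2", "g3"),
                    microbe = "m1", domain = "bacteria", rank = "species",
                    transform = "log", coefficient = 1,
                    slope = c(2, 1, -1), slope_se = 1,
                    p_value = c(1e-7, 0.04, 0.06), crew_variance = 0,
                    method = "lmm", stringsAsFactors = FALSE)
  out <- classify_associations(res, sch)
  expect_identical(out$nominal, c(TRUE, TRUE, FALSE))
  expect_identical(out$bonf_020, c(TRUE, FALSE, FALSE))
  expect_identical(out$bonf_005, c(TRUE, FALSE, FALSE))
  expect_identical(out$slope_sign, c("+", "+", "-"))
  expect_true(all(out$p_bonferroni >= out$p_value))
  expect_true(all((!out$bonf_005 | out$bonf_020) & (!out$bonf_020 | out$nominal)))
})

test_that("flag nesting holds on a full simulated run", {
  co <- small_planted_cohort(seed = 12)
  degs <- cohort_deg_lists(co)
  out <- run_two_stage(co, degs, seed = 12)
  res <- out$results
  expect_true(all((!res$bonf_005 | res$bonf_020) & (!res$bonf_020 | res$nominal)))
  # every Bonferroni-significant association originates from a screen candidate
  key <- function(df) paste(df$cell_type, df$gene, df$microbe, df$transform)
  expect_true(all(key(res[res$bonf_005, ]) %in% key(out$candidates)))
})

test_that("tally counts positive Bonferroni-significant hits per cell type", {
  res <- data.frame(cell_type = c("A", "A", "A", "A", "A", "B"),
                    slope = c(1, 2, 3, -1, -2, 1),
                    bonf_005 = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  tally <- tally_positive_significant(res)
  expect_identical(tally[["A"]], 3L)
  expect_identical(tally[["B"]], 0L)
})

test_that("gene ranking orders by bonf_020 count then nominal count", {
  base <- data.frame(cell_type = "A", domain = "bacteria", rank = "species",
                     transform = "log", stringsAsFactors = FALSE)
  mk <- function(gene, n_bonf, n_nom) {
    n <- max(n_nom, 1)
    cbind(base[rep(1, n), , drop = FALSE],
          data.frame(gene = gene, microbe = sprintf("m%02d", seq_len(n)),
                     nominal = seq_len(n) <= n_nom,
                     bonf_020 = seq_len(n) <= n_bonf))
  }
  res <- rbind(mk("geneA", 2, 5), mk("geneB", 1, 9), mk("geneZ", 0, 0))
  out <- rank_genes(res)
  expect_identical(out$gene, c("geneA", "geneB"))
  # 12 qualifying genes truncate to ten, lexicographic tie-break
  many <- do.call(rbind, lapply(sprintf("g%02d", 12:1), function(g) mk(g, 0, 1)))
  out2 <- rank_genes(many)
  expect_identical(nrow(out2), 10L)
  expect_identical(out2$gene, sprintf("g%02d", 1:10))
})

test_that("randomized-data comparison bounds overlap and stays exchangeable under the null", {
  co <- small_planted_cohort(seed = 20, n_planted = 0, n_genes = 30,
                             n_microbes = 15, cell_types = "NK")
  degs <- list(NK = rownames(co$expression$NK))
  cmp <- suppressMessages(suppressWarnings(
    randomize_and_compare(co, degs, screen_config(seed = 20), seed = 20)))
  expect_identical(cmp$level, c("lasso", "nominal", "bonferroni"))
  expect_true(all(cmp$count_overlap <= pmin(cmp$count_real, cmp$count_randomized)))
  # under the global null, real and randomized candidate counts are comparable
  expect_lt(abs(cmp$count_real[1] - cmp$count_randomized[1]),
            0.6 * max(cmp$count_real[1], cmp$count_randomized[1], 10))
})

test_that("planted cohorts show real signal with near-zero null overlap", {
  co <- small_planted_cohort(seed = 21, n_crew = 6, n_planted = 8,
                             noise_sd = 0.4, cell_types = "CD14_Mono")
  degs <- cohort_deg_lists(co)
  cmp <- suppressMessages(suppressWarnings(
    randomize_and_compare(co, degs, screen_config(seed = 21), seed = 21)))
  bon <- cmp[cmp$level == "bonferroni", ]
  expect_gt(bon$count_real, 0)
  expect_lte(bon$count_overlap, 1)
})
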