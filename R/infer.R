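# Stage 2: per-candidate random-intercept mixed models, the family-wise
# Bonferroni scheme, stringency classification, randomized-data null
# comparison, per-cell-type tallies and gene ranking.
#
# The model is `gene ~ microbe + (1|crew)`, REML-fitted with lme4. Fits go
# through lme4's modular API (lFormula / mkLmerDevfun / optimizeLmer) with
# the slope, its standard error and the variance components read off the
# optimized deviance function; this is numerically identical to a stock
# lmer() fit (asserted in the test suite) and fast enough for the tens of
# thousands of per-pair fits the null-calibration experiments need.

lmm_control <- function() {
  lme4::lmerControl(calc.derivs = FALSE,
                    check.conv.singular = "ignore")
}

# Build the reusable lFormula skeleton for a crew grouping.
lmm_template <- function(crew) {
  crew <- factor(crew)
  df <- data.frame(y = stats::rnorm(length(crew)), x = stats::rnorm(length(crew)),
                   crew = crew)
  lme4::lFormula(y ~ x + (1 | crew), data = df, REML = TRUE,
                 control = lmm_control())
}

# REML fit of one (y, x) pair on a prepared template. Returns NULL on
# optimizer failure.
lmm_fit_pair <- function(pf, y, x) {
  pf$fr[[1L]] <- y
  pf$fr$x <- x
  pf$X[, 2L] <- x
  out <- tryCatch({
    devfun <- do.call(lme4::mkLmerDevfun, pf)
    opt <- lme4::optimizeLmer(devfun, control = lmm_control()$optCtrl)
    rho <- environment(devfun)
    pp <- rho$pp
    n <- length(y)
    p <- ncol(pf$X)
    beta <- pp$beta(1)
    sigma2 <- (rho$resp$wrss() + pp$sqrL(1)) / (n - p) # REML scale
    se <- sqrt(diag(chol2inv(pp$RX())) * sigma2)
    g <- nlevels(pf$fr$crew)
    list(slope = beta[2L], slope_se = se[2L],
         crew_variance = sigma2 * opt$par^2,
         df = max(1L, n - p - (g - 1L)),
         converged = is.null(opt$conv) || opt$conv == 0L)
  }, error = function(e) NULL)
  out
}

ols_fit_pair <- function(y, x) {
  fit <- stats::lm(y ~ x)
  cs <- stats::coef(summary(fit))
  list(slope = cs["x", "Estimate"], slope_se = cs["x", "Std. Error"],
       p_value = cs["x", "Pr(>|t|)"], crew_variance = 0,
       method = "ols", converged = TRUE)
}

#' Random-intercept mixed model for one gene-microbe pair
#'
#' Fits `y ~ x + (1|crew)` by REML and reports a two-sided Wald t p-value
#' for the fixed slope, with within-group residual degrees of freedom
#' `n - 2 - (g - 1)` (g = number of crew members). A normal reference is
#' badly anti-conservative in the far tail at these sample sizes, which
#' would defeat the Bonferroni control downstream. The caller supplies
#' already-transformed values (the gene centered and scaled, the microbe
#' log- or CLR-transformed), matching the screening stage. With only a
#' handful of crew members the REML
#' crew-variance estimate frequently hits the zero boundary; such fits (and
#' non-converged ones) fall back to ordinary least squares, flagged with
#' `method = "ols"`.
#'
#' @param y Numeric response (one gene across samples).
#' @param x Numeric predictor (one transformed microbial feature).
#' @param crew Factor (or coercible) of crew ids, one per sample.
#' @return List with slope, slope_se, p_value, crew_variance, method
#'   ("lmm" or "ols") and converged.
#' @export
fit_lmm <- function(y, x, crew) {
  if (length(y) != length(x) || length(y) != length(crew)) {
    stop("y, x and crew must have the same length")
  }
  if (stats::sd(x) == 0) {
    stop("degenerate predictor: microbe abundances are constant")
  }
  crew <- factor(crew)
  if (nlevels(crew) < 2L) {
    warning("single crew group: falling back to ordinary least squares")
    return(ols_fit_pair(y, x))
  }
  fit <- lmm_fit_pair(lmm_template(crew), y, x)
  finish_lmm_fit(fit, y, x)
}

finish_lmm_fit <- function(fit, y, x) {
  if (is.null(fit) || !fit$converged || fit$crew_variance == 0) {
    return(ols_fit_pair(y, x))
  }
  tstat <- fit$slope / fit$slope_se
  list(slope = fit$slope, slope_se = fit$slope_se,
       p_value = 2 * stats::pt(-abs(tstat), df = fit$df),
       crew_variance = fit$crew_variance, method = "lmm", converged = TRUE)
}

#' Mixed-model inference for every candidate association
#'
#' Applies [fit_lmm()] to each screened (gene, microbe) pair, using the same
#' transforms as the screening stage (gene centered/scaled; microbe log or
#' CLR as recorded in the candidate's `transform` field).
#'
#' @param candidates Candidate data.frame from [run_screen_all()].
#' @param cohort The cohort the candidates came from.
#' @param scheme Optional [bonferroni_scheme()]; when given, results are
#'   classified (see [classify_associations()]) before being returned.
#' @return data.frame with the candidate columns plus slope, slope_se,
#'   p_value, crew_variance and method.
#' @export
infer_associations <- function(candidates, cohort, scheme = NULL) {
  cols <- c("cell_type", "gene", "microbe", "domain", "rank", "transform")
  if (!all(cols %in% names(candidates))) {
    stop("candidates must carry columns: ", paste(cols, collapse = ", "))
  }
  if (nrow(candidates) == 0L) {
    out <- candidates
    out$slope <- out$slope_se <- out$p_value <- out$crew_variance <- numeric(0)
    out$method <- character(0)
    return(out)
  }
  key <- interaction(candidates$cell_type, candidates$domain, candidates$rank,
                     candidates$transform, drop = TRUE)
  pieces <- lapply(split(candidates, key), function(grp) {
    ct <- grp$cell_type[1L]
    dr <- paste(grp$domain[1L], grp$rank[1L], sep = ":")
    expr <- cohort$expression[[ct]]
    tm <- transform_microbes(cohort$microbes[[dr]], grp$transform[1L])
    tm <- tm[, colnames(expr), drop = FALSE]
    crew <- factor(parse_sample_ids(colnames(expr))$crew)
    pf <- lmm_template(crew)
    res <- vector("list", nrow(grp))
    for (i in seq_len(nrow(grp))) {
      x <- tm[grp$microbe[i], ]
      if (stats::sd(x) == 0) {
        warning(sprintf("infer: skipping constant predictor '%s'", grp$microbe[i]))
        next
      }
      y <- center_scale(expr[grp$gene[i], ])
      fit <- finish_lmm_fit(lmm_fit_pair(pf, y, x), y, x)
      res[[i]] <- cbind(grp[i, , drop = FALSE],
                        data.frame(slope = fit$slope, slope_se = fit$slope_se,
                                   p_value = fit$p_value,
                                   crew_variance = fit$crew_variance,
                                   method = fit$method,
                                   stringsAsFactors = FALSE))
    }
    do.call(rbind, res[!vapply(res, is.null, logical(1))])
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (!is.null(scheme)) out <- classify_associations(out, scheme)
  out
}

#' Family-wise Bonferroni scheme
#'
#' The family of one test is the number of microbial features in its
#' (domain, rank) matrix times the number of DEGs of its cell type; the
#' significance threshold for level `alpha` is `alpha / family size`.
#'
#' @param alpha Family-wise error level in (0, 1).
#' @param n_microbes Named numeric vector, names `"<domain>:<rank>"`.
#' @param n_degs Named numeric vector, names = cell types.
#' @return List of class `bonferroni_scheme`.
#' @export
bonferroni_scheme <- function(alpha = 0.05, n_microbes, n_degs) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("configuration error: alpha must lie in (0, 1)")
  }
  if (is.null(names(n_microbes)) || any(n_microbes < 1)) {
    stop("configuration error: n_microbes must be a named vector of positive counts")
  }
  if (is.null(names(n_degs)) || any(n_degs < 1)) {
    stop("configuration error: n_degs must be a named vector of positive counts")
  }
  structure(list(alpha = alpha, n_microbes = n_microbes, n_degs = n_degs),
            class = "bonferroni_scheme")
}

#' Derive the Bonferroni scheme implied by a cohort and its DEG lists
#'
#' @param cohort A `cohort`.
#' @param deg_lists Named list of DEG ids per cell type.
#' @param alpha Family-wise error level.
#' @return A [bonferroni_scheme()] covering the non-empty cell types.
#' @export
scheme_from_cohort <- function(cohort, deg_lists, alpha = 0.05) {
  nm <- vapply(cohort$microbes, nrow, integer(1))
  nd <- vapply(deg_lists, length, integer(1))
  nd <- nd[nd > 0]
  bonferroni_scheme(alpha = alpha, n_microbes = nm, n_degs = nd)
}

#' Bonferroni-corrected significance threshold for one family
#'
#' @param scheme A [bonferroni_scheme()].
#' @param cell_type,domain,rank Keys identifying the family.
#' @return `alpha / (n_microbes[domain:rank] * n_degs[cell_type])`.
#' @export
bonferroni_threshold <- function(scheme, cell_type, domain, rank) {
  dr <- paste(domain, rank, sep = ":")
  if (!dr %in% names(scheme$n_microbes)) {
    stop(sprintf("configuration error: no microbe count for family '%s'", dr))
  }
  if (!cell_type %in% names(scheme$n_degs)) {
    stop(sprintf("configuration error: no DEG count for cell type '%s'", cell_type))
  }
  scheme$alpha / (scheme$n_microbes[[dr]] * scheme$n_degs[[cell_type]])
}

#' Classify associations at the three stringency levels
#'
#' Adds the nested significance flags: `nominal` (p < 0.05), `bonf_020`
#' (p below 0.2 / family size) and `bonf_005` (p below 0.05 / family size),
#' plus the Bonferroni-adjusted p-value and the slope sign.
#'
#' @param results Output of [infer_associations()].
#' @param scheme A [bonferroni_scheme()].
#' @return `results` with columns p_bonferroni, nominal, bonf_020,
#'   bonf_005, slope_sign added.
#' @export
classify_associations <- function(results, scheme) {
  if (nrow(results) == 0L) {
    results$p_bonferroni <- numeric(0)
    results$nominal <- results$bonf_020 <- results$bonf_005 <- logical(0)
    results$slope_sign <- character(0)
    return(results)
  }
  dr <- paste(results$domain, results$rank, sep = ":")
  bad_dr <- setdiff(dr, names(scheme$n_microbes))
  if (length(bad_dr)) {
    stop(sprintf("configuration error: no microbe count for family '%s'", bad_dr[1]))
  }
  bad_ct <- setdiff(results$cell_type, names(scheme$n_degs))
  if (length(bad_ct)) {
    stop(sprintf("configuration error: no DEG count for cell type '%s'", bad_ct[1]))
  }
  fam <- scheme$n_microbes[dr] * scheme$n_degs[results$cell_type]
  results$p_bonferroni <- pmin(1, results$p_value * fam)
  results$nominal <- results$p_value < 0.05
  results$bonf_020 <- results$p_value < 0.2 / fam
  results$bonf_005 <- results$p_value < 0.05 / fam
  results$slope_sign <- ifelse(results$slope > 0, "+",
                               ifelse(results$slope < 0, "-", "0"))
  results
}

#' Count positive Bonferroni-significant associations per cell type
#'
#' @param results Classified association results.
#' @return Named integer vector: per cell type, the number of associations
#'   with the `bonf_005` flag and a positive slope.
#' @export
tally_positive_significant <- function(results) {
  cts <- unique(results$cell_type)
  hit <- results$bonf_005 & results$slope > 0
  out <- vapply(cts, function(ct) sum(hit & results$cell_type == ct), integer(1))
  names(out) <- cts
  out
}

#' Rank genes by their number of significant microbial associations
#'
#' Per cell type, genes are sorted first by the number of `bonf_020`
#' findings, then by the number of nominally significant (p < 0.05)
#' microbial features, with lexicographic gene id as the deterministic
#' tie-break; genes with no nominal association are dropped and at most
#' `top_n` genes are reported.
#'
#' @param results Classified association results.
#' @param top_n Maximum genes reported per cell type (default 10).
#' @return data.frame with cell_type, gene, n_bonf020, n_nominal, rank.
#' @export
rank_genes <- function(results, top_n = 10) {
  empty <- data.frame(cell_type = character(0), gene = character(0),
                      n_bonf020 = integer(0), n_nominal = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE)
  if (nrow(results) == 0L) return(empty)
  agg <- stats::aggregate(cbind(n_bonf020 = results$bonf_020,
                                n_nominal = results$nominal),
                          by = list(cell_type = results$cell_type,
                                    gene = results$gene),
                          FUN = sum)
  agg <- agg[agg$n_nominal > 0, , drop = FALSE]
  if (nrow(agg) == 0L) return(empty)
  pieces <- lapply(split(agg, agg$cell_type), function(grp) {
    grp <- grp[order(-grp$n_bonf020, -grp$n_nominal, grp$gene), , drop = FALSE]
    grp <- utils::head(grp, top_n)
    grp$rank <- seq_len(nrow(grp))
    grp
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Randomize a cohort to build an empirical null
#'
#' The default scheme permutes the sample-column order of each cell type's
#' expression matrix (keeping the sample labels in place), which breaks the
#' gene-microbe pairing while preserving both marginal distributions. The
#' alternative shuffles each gene's values independently.
#'
#' @param cohort A `cohort`.
#' @param seed Integer seed.
#' @param scheme `"shuffle_samples"` (default) or `"shuffle_genes"`.
#' @return A cohort with randomized expression matrices.
#' @export
randomize_cohort <- function(cohort, seed = 1,
                             scheme = c("shuffle_samples", "shuffle_genes")) {
  scheme <- match.arg(scheme)
  withr::with_seed(as.integer(seed), {
    for (ct in names(cohort$expression)) {
      e <- cohort$expression[[ct]]
      ids <- colnames(e)
      if (scheme == "shuffle_samples") {
        e <- e[, sample(ncol(e)), drop = FALSE]
        colnames(e) <- ids
      } else {
        for (i in seq_len(nrow(e))) e[i, ] <- e[i, sample(ncol(e))]
      }
      attr(e, "cell_type") <- ct
      cohort$expression[[ct]] <- e
    }
    cohort
  })
}

#' Compare real associations against a randomized-data null
#'
#' Runs the full screen + inference pipeline on the cohort and on
#' randomized copies, and reports the number of associations and their
#' overlap (by pair identity) at the three stringency levels: non-zero
#' LASSO coefficient, nominal p < 0.05, and Bonferroni (0.05) significance.
#' With several randomizations the randomized counts and overlaps are
#' averaged.
#'
#' @param cohort A `cohort`.
#' @param deg_lists Named list of DEG ids per cell type.
#' @param cfg A [screen_config()].
#' @param transforms Transform(s) to screen with (default `"log"`).
#' @param alpha Bonferroni level (default 0.05).
#' @param n_randomizations Number of randomized copies.
#' @param seed Integer seed for the randomizations.
#' @param scheme Randomization scheme, see [randomize_cohort()].
#' @return data.frame with columns level, count_real, count_randomized,
#'   count_overlap.
#' @export
randomize_and_compare <- function(cohort, deg_lists, cfg = screen_config(),
                                  transforms = "log", alpha = 0.05,
                                  n_randomizations = 1, seed = 1,
                                  scheme = c("shuffle_samples", "shuffle_genes")) {
  scheme <- match.arg(scheme)
  bonf <- scheme_from_cohort(cohort, deg_lists, alpha)
  keys_at_levels <- function(ch) {
    cands <- run_screen_all(ch, deg_lists, cfg, transforms)
    res <- infer_associations(cands, ch, scheme = bonf)
    pair_key <- function(df) {
      if (nrow(df) == 0L) return(character(0))
      paste(df$cell_type, df$gene, df$microbe, df$domain, df$rank,
            df$transform, sep = "|")
    }
    list(lasso = pair_key(cands),
         nominal = pair_key(res[res$nominal, , drop = FALSE]),
         bonferroni = pair_key(res[res$bonf_005, , drop = FALSE]))
  }
  real <- keys_at_levels(cohort)
  rand_counts <- matrix(0, nrow = n_randomizations, ncol = 3,
                        dimnames = list(NULL, names(real)))
  over_counts <- rand_counts
  for (r in seq_len(n_randomizations)) {
    rnd <- keys_at_levels(randomize_cohort(cohort, seed = seed + r - 1,
                                           scheme = scheme))
    for (lv in names(real)) {
      rand_counts[r, lv] <- length(rnd[[lv]])
      over_counts[r, lv] <- length(intersect(real[[lv]], rnd[[lv]]))
    }
  }
  data.frame(level = names(real),
             count_real = vapply(real, length, integer(1)),
             count_randomized = colMeans(rand_counts),
             count_overlap = colMeans(over_counts),
             row.names = NULL, stringsAsFactors = FALSE)
}
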