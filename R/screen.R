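# Stage 1: LASSO screen. One L1-penalized model per (gene, microbial
# matrix): the centered/scaled gene is regressed on all features of a
# (domain, rank) abundance matrix; every non-zero coefficient is a
# candidate association passed to the mixed-model stage. p >> n is the
# expected regime (tens of samples, up to hundreds of features).

#' Configuration of the LASSO screening stage
#'
#' @param lambda_strategy How the penalty is chosen: `"cv_min"` (k-fold CV,
#'   minimum mean squared error; the default, maximizing screen
#'   sensitivity), `"cv_1se"` (one-standard-error rule) or `"fixed"`.
#' @param n_folds Folds for cross-validation (>= 2).
#' @param fixed_lambda Penalty used when `lambda_strategy = "fixed"`.
#' @param seed Integer seed controlling the CV fold assignment.
#' @return Validated list of class `screen_config`.
#' @export
screen_config <- function(lambda_strategy = c("cv_min", "cv_1se", "fixed"),
                          n_folds = 5, fixed_lambda = NULL, seed = 1) {
  lambda_strategy <- match.arg(lambda_strategy)
  if (lambda_strategy != "fixed" && (!is.numeric(n_folds) || n_folds < 2)) {
    stop("invalid screen configuration: field 'n_folds' must be >= 2")
  }
  if (lambda_strategy == "fixed" &&
      (is.null(fixed_lambda) || !is.numeric(fixed_lambda) || fixed_lambda < 0)) {
    stop("invalid screen configuration: field 'fixed_lambda' must be a non-negative number")
  }
  structure(list(lambda_strategy = lambda_strategy, n_folds = n_folds,
                 fixed_lambda = fixed_lambda, seed = seed),
            class = "screen_config")
}

# k-fold cross-validation over the glmnet lambda path (grouped-fold MSE,
# as in cv.glmnet with grouped=TRUE). A lean loop is used instead of
# cv.glmnet because the null-calibration experiments run tens of thousands
# of per-gene fits; lambdas whose path a fold truncates are dropped.
cv_lasso <- function(x, y, foldid) {
  full <- glmnet::glmnet(x, y, alpha = 1)
  lam <- full$lambda
  n_folds <- max(foldid)
  mse <- matrix(NA_real_, n_folds, length(lam))
  for (k in seq_len(n_folds)) {
    tr <- foldid != k
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], alpha = 1, lambda = lam)
    pred <- stats::predict(fit, x[!tr, , drop = FALSE])
    m <- colMeans((y[!tr] - pred)^2)
    mse[k, seq_along(m)] <- m
  }
  cvm <- colMeans(mse)
  cvsd <- apply(mse, 2L, stats::sd) / sqrt(n_folds)
  ok <- which(!is.na(cvm))
  i_min <- ok[which.min(cvm[ok])]
  i_1se <- ok[which(cvm[ok] <= cvm[i_min] + cvsd[i_min])[1L]]
  list(fit = full, lambda = lam, cvm = cvm, cvsd = cvsd,
       lambda_min = lam[i_min], lambda_1se = lam[i_1se])
}

#' LASSO screen of DEGs against one transformed microbial matrix
#'
#' Fits, for each DEG, `z(gene) ~ microbe_1 + ... + microbe_p` with an L1
#' penalty (glmnet), where `z()` centers and scales the gene and the
#' microbial predictors are already log- or CLR-transformed (see
#' [transform_microbes()]). Non-zero coefficients at the selected penalty
#' are returned as candidate associations. Deterministic under a fixed
#' seed: the CV fold assignment is drawn once from `cfg$seed`.
#'
#' @param expr Expression matrix (genes x samples) with `cell_type` attribute.
#' @param microbes Transformed microbial matrix (features x samples) with
#'   `domain`, `rank` and `transform` attributes.
#' @param degs Character vector of gene ids to screen (subset of
#'   `rownames(expr)`).
#' @param cfg A [screen_config()].
#' @return data.frame with columns cell_type, gene, microbe, domain, rank,
#'   transform, coefficient (all coefficients non-zero, standardized scale).
#' @export
lasso_screen <- function(expr, microbes, degs, cfg = screen_config()) {
  if (!setequal(colnames(expr), colnames(microbes))) {
    stop("alignment error: sample ids of expression and microbe matrices differ")
  }
  ct <- attr(expr, "cell_type")
  domain <- attr(microbes, "domain")
  rank <- attr(microbes, "rank")
  transform <- attr(microbes, "transform")
  microbes <- microbes[, colnames(expr), drop = FALSE]
  missing <- setdiff(degs, rownames(expr))
  if (length(missing)) {
    stop("DEG ids absent from the expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  x <- t(microbes)
  keep <- apply(x, 2L, function(col) stats::sd(col) > 0)
  if (any(!keep)) {
    message(sprintf("screen: dropping %d zero-variance microbial feature(s)",
                    sum(!keep)))
  }
  x <- x[, keep, drop = FALSE]
  empty <- data.frame(cell_type = character(0), gene = character(0),
                      microbe = character(0), domain = character(0),
                      rank = character(0), transform = character(0),
                      coefficient = numeric(0), stringsAsFactors = FALSE)
  if (ncol(x) == 0L || length(degs) == 0L) return(empty)

  n <- nrow(x)
  foldid <- NULL
  if (cfg$lambda_strategy != "fixed") {
    n_folds <- min(cfg$n_folds, n)
    foldid <- withr::with_seed(as.integer(cfg$seed),
                               sample(rep_len(seq_len(n_folds), n)))
  }

  rows <- vector("list", length(degs))
  for (i in seq_along(degs)) {
    g <- degs[i]
    y <- expr[g, ]
    if (stats::sd(y) == 0) {
      warning(sprintf("screen: skipping constant gene '%s'", g))
      next
    }
    y <- center_scale(y)
    cf <- if (cfg$lambda_strategy == "fixed") {
      fit <- glmnet::glmnet(x, y, alpha = 1)
      stats::coef(fit, s = cfg$fixed_lambda, exact = TRUE, x = x, y = y)
    } else {
      cv <- cv_lasso(x, y, foldid)
      s <- if (cfg$lambda_strategy == "cv_min") cv$lambda_min else cv$lambda_1se
      stats::coef(cv$fit, s = s)
    }
    cf <- as.matrix(cf)[-1L, 1L] # drop intercept
    nz <- which(cf != 0)
    if (length(nz)) {
      rows[[i]] <- data.frame(cell_type = ct,
                              gene = g, microbe = names(cf)[nz],
                              domain = domain, rank = rank,
                              transform = transform,
                              coefficient = unname(cf[nz]),
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))], list(empty)))
  rownames(out) <- NULL
  out
}

#' Run the LASSO screen over every cell type, microbial family and transform
#'
#' Bacteria and viruses (and each taxonomic rank) are fit as separate
#' models; log- and CLR-transformed candidate sets are kept in parallel,
#' tagged by the `transform` column. Per-model errors are collected as
#' warnings rather than aborting the sweep.
#'
#' @param cohort A `cohort` (or any list with `expression` and `microbes`).
#' @param deg_lists Named list (by cell type) of DEG id vectors; cell types
#'   with empty lists are skipped.
#' @param cfg A [screen_config()].
#' @param transforms Subset of `c("log", "clr")`.
#' @return Combined candidate data.frame (see [lasso_screen()]).
#' @export
run_screen_all <- function(cohort, deg_lists, cfg = screen_config(),
                           transforms = c("log", "clr")) {
  transforms <- match.arg(transforms, several.ok = TRUE)
  out <- list()
  n_models <- 0L
  for (ct in names(deg_lists)) {
    degs <- deg_lists[[ct]]
    if (!length(degs)) next
    expr <- cohort$expression[[ct]]
    if (is.null(expr)) {
      warning(sprintf("screen: no expression matrix for cell type '%s'", ct))
      next
    }
    for (dr in names(cohort$microbes)) {
      for (tf in transforms) {
        n_models <- n_models + 1L
        res <- tryCatch(
          lasso_screen(expr, transform_microbes(cohort$microbes[[dr]], tf),
                       degs, cfg),
          error = function(e) {
            warning(sprintf("screen failed for (%s, %s, %s): %s",
                            ct, dr, tf, conditionMessage(e)))
            NULL
          })
        if (!is.null(res)) out[[length(out) + 1L]] <- res
      }
    }
  }
  message(sprintf("screen: executed %d model famil%s", n_models,
                  if (n_models == 1L) "y" else "ies"))
  if (!length(out)) {
    return(data.frame(cell_type = character(0), gene = character(0),
                      microbe = character(0), domain = character(0),
                      rank = character(0), transform = character(0),
                      coefficient = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
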