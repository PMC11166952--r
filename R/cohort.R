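# Synthetic cohort generator. Emulates the data model the association
# pipeline assumes: per-cell-type pseudo-bulk expression over crew x
# timepoint samples with crew-level random intercepts, zero-inflated
# compositional microbial counts per (domain, rank), and planted
# gene-microbe effects injected on the log-abundance scale.

#' Construct an expression matrix with cohort metadata
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Column
#'   names must follow the `crew<k>_T<j>` convention.
#' @param cell_type Label of the annotated cell type this pseudo-bulk
#'   profile belongs to.
#' @return The matrix with `cell_type` attribute set.
#' @export
expression_matrix <- function(values, cell_type) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("gene ids (rownames) must be present and unique")
  }
  parse_sample_ids(colnames(values)) # validates the id convention
  attr(values, "cell_type") <- cell_type
  values
}

#' Construct a microbial abundance matrix with taxonomic metadata
#'
#' @param values Non-negative numeric matrix, features in rows, samples in
#'   columns (sample ids `crew<k>_T<j>`).
#' @param domain `"bacteria"` or `"virus"`.
#' @param rank Taxonomic rank label, e.g. `"species"`.
#' @return The matrix with `domain` and `rank` attributes set.
#' @export
microbe_matrix <- function(values, domain, rank) {
  values <- as_abundance_matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("microbial feature ids (rownames) must be present and unique")
  }
  parse_sample_ids(colnames(values))
  attr(values, "domain") <- domain
  attr(values, "rank") <- rank
  values
}

#' Configuration of a synthetic crew cohort
#'
#' Defaults mirror the cohort structure of a four-person orbital mission
#' sampled at three pre-flight and three post-flight timepoints, with nine
#' annotated immune cell types and five microbial (domain, rank) families.
#'
#' @param n_crew Number of crew members (>= 2).
#' @param n_timepoints Number of timepoints per crew member (>= 2); the
#'   first half is labelled pre-flight, the second half post-flight.
#' @param cell_types Character vector of cell-type labels.
#' @param n_genes Genes per cell-type expression matrix.
#' @param n_microbes_per_rank Named integer vector, names formatted
#'   `"<domain>:<rank>"`, giving the feature count of each abundance matrix.
#' @param n_planted Number of true gene-microbe pairs to plant.
#' @param effect_size Planted slope, in expression-SD units per SD of the
#'   log-transformed microbial predictor.
#' @param crew_sd SD of the Gaussian crew-level random intercepts.
#' @param noise_sd Residual SD of expression noise.
#' @param zero_inflation Fraction of microbial counts forced to zero, in [0, 1).
#' @param deg_log2fc Pre/post log2 fold change given to planted genes (and a
#'   fraction of extra genes) so they qualify as DEGs.
#' @param frac_extra_degs Fraction of non-planted genes that also receive the
#'   pre/post shift, so DEG tables have realistic size.
#' @param planted_cell_type Cell type carrying the planted pairs.
#' @param planted_rank `"<domain>:<rank>"` family the planted microbes come from.
#' @param planted_sign `"positive"` (all planted slopes +) or `"mixed"`.
#' @param baseline_range Range of per-gene baseline expression (uniform draw).
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_crew = 4,
                          n_timepoints = 6,
                          cell_types = c("PBMC", "CD4_T", "CD8_T", "other_T",
                                         "B", "NK", "CD14_Mono", "CD16_Mono",
                                         "DC"),
                          n_genes = 200,
                          n_microbes_per_rank = c("bacteria:phylum" = 20,
                                                  "bacteria:genus" = 60,
                                                  "bacteria:species" = 100,
                                                  "virus:phylum" = 8,
                                                  "virus:genus" = 30),
                          n_planted = 20,
                          effect_size = 1.0,
                          crew_sd = 0.5,
                          noise_sd = 1.0,
                          zero_inflation = 0.3,
                          deg_log2fc = 0.5,
                          frac_extra_degs = 0.15,
                          planted_cell_type = "CD14_Mono",
                          planted_rank = "bacteria:species",
                          planted_sign = c("positive", "mixed"),
                          baseline_range = c(4, 8),
                          seed = 1) {
  planted_sign <- match.arg(planted_sign)
  cfg <- list(n_crew = n_crew, n_timepoints = n_timepoints,
              cell_types = cell_types, n_genes = n_genes,
              n_microbes_per_rank = n_microbes_per_rank,
              n_planted = n_planted, effect_size = effect_size,
              crew_sd = crew_sd, noise_sd = noise_sd,
              zero_inflation = zero_inflation, deg_log2fc = deg_log2fc,
              frac_extra_degs = frac_extra_degs,
              planted_cell_type = planted_cell_type,
              planted_rank = planted_rank, planted_sign = planted_sign,
              baseline_range = baseline_range, seed = seed)

  bad <- function(field, why) {
    stop(sprintf("invalid cohort configuration: field '%s' %s", field, why))
  }
  if (!is.numeric(n_crew) || n_crew < 2) bad("n_crew", "must be >= 2")
  if (!is.numeric(n_timepoints) || n_timepoints < 2) bad("n_timepoints", "must be >= 2")
  if (length(cell_types) < 1 || anyDuplicated(cell_types)) {
    bad("cell_types", "must be a non-empty set of unique labels")
  }
  if (!is.numeric(n_genes) || n_genes < 1) bad("n_genes", "must be a positive count")
  if (length(n_microbes_per_rank) < 1 || any(n_microbes_per_rank < 1)) {
    bad("n_microbes_per_rank", "must contain positive counts")
  }
  if (is.null(names(n_microbes_per_rank)) ||
      !all(grepl("^(bacteria|virus):[a-z]+$", names(n_microbes_per_rank)))) {
    bad("n_microbes_per_rank", "names must be formatted '<domain>:<rank>'")
  }
  if (!is.numeric(n_planted) || n_planted < 0) bad("n_planted", "must be >= 0")
  if (n_planted > n_genes * min(n_microbes_per_rank)) {
    bad("n_planted", "exceeds n_genes x smallest microbe family")
  }
  if (zero_inflation < 0 || zero_inflation >= 1) {
    bad("zero_inflation", "must lie in [0, 1)")
  }
  if (crew_sd < 0) bad("crew_sd", "must be >= 0")
  if (noise_sd <= 0) bad("noise_sd", "must be > 0")
  if (n_planted > 0 && !planted_cell_type %in% cell_types) {
    bad("planted_cell_type", "is not one of cell_types")
  }
  if (n_planted > 0 && !planted_rank %in% names(n_microbes_per_rank)) {
    bad("planted_rank", "is not a key of n_microbes_per_rank")
  }
  if (!is.numeric(seed) || length(seed) != 1) bad("seed", "must be a single integer")
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic cohort with planted gene-microbe effects
#'
#' Expression for a planted (gene, microbe) pair follows
#' `baseline + crew intercept + effect_size * sign * z(log(microbe + pc)) + noise`,
#' where `z()` centers and scales and `pc` is the matrix pseudocount, i.e.
#' the effect is injected on the same transformed scale the association
#' stages fit on. Non-planted genes are baseline + crew intercept + noise.
#' Microbial counts are zero-inflated rounded log-normal draws.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort` with elements `expression` (named list
#'   of per-cell-type matrices), `microbes` (named list of per-(domain,
#'   rank) abundance matrices), `truth` (planted pairs and, initially empty,
#'   planted compound/pathway slots) and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  withr::with_seed(as.integer(config$seed), generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n_samp <- cfg$n_crew * cfg$n_timepoints
  crew <- rep(seq_len(cfg$n_crew), each = cfg$n_timepoints)
  tp <- rep(seq_len(cfg$n_timepoints), times = cfg$n_crew)
  sample_ids <- sprintf("crew%d_T%d", crew, tp)
  post <- tp > cfg$n_timepoints / 2
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))

  microbes <- list()
  for (dr in names(cfg$n_microbes_per_rank)) {
    k <- cfg$n_microbes_per_rank[[dr]]
    parts <- strsplit(dr, ":", fixed = TRUE)[[1]]
    mu <- stats::runif(k, log(10), log(1e4))
    vals <- round(exp(matrix(stats::rnorm(k * n_samp, mean = rep(mu, n_samp), sd = 1),
                             nrow = k)))
    if (cfg$zero_inflation > 0) {
      vals[matrix(stats::runif(k * n_samp) < cfg$zero_inflation, k, n_samp)] <- 0
    }
    rownames(vals) <- sprintf("%s_%s_%03d", parts[1], parts[2], seq_len(k))
    colnames(vals) <- sample_ids
    microbes[[dr]] <- microbe_matrix(vals, domain = parts[1], rank = parts[2])
  }

  # Planted pairs: distinct genes, microbes drawn (without replacement where
  # possible) from features of the planted family that actually vary.
  planted <- data.frame(cell_type = character(0), gene = character(0),
                        microbe = character(0), domain = character(0),
                        rank = character(0), sign = numeric(0))
  if (cfg$n_planted > 0) {
    pm <- microbes[[cfg$planted_rank]]
    varying <- rownames(pm)[apply(pm, 1L, function(x) length(unique(x)) > 1L)]
    if (length(varying) == 0L) stop("planted microbe family has no varying feature")
    pg <- sample(genes, min(cfg$n_planted, cfg$n_genes))
    pmic <- sample(varying, cfg$n_planted, replace = cfg$n_planted > length(varying))
    if (length(pg) < cfg$n_planted) {
      pg <- c(pg, sample(genes, cfg$n_planted - length(pg), replace = TRUE))
    }
    parts <- strsplit(cfg$planted_rank, ":", fixed = TRUE)[[1]]
    sgn <- if (cfg$planted_sign == "positive") rep(1, cfg$n_planted) else
      sample(c(-1, 1), cfg$n_planted, replace = TRUE)
    planted <- data.frame(cell_type = cfg$planted_cell_type, gene = pg,
                          microbe = pmic, domain = parts[1], rank = parts[2],
                          sign = sgn, stringsAsFactors = FALSE)
  }

  # Predictors on the transformed scale, standardized, for effect injection.
  planted_pred <- NULL
  if (nrow(planted) > 0) {
    tm <- transform_microbes(microbes[[cfg$planted_rank]], "log")
    planted_pred <- lapply(planted$microbe, function(f) center_scale(tm[f, ]))
  }

  extra_pool <- setdiff(genes, planted$gene)

  expression <- list()
  for (ct in cfg$cell_types) {
    # planted genes respond in every cell type (a conserved flight shift);
    # the extra DEGs are cell-type-specific, so DEG sets overlap partially
    shifted <- planted$gene
    if (cfg$frac_extra_degs > 0) {
      shifted <- union(shifted,
                       sample(extra_pool,
                              round(cfg$frac_extra_degs * length(extra_pool))))
    }
    baseline <- stats::runif(cfg$n_genes, cfg$baseline_range[1], cfg$baseline_range[2])
    intercepts <- matrix(stats::rnorm(cfg$n_genes * cfg$n_crew, 0, cfg$crew_sd),
                         nrow = cfg$n_genes)
    e <- baseline +
      intercepts[, crew, drop = FALSE] +
      matrix(stats::rnorm(cfg$n_genes * n_samp, 0, cfg$noise_sd), nrow = cfg$n_genes)
    rownames(e) <- genes
    colnames(e) <- sample_ids
    idx <- match(shifted, genes)
    if (length(idx)) {
      e[idx, post] <- e[idx, post] + baseline[idx] * (2^cfg$deg_log2fc - 1)
    }
    if (ct == cfg$planted_cell_type && nrow(planted) > 0) {
      for (i in seq_len(nrow(planted))) {
        g <- planted$gene[i]
        e[g, ] <- e[g, ] + cfg$effect_size * planted$sign[i] * planted_pred[[i]]
      }
    }
    expression[[ct]] <- expression_matrix(e, cell_type = ct)
  }

  truth <- list(planted_pairs = planted,
                planted_compounds = character(0),
                planted_pathways = character(0))
  structure(list(expression = expression, microbes = microbes,
                 truth = truth, config = cfg),
            class = "cohort")
}

#' Per-gene pre/post differential expression table
#'
#' Two-group comparison of each gene between pre-flight and post-flight
#' samples: Welch t-test p-value, log2 fold change of group means, BH
#' adjustment, and the DEG flag `|log2FC| > 0.25 & padj < 0.05`.
#'
#' @param expr Expression matrix from [expression_matrix()] /
#'   [generate_cohort()].
#' @param design Optional character/factor over samples with levels `"pre"`
#'   and `"post"`; by default the first half of the timepoints is pre.
#' @return data.frame with columns gene, log2FC, p, padj, direction, is_deg.
#' @export
generate_deg_table <- function(expr, design = NULL) {
  meta <- parse_sample_ids(colnames(expr))
  if (is.null(design)) {
    tps <- sort(unique(meta$timepoint))
    design <- ifelse(meta$timepoint <= tps[ceiling(length(tps) / 2)], "pre", "post")
  }
  design <- as.character(design)
  if (length(design) != ncol(expr) || !all(design %in% c("pre", "post"))) {
    stop("design must assign every sample to 'pre' or 'post'")
  }
  if (sum(design == "pre") < 2 || sum(design == "post") < 2) {
    stop("degenerate design: each group needs at least 2 samples")
  }
  pre <- expr[, design == "pre", drop = FALSE]
  post <- expr[, design == "post", drop = FALSE]

  n <- nrow(expr)
  log2fc <- p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- pre[i, ]; b <- post[i, ]
    ma <- mean(a); mb <- mean(b)
    log2fc[i] <- if (ma > 0 && mb > 0) log2(mb / ma) else NA_real_
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      p[i] <- if (ma == mb) 1 else 0
    } else {
      p[i] <- stats::t.test(b, a)$p.value
    }
  }
  padj <- rep(NA_real_, n)
  ok <- !is.na(p)
  padj[ok] <- stats::p.adjust(p[ok], method = "BH")
  out <- data.frame(gene = rownames(expr), log2FC = log2fc, p = p, padj = padj,
                    direction = ifelse(is.na(log2fc) | log2fc == 0, "none",
                                       ifelse(log2fc > 0, "up", "down")),
                    stringsAsFactors = FALSE)
  out$is_deg <- !is.na(out$log2FC) & !is.na(out$padj) &
    abs(out$log2FC) > 0.25 & out$padj < 0.05
  out
}

#' Extract DEG gene lists per cell type from a cohort
#'
#' Runs [generate_deg_table()] on every cell type and returns either the
#' thresholded DEG sets or all genes (the latter is the natural choice for
#' global-null calibration experiments, where no gene passes the DEG rule).
#'
#' @param cohort A `cohort` object.
#' @param selection `"table"` (apply the DEG rule) or `"all"`.
#' @return Named list of character vectors, one per cell type.
#' @export
cohort_deg_lists <- function(cohort, selection = c("table", "all")) {
  selection <- match.arg(selection)
  lapply(cohort$expression, function(e) {
    if (selection == "all") return(rownames(e))
    tab <- generate_deg_table(e)
    tab$gene[tab$is_deg]
  })
}
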