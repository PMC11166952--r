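# Pipeline driver binding the stages into the analysis graph:
# simulate -> DEG tables -> transform -> LASSO screen -> mixed-model
# inference -> classification -> randomized-null comparison -> tallies and
# gene ranking -> pathway and compound enrichment -> truth recovery.

pipeline_defaults <- function() {
  list(
    seed = 1,
    cohort = list(),
    deg_selection = "table",
    transforms = c("log", "clr"),
    screen = list(lambda_strategy = "cv_min", n_folds = 5),
    alpha = 0.05,
    null_comparison = list(enabled = TRUE, n_randomizations = 1,
                           transforms = "log"),
    enrichment = list(enabled = TRUE, n_sets = 40, set_size = c(10, 30),
                      n_perm = 500, n_planted = 5, top_frac = 0.15),
    compounds = list(enabled = TRUE, n_compounds = 80, density = 0.05,
                     n_planted = 5, planted_frac = 0.9)
  )
}

#' Resolve a pipeline configuration
#'
#' Accepts a YAML file path or a (possibly partial) named list; unspecified
#' keys fall back to the documented defaults. All stage seeds are derived
#' from the single top-level `seed`, so one integer fixes the whole run.
#'
#' @param config YAML path, named list, or `NULL` for pure defaults.
#' @return Fully populated configuration list.
#' @export
pipeline_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a YAML path or a named list")
  utils::modifyList(pipeline_defaults(), config)
}

#' Run the full association pipeline on a synthetic cohort
#'
#' Executes every stage, writes all outputs as schema-commented TSV (plus a
#' GMT pathway collection) under `out_dir`, and records a YAML manifest of
#' seeds, parameters and per-output row counts. Reruns with an identical
#' configuration produce bit-identical outputs.
#'
#' @param config See [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  put <- function(name, writer, n_rows) {
    outputs[[name]] <<- n_rows
    invisible(NULL)
  }

  stage <- function(name) message(sprintf("[%s] running", name))

  stage("simulate")
  cohort_args <- cfg$cohort
  if (is.null(cohort_args$seed)) cohort_args$seed <- cfg$seed
  if (!is.null(cohort_args$n_microbes_per_rank)) {
    cohort_args$n_microbes_per_rank <- unlist(cohort_args$n_microbes_per_rank)
  }
  ccfg <- do.call(cohort_config, cohort_args)
  cohort <- generate_cohort(ccfg)
  for (ct in names(cohort$expression)) {
    f <- file.path(out_dir, sprintf("expression_%s.tsv", ct))
    write_matrix_tsv(cohort$expression[[ct]], f)
    put(basename(f), NULL, nrow(cohort$expression[[ct]]))
  }
  for (dr in names(cohort$microbes)) {
    f <- file.path(out_dir, sprintf("microbes_%s.tsv", gsub(":", "_", dr)))
    write_matrix_tsv(cohort$microbes[[dr]], f)
    put(basename(f), NULL, nrow(cohort$microbes[[dr]]))
  }

  stage("deg")
  deg_tables <- lapply(cohort$expression, generate_deg_table)
  for (ct in names(deg_tables)) {
    f <- file.path(out_dir, sprintf("deg_%s.tsv", ct))
    write_tsv_schema(deg_tables[[ct]], f)
    put(basename(f), NULL, nrow(deg_tables[[ct]]))
  }
  deg_lists <- if (identical(cfg$deg_selection, "all")) {
    lapply(cohort$expression, rownames)
  } else {
    lapply(deg_tables, function(t) t$gene[t$is_deg])
  }

  stage("screen")
  scr <- screen_config(lambda_strategy = cfg$screen$lambda_strategy,
                       n_folds = cfg$screen$n_folds,
                       fixed_lambda = cfg$screen$fixed_lambda,
                       seed = cfg$seed)
  candidates <- run_screen_all(cohort, deg_lists, scr,
                               transforms = cfg$transforms)
  write_tsv_schema(candidates, file.path(out_dir, "candidates.tsv"))
  put("candidates.tsv", NULL, nrow(candidates))

  stage("infer")
  scheme <- scheme_from_cohort(cohort, deg_lists, alpha = cfg$alpha)
  associations <- infer_associations(candidates, cohort, scheme = scheme)
  write_tsv_schema(associations, file.path(out_dir, "associations.tsv"))
  put("associations.tsv", NULL, nrow(associations))

  null_cmp <- NULL
  if (isTRUE(cfg$null_comparison$enabled)) {
    stage("nullcheck")
    null_cmp <- randomize_and_compare(
      cohort, deg_lists, scr,
      transforms = cfg$null_comparison$transforms,
      alpha = cfg$alpha,
      n_randomizations = cfg$null_comparison$n_randomizations,
      seed = cfg$seed + 1000L)
    write_tsv_schema(null_cmp, file.path(out_dir, "null_comparison.tsv"))
    put("null_comparison.tsv", NULL, nrow(null_cmp))
  }

  stage("tally")
  tally <- tally_positive_significant(associations)
  tally_df <- data.frame(cell_type = names(tally), n_positive_bonf005 = unname(tally),
                         stringsAsFactors = FALSE)
  write_tsv_schema(tally_df, file.path(out_dir, "tally.tsv"))
  put("tally.tsv", NULL, nrow(tally_df))

  stage("rank")
  ranking_tab <- rank_genes(associations)
  write_tsv_schema(ranking_tab, file.path(out_dir, "gene_ranking.tsv"))
  put("gene_ranking.tsv", NULL, nrow(ranking_tab))

  truth <- cohort$truth
  gsea_tab <- NULL
  if (isTRUE(cfg$enrichment$enabled)) {
    stage("gsea")
    ect <- cfg$enrichment$cell_type %||% ccfg$planted_cell_type
    if (!ect %in% names(deg_tables)) ect <- names(deg_tables)[1]
    tab <- deg_tables[[ect]]
    tab <- tab[!is.na(tab$log2FC) & !is.na(tab$p) & tab$p > 0, , drop = FALSE]
    rnk <- ranked_gene_list(tab$gene, rank_metric(tab$log2FC, tab$p, "signed_logp"))
    pw <- generate_pathways(cfg$enrichment$n_sets,
                            set_size = unlist(cfg$enrichment$set_size),
                            genes = rownames(cohort$expression[[ect]]),
                            n_planted = cfg$enrichment$n_planted,
                            ranking = rnk, top_frac = cfg$enrichment$top_frac,
                            seed = cfg$seed + 2000L)
    write_gmt(pw$pathways, file.path(out_dir, "pathways.gmt"))
    put("pathways.gmt", NULL, length(pw$pathways))
    gsea_tab <- preranked_gsea(rnk, pw$pathways, n_perm = cfg$enrichment$n_perm,
                               seed = cfg$seed + 2001L)
    write_tsv_schema(gsea_tab, file.path(out_dir, "gsea.tsv"))
    put("gsea.tsv", NULL, nrow(gsea_tab))
    truth$planted_pathways <- pw$planted_pathways
  }

  comp_tab <- NULL
  if (isTRUE(cfg$compounds$enabled)) {
    stage("compounds")
    deg_genes <- NULL
    for (dl in deg_lists) if (length(dl)) { deg_genes <- dl; break }
    n_pl <- if (is.null(deg_genes)) 0L else cfg$compounds$n_planted
    genes_ns <- rownames(cohort$expression[[1]])
    inter <- generate_interactome(cfg$compounds$n_compounds, genes = genes_ns,
                                  density = cfg$compounds$density,
                                  n_planted = n_pl, deg_genes = deg_genes,
                                  planted_frac = cfg$compounds$planted_frac,
                                  seed = cfg$seed + 3000L)
    if (!is.null(deg_genes)) {
      comp_tab <- compound_enrichment(deg_genes, inter$interactome,
                                      alpha = cfg$alpha)
      write_tsv_schema(comp_tab, file.path(out_dir, "compounds.tsv"))
      put("compounds.tsv", NULL, nrow(comp_tab))
    }
    truth$planted_compounds <- inter$planted_compounds
  }

  stage("recover")
  write_tsv_schema(truth$planted_pairs,
                   file.path(out_dir, "truth_planted_pairs.tsv"))
  put("truth_planted_pairs.tsv", NULL, nrow(truth$planted_pairs))
  recovery <- truth_recovery(truth, candidates, associations, gsea_tab, comp_tab)
  write_tsv_schema(recovery, file.path(out_dir, "recovery.tsv"))
  put("recovery.tsv", NULL, nrow(recovery))

  manifest <- list(package = "mbassoc",
                   version = as.character(utils::packageVersion("mbassoc")),
                   seed = cfg$seed,
                   config = cfg,
                   outputs = outputs)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Compare pipeline outputs against the planted truth
#'
#' @param truth Truth list (planted pairs / compounds / pathways).
#' @param candidates Screen candidates.
#' @param associations Classified associations.
#' @param gsea_tab Optional GSEA results.
#' @param comp_tab Optional compound enrichment results.
#' @return data.frame (quantity, n_planted, n_recovered) summarizing how
#'   many planted signals were recovered at each stage.
#' @export
truth_recovery <- function(truth, candidates, associations,
                           gsea_tab = NULL, comp_tab = NULL) {
  pairs <- truth$planted_pairs
  key <- function(df) paste(df$cell_type, df$gene, df$microbe, sep = "|")
  pk <- if (nrow(pairs)) key(pairs) else character(0)
  cand_k <- unique(key(candidates))
  nom_k <- unique(key(associations[associations$nominal, , drop = FALSE]))
  bon_k <- unique(key(associations[associations$bonf_005, , drop = FALSE]))
  rows <- list(
    data.frame(quantity = "planted_pairs_lasso", n_planted = length(pk),
               n_recovered = sum(pk %in% cand_k)),
    data.frame(quantity = "planted_pairs_nominal", n_planted = length(pk),
               n_recovered = sum(pk %in% nom_k)),
    data.frame(quantity = "planted_pairs_bonf005", n_planted = length(pk),
               n_recovered = sum(pk %in% bon_k)))
  if (!is.null(gsea_tab)) {
    hit <- gsea_tab$pathway[!is.na(gsea_tab$padj) & gsea_tab$padj < 0.05 &
                              gsea_tab$ES > 0]
    rows[[length(rows) + 1L]] <-
      data.frame(quantity = "planted_pathways",
                 n_planted = length(truth$planted_pathways),
                 n_recovered = sum(truth$planted_pathways %in% hit))
  }
  if (!is.null(comp_tab)) {
    hit <- comp_tab$compound[comp_tab$significant]
    rows[[length(rows) + 1L]] <-
      data.frame(quantity = "planted_compounds",
                 n_planted = length(truth$planted_compounds),
                 n_recovered = sum(truth$planted_compounds %in% hit))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
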