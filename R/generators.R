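# Generators for the compound interactome and pathway collections used by
# the enrichment stages, with planted signals recorded as ground truth.

#' Generate a bipartite compound-gene interactome
#'
#' Non-planted compounds draw their interaction partners uniformly from the
#' gene namespace; planted compounds over-sample a supplied DEG list so that
#' a hypergeometric enrichment screen should recover them.
#'
#' @param n_compounds Number of compounds.
#' @param genes Character vector: the gene namespace.
#' @param density Expected fraction of the namespace each compound interacts
#'   with, in (0, 1).
#' @param n_planted Number of planted (DEG-enriched) compounds.
#' @param deg_genes DEG list the planted compounds over-sample (required
#'   when `n_planted > 0`).
#' @param planted_frac Fraction of a planted compound's genes drawn from
#'   `deg_genes` (default 0.9).
#' @param class_label Compound class: `"drug"`, `"food"` or `"lincs"`.
#' @param seed Integer seed.
#' @return List with `interactome` (named list compound -> gene set, with
#'   attribute `class_label`) and `planted_compounds`.
#' @export
generate_interactome <- function(n_compounds, genes, density,
                                 n_planted = 0, deg_genes = NULL,
                                 planted_frac = 0.9,
                                 class_label = c("drug", "food", "lincs"),
                                 seed = 1) {
  class_label <- match.arg(class_label)
  if (!is.numeric(density) || density <= 0 || density >= 1) {
    stop("invalid configuration: field 'density' must lie in (0, 1)")
  }
  if (n_compounds < 1) stop("invalid configuration: field 'n_compounds' must be positive")
  if (n_planted > n_compounds) {
    stop("invalid configuration: field 'n_planted' exceeds n_compounds")
  }
  if (n_planted > 0 && (is.null(deg_genes) || !length(deg_genes))) {
    stop("invalid configuration: field 'deg_genes' is required when planting compounds")
  }
  if (n_planted > 0 && !all(deg_genes %in% genes)) {
    stop("invalid configuration: field 'deg_genes' must be drawn from 'genes'")
  }
  withr::with_seed(as.integer(seed), {
    ids <- sprintf("%s_c%04d", class_label, seq_len(n_compounds))
    planted_ids <- if (n_planted > 0) sample(ids, n_planted) else character(0)
    non_deg <- setdiff(genes, deg_genes)
    inter <- lapply(ids, function(id) {
      k <- max(1L, stats::rbinom(1L, length(genes), density))
      if (id %in% planted_ids) {
        k_in <- min(max(1L, round(planted_frac * k)), length(deg_genes))
        k_out <- min(k - k_in, length(non_deg))
        c(sample(deg_genes, k_in), if (k_out > 0) sample(non_deg, k_out))
      } else {
        sample(genes, k)
      }
    })
    names(inter) <- ids
    attr(inter, "class_label") <- class_label
    list(interactome = inter, planted_compounds = sort(planted_ids))
  })
}

#' Generate a pathway (gene-set) collection
#'
#' Random sets are sampled uniformly from the gene namespace; planted sets
#' concentrate in the top of a supplied ranking so that a preranked
#' enrichment analysis should flag them with positive enrichment scores.
#'
#' @param n_sets Number of gene sets (0 gives an empty collection).
#' @param set_size Length-2 integer range of set sizes.
#' @param genes Character vector: the gene namespace.
#' @param n_planted Number of planted (ranking-concordant) sets.
#' @param ranking Gene ids in ranking order (best first), or a
#'   [ranked_gene_list()] data.frame; required when `n_planted > 0`.
#' @param top_frac Fraction of the ranking that planted sets draw from.
#' @param seed Integer seed.
#' @return List with `pathways` (named list set -> genes) and
#'   `planted_pathways`.
#' @export
generate_pathways <- function(n_sets, set_size = c(10, 50), genes,
                              n_planted = 0, ranking = NULL,
                              top_frac = 0.1, seed = 1) {
  if (length(set_size) != 2 || any(set_size < 1)) {
    stop("invalid configuration: field 'set_size' must be a positive range")
  }
  if (max(set_size) > length(genes)) {
    stop("invalid configuration: field 'set_size' exceeds the number of genes")
  }
  if (n_sets == 0) {
    return(list(pathways = structure(list(), names = character(0)),
                planted_pathways = character(0)))
  }
  if (n_planted > n_sets) {
    stop("invalid configuration: field 'n_planted' exceeds n_sets")
  }
  if (n_planted > 0 && is.null(ranking)) {
    stop("invalid configuration: field 'ranking' is required when planting pathways")
  }
  if (is.data.frame(ranking)) ranking <- ranking$gene
  withr::with_seed(as.integer(seed), {
    ids <- sprintf("pathway_%03d", seq_len(n_sets))
    planted_ids <- if (n_planted > 0) sample(ids, n_planted) else character(0)
    top <- if (n_planted > 0) {
      ranking[seq_len(max(min(set_size), ceiling(top_frac * length(ranking))))]
    } else character(0)
    sets <- lapply(ids, function(id) {
      k <- sample(seq(set_size[1], set_size[2]), 1L)
      if (id %in% planted_ids) {
        sample(top, min(k, length(top)))
      } else {
        sample(genes, k)
      }
    })
    names(sets) <- ids
    list(pathways = sets, planted_pathways = sort(planted_ids))
  })
}
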