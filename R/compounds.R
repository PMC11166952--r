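# Compound-gene interactome enrichment: does a compound's interaction
# partner set over-represent a DEG list relative to the universal gene set
# (all genes interacting with at least one compound)?

#' Universal gene set of an interactome
#'
#' @param interactome Named list: compound id -> character vector of genes.
#' @return Sorted character vector, the union of all compounds' gene sets.
#' @export
build_universal_gene_set <- function(interactome) {
  if (length(interactome) == 0L) stop("empty interactome")
  if (any(vapply(interactome, length, integer(1)) == 0L)) {
    stop("every compound must interact with at least one gene")
  }
  out <- sort(unique(unlist(interactome, use.names = FALSE)))
  message(sprintf("universal gene set: %d genes across %d compounds",
                  length(out), length(interactome)))
  out
}

#' Hypergeometric enrichment of DEGs in each compound's gene set
#'
#' For each compound, tests whether its interaction partners contain more
#' DEGs than expected by chance within the universal gene set (upper-tail
#' hypergeometric), with Bonferroni adjustment over the number of compounds
#' tested. DEGs outside the universal gene set are dropped (and counted).
#'
#' @param degs Character vector of DEG ids.
#' @param interactome Named list: compound id -> gene set.
#' @param alpha Significance level on the Bonferroni-adjusted p (default 0.05).
#' @return data.frame (compound, n_genes, overlap, expected, p_value,
#'   p_bonferroni, significant), sorted by p-value.
#' @export
compound_enrichment <- function(degs, interactome, alpha = 0.05) {
  universe <- build_universal_gene_set(interactome)
  degs <- unique(degs)
  dropped <- sum(!degs %in% universe)
  if (dropped > 0) {
    message(sprintf("compound enrichment: %d DEG(s) outside the universal gene set dropped",
                    dropped))
  }
  degs <- intersect(degs, universe)
  if (length(degs) == 0L) {
    stop("no DEG lies within the universal gene set")
  }
  n <- length(universe)
  m <- length(degs)
  n_tested <- length(interactome)
  rows <- lapply(names(interactome), function(cmp) {
    s <- unique(interactome[[cmp]])
    q <- length(intersect(s, degs))
    p <- stats::phyper(q - 1, m, n - m, length(s), lower.tail = FALSE)
    data.frame(compound = cmp, n_genes = length(s), overlap = q,
               expected = length(s) * m / n, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * n_tested)
  out$significant <- out$p_bonferroni < alpha
  out <- out[order(out$p_value, out$compound), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compound enrichment across cell types and compound classes
#'
#' Runs [compound_enrichment()] for every (cell type, class) combination
#' (each class -- drugs, food compounds, LINCS compounds -- forms its own
#' Bonferroni family) and reports the deduplicated union of significant
#' compounds with their provenance.
#'
#' @param deg_lists Named list (by cell type) of DEG id vectors.
#' @param interactomes Named list (by class) of interactomes.
#' @param alpha Significance level.
#' @return List with `tables` (one combined data.frame with cell_type and
#'   class columns) and `significant_union` (compound, n_hits, provenance).
#' @export
screen_compound_classes <- function(deg_lists, interactomes, alpha = 0.05) {
  if (!length(deg_lists) || !length(interactomes)) {
    stop("need at least one cell type and one compound class")
  }
  tabs <- list()
  for (ct in names(deg_lists)) {
    for (cl in names(interactomes)) {
      tab <- tryCatch(compound_enrichment(deg_lists[[ct]], interactomes[[cl]],
                                          alpha = alpha),
                      error = function(e) {
                        warning(sprintf("compound screen failed for (%s, %s): %s",
                                        ct, cl, conditionMessage(e)))
                        NULL
                      })
      if (is.null(tab)) next
      tab$cell_type <- ct
      tab$class <- cl
      tabs[[length(tabs) + 1L]] <- tab
    }
  }
  combined <- if (length(tabs)) do.call(rbind, tabs) else
    data.frame(compound = character(0), n_genes = integer(0),
               overlap = integer(0), expected = numeric(0),
               p_value = numeric(0), p_bonferroni = numeric(0),
               significant = logical(0), cell_type = character(0),
               class = character(0), stringsAsFactors = FALSE)
  sig <- combined[combined$significant, , drop = FALSE]
  union_tab <- if (nrow(sig)) {
    prov <- tapply(paste(sig$cell_type, sig$class, sep = ":"), sig$compound,
                   function(x) paste(sort(unique(x)), collapse = ";"))
    data.frame(compound = names(prov),
               n_hits = as.integer(table(sig$compound)[names(prov)]),
               provenance = unname(prov), stringsAsFactors = FALSE)
  } else {
    data.frame(compound = character(0), n_hits = integer(0),
               provenance = character(0), stringsAsFactors = FALSE)
  }
  rownames(combined) <- NULL
  list(tables = combined, significant_union = union_tab)
}
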