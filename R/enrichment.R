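# Cross-signature comparison statistics: Fisher/hypergeometric set overlap,
# BH adjustment, ranking metrics, preranked GSEA with a permutation (or
# exact enumeration) null, pathway scores and their correlation across
# studies.

#' Fisher's exact test for the overlap of two gene sets
#'
#' Builds the 2x2 contingency table (in A / not in A) x (in B / not in B)
#' over a finite gene universe and tests for over-representation of the
#' overlap. The one-sided enrichment p-value equals the hypergeometric
#' upper tail.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector: the finite gene universe.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return List with the table counts (a = overlap, b = A only, c = B only,
#'   d = neither), odds_ratio, p_value and n_universe.
#' @export
fisher_overlap <- function(set_a, set_b, universe,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe)) stop("set A is not a subset of the universe")
  if (!all(set_b %in% universe)) stop("set B is not a subset of the universe")
  a <- length(intersect(set_a, set_b))
  b <- length(set_a) - a
  c_ <- length(set_b) - a
  d <- length(universe) - a - b - c_
  ft <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE),
                           alternative = alternative)
  list(a = a, b = b, c = c_, d = d,
       odds_ratio = unname(ft$estimate), p_value = ft$p.value,
       n_universe = length(universe))
}

#' Benjamini-Hochberg adjustment
#'
#' Thin validated wrapper over `p.adjust(..., method = "BH")` so the
#' adjustment used throughout the package is explicit and input-checked.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Step-up adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Ranking metric for preranked enrichment
#'
#' @param log2fc Log2 fold changes.
#' @param p P-values (raw or adjusted, caller's choice) in (0, 1]; exact
#'   zeros are clamped to the smallest representable positive double with a
#'   warning.
#' @param mode `"signed_logp"` (`-log10(p) * sign(log2fc)`),
#'   `"lfc_times_logp"` (`log2fc * -log10(p)`) or `"stat"` (pass an
#'   externally supplied statistic through unchanged).
#' @param stat Statistic vector, used only in `"stat"` mode.
#' @return Numeric score vector.
#' @export
rank_metric <- function(log2fc, p, mode = c("signed_logp", "lfc_times_logp", "stat"),
                        stat = NULL) {
  mode <- match.arg(mode)
  if (mode == "stat") {
    if (is.null(stat)) stop("mode 'stat' needs the 'stat' argument")
    return(stat)
  }
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  if (any(p < 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (any(p == 0)) {
    warning("p-value of 0 clamped to the smallest representable positive value")
    p[p == 0] <- .Machine$double.xmin
  }
  switch(mode,
         signed_logp = -log10(p) * sign(log2fc),
         lfc_times_logp = log2fc * (-log10(p)))
}

#' Build a ranked gene list
#'
#' Orders genes by decreasing score with lexicographic gene id as the
#' deterministic tie-break.
#'
#' @param genes Unique gene ids.
#' @param scores Numeric scores, one per gene.
#' @return data.frame (gene, score), ordered best-first.
#' @export
ranked_gene_list <- function(genes, scores) {
  if (length(genes) != length(scores)) stop("genes and scores differ in length")
  if (anyDuplicated(genes)) stop("gene ids must be unique")
  if (anyNA(scores)) stop("scores must not be missing")
  ord <- order(-scores, genes)
  data.frame(gene = genes[ord], score = scores[ord], stringsAsFactors = FALSE)
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score of `set` against
# a ranking (scores sorted best-first). Returns the signed maximal
# deviation and the position at which it is attained.
gsea_running_es <- function(scores, in_set, weight = 1) {
  n <- length(scores)
  k <- sum(in_set)
  w <- abs(scores)^weight
  ws <- sum(w[in_set])
  if (ws == 0) { # all-zero scores inside the set: fall back to equal weights
    w[] <- 1
    ws <- k
  }
  p_hit <- cumsum(ifelse(in_set, w, 0)) / ws
  p_miss <- cumsum(!in_set) / (n - k)
  dev <- p_hit - p_miss
  i <- which.max(abs(dev))
  list(es = dev[i], at = i)
}

#' Enrichment score of a gene set against a ranked list
#'
#' The weighted Kolmogorov-Smirnov running-sum statistic of preranked GSEA,
#' exposed directly for inspection and testing.
#'
#' @param ranking A [ranked_gene_list()] data.frame (or named score vector).
#' @param set Character vector of genes.
#' @param weight Weighting exponent on `|score|` (1 = standard weighted KS).
#' @return The signed enrichment score in [-1, 1].
#' @export
gsea_es <- function(ranking, set, weight = 1) {
  ranking <- normalize_ranking(ranking)
  in_set <- ranking$gene %in% set
  if (!any(in_set)) stop("set has no gene in the ranking")
  if (all(in_set)) stop("set covers the entire ranking; ES is degenerate")
  gsea_running_es(ranking$score, in_set, weight)$es
}

normalize_ranking <- function(ranking) {
  if (is.numeric(ranking) && !is.null(names(ranking))) {
    ranking <- ranked_gene_list(names(ranking), unname(ranking))
  }
  if (!is.data.frame(ranking) || !all(c("gene", "score") %in% names(ranking))) {
    stop("ranking must be a ranked_gene_list() data.frame or a named score vector")
  }
  if (is.unsorted(rev(ranking$score))) {
    ranking <- ranked_gene_list(ranking$gene, ranking$score)
  }
  ranking
}

#' Preranked gene-set enrichment analysis
#'
#' Computes the weighted KS enrichment score of each set against the
#' ranking and assesses significance with a gene-label permutation null:
#' random same-size gene sets are drawn from the ranking, the one-sided
#' p-value is taken among same-signed permutation scores, and NES is the
#' observed ES divided by the mean magnitude of same-signed permutation
#' scores. With `exact = TRUE` the complete enumeration of all same-size
#' subsets replaces random sampling (feasible for small rankings), making
#' the p-value exact. BH adjustment is applied across the sets with a
#' defined NES.
#'
#' @param ranking A [ranked_gene_list()] data.frame or named score vector.
#' @param pathways Named list of gene sets.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutations.
#' @param weight Weighting exponent (default 1).
#' @param exact Use full enumeration of same-size subsets instead of
#'   sampling (requires `choose(n, k) <= max_enumeration`).
#' @param max_enumeration Cap on the enumeration size (default 2e5).
#' @param min_size Minimum number of set genes present in the ranking.
#' @return data.frame with pathway, size, ES, NES, p_value, padj and
#'   leading_edge (comma-separated). Sets with no ranked genes, or covering
#'   the whole ranking, are dropped with a warning; sets with no same-sign
#'   permutation scores get NA NES/padj and are excluded from the BH family.
#' @export
preranked_gsea <- function(ranking, pathways, n_perm = 1000, seed = 1,
                           weight = 1, exact = FALSE, max_enumeration = 2e5,
                           min_size = 1) {
  ranking <- normalize_ranking(ranking)
  if (!exact && (!is.numeric(n_perm) || n_perm < 100)) {
    stop("configuration error: n_perm must be at least 100")
  }
  if (length(pathways) == 0L) {
    return(data.frame(pathway = character(0), size = integer(0),
                      ES = numeric(0), NES = numeric(0),
                      p_value = numeric(0), padj = numeric(0),
                      leading_edge = character(0), stringsAsFactors = FALSE))
  }
  n <- nrow(ranking)
  scores <- ranking$score
  keep <- list()
  for (pw in names(pathways)) {
    genes_in <- intersect(pathways[[pw]], ranking$gene)
    k <- length(genes_in)
    if (k < min_size || k == 0L) {
      warning(sprintf("gsea: dropping set '%s' (no ranked genes)", pw))
      next
    }
    if (k == n) {
      warning(sprintf("gsea: dropping set '%s' (covers the entire ranking)", pw))
      next
    }
    keep[[pw]] <- genes_in
  }
  if (!length(keep)) {
    return(data.frame(pathway = character(0), size = integer(0),
                      ES = numeric(0), NES = numeric(0),
                      p_value = numeric(0), padj = numeric(0),
                      leading_edge = character(0), stringsAsFactors = FALSE))
  }

  null_es <- function(k) {
    if (exact) {
      if (choose(n, k) > max_enumeration) {
        stop(sprintf("exact enumeration infeasible: choose(%d, %d) subsets", n, k))
      }
      combs <- utils::combn(n, k)
      apply(combs, 2L, function(idx) {
        in_set <- logical(n); in_set[idx] <- TRUE
        gsea_running_es(scores, in_set, weight)$es
      })
    } else {
      vapply(seq_len(n_perm), function(i) {
        in_set <- logical(n); in_set[sample.int(n, k)] <- TRUE
        gsea_running_es(scores, in_set, weight)$es
      }, numeric(1))
    }
  }

  rows <- withr::with_seed(as.integer(seed), {
    null_cache <- list()
    lapply(names(keep), function(pw) {
      genes_in <- keep[[pw]]
      in_set <- ranking$gene %in% genes_in
      obs <- gsea_running_es(scores, in_set, weight)
      kk <- as.character(sum(in_set))
      if (is.null(null_cache[[kk]])) null_cache[[kk]] <<- null_es(sum(in_set))
      nes_null <- null_cache[[kk]]
      eps <- 1e-12 # tie tolerance: equal-ES subsets differ only by summation order
      if (obs$es >= 0) {
        same <- nes_null[nes_null >= 0]
        hits <- sum(nes_null >= obs$es - eps)
        pv <- if (exact) hits / max(1L, length(same)) else
          (1 + hits) / (1 + length(same))
        nes <- if (length(same) && mean(same) > 0) obs$es / mean(same) else NA_real_
        le <- ranking$gene[seq_len(obs$at)]
      } else {
        same <- nes_null[nes_null < 0]
        hits <- sum(nes_null <= obs$es + eps)
        pv <- if (exact) hits / max(1L, length(same)) else
          (1 + hits) / (1 + length(same))
        nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
        le <- ranking$gene[obs$at:n]
      }
      data.frame(pathway = pw, size = length(genes_in), ES = obs$es, NES = nes,
                 p_value = min(1, pv), padj = NA_real_,
                 leading_edge = paste(intersect(le, genes_in), collapse = ","),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$NES)
  out$padj[ok] <- bh_adjust(out$p_value[ok])
  rownames(out) <- NULL
  out
}

#' Signed pathway score
#'
#' `-log10(padj) * sign(NES)`, the scalar summary used to compare
#' enrichment profiles across studies.
#'
#' @param padj Adjusted p-values in (0, 1].
#' @param nes Normalized enrichment scores (only the sign is used;
#'   `sign(0) = 0`).
#' @return Numeric score vector.
#' @export
pathway_score <- function(padj, nes) {
  if (any(padj <= 0 | padj > 1, na.rm = TRUE)) stop("padj must lie in (0, 1]")
  if (any(!is.finite(nes))) stop("NES must be finite")
  -log10(padj) * sign(nes)
}

#' Correlation of pathway scores between two studies
#'
#' Matches pathways by id, and reports the Pearson correlation and the
#' ordinary least-squares slope of B on A over the intersection.
#'
#' @param scores_a,scores_b Named numeric vectors (names = pathway ids).
#' @return List with pearson_r, slope, n (matched pathways) and n_dropped.
#' @export
score_correlation <- function(scores_a, scores_b) {
  if (is.null(names(scores_a)) || is.null(names(scores_b))) {
    stop("scores must be named by pathway id")
  }
  common <- intersect(names(scores_a), names(scores_b))
  if (length(common) < 3L) stop("fewer than 3 matched pathways")
  a <- scores_a[common]; b <- scores_b[common]
  list(pearson_r = stats::cor(a, b),
       slope = unname(stats::coef(stats::lm(b ~ a))[2L]),
       n = length(common),
       n_dropped = length(scores_a) + length(scores_b) - 2L * length(common))
}

#' Hypergeometric over-representation analysis
#'
#' Tests each annotation set for over-representation of a query gene set
#' within a finite universe (upper-tail hypergeometric), with BH adjustment
#' across sets.
#'
#' @param query Character vector of query genes (subset of `universe`).
#' @param annotation_sets Named list of gene sets.
#' @param universe Character vector: the gene universe.
#' @return data.frame (set, size, overlap, expected, p_value, padj) sorted
#'   by adjusted then raw p-value.
#' @export
ora <- function(query, annotation_sets, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(query) == 0L) stop("empty query set")
  if (!all(query %in% universe)) stop("query is not a subset of the universe")
  n <- length(universe)
  rows <- lapply(names(annotation_sets), function(nm) {
    s <- intersect(unique(annotation_sets[[nm]]), universe)
    q <- length(intersect(s, query))
    data.frame(set = nm, size = length(s), overlap = q,
               expected = length(s) * length(query) / n,
               p_value = stats::phyper(q - 1, length(s), n - length(s),
                                       length(query), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p_value)
  out <- out[order(out$padj, out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage of a reference DEG set recovered in another set
#'
#' `100 * |A intersect B| / |A|`; directional comparisons are made by
#' passing the up- or down-regulated subsets.
#'
#' @param degs_a Reference set (denominator); must be non-empty.
#' @param degs_b Comparison set.
#' @return Overlap percentage in [0, 100].
#' @export
overlap_percentage <- function(degs_a, degs_b) {
  degs_a <- unique(degs_a)
  if (length(degs_a) == 0L) stop("empty reference set")
  100 * length(intersect(degs_a, degs_b)) / length(degs_a)
}
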