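#!/usr/bin/env Rscript
# Stage 5: signature comparison statistics. Builds a signed -log10(p)
# ranking from the CD14 monocyte DEG table, runs preranked GSEA against a
# pathway collection with planted concordant sets, compares DEG sets
# across cell types with Fisher's exact overlap, and correlates pathway
# scores (-log10(padj) * sign(NES)) between two cell types' GSEA profiles.

suppressMessages(library(mbassoc))

data_dir <- "results/data"
out <- "results"
dir.create(out, showWarnings = FALSE)

deg_tab <- function(ct) {
  read_tsv_schema(file.path(data_dir, sprintf("deg_%s.tsv", ct)))
}

tab <- deg_tab("CD14_Mono")
tab <- tab[!is.na(tab$log2FC) & tab$p > 0, ]
rnk <- ranked_gene_list(tab$gene, rank_metric(tab$log2FC, tab$p, "signed_logp"))

pw <- generate_pathways(30, set_size = c(8, 20), genes = tab$gene,
                        n_planted = 5, ranking = rnk, top_frac = 0.2,
                        seed = 2026)
write_gmt(pw$pathways, file.path(out, "pathways.gmt"))
gsea <- preranked_gsea(rnk, pw$pathways, n_perm = 2000, seed = 2026)
write_tsv_schema(gsea, file.path(out, "gsea_CD14_Mono.tsv"))

sig <- gsea$pathway[!is.na(gsea$padj) & gsea$padj < 0.05 & gsea$ES > 0]
cat("GSEA:", nrow(gsea), "sets tested;", length(sig),
    "significant (padj < 0.05, ES > 0)\n")
cat("Planted concordant sets recovered:",
    sum(pw$planted_pathways %in% sig), "of", length(pw$planted_pathways), "\n")

# Directional DEG overlap between cell types (Fisher's exact test)
tab_nk <- deg_tab("NK")
universe <- union(tab$gene, tab_nk$gene)
up_cd14 <- tab$gene[as.logical(tab$is_deg) & tab$direction == "up"]
up_nk <- tab_nk$gene[as.logical(tab_nk$is_deg) & tab_nk$direction == "up"]
ov <- fisher_overlap(up_cd14, up_nk, universe)
cat(sprintf("Up-regulated DEG overlap CD14_Mono vs NK: %d genes, OR %.1f, p %.3g\n",
            ov$a, ov$odds_ratio, ov$p_value))
cat(sprintf("Overlap percentage (reference CD14_Mono): %.1f%%\n",
            overlap_percentage(up_cd14, up_nk)))

# Pathway-score correlation between two cell types' enrichment profiles
tab_nk2 <- tab_nk[!is.na(tab_nk$log2FC) & tab_nk$p > 0, ]
rnk_nk <- ranked_gene_list(tab_nk2$gene,
                           rank_metric(tab_nk2$log2FC, tab_nk2$p, "signed_logp"))
gsea_nk <- preranked_gsea(rnk_nk, pw$pathways, n_perm = 2000, seed = 2027)
ok_a <- !is.na(gsea$padj); ok_b <- !is.na(gsea_nk$padj)
scores_a <- setNames(pathway_score(gsea$padj[ok_a], gsea$NES[ok_a]),
                     gsea$pathway[ok_a])
scores_b <- setNames(pathway_score(gsea_nk$padj[ok_b], gsea_nk$NES[ok_b]),
                     gsea_nk$pathway[ok_b])
cc <- score_correlation(scores_a, scores_b)
write_tsv_schema(data.frame(pearson_r = cc$pearson_r, slope = cc$slope,
                            n = cc$n),
                 file.path(out, "pathway_score_correlation.tsv"))
cat(sprintf("Pathway-score correlation CD14_Mono vs NK: R = %.2f, slope = %.2f (n = %d)\n",
            cc$pearson_r, cc$slope, cc$n))
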