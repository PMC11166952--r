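#!/usr/bin/env Rscript
# Stage 1: simulate a crew cohort with planted gene-microbe effects and
# derive the per-cell-type differential expression tables.
#
# The cohort mirrors the study design: 4 crew members x 6 timepoints
# (3 pre-flight, 3 post-flight), pseudo-bulk expression for three immune
# cell types, and two microbial families (bacterial species, viral genera).
# 15 positive effects of 1 SD per predictor-SD are planted in CD14
# monocytes against bacterial species.

suppressMessages(library(mbassoc))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(
  cell_types = c("CD14_Mono", "NK", "B"),
  n_genes = 120,
  n_microbes_per_rank = c("bacteria:species" = 60, "virus:genus" = 25),
  n_planted = 15, effect_size = 1.0, noise_sd = 0.8,
  seed = 2026)
cohort <- generate_cohort(cfg)

for (ct in names(cohort$expression)) {
  write_matrix_tsv(cohort$expression[[ct]],
                   file.path(out, sprintf("expression_%s.tsv", ct)))
}
for (dr in names(cohort$microbes)) {
  write_matrix_tsv(cohort$microbes[[dr]],
                   file.path(out, sprintf("microbes_%s.tsv", gsub(":", "_", dr))))
}
write_tsv_schema(cohort$truth$planted_pairs, file.path(out, "truth_planted_pairs.tsv"))

n_deg <- integer(0)
deg_tabs <- list()
for (ct in names(cohort$expression)) {
  tab <- generate_deg_table(cohort$expression[[ct]])
  write_tsv_schema(tab, file.path(out, sprintf("deg_%s.tsv", ct)))
  deg_tabs[[ct]] <- tab
  n_deg[ct] <- sum(tab$is_deg)
}

cat("Simulated cohort:", length(cohort$expression), "cell types,",
    sum(sapply(cohort$microbes, nrow)), "microbial features,",
    nrow(cohort$truth$planted_pairs), "planted pairs\n")
cat("DEGs per cell type:", paste(names(n_deg), n_deg, collapse = ", "), "\n")
planted_deg <- sum(cohort$truth$planted_pairs$gene %in%
                     deg_tabs$CD14_Mono$gene[deg_tabs$CD14_Mono$is_deg])
cat("Planted genes flagged as CD14_Mono DEGs:", planted_deg, "of",
    nrow(cohort$truth$planted_pairs), "\n")
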