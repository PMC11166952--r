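#!/usr/bin/env Rscript
# Stage 2: LASSO screen. Each cell type's DEGs are regressed (with an L1
# penalty, lambda by 5-fold CV-min) on all features of each microbial
# family, once on log-transformed and once on CLR-transformed abundances.
# Non-zero coefficients become candidate associations.

suppressMessages(library(mbassoc))

data_dir <- "results/data"
out <- "results"

cell_types <- sub("^expression_(.*)\\.tsv$", "\\1",
                  list.files(data_dir, pattern = "^expression_"))
expression <- lapply(cell_types, function(ct) {
  read_matrix_tsv(file.path(data_dir, sprintf("expression_%s.tsv", ct)),
                  "expression", cell_type = ct)
})
names(expression) <- cell_types

microbe_files <- list.files(data_dir, pattern = "^microbes_")
microbes <- lapply(microbe_files, function(f) {
  parts <- strsplit(sub("^microbes_(.*)\\.tsv$", "\\1", f), "_")[[1]]
  read_matrix_tsv(file.path(data_dir, f), "microbe",
                  domain = parts[1], rank = parts[2])
})
names(microbes) <- vapply(microbe_files, function(f) {
  parts <- strsplit(sub("^microbes_(.*)\\.tsv$", "\\1", f), "_")[[1]]
  paste(parts[1], parts[2], sep = ":")
}, character(1))

deg_lists <- lapply(cell_types, function(ct) {
  tab <- read_tsv_schema(file.path(data_dir, sprintf("deg_%s.tsv", ct)))
  tab$gene[as.logical(tab$is_deg)]
})
names(deg_lists) <- cell_types

cohort <- list(expression = expression, microbes = microbes)
candidates <- run_screen_all(cohort, deg_lists,
                             screen_config(seed = 2026),
                             transforms = c("log", "clr"))
write_tsv_schema(candidates, file.path(out, "candidates.tsv"))

cat("Candidate associations (non-zero LASSO coefficients):",
    nrow(candidates), "\n")
print(table(candidates$cell_type, candidates$transform))
cat("Per domain:", paste(names(table(candidates$domain)),
                         table(candidates$domain), collapse = ", "), "\n")
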