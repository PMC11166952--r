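# Independent oracles used across the suite. These are deliberately naive
# (combinatorial sums, cumulative-sum running statistics) so they stay
# independent of the package's implementation paths.

# Upper-tail hypergeometric probability P(X >= q) computed from binomial
# coefficients: X = overlap when drawing `k` items from a universe of `n`
# containing `m` marked items.
hyper_tail_oracle <- function(q, m, n, k) {
  total <- choose(n, k)
  qs <- seq(max(q, 0), min(k, m))
  if (length(qs) == 0) return(0)
  sum(choose(m, qs) * choose(n - m, k - qs)) / total
}

# Plain running-sum GSEA enrichment score (weight 1), independent of the
# package's vectorized version.
es_oracle <- function(scores, in_set) {
  n <- length(scores)
  nr <- sum(abs(scores[in_set]))
  if (nr == 0) {
    hit_step <- ifelse(in_set, 1 / sum(in_set), 0)
  } else {
    hit_step <- ifelse(in_set, abs(scores) / nr, 0)
  }
  miss_step <- ifelse(in_set, 0, 1 / (n - sum(in_set)))
  run <- cumsum(hit_step - miss_step)
  run[which.max(abs(run))]
}

# Small planted cohort used by several pipeline-level tests.
small_planted_cohort <- function(seed, n_crew = 4, n_genes = 40,
                                 n_microbes = 25, n_planted = 6,
                                 effect_size = 1, noise_sd = 0.5,
                                 cell_types = c("CD14_Mono", "NK")) {
  generate_cohort(cohort_config(
    n_crew = n_crew, cell_types = cell_types, n_genes = n_genes,
    n_microbes_per_rank = c("bacteria:species" = n_microbes),
    n_planted = n_planted, effect_size = effect_size, noise_sd = noise_sd,
    seed = seed))
}

# Run screen + inference + classification on a cohort with given DEG lists.
run_two_stage <- function(cohort, deg_lists, seed = 1, transforms = "log",
                          cfg = screen_config(seed = seed)) {
  cands <- suppressMessages(suppressWarnings(
    run_screen_all(cohort, deg_lists, cfg, transforms = transforms)))
  res <- suppressMessages(suppressWarnings(
    infer_associations(cands, cohort,
                       scheme = scheme_from_cohort(cohort, deg_lists))))
  list(candidates = cands, results = res)
}
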