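---
title: "Two-stage host gene–microbiome association and cross-signature enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage host gene–microbiome association and cross-signature enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbassoc)
```

## The problem

Short-duration human spaceflight cohorts pair deep molecular profiling with
very small sample sizes: a handful of crew members, each sampled at a few
pre-flight and post-flight timepoints. `mbassoc` implements the downstream
analytics for asking whether host immune gene expression co-varies with
microbial abundances in such a design, and for comparing differential
signatures across studies. Everything operates on plain matrices: per-cell-type
pseudo-bulk expression (genes × samples) and per-(domain, rank) microbial
abundance tables (features × samples), with samples indexed by crew member and
timepoint.

Because real cohorts of this kind are controlled-access, the package ships a
synthetic-cohort generator that reproduces the statistical structure the
analysis assumes — crew-level random intercepts, compositional zero-heavy
microbial counts, planted gene–microbe effects, planted enriched pathways and
compounds — so every stage is testable end to end against a known truth.

## The association model

The association procedure has two stages, run separately per cell type and
per microbial family (a *family* is one domain at one taxonomic rank, e.g.
all bacterial species, or all viral genera).

**Stage 1 — LASSO screen.** For each differentially expressed gene (DEG) $g$
of a cell type, an L1-penalized regression

$$ z(g) \sim \mathrm{microbe}_1 + \dots + \mathrm{microbe}_p $$

is fit on all $p$ features of the family, where $z(\cdot)$ centers and scales
the gene across samples and the microbial predictors are log- or CLR-
transformed abundances (below). With ~24 samples and up to hundreds of
features this is the $p \gg n$ regime the L1 penalty is designed for. Every
non-zero coefficient at the selected penalty is a *candidate association* —
a screening call only, with no inferential content. The penalty is chosen by
5-fold cross-validation minimizing mean squared error (`cv_min`); CV-min
rather than the 1-SE rule because the screen should maximize sensitivity,
with false positives controlled downstream. Fold assignment is drawn once
from the screen seed, making the stage fully deterministic.

**Stage 2 — mixed-model inference.** Each candidate pair is refit as a
random-intercept model

$$ z(g) = \beta_0 + \beta_1 \cdot \mathrm{microbe} + u_{\mathrm{crew}} + \varepsilon,
   \qquad u_{\mathrm{crew}} \sim N(0, \sigma^2_c), $$

REML-estimated with lme4, where the crew intercept absorbs stable
inter-individual differences. The slope is tested with a two-sided Wald $t$
statistic using within-group residual degrees of freedom
$\mathrm{df} = n - 2 - (g_\mathrm{crew} - 1)$. The reference distribution
matters here: with $n = 24$ a normal (z) reference is roughly 30× too liberal
at the $10^{-6}$-scale thresholds the Bonferroni scheme produces, and would
generate spurious "significant" associations in every null data set; the $t$
reference restores family-wise control (verified by simulation in the test
suite). With as few as 4 crew members the REML crew variance frequently hits
the zero boundary; those fits (and any non-converged ones) fall back to
ordinary least squares, flagged `method = "ols"` in the output, whose exact
$t(n-2)$ test is the correct degenerate-case inference.

**Multiplicity.** The Bonferroni family of one test is
(microbes in the family) × (DEGs in the cell type); `bonferroni_threshold()`
returns $\alpha$ divided by that product. Results are classified at three
nested stringency levels — non-zero LASSO coefficient, nominal $p < 0.05$,
and Bonferroni ($p$ below $0.2$ or $0.05$ over the family size) — and
summarized two ways: `tally_positive_significant()` counts positive
Bonferroni-significant associations per cell type, and `rank_genes()` orders
genes by (number of Bonferroni < 0.2 findings, number of nominal findings),
lexicographic gene id as tie-break, reporting at most ten genes per cell type
and dropping genes with no nominal association.

## Abundance transforms

Microbial abundances are compositional and zero-heavy. Before any log-based
transform, `add_pseudocount()` adds the smallest strictly positive entry of
the *whole matrix* to every cell — interpreting "smallest abundance value" as
smallest positive, since a literal minimum of zero would leave zeros
undefined under the log. Two transforms are then available and carried in
parallel through the pipeline, tagged in every result row:

* `log`: elementwise natural log;
* `clr`: centered log-ratio, $\ln x_i - \overline{\ln x}$ per sample
  (the compositional convention; the per-sample axis is a package choice —
  the alternative per-feature centering is not implemented). CLR columns sum
  to zero and the transform is invariant to per-sample rescaling.

Gene expression is centered and scaled with the unbiased $(n-1)$ sample SD,
documented so numerical oracles match exactly. The natural log base is a
convention only: base changes rescale the predictors and therefore never
change the LASSO support or mixed-model p-values.

## Randomized-data null

`randomize_and_compare()` reruns the full two-stage pipeline on a cohort
whose expression sample columns have been permuted (seeded), breaking the
gene–microbe pairing while preserving both marginal distributions, and
reports counts and pair-identity overlap at the three stringency levels. The
instructive property is that randomized data yields a *comparable number* of
candidates and nominal associations — the screen+refit procedure reuses the
same data twice and is therefore optimistically biased at fixed stringency —
but essentially *zero overlap* with the real associations at the Bonferroni
level. A per-gene value shuffle is available as an alternative scheme
(`scheme = "shuffle_genes"`).

## Enrichment statistics

* `fisher_overlap()`: 2×2 Fisher's exact test for the overlap of two gene
  sets in a finite universe; one-sided (enrichment) by default, equal to the
  hypergeometric upper tail.
* `ora()`: hypergeometric over-representation of a query set across an
  annotation collection, BH-adjusted.
* `preranked_gsea()`: weighted Kolmogorov–Smirnov running-sum enrichment
  score (weight exponent 1, configurable) with a gene-label permutation
  null. The one-sided p-value is computed among same-signed permutation
  scores and NES normalizes by the mean magnitude of same-signed permutation
  scores; sets with no same-signed permutations get an undefined NES and are
  excluded from the BH family. For small rankings `exact = TRUE` replaces
  sampling with complete enumeration of all same-size subsets, making the
  p-value exact — this is also how the implementation is validated. Ties are
  counted with a $10^{-12}$ tolerance so that subsets with mathematically
  equal scores are not split by floating-point summation order.
* `rank_metric()`: the three ranking conventions used for preranked
  analyses — $-\log_{10}(p) \cdot \mathrm{sign}(\mathrm{lfc})$,
  $\mathrm{lfc} \cdot (-\log_{10} p)$, or a pass-through statistic — none
  privileged; callers choose per analysis.
* `pathway_score()` and `score_correlation()`: the scalar profile
  $-\log_{10}(\mathrm{padj}) \cdot \mathrm{sign}(\mathrm{NES})$ and its
  Pearson correlation / OLS slope between two studies over matched pathways.
* `compound_enrichment()`: for each compound in a compound→gene interactome,
  a hypergeometric upper-tail test of whether its partners over-represent a
  DEG list within the *universal gene set* (all genes interacting with at
  least one compound), Bonferroni-adjusted over the compounds tested.
  Classes (drugs, food compounds, LINCS perturbagens) form separate
  Bonferroni families in `screen_compound_classes()`, which also returns the
  deduplicated union of significant compounds with provenance. Edge
  confidence scores, where present, are ignored by the statistic.

## The synthetic cohort generator

`cohort_config()` fixes the study conditions; `generate_cohort()` is a pure
function of it (identical seeds give bit-identical cohorts). Defaults mirror
the motivating design: 4 crew × 6 timepoints (first half pre-flight), nine
immune cell types, five microbial families (bacterial phylum/genus/species,
viral phylum/genus).

* **Microbial counts** are rounded log-normal draws (per-feature mean
  abundance uniform on log scale between 10 and 10⁴ counts, log-SD 1) with a
  configurable fraction (default 0.3) forced to zero — matching zero-heavy
  compositional profiles without modeling read depth.
* **Expression** is baseline (uniform 4–8) + per-(gene, crew) Gaussian
  intercepts (SD `crew_sd`, default 0.5) + Gaussian noise (SD `noise_sd`,
  default 1), all in arbitrary linear units.
* **Planted effects** add `effect_size` × sign × $z(\log(\mathrm{microbe} +
  \mathrm{pc}))$ to the planted gene — i.e. the effect lives on the same
  transformed scale the models fit on, so `effect_size` is an SD-per-SD
  slope. Planted pairs default to one cell type (CD14 monocytes, the
  compartment where such associations concentrate) and one family
  (bacterial species), with positive signs.
* **DEG structure**: planted genes carry a pre/post shift (log2FC 0.5 by
  default) in *every* cell type — a conserved response — while an additional
  `frac_extra_degs` (default 15%) of genes are shifted per cell type
  independently. DEG tables therefore have realistic sizes, planted genes
  pass the DEG filter that gates the screen, and DEG sets overlap partially
  across cell types, which is what the overlap statistics are for.
* Body sites are collapsed to one site per family; multi-site cohorts can be
  emulated by generating several cohorts.

What the generator does *not* emulate: sequencing depth and read-level
noise, count overdispersion in expression (pseudo-bulk is modeled as
Gaussian), taxonomic correlation structure between ranks, temporal
autocorrelation beyond the crew intercept, and microbiome compositional
dependence between features. Passing tests therefore demonstrate that the
*procedures* behave as specified under the assumed model, not that the model
captures every property of real mission data.

`generate_interactome()` and `generate_pathways()` plant, respectively,
DEG-enriched compounds (a planted compound draws ~90% of its partners from
the DEG list) and ranking-concordant gene sets (drawn from the top fraction
of a supplied ranking), recording the planted ids as ground truth.

## Numerical and design choices

* CV for the screen runs a lean fold loop over the glmnet lambda path
  (grouped-fold MSE, as `cv.glmnet(grouped = TRUE)`); curves agree with
  `cv.glmnet` in shape and minimum but not pointwise, since `cv.glmnet`
  refits folds on their own paths.
* Mixed models use lme4's modular API with parameters read off the optimized
  deviance function; a unit test asserts exact agreement with stock `lmer`.
* Zero-variance microbial features are dropped from screens (logged);
  constant genes are skipped with a warning; duplicate predictor columns are
  left to the deterministic solver — determinism, not uniqueness of the
  selected support, is the contract.
* `p = 0` inputs to ranking metrics are clamped to the smallest positive
  double with a warning.
* All randomness flows from explicit integer seeds; the pipeline driver
  derives stage seeds from one top-level seed and two runs from the same
  configuration are hash-identical.

## Problem sizes used in the validation suite

The test suite and acceptance script exercise: oracle equivalence of all
hypergeometric tests on 200 random instances with universes up to 30 genes;
exact GSEA enumeration on an 8-gene ranking with a 3-gene set (all 56
subsets); mixed-model calibration on 2000 null replicates (4 crew × 6
timepoints, crew SD 0.5); family-wise control on seeded global-null cohorts
of 200 genes × 50 microbes; planted-signal recovery at effect size 1.0,
noise SD 0.5, 8 crew members; and real-vs-randomized overlap on planted
cohorts of 40 genes × 25 microbes. These sizes were chosen to make each
property measurable with stable statistics while keeping a full validation
run on a laptop-scale machine.

## Known limitations

* Stage-2 p-values on screened pairs are conditional on selection and
  therefore optimistic at fixed stringency; the Bonferroni scheme divides by
  the full family size precisely to compensate, and the randomized-data
  comparison is the empirical check. Post-selection-corrected inference is
  out of scope.
* With 4 crew members the crew variance is weakly identified; the OLS
  fallback is reported transparently rather than hidden behind a boundary
  REML fit.
* The GSEA implementation targets the preranked, gene-permutation analysis
  at these scales; it is not a byte-level clone of any named tool and does
  not implement multilevel/adaptive permutation p-values.
* Timepoint enters only through the pre/post DEG contrast; it is not a
  covariate of the association model, matching the stated model form.
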