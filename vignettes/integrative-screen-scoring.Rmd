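---
title: "Integrative scoring of CRISPR immune screens and ICB cohorts: methods"
author: "icbscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative scoring of CRISPR immune screens and ICB cohorts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icbscreen)
```

## The problem

Pooled CRISPR immune screens measure how knocking out each gene in a tumor
cell changes its survival under immune attack: guides targeting
immune-*resistance* genes deplete when T cells are present (their loss
sensitizes the cell), while guides targeting immune-*sensitizing* genes
enrich. A screen alone, however, ranks genes by cell-culture behavior; the
clinically interesting candidates are those whose expression also tracks
patient outcome under immune checkpoint blockade (ICB). `icbscreen`
implements a staged integration of the two evidence streams:

1. **In vitro screen** (control vs two T-cell effector-to-target ratios):
   guide log2 fold changes, a robust per-gene summary, significance, and a
   signed 0–4 *in vitro score*.
2. **Patient score**: per-cohort gene effects (expression fold change
   between responders and nonresponders, or −log2 hazard ratio), averaged
   across cohorts and rescaled to a common |P90| = 2 scale.
3. **Merged score** = patient score + in vitro score; the top 100 positive
   and top 400 negative merged scores define an ICB sublibrary.
4. **In vivo screen** on that sublibrary (NSG / mock / anti-PD-1 mice, the
   treated mice split into responders and nonresponders at the median tumor
   volume): a modified DrugZ gene statistic.
5. **Total score** = normalized merged score + the matching normalized
   DrugZ score (responder branch for negative merged scores, nonresponder
   branch otherwise), ranked ascending — the most negative totals are the
   strongest resistance candidates.
6. **Concordance** of in vivo directions with the in vitro screen or with
   expression–survival associations, tested against 50% with an exact
   binomial test.

Every stage runs on synthetic data with planted ground truth, so the whole
chain is testable without any external accession.

## Stage models and conventions

### Normalization and guide fold changes

Counts are scaled either to a common library size of 10^7 reads (`total`,
the convention for genome-wide libraries) or so that each sample's median
safe-targeting-guide count equals the pooled safe-guide grand median
(`safe_guides`). The safe-guide method exists because the in vivo
sublibrary is deliberately skewed toward depleted genes: total-count
scaling would absorb real signal into the size factor, whereas safe guides
cut non-functional loci and are selection-neutral by construction.

Guide fold changes use replicate-averaged normalized abundances with a
pseudocount of 5 on both sides (the published DrugZ default; it bounds the
statistic for dropout guides):
`log2fc = log2((mean_t + 5) / (mean_c + 5))`. The pseudocount makes every
value finite and the statistic antisymmetric under arm swap.

### Second-best gene summary and significance

The per-gene summary is the log2 fold change of the *second-most-extreme*
guide in the gene's dominant direction (the sign of the median guide LFC;
median ties resolve toward depletion, matching the screen's emphasis on
resistance genes). Requiring two concordant guides makes the summary robust
to a single outlier guide; single-guide genes report their only value.

Significance is a permutation test: the gene's mean guide LFC against
`n_perm` same-size draws from the full guide population, with
`p = (1 + #{perm ≤ obs}) / (n_perm + 1)` for depletion and the mirror for
enrichment. This is a deliberate, documented stand-in for count-model gene
tests (e.g. MAGeCK's negative-binomial/RRA machinery, an external published
tool outside this package's scope); the output carries
`test = "permutation-mean-lfc"` metadata so downstream consumers can tell
which test produced the p-values. Hits require both
`|second-best LFC| > 0.25` and `p < 0.05`.

### The 0–4 in vitro score

The exact scoring rubric behind the published 0–4 range is not specified in
text form, so the package defines one (`rubric = "default-v1"`, recorded in
the output and swappable): per contrast, 2 points for a full hit, 1 point
when only the LFC cutoff is exceeded, 0 otherwise, signed by direction;
contrasts that disagree contribute only the dominant direction (larger
summed magnitude, ties toward depletion). The rubric is monotone in
evidence and attains ±4 exactly for a double full hit — the acceptance
suite enumerates all outcome combinations to verify the bound.

### Patient score

Per cohort, response-mode effects are
`log2((mean TPM_responders + 1) / (mean TPM_nonresponders + 1))` and
survival-mode effects are `−log2(HR)` from an upper-quartile-vs-rest
split, so negative effects always mean "higher expression tracks
resistance/worse outcome". The cross-cohort patient score is the weighted
mean of available effects. Cohort size `n` is the default weight — the
natural precision proxy when per-cohort variances are unavailable —
with equal weighting exposed as an option. Genes missing from a cohort
simply average over the cohorts that cover them; no imputation.

The hazard ratio uses the log-rank observed/expected ratio
`(O1/E1)/(O2/E2)` (group 1 = top-25% expressors) rather than an iterative
Cox fit: it is closed-form, monotone in the evidence, and adequate for
ranking. It is known to attenuate slightly toward 1 for strong effects —
the recovery suite checks that a true HR of 2.0 at n = 400 is estimated
within [1.6, 2.5] in the median over 100 simulations.

### |P90| = 2 normalization

`normalize_q90` rescales a score vector by `target / |P90|` (90th
percentile, linear interpolation — quantile type 7 everywhere in the
package, frozen by tests). It puts expression fold changes, hazard ratios
and screen z-scores on one additive scale before summation, is idempotent
and positively homogeneous, and errors on the degenerate P90 = 0 input.
Note it is *not* odd under negating the score vector: the factor uses the
absolute 90th percentile of the vector as given, and P90(−x) = −Q10(x).

### Modified DrugZ

Guide z-scores follow DrugZ: per replicate pair, fold change with
pseudocount 5; guides ranked by control abundance; the empirical-Bayes SD
of each guide is the SD of fold changes within ±500 ranks (the published
DrugZ window, clipped at boundaries, shrunk with a warning for small
libraries); `z = fc / EB-SD`. Two modifications reflect the skewed
sublibrary: (i) counts are safe-guide-normalized, and (ii) the reported
gene score is *not* z-normalized — `gene_score = sumZ / n`, the mean guide
z, keeping the fold-change scale — because re-standardizing a library in
which 80% of genes were selected for depletion would recenter real signal.
The statement "final fold changes were not z-normalized" admits more than
one reading; this package interprets it as dropping the `sumZ/√n`
renormalization from the reported score while p-values retain the
classical normal null on `sumZ/√n` (lower tail = depletion), with BH-FDR
within each tail. Both modes are exposed (`z_normalize_final`) and the
chosen one is recorded in the output metadata; they rank genes identically
for a fixed guide count.

Two small calibration caveats, both visible in the null suites and worth
knowing when reading z-scores: the safe-median scale factor is itself
estimated, so each contrast carries a shared offset of order
`1/√n_safe` that vanishes only on average over screens; and the EB window
mixes guides of unequal count noise, inflating the z SD a few percent above
1 and the nominal 5% tail slightly. The acceptance suite therefore checks
centering and type-I error as averages over ten seeded null screens.

### Responder stratification and total score

Anti-PD-1 mice below the median tumor volume are responders; at or above,
nonresponders — ties deliberately fall to the nonresponder side so the
responder arm is never inflated. The total score adds to each gene's
normalized merged score the normalized responder DrugZ score when the
merged score is negative (a resistance candidate should also deplete where
immunity is effective) and the nonresponder score when positive. A merged
score of exactly zero is routed to the nonresponder branch — the
underlying rule only specifies strict signs, so the boundary case needed a
convention; it is configurable (`zero_branch`) and logged. All three
inputs must arrive already normalized to |P90| = 2; `total_score` asserts
this rather than silently renormalizing, so the normalization step has
exactly one owner. Ranking is ascending: rank 1 is the strongest
resistance candidate.

### Concordance

A gene is concordant when the in vivo direction matches the reference:
depleted with a resistance reference (survival HR > 1, or an in vitro
depleted call), enriched with a sensitizing one. Directionless reference
genes (HR exactly 1, `ns` calls) are excluded and counted rather than
guessed. The rate is tested against 0.5 with the two-sided exact binomial
test (sum of tail probabilities not exceeding the observed point mass);
a brute-force pmf enumeration for n ≤ 20 serves as the oracle in tests.

### Gene sets, enrichment, TE and Kozak categories

Responder/nonresponder gene sets are the top/bottom `k = 100` genes by
log2 fold change with lexicographic tie-breaks. Preranked enrichment is
the classic weighted Kolmogorov–Smirnov running sum (member increments
∝ |metric|^p with p = 1, uniform decrements); significance comes from
gene-label permutations with `NES = ES / mean(|perm ES|)` over same-sign
permutations. This label-permutation null is implemented in-package
because it is the contract the scores are defined by; the independent
`fgsea` implementation is used in the test suite only as a cross-check of
ES values.

Translation efficiency is `log2(fc_ribo / fc_rna)` on strictly positive
linear-scale fold changes. Kozak categories from a transcript's strength
multiset: ≥2 strong → Supreme, exactly 1 strong → Strong, else ≥1
moderate → Moderate, else No. Categories are compared against the `No`
baseline with a two-sided rank-sum test; single-record categories report
p = 1 with a warning instead of failing.

## The synthetic-data generator

The generator exists so that every downstream stage has a testable input
with known truth. What it emulates:

- **Library structure**: genes of interest expected to deplete or enrich,
  essential positive controls (negative effect in every expanded arm), and
  single safe-targeting guides under a reserved non-genic label.
- **Counts**: gamma-Poisson (negative binomial) around
  `depth × relative abundance`, with a log-normal plasmid-pool skew
  (SD 0.5 on the log scale) and a single user-set dispersion. A treated
  arm multiplies a guide's reference abundance by `2^effect`.
- **In vivo bottleneck**: before selection, each mouse's lineage pool
  (default 100 lineages per guide) is binomially subsampled at the
  engraftment fraction — engraftment loss being the dominant extra noise
  source in transplantation screens. The bottleneck demonstrably inflates
  replicate-to-replicate variance in the test suite.
- **Cohorts**: log-normal expression; response probability follows a
  logistic link on planted genes' standardized log-expression; survival is
  exponential with a log-linear hazard and independent uniform censoring
  over [0, 2 × median survival] (no censoring mechanism is published for
  the real cohorts, so the simplest independent one is used).
- **TE tables**: per-category TE shifts with SD 0.5 around the planted
  mean, and strength multisets consistent with each category.

Default study conditions (`simulate_pipeline_inputs`): 400 depletion-class
+ 100 enrichment-class + 30 essential genes, 5 guides per gene, 100 safe
guides — mirroring the published sublibrary composition — with planted
effects of ±2 log2 units in the strong-selection arms, a quarter of that
in the nonresponder arm, sequencing depth 5 × 10^6, dispersion 0.2,
engraftment bottleneck 0.2, and three cohorts of 120–150 patients with
per-gene outcome effects of ±0.12 per SD of log-expression. These are
chosen once as realistic for a well-powered screen plus mid-sized ICB
cohorts and are not revisited per test.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: PCR/sequencing error and GC bias,
guide-efficiency heterogeneity within a gene, off-target cutting,
copy-number artifacts, batch structure between cohorts, non-proportional
hazards, and correlated gene expression (each gene is simulated
independently, so cohort effect estimates on real co-expressed genes will
be more correlated than here).

All randomness flows from explicit integer seeds; the generators save and
restore the caller's RNG state, and identical seeds give bit-identical
outputs.

## Numerical choices and degenerate inputs

- Quantiles: linear interpolation (type 7) everywhere.
- Ties: lexicographic by gene/patient id in all top-k selections; median
  tumor-volume ties → nonresponder; second-best dominant-direction ties →
  depletion.
- All-zero samples, empty gene intersections, P90 = 0, unknown labels and
  missing columns raise errors naming the offender; genes dropped at merge
  or total-score stages are counted in messages, never silent.
- Permutation and exact-binomial p-values are bounded away from 0 by
  construction (`(1 + k)/(n + 1)` and the point mass respectively).
- EB-SD windows with zero variance fall back to z = 0 for the affected
  guides rather than dividing by zero.

## Problem sizes used by the test suite

The suite's simulation scales are package choices balancing resolution
against runtime: null calibrations use 10,000-guide screens (ten seeds,
averaged); the permutation oracle enumerates an 8-guide library; the
enrichment oracle enumerates all 1,140 placements of a 3-gene set in 20;
HR recovery uses 100 cohorts of 400 patients; end-to-end recovery runs 50
seeded pipelines with 20 planted resistance genes among 1,000 (five guides
each) and requires the planted genes to occupy the bottom 5% of total-score
ranks. The full suite and the acceptance script each run in minutes on a
single CPU.

## Known limitations

- The permutation gene test is a stand-in, not a reimplementation of the
  published count-model test; p-values agree in calibration but not
  numerically with MAGeCK's.
- The in vitro scoring rubric is this package's explicit default, not a
  transcription of the unpublished criteria figure.
- The O/E hazard ratio attenuates for strong effects and small event
  counts; it is a ranking statistic, not an effect estimate.
- DrugZ z-scores inherit a small shared offset from the safe-median scale
  factor and mild variance inflation from window heterogeneity (see above).
- The in vivo simulator sequences the full pool rather than re-cloning the
  selected sublibrary; the pipeline subsets scores to the sublibrary at the
  total-score stage, which preserves the integration logic while keeping
  the simulated study single-pass.

## A worked example

```{r example, eval = FALSE}
library(icbscreen)

inputs <- simulate_pipeline_inputs(seed = 1)
res <- pipeline_compute(inputs, pipeline_params(seed = 1, n_perm = 300))

head(res$total)          # ranked candidates; rank 1 = strongest resistance
res$concordance          # per-group rates and exact binomial p-values
```

The same run is available from the shell via the wrapper in
`inst/scripts/immunoscreen.R` with a YAML configuration, and
`run_pipeline()` writes every stage table plus a `manifest.json` recording
parameters, seeds and stage versions for provenance.
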