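---
title: "Methods: injury-rescue differential expression and call-back classification"
author: "CallbackSeq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: injury-rescue differential expression and call-back classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CallbackSeq)
```

## The problem

A common pharmacological screen compares three conditions: a normal control
(`NC`), a chemically injured model (here `ADM`, adriamycin-injured mpc5
podocytes), and one or more candidate treatments applied on top of the
injury (`W1CC`, `W5CC`). A treatment is interesting when it *calls back*
genes: expression that the injury pushed away from normal is pushed back in
the opposite direction by the treatment. CallbackSeq implements the full
desk-scale analysis for this design: normalization and FPKM, per-contrast
negative-binomial testing, the three-level call-back classification,
cross-treatment intersections, gene-set over-representation, and 2^-ddCt
qPCR concordance — together with a synthetic-data generator carrying known
ground truth, so the whole chain can be validated end to end.

## The count model

Counts are modelled as negative binomial with mean `mu = s_j * q_{g,arm}`
and variance `mu + alpha * mu^2`, where `s_j` is a per-sample depth factor
and `alpha` the gene's dispersion. Depth factors are estimated by
median-of-ratios (each sample's median ratio to the per-gene geometric
mean, over genes positive in all samples), rescaled to geometric mean 1.
When no gene is expressed in every sample the estimator refuses and offers
an explicit total-count fallback rather than silently switching.

Dispersion is estimated per gene by the method of moments on normalized
counts, `alpha_hat = max(0, (s^2 - m) / m^2)`, pooled across the two
contrast arms with replicate-count weights. Because per-gene estimates are
extremely noisy at 3 replicates, a mean-dispersion trend
`alpha(mu) = a0 + a1/mu` is fitted across all genes by least squares and
the reported value is `max(gene estimate, trend, 1e-8)`. Taking the
maximum is deliberately conservative: genes whose raw estimate is an
underestimate are lifted to the trend, while apparent high-dispersion genes
keep their own estimate. The floor of `1e-8` only guards degenerate
all-constant genes.

Testing uses a Wald statistic on the log2 fold change
`log2((q1 + pc) / (q0 + pc))` with pseudo-count `pc = 0.5` on the
normalized-count scale, the standard error coming from the delta method
with per-arm NB variances. This choice (rather than an exact conditional
test) keeps the statistic transparent and directly checkable against
independent oracles; on simulated data its gene ranking agrees closely
with DESeq2's Wald test, and its type-I error under a pure null
(`alpha = 0.1`, 3 vs 3) sits near 0.04 at nominal 0.05 — slightly
conservative, as expected from the max-shrinkage rule. Genes with zero
counts in every sample of both arms are untestable: they get missing
p-values and are excluded from the Benjamini-Hochberg ranking, so the BH
`m` reflects tested genes only. No other independent filtering is applied
before FDR adjustment.

DEGs are genes with `FDR < 0.05` and `|log2FC| >= 0.5` (the fold-change
boundary is inclusive for the DEG rule).

## The call-back classification

For each treatment, two DE tables are compared per gene: the *model*
contrast (ADM vs NC) and the *treatment* contrast (treatment vs ADM).

* **Level 1** — `|log2FC| > 0.5` and `FDR < 0.05` in *both* contrasts,
  with opposite signs: a strong call-back.
* **Level 2** — otherwise, the same pattern at the `0.1` threshold: a weak
  call-back.
* **Level 3** — otherwise, model contrast non-significant (`FDR > 0.05`)
  but `|log2FC|_treat > 0.1` with `FDR_treat < 0.05`: a treatment-specific
  change with no injury effect.
* **none** — everything else, including same-direction changes.

Genes suppressed by injury and restored upward (`lfc_model < 0`,
`lfc_treat > 0`) are *up-called-back*; the inverse pattern is
*down-called-back*; level-3 genes are *treatment-up/down* by the sign of
the treatment fold change.

Design choices worth stating explicitly:

* Levels are assigned **mutually exclusively** in order 1 → 2 → 3, so
  per-level counts form disjoint buckets (the slash-separated triples in
  the intersection reports partition the classified genes).
* Level thresholds are **strict** (`>`), matching the classification rules
  as published, even though the DEG rule uses `>=`. Boundary cases are
  pinned in the tests.
* Level 3 requires `|log2FC|_treat > 0.1`, not merely a nonzero change.
* Genes untestable in either contrast are classified `none`, never
  level 3: "unaltered after injury" requires a tested, non-significant
  result, not a missing one.

Cross-treatment reporting intersects, per level and direction class, the
call-back sets of all treatments (shared genes and per-treatment unique
genes), and an UpSet-style table gives exact exclusive intersection sizes
over any family of DEG lists.

## Gene-set enrichment

Over-representation is tested with the exact hypergeometric upper tail
`P(X >= k)` for a term of size `K` in a universe of size `N` against a
query of size `n` with overlap `k`; terms with no overlap report `p = 1`.
The universe defaults to the genes tested in the relevant DE contrast that
are annotated to at least one term — the standard over-representation
background; it is an explicit argument, not a hidden constant. GO-style
output uses Bonferroni correction `min(1, m p)` and pathway-style output
BH, both at threshold 0.05 (inclusive), and both raw and corrected
p-values are always emitted. `m` counts the testable terms — those with
`K >= 1` in the universe — so untestable terms neither dilute nor inflate
the correction. The *rich factor* `k / K` is reported for bubble-plot
style summaries. Annotation arrives as GMT; there is no live ontology
retrieval or term-hierarchy propagation.

## qPCR relative expression and concordance

The 2^-ddCt computation pairs target and reference Ct **within the same
sample** (`dCt = Ct_target - Ct_ref`), subtracts the gene's mean
calibrator-arm dCt (calibrator defaults to `NC`), and reports the per-arm
fold as `2^(-mean ddCt)` — the geometric-mean convention, which makes the
calibrator arm's fold exactly 1 and makes the fold invariant to any
per-sample Ct offset. Amplification efficiency is fixed at 2 per cycle; no
efficiency correction is attempted. Concordance with RNA-seq pairs
`-ddCt` (qPCR log2 fold) with the DE log2FC over genes and contrasts —
differences of ddCt values give treatment-vs-model contrasts — and reports
the Pearson correlation, sign agreement, and the correlation-test p-value
descriptively. qPCR replicates are treated as arm-level summaries, not
paired with specific RNA-seq libraries.

## The synthetic-data generator

`simulateCounts()` emulates the 4-arm design (NC, ADM, W1CC, W5CC; 3
replicates each) with negative-binomial counts and full ground truth. Its
defaults define the reference simulation conditions used throughout the
package's validation:

| parameter | default | rationale |
|---|---|---|
| genes | 2000 | enough for stable trend fitting and FDR behaviour at desk scale |
| replicates per arm | 3 | the design being emulated |
| baseline log2 mean range | (3, 13) | log-uniform means from ~8 to ~8000 counts, a realistic bulk dynamic range after low-count filtering |
| dispersion trend | `alpha(mu) = 0.05 + 1/mu` | typical cell-line biological variability with shot-noise inflation at low counts |
| injury effect | 1.5 log2 units | a strong, clearly detectable insult |
| rescue fraction | 1 (full), 0.3 for `partial_restored` | full call-back for the restored archetypes; the partial archetype exercises the level-2-but-not-level-1 band (rebound without reaching normal) |
| archetype mix | 15/15/10/10/10/40 % | a minority of treatment-only genes and a large null background |
| library-size log-sd | 0.1 | ~10 % depth variation, typical of matched libraries |
| Ct base / noise | 20 cycles / 0.2 cycles | conventional qPCR operating point and replicate noise |

Each gene draws a baseline mean log-uniformly, applies its archetype's true
log2 effects per arm, and draws counts `NB(s_j * q, alpha(q))` with
per-sample lognormal depth factors that are exposed in `colData` so
size-factor recovery is itself testable. The truth table records the
archetype, the true effects, and the call-back level a perfect classifier
would assign (`expectedCallbackLevel()`, where statistical significance is
identified with a nonzero true effect). All randomness flows through
explicit seeds via `withr::with_seed`; no global RNG state is touched, and
identical configurations are bit-reproducible.

The matching generators produce GMT gene sets (a flagged fraction
oversamples restored-archetype genes at 80 %, so enrichment rankings can be
validated) and qPCR Ct tables that invert the 2^-ddCt model exactly at
zero noise. The reference gene must have the null archetype — a non-null
normalizer is rejected as invalid.

**What the simulation does and does not show.** It reproduces the
mean-variance structure the tests assume, library-size variation, and the
injury/rescue effect geometry — so passing the recovery and calibration
checks demonstrates internal consistency of the estimator, test, and
classifier. It does not emulate alignment artefacts, gene-length biases
within a sample, correlated gene modules, outlier replicates, or
batch effects; conclusions about robustness to those must come from real
data. Headline counts from any particular real dataset (numbers of DEGs or
enriched processes) depend on that dataset and are not targets of the
simulation.

## Numerical choices and degenerate inputs

* Dispersion floor `1e-8`; trend coefficients clamped to `a0 >= floor`,
  `a1 >= 0`.
* `p = 1` exactly when both arm means are equal (z = 0), and `z` is set to
  0 when the standard error degenerates to 0.
* PCA components are sign-canonicalized (largest-magnitude loading made
  positive) so coordinates are reproducible across BLAS implementations.
* Replicate correlation is Pearson on `log2(x + 1)`; zero-variance samples
  yield `NA` with a warning rather than an error.
* FPKM uses the in-matrix column total as "mapped fragments": at desk
  scale the alignment-level total is unavailable, and this divergence is
  intentional and documented.
* The pipeline manifest contains only deterministic content (config echo,
  version, seed, row counts); stage timings go to the message stream so
  that rerunning with the same seed reproduces every output file
  byte-identically.

## Validation problem sizes

The shipped test suite validates the classifier against a straight-line
rule-by-rule oracle on 1000 random gene pairs; recovery of fully rescued
genes (>= 90 % of restored-archetype genes with baseline mean >= 50
classified level 1 or 2, <= 10 % of null genes receiving any level) over 5
seeded 2000-gene simulations; type-I error of the Wald test within
0.05 ± 0.02 over 5 seeded null simulations; exactness of the
hypergeometric p against full combinatorial enumeration for every
configuration with `N <= 12`; BH against the textbook step-up definition
on 1000 random vectors; exact inversion of noise-free Ct tables; the
within-arm correlation property (> 0.98 at low dispersion); and byte-level
determinism of the full pipeline. These sizes keep the suite fast while
leaving each check statistically meaningful.

## Known limitations

* Two-group contrasts only; no GLM with covariates or batch terms.
* The Wald test with moment dispersions is conservative for
  high-dispersion genes; exact or likelihood-based tests would gain some
  power at n = 3.
* Partially rescued genes (0.45 log2 rescue) are usually *not* detected at
  3 replicates — by design they sit near the power boundary of the level-2
  band.
* Enrichment treats gene sets as flat lists; no ontology hierarchy.
* qPCR concordance assumes perfect doubling per cycle.
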