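---
title: "AP-MS interactome discovery with apmsEnrich: models, parameters and design choices"
author: "apmsEnrich authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AP-MS interactome discovery with apmsEnrich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmsEnrich)
```

## The analysis problem

Affinity-purification mass spectrometry (AP-MS) asks which proteins a bait
captures from a lysate beyond what sticks non-specifically to the affinity
matrix. The data arrive as a label-free quantification (LFQ) table — one
MaxLFQ intensity per protein per sample, with zeros where a protein was not
detected — for a set of bait pulldowns and matched controls (GST alone for
a GST-tagged bait; IgG for a co-immunoprecipitation). Three statistical
features dominate the analysis and drive every design choice in this
package:

1. **Missingness is informative.** Low-abundance proteins preferentially
   fall below the detection limit, so missing values are
   missing-not-at-random (MNAR) and cannot be imputed from row or column
   means without biasing fold changes toward zero.
2. **Few replicates, many proteins.** With typically six replicates per
   condition, per-protein variance estimates are noisy; empirical-Bayes
   moderation borrows strength across proteins.
3. **Interaction evidence is graded, not binary.** A pulldown candidate is
   more believable when an orthogonal co-IP detects it consistently and
   enriches it over the IgG control, which the credibility tiers encode.

## Data model

`ProteinQuantTable` extends `SummarizedExperiment` with two assays:
`intensity` and `missing`. The mask records the *original* detection
pattern and is deliberately preserved through imputation, so detection
rates, per-sample detection counts and overlap partitions are always
computed on pre-imputation missingness, never on imputed values.
`StudyDesign` maps samples to six recognised conditions and carries the
replicate index and, for the nucleotide-loading experiment, a `pair_id`
linking the GTP&gamma;S- and GDP&beta;S-loaded pulldowns derived from the
same lysate portion.

## The preprocessing chain

The default order is **log2 &rarr; filter &rarr; impute &rarr; normalize**.
Filtering before imputation ensures that the imputation model only sees
proteins with a defensible amount of signal; imputing before normalization
lets the calibration work on complete columns. The reverse
impute/normalize order is available by calling the steps directly.

**Detection filter.** A protein is kept when its non-missing fraction is at
least `minFracGlobal` (default 0) overall *and* at least
`minFracOneCondition` (default 0.60) in at least one condition. Both
comparisons are inclusive: a protein detected in exactly 60% of one
condition's samples — e.g. 4 of 6 pulldowns — survives. The filter is
idempotent and insensitive to imputation because it reads the mask.

**MNAR imputation.** Missing cells in sample $j$ are replaced by draws from

$$N\!\left(\mu_j - 1.8\,\sigma_j,\; (0.3\,\sigma_j)^2\right),$$

where $\mu_j$ and $\sigma_j$ are the mean and standard deviation of the
sample's observed log2 intensities. The downward shift (1.8 SD) places
imputed values where censored proteins plausibly live; the narrow width
(0.3 SD) keeps them from contaminating the observed variance structure.
Both are tunable (`shiftSd`, `widthSd`). Statistics are per sample by
default — each run has its own detection limit — with a pooled option
(`perSample = FALSE`). The draw is seed-reproducible and never touches an
observed cell. For a sample with $\mu = 25$, $\sigma = 2$ the imputed
distribution is $N(21.4, 0.6^2)$, which the test suite verifies by Monte
Carlo.

**Normalization.** Three methods, recorded in provenance:

* `vsn_like` (default): each sample's log2 vector is calibrated onto a
  pooled reference (the mean of the samples' sorted vectors, i.e.
  rank-matched quantiles) by a robust scale-and-shift fitted with
  median/IQR, then passed through the generalized-log guard
  $\operatorname{asinh}(2^y/2)/\ln 2$, which is indistinguishable from the
  identity for intensities well above zero. The map is monotone per
  sample, so ranks survive, constant between-sample offsets cancel
  exactly, and log2 fold changes of well-measured proteins are essentially
  unchanged. We deliberately calibrate on the log2 scale: affine fits on
  raw linear intensities are unstable for lognormal LFQ data because an
  additive offset comparable to the median can push low-intensity cells
  negative.
* `median_center`: subtract each sample's median; the fallback when the
  rank-matching assumption (mostly shared protein complement) is doubtful.
* `none`: identity, for externally normalized tables.

**Row z-scores** (for heatmaps) use the population SD by convention
(divide by $n$), with the sample-SD convention available — heatmap tooling
differs, so the choice is explicit and documented.

## Differential enrichment

For conditions $a$ (bait) and $b$ (control) with $n_a, n_b$ replicates,
the per-protein two-group model gives $\widehat{\text{lfc}} = \bar y_a -
\bar y_b$ and pooled variance $s^2$ on $d = n_a + n_b - 2$ df. The
variance prior $s^2 \sim s_0^2 F(d, d_0)$ is fitted by matching the first
two moments of $\log s^2$ using digamma/trigamma inversion; when the
dispersion of $\log s^2$ does not exceed its sampling floor
$\psi'(d/2)$, $d_0 = \infty$ and $s_0^2$ is the mean variance. The
moderated statistic is

$$\tilde s^2 = \frac{d_0 s_0^2 + d s^2}{d_0 + d}, \qquad
  t = \frac{\widehat{\text{lfc}}}{\tilde s \sqrt{1/n_a + 1/n_b}}$$

on $d + d_0$ df ($d_0 = 0$ recovers the ordinary t; $d_0 = \infty$ a
z-like statistic). The test suite cross-checks the whole chain against an
independent reference implementation of the moderated-t framework to
1e-6. Benjamini–Hochberg adjustment controls the FDR, and candidates are
selected at `adj_p < 0.01` and `log2fc >= 2` — one-sided toward the bait
by default, since the biological question is what the bait captures; the
symmetric mode exists for volcano plots.

## Co-IP credibility tiers

Each pulldown candidate is re-examined in the co-IP experiment:

* **Confidence** from the detection rate across co-IP bait samples:
  `high` above 80%, `moderate` from 60% to 80% inclusive (a literal
  reading of "between 60 and 80%" — both endpoints are configurable),
  `unlikely` below 60% (excluded).
* **Enrichment** from the bait-over-control fold change against the
  median fold change of the evaluable candidates, recomputed from the data
  rather than hard-coded: `high` strictly above the median, `low` at or
  below it. The scale is configurable (linear `2^lfc` by default, log2
  optionally) and the median is taken on the same scale, because a
  fold-change threshold is only meaningful relative to its scale.
* **Category**: high/high &rarr; `high_credibility`; high/low or
  moderate/high &rarr; `satisfactory`; moderate/low &rarr;
  `low_credibility`; any `unlikely` confidence excludes the candidate.

The bait protein itself is always left out of the tier tallies, and
candidates absent from the co-IP table are reported as not evaluable
rather than dropped. Scoring is fully deterministic.

## Nucleotide-loading comparison

For a small GTPase bait partner, binding may depend on the nucleotide
state. The paired design — GTP&gamma;S- and GDP&beta;S-loaded portions of
the same lysate — cancels lysate-to-lysate variability in the per-pair
log2 difference. `pairedDelta` averages the per-pair differences
(`log2_delta_fc`) and applies a two-sided paired t-test; pairs with a
missing member are dropped per protein, and fewer than two usable pairs
yields a flagged row without a p-value. By default only originally
observed values enter the differences even on an imputed table: with
three pairs, imputation noise would dominate the paired signal. A protein
is called state-dependent when $|\Delta| \ge 0.2$ and $p < 0.05$; the
test is two-sided even though the hypothesis is directional, so the
reported p-values are interpretable without a directionality caveat.

## QC battery

PCA runs on the centered, imputed log2 matrix without unit-variance
scaling (abundant proteins should dominate, as in standard LFQ QC; a
scaling flag exists). The Pearson matrix, per-sample detection counts
(compared by an unpaired equal-variance Student t-test on the
pre-imputation mask), the detection-overlap partition, average-linkage
Euclidean clustering of z-scored rows, and a normality summary (skewness,
excess kurtosis, Anderson–Darling omnibus p) complete the battery.

Overlap percentages are reported to two decimals using largest-remainder
rounding, so the three printed percentages always sum to exactly 100.00 —
plain per-entry rounding can be off by 0.01 and disagree with the
partition identity.

## The synthetic generator: what it emulates, and what it does not

`generatePulldown`, `generateCoip` and `generateLoading` produce
linear-scale tables (zeros at dropped cells) with full ground truth. The
defaults encode the targeted study design: 6 control + 6 bait pulldowns,
5 + 5 co-IP, 3 loading pairs; log2 baselines $N(25, 2^2)$ (typical MaxLFQ
magnitudes); replicate noise SD 0.5; 10% true interactors with uniform
log2 effects in $[2.5, 6]$; co-IP effects attenuated by 0.85 (orthogonal
capture is usually weaker); half of the true interactors state-dependent
with a 0.785 log2 shift; and logistic dropout
$P(\text{missing}) = \text{logit}^{-1}((22 - y))$ — midpoint 1.5
baseline-SD below the mean, one log2 unit of slope — which yields the
left-censored missingness pattern MNAR imputation assumes, with roughly
5–10% missing cells overall. A configurable fraction (default 15%) of
true interactors is forced below 60% co-IP detection to exercise the
excluded tier.

The generator emulates log-scale intensities with replicate noise,
intensity-dependent dropout, a shared-lysate pair effect, and effect
attenuation between experiments. It does **not** emulate peptide-level
quantification, match-between-runs artifacts, correlated contaminant
background, batch effects, or compositional distortions from very
abundant baits. Passing tests on synthetic data therefore demonstrate
calibration and power of the statistical chain under the stated model,
not robustness to every failure mode of real acquisitions.

## Numerical choices and degenerate inputs

* Zero intensities are missing, never measured zeros; log2 of a missing
  cell stays missing.
* Double log2 transformation is a guarded error, as is normalizing or
  contrasting an unimputed table.
* p-values that underflow to zero are floored at the smallest positive
  double before BH adjustment.
* A paired difference vector with zero variance returns $p = 1$ when its
  mean is zero and $p = 0$ otherwise; identical detection-count groups
  with zero spread return $p = 1$.
* Trigamma inversion uses Newton iteration with the standard asymptotic
  end-points ($1/\sqrt y$ for large $y$, $1/y$ for small).
* Fold-change ties sit in the `low` enrichment band; detection rates at
  exactly 0.60 or 0.80 are `moderate`.
* One global seed fans out to fixed per-stage seeds (`seed + 101` for
  imputation) so stages rerun identically in isolation.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the calibration studies
at 300 simulated proteins per dataset with 500 null and 200 spike-in
replicates, 1000 replicate proteins for the paired-loading recovery, and
an 800-protein run of the full study-design preset — sizes chosen so the
whole battery completes in a few minutes while keeping Monte-Carlo error
well inside the asserted tolerances (binomial SE &le; 0.7 percentage
points at 500 replicates; SE of the recovered loading shift &le; 0.002).

## Known limitations

* Two-group contrasts only; no batch covariates or multi-factor designs.
* The vsn-like calibration assumes most proteins are shared across
  samples; designs where the bait dominates the proteome should use
  `median_center`.
* The credibility scheme is the deliberate scope — no probabilistic
  interaction scoring (SAINT/CompPASS-style) is attempted.
* With three loading pairs the paired test has limited power at realistic
  noise; the package reports effect sizes alongside p-values for exactly
  this reason.
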