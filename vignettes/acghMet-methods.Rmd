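---
title: "Methods and design notes for acghMet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for acghMet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind each stage of
`acghMet`, the tunable parameters and their defaults, the numerical
conventions, and the design decisions taken where the methodology left
genuine freedom. It states no empirical result beyond what the package's
tests and `scripts/acceptance.R` themselves compute.

## Data model

An `AcghSet` holds a clones × samples matrix of log2 tumor/reference
intensity ratios over a `CloneMap`: genomic clones (~1 Mb spacing) with
1-based midpoint coordinates, chromosome-arm assignments derived from a
packaged centromere table, and a head-to-tail global coordinate formed by
cumulative chromosome offsets. Conventions:

* Coordinates are 1-based clone midpoints; all bp intervals are half-open
  `[start, end)`, so region membership is unambiguous.
* Chromosome lengths and centromeres ship as GRCh37-era reference values
  (`hsGenomeInfo()`) and are overridable — arrays mapped to other builds
  only shift nominal positions, not the analysis logic.
* X and Y clones are loaded but excluded from downstream statistics by
  default (`keepAutosomes()` in the pipeline): with pooled single-sex
  reference DNA, sex-chromosome ratios measure sex, not tumor biology.
* Missing cells are explicit `NA`s; they contribute zero mass to aggregate
  profiles (absent evidence), drop out of the kernel weight mass in
  normalized smoothing, and are imputed by per-sample chromosome-arm
  medians (`imputeArmMedian()`) only where the classifier needs complete
  data — the arm median keeps local copy-number context.
* Per-sample median centering (`medianCenter()`) removes sample-level
  offset. The original arrays were normalized per print-tip subgrid; that
  layout is unrecoverable from clone-level matrices, so centering is
  applied at whole-sample granularity, which preserves the intent
  (removing per-hybridization offset) and is idempotent.

## Recurrent aberrations: aggregate KSE with a max-statistic null

Gains and losses are handled separately: the gain aggregate at clone c is
the sum over tumors of max(log2, 0), the loss aggregate of min(log2, 0).
Each aggregate is smoothed by Gaussian kernel convolution onto a genomic
grid, never across chromosome boundaries:

KSE(x) = Σ_c a_c exp(−(x − p_c)² / 2w²).

Parameters:

* `kernelWidth` (w, bp) — Gaussian sd, default 1 Mb. The method's source
  does not state a width; 1 Mb matches the array resolution, so the kernel
  pools a handful of neighbouring clones without washing out arm-level
  structure.
* `gridSpacing` (bp) — default 50 kb for consistency with the comparative
  analysis; the pipeline and tests use coarser grids (250 kb - 1 Mb)
  purely to bound runtime, which leaves peak heights essentially unchanged
  at w = 1 Mb.
* `truncMult` — kernel evaluation is truncated beyond 4 kernel widths.
  With near-uniform 1 Mb clone spacing, the first omitted clone sits at
  ≥ 5w for the default grids, so the truncation error is below 1e-4 of
  the untruncated value (verified against a brute-force double loop in
  the tests and the acceptance script).

The default smoother is the **unnormalized kernel-weighted sum**, not a
Nadaraya–Watson weighted mean: the aggregate is a mass (summed evidence
across tumors), and the sum keeps the KSE linear in the aggregate —
doubling every sample exactly doubles the profile. With near-uniform clone
spacing the two differ appreciably only at chromosome ends; the normalized
variant is available via `normalize = TRUE`.

**Null model.** Each randomized instance shuffles the clone-to-position
assignment once, shared across samples, and the genome-wide maximum
(gains) / minimum (losses) of the randomized KSE is recorded. The shared
shuffle preserves the between-sample correlation structure at a locus;
an independent per-sample shuffle is available (`shuffle = "perSample"`)
for sensitivity analysis. The threshold is the m-th largest null extreme
with m = floor(α(B+1)) — the permutation-test quantile convention, which
gives an exact family-wise error rate m/(B+1) under exchangeability
(α = 0.05 with B = 59 gives exactly 3/60). `nPermutations` must satisfy
floor(α(B+1)) ≥ 1; α = 1 degenerates to the null minimum. As an
alternative multiple-testing mode, `correction = "bonferroni"` computes
per-grid-point null quantiles at level α/G. Gains and losses get separate
thresholds from separate max/min statistics.

## Differential aberrations: per-tumor SNR with permutation FDR

Each tumor's **signed** profile (gains and losses together) is smoothed
onto the fixed grid with the same kernel contract, here as a normalized
weighted mean so a tumor's smoothed profile stays on the log2 scale (a
constant profile smooths to that constant, and missing clones drop out of
the local weight mass). The source describes per-tumor smoothing only by
reference to the aggregate procedure, which is sign-split; we judged the
signed per-tumor profile the natural two-sample statistic and provide the
sign-split alternative by smoothing sign-truncated matrices explicitly.

At grid point g, SNR(g) = |mean_A − mean_B| / (sd_A + sd_B), with n−1
standard deviations. If both sds vanish the SNR is 0 for equal means and
+Inf otherwise; the Inf sentinel sorts above all finite values. The SNR is
symmetric in group order, shift-invariant, and invariant to positive
rescaling of the data.

**FDR estimation.** Group labels are permuted uniformly at random
(preserving group sizes; default `nPermutations = 1000`, the convention
of the original analysis; reduced-scale runs use 200 with widened
tolerances). For each candidate threshold t (the sorted observed SNR
values — an exact step function, not a continuous grid):

FDR(t) = mean over permutations of #{g : SNR_perm(g) > t} / max(1, #{g :
SNR_obs(g) > t}), capped at 1.

This is the plug-in estimator of the SAM lineage; the source names no
estimator. The curve is then made monotone by the q-value convention —
the FDR attainable at cutoff t is the smallest estimate over cutoffs
≤ t — which guarantees thresholds nest across levels (the 5% threshold
never exceeds the 1% threshold). The threshold for level q is the
smallest observed SNR with FDR ≤ q; an unattainable level yields an
absent threshold (and an empty region set), not an error. Grid points
with no kernel mass (possible on clone-free chromosomes) are excluded
from estimation and reported as `NA`.

## Nearest shrunken centroids classifier

Training uses the standard four formulas with m_k = sqrt(1/n_k − 1/n) and
s0 = the median of the per-feature pooled within-class sds (a configurable
percentile in spirit; the median is the common default). Priors default to
empirical class frequencies, with uniform priors available. Prediction
minimizes δ_k(x) = Σ_i (x_i − x̄'_ik)² / (s_i + s0)² − 2 log π_k;
discriminant ties break toward the larger prior, then label order.
Class probabilities are proportional to exp(−δ_k/2), computed with a
min-shift for numerical stability.

Shrinkage Δ is tuned by stratified cross-validation (default 10-fold,
capped at the smallest class size; the source does not state a fold
count). The chosen Δ is the **largest** value whose mean misclassification
error lies within one standard error of the minimum — the parsimony rule,
biased toward fewer clones. The two packaged tasks mirror the study
design: LM vs PM∪M0 and PM vs M0; the machinery is multi-class.

ROC curves rank samples by score with ties grouped; the AUC by the
trapezoid rule then equals the Mann–Whitney statistic with the usual tie
correction (asserted against `wilcox.test` and `pROC` in the tests).
Feature reports annotate selected clones with chromosome arms and test
each arm's enrichment among selected clones with a one-sided
hypergeometric tail.

## Cohort statistics

Group comparisons of categorical covariates use Pearson chi-square
without continuity correction, after dropping all-zero rows/columns and
excluding explicitly coded "unknown" categories at test time (never at
load time). This choice reproduces the printed p-values of the packaged
patient-characteristics tables to their printed precision (location
0.027, gender 0.185, N-status 0.01, adjuvant treatment 0.014, MSI 0.124),
which is how the original test — unnamed in the source — was identified.
A warning (not an error, and no exact-test fallback) is emitted when any
expected cell is below 5; several of the packaged tables trip this, as
they evidently did originally. Logistic regression is a standard IRLS fit
(relative deviance tolerance 1e-8, ≤ 100 iterations) with Wald intervals
at a default 90% level — the reporting convention of the 20q odds-ratio
analysis — and odds ratios per 0.1 log2 via exp(0.1·β). Perfect
separation is detected and raised as an error naming the covariate.

## Synthetic cohorts: what they emulate, and what they do not

`generateCohort()` draws, for sample s and clone c:

log2_cs = Σ (amplitudes of segments carried by s covering c) + offset_s +
ε_cs,

with ε ~ N(0, noiseSd²) independent per clone and offset_s ~ N(0,
sampleOffsetSd²). Segment carriage is Bernoulli(penetrance) per sample
within the target groups. The random stream order is fixed and documented
(offsets; then carriage, segments in list order × samples in id order,
shared before specific; then the noise matrix sample by sample), so
truths are exactly reproducible from the seed.

Defaults encode the emulated study conditions: group sizes LM = 36,
PM = 37, M0 = 25; clones at 1 Mb spacing over the packaged genome;
per-clone noise sd 0.1 (a typical clone-level sd for averaged-triplicate
BAC aCGH); sample offset sd 0.02; a shared baseline of qualitatively
common colorectal aberrations (gains 7, 8q, 13q, low-level 20q; losses
8p, 17p, 18q — amplitudes are configuration, not biological claims); and
one LM-specific 20q gain. The planted amplitude default of 0.3 log2 is a
free choice — the source reports no effect size for the 20q gain — and is
flagged as such; calibration/recovery experiments in the acceptance suite
use amplitude 0.5 = 5 × noiseSd and penetrance 0.8, the regime in which
recovery is asserted.

The generator deliberately does **not** model FFPE artifacts,
tumor-cell-fraction dilution, replicate spot structure, print-tip layout,
GC waves, or segmentation-scale breakpoint noise. Noise is independent
across clones by default (an optional AR(1) along-genome coefficient
exists for robustness checks), so passing calibration tests shows the
permutation machinery is correct under the stated model — not that real
aCGH noise satisfies it. Recovery results on synthetic cohorts are
structural analogues of the original findings, not reproductions of
real-data numbers: the headline real-data quantities (80% accuracy, AUC
0.76/0.86, OR 16.2, KSE correlations 0.84/0.90, the 84- and 140-clone
lists) depend on the original cohort and are outside what synthetic data
can or should reproduce.

## Problem sizes in tests and the acceptance script

Simulation experiments run at reduced scale chosen once as the package's
own test conditions: calibration uses a 4-chromosome × 50 Mb genome (200
clones) with 20 samples, B = 59 randomized instances (the smallest B
giving the exact 3/60 rate at α = 0.05) over 200 replicates, and 200
label permutations over 60 replicates for the comparative null; recovery
uses the full autosome map (2,875 clones) at study-scale group sizes with
a 500 kb SNR grid, 200 permutations and 10 replicates. The pipeline
defaults (`gridSpacingKse`/`gridSpacingSnr` 250 kb) favour interactive
turnaround; production analyses of real arrays should use the 50 kb grid
and 1000 permutations.

## Known limitations

* No segmentation (CBS etc.): the kernel approach works directly on clone
  ratios by design; breakpoint estimates are only as sharp as the grid
  and kernel width.
* The FWER threshold assumes exchangeability of clone positions under the
  null; long-range waves in real data violate this and would inflate the
  null extremes (conservative for detection, not anticonservative).
* The plug-in FDR estimator is not guaranteed conservative at very small
  numbers of exceedances; the q-value monotonization mitigates threshold
  instability but cannot repair a poorly estimated tail at B ≪ 1000.
* Wald intervals on near-separated logistic fits are unstable; the
  package raises separation as an error rather than reporting a CI whose
  coverage is undefined.
* The chromosome-20 clone fixture carries nominal, evenly spaced
  positions: clone order and arm assignment are its tested content, not
  absolute coordinates.
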