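# acghMet

Copy-number aberration analysis for predicting the **site of colorectal-cancer
metastasis** from array-CGH profiles of the primary tumor.

Primary colorectal tumors that later seed liver metastases (LM) carry a
different copy-number landscape than tumors that seed peritoneal metastases
(PM) or never metastasize (M0) — most prominently a gain of the long arm of
chromosome 20. `acghMet` implements the complete analysis chain needed to
detect and exploit such differences on clone-level log2 tumor/reference
ratio matrices (~3,500 genomic clones at ~1 Mb spacing):

1. **Recurrent-aberration detection** (KC-SMART style). Positive and
   negative log2 values are summed separately across tumors into gain/loss
   aggregate profiles, smoothed by Gaussian kernel convolution into a
   Kernel Smoothed Estimate on a genomic grid,

   KSE(x) = Σ_c a_c · exp( −(x − p_c)² / 2w² ),

   and thresholded against a randomization null: clone-to-position
   assignments are shuffled, the genome-wide maximum of each randomized KSE
   is recorded, and the α = 0.05 quantile of that max-statistic
   distribution gives a multiple-testing-corrected (family-wise)
   significance threshold.

2. **Differential-aberration detection** between groups (comparative
   KC-SMART). Each tumor's signed profile is smoothed onto a fixed grid
   (default 50 kb) and at every grid point the signal-to-noise ratio

   SNR(g) = |mean_A(g) − mean_B(g)| / (sd_A(g) + sd_B(g))

   is compared against group-label permutations (default 1000) to estimate
   the false discovery rate; runs of grid points above the 1% (or 5%) FDR
   threshold are reported as differentially aberrant regions.

3. **Metastasis-site classification** by nearest shrunken centroids (PAM):
   standardized class-centroid differences d_ik = (x̄_ik − x̄_i)/(m_k(s_i+s0))
   are soft-thresholded by Δ, leaving a sparse clone set; prediction
   minimizes the penalized distance δ_k(x) = Σ_i (x_i − x̄'_ik)²/(s_i+s0)² −
   2·log π_k. Shrinkage is tuned by stratified cross-validation; evaluation
   produces confusion matrices, sensitivity/specificity, ROC curves and AUC.

4. **Regional copy-number statistics**: per-sample mean log2 over a region
   (e.g. 20q), approximate absolute copy number P·2^(mean log2), logistic
   regression of metastasis outcome on the regional score with odds ratios
   per 0.1 log2 (90% Wald CI), and Pearson chi-square comparisons of
   clinicopathological covariates.

A **synthetic cohort generator** (`generateCohort()`) produces aCGH cohorts
with planted aberration segments (shared or group-specific, with
configurable amplitude and penetrance) plus per-clone Gaussian noise, so
every stage is testable and calibratable without external data.

## Worked example

Simulate a 98-tumor cohort (LM = 36, PM = 37, M0 = 25) with a common
colorectal aberration baseline and an LM-specific 20q gain (amplitude
0.4 log2, penetrance 0.8), then ask whether the comparative analysis finds
it and how well the mean 20q log2 predicts the LM group:

```r
library(acghMet)

spec <- syntheticSpec(
  specificSegments = aberrationSegment("20", 27500000, 63025520,
                                       amplitude = 0.4, penetrance = 0.8,
                                       groups = "LM"),
  noiseSd = 0.1, seed = 42)
sim  <- generateCohort(spec)
acgh <- medianCenter(sim$acgh)
acgh
#> AcghSet: 98 samples x 2875 clones
#>   groups: LM=36, M0=25, PM=37
#>   missing values: 0 (0.00%)

sm   <- smoothSamples(acgh, gridSpacing = 250000)
prof <- permutationFdr(sm, "LM", "PM+M0", nPermutations = 500, seed = 43)
prof
#> SnrProfile: LM vs PM+M0 on 11515 grid points
#>   500 permutations; thresholds: FDR 0.01 -> 0.5873, FDR 0.05 -> 0.3730

differentialRegions(prof, 0.01)
#> GRanges object with 1 range and 2 metadata columns:
#>       seqnames            ranges strand |   peakSnr         q
#>   [1]       20 27125000-63125000      * |   1.21663      0.01
```

The single 1%-FDR region spans the whole planted 20q segment. The regional
score downstream:

```r
score <- regionMeanLog2(acgh, "20", arm = "q")
rocFromScore(score, sampleGroups(acgh), "LM")$auc
#> 0.889

fit <- logisticFit(as.integer(sampleGroups(acgh) == "LM"),
                   data.frame(mean20q = score))
oddsRatioPerUnit(fit, "mean20q", unit = 0.1)
#> or = 4.09, 90% CI [2.61, 6.43]   (odds ratio per 0.1 log2 of 20q gain)

copyNumberEstimate(mean(score[sampleGroups(acgh) == "LM"]))
#> 2.56   (approximate 20q copies in the LM group, reference ploidy 2)
```

So in this simulated cohort every 0.1 log2 of 20q amplification multiplies
the odds of liver metastasis by ~4, and the LM group carries on average
about half an extra copy of 20q.

`runPipeline(pipelineConfig(...))` chains all stages (per-group KSE tracks
with significance thresholds, KSE correlations between groups, comparative
SNR tracks and FDR regions, both packaged classifier tasks, the regional
regression) and writes plain TSV/JSON outputs; `demoRun()` is a packaged
fixed-seed run that asserts the planted 20q gain is recovered at FDR 0.01
and that the classifier's selected clones are 20q-enriched.

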