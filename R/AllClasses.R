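#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

#' CloneMap: genomic coordinates of array clones
#'
#' Ordered genomic positions and chromosome-arm assignments for the clones
#' (probes) of an aCGH array, together with the chromosome lengths and
#' centromere positions used to lay the genome out head-to-tail. This is the
#' coordinate backbone for every downstream computation: aggregate profiles,
#' kernel smoothing grids, region means and feature annotation all index into
#' the clone order stored here.
#'
#' Slots:
#' \describe{
#'   \item{clones}{data.frame with columns \code{cloneId}, \code{chrom},
#'     \code{arm} (\code{"p"} or \code{"q"}), \code{pos} (clone midpoint, bp,
#'     1-based) and \code{globalBp} (head-to-tail coordinate obtained by
#'     cumulative chromosome offsets). Rows are in head-to-tail genome order.}
#'   \item{chromLengths}{named numeric, chromosome lengths in bp; name order
#'     defines the head-to-tail chromosome order.}
#'   \item{centromeres}{named numeric, centromere position per chromosome;
#'     a clone with \code{pos <= centromere} is on the p arm.}
#' }
#'
#' @aliases CloneMap-class
#' @exportClass CloneMap
setClass("CloneMap",
  representation(
    clones = "data.frame",
    chromLengths = "numeric",
    centromeres = "numeric"
  )
)

setValidity("CloneMap", function(object) {
  cl <- object@clones
  need <- c("cloneId", "chrom", "arm", "pos", "globalBp")
  if (!all(need %in% names(cl)))
    return(paste("clones must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(cl$cloneId))
    return("duplicate cloneId values")
  if (!all(cl$chrom %in% names(object@chromLengths)))
    return("chromosome label without a declared length")
  if (!all(names(object@chromLengths) %in% names(object@centromeres)))
    return("centromere table does not cover all chromosomes")
  if (!all(cl$arm %in% c("p", "q")))
    return("arm must be 'p' or 'q'")
  for (ch in unique(cl$chrom)) {
    p <- cl$pos[cl$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      return(sprintf("positions not strictly increasing on chromosome %s", ch))
    if (any(p < 1) || any(p > object@chromLengths[[ch]]))
      return(sprintf("position outside chromosome %s", ch))
  }
  if (is.unsorted(cl$globalBp, strictly = TRUE))
    return("globalBp not strictly increasing in head-to-tail order")
  wantArm <- ifelse(cl$pos <= object@centromeres[cl$chrom], "p", "q")
  if (!all(cl$arm == wantArm))
    return("arm assignment inconsistent with centromere table")
  TRUE
})

#' AcghSet: samples-by-clones log2-ratio container
#'
#' A \linkS4class{SummarizedExperiment} holding the log2 tumor/reference
#' ratio matrix of an aCGH cohort (clones as rows, samples as columns, assay
#' \code{"log2"}), the \linkS4class{CloneMap} of the array, and per-sample
#' group labels in \code{colData()$group} (e.g. \code{LM}, \code{PM},
#' \code{M0}). Missing measurements are stored as \code{NA} in the assay;
#' \code{\link{missingMask}} exposes them as a logical matrix.
#'
#' @aliases AcghSet-class
#' @exportClass AcghSet
setClass("AcghSet",
  contains = "SummarizedExperiment",
  representation(cloneMap = "CloneMap")
)

setValidity("AcghSet", function(object) {
  if (!"log2" %in% names(assays(object)))
    return("assay 'log2' required")
  cl <- object@cloneMap@clones
  if (nrow(object) != nrow(cl))
    return("row count does not match clone map")
  if (!identical(rownames(object), cl$cloneId))
    return("rownames must equal clone map cloneId in clone-map order")
  if (!"group" %in% names(colData(object)))
    return("colData must have a 'group' column")
  TRUE
})

#' KseProfile: kernel-smoothed aggregate aberration profile
#'
#' Genome-wide Kernel Smoothed Estimate (KSE) of the gain and loss aggregate
#' profiles of a tumor group on a fixed grid, optionally with
#' randomization-null significance thresholds. \code{kseGain} is everywhere
#' nonnegative and \code{kseLoss} everywhere nonpositive; thresholds are
#' \code{NA} until a null run has been performed.
#'
#' @aliases KseProfile-class
#' @exportClass KseProfile
setClass("KseProfile",
  representation(
    gridChrom = "character",
    gridPos = "numeric",
    gridGlobal = "numeric",
    kseGain = "numeric",
    kseLoss = "numeric",
    kernelWidth = "numeric",
    gridSpacing = "numeric",
    nSamples = "integer",
    thresholdGain = "numeric",
    thresholdLoss = "numeric",
    nPermutations = "integer",
    alpha = "numeric",
    correction = "character"
  )
)

setValidity("KseProfile", function(object) {
  n <- length(object@gridGlobal)
  if (length(object@gridChrom) != n || length(object@gridPos) != n)
    return("grid vectors must have equal length")
  if (length(object@kseGain) != n || length(object@kseLoss) != n)
    return("KSE vectors must match grid length")
  if (is.unsorted(object@gridGlobal, strictly = TRUE))
    return("grid not strictly increasing")
  if (any(object@kseGain < 0))
    return("kseGain must be nonnegative")
  if (any(object@kseLoss > 0))
    return("kseLoss must be nonpositive")
  okLen <- function(x) length(x) %in% c(1L, n)
  if (!okLen(object@thresholdGain) || !okLen(object@thresholdLoss))
    return("thresholds must be scalar or per-grid-point")
  TRUE
})

#' SmoothedSampleMatrix: per-tumor smoothed profiles on a fixed grid
#'
#' Each tumor's full signed log2 profile smoothed with a Gaussian kernel and
#' evaluated on a fixed genomic grid (default spacing 50 kb), the input to
#' the comparative signal-to-noise analysis. Rows are samples, columns grid
#' points.
#'
#' @aliases SmoothedSampleMatrix-class
#' @exportClass SmoothedSampleMatrix
setClass("SmoothedSampleMatrix",
  representation(
    gridChrom = "character",
    gridPos = "numeric",
    gridGlobal = "numeric",
    values = "matrix",
    kernelWidth = "numeric",
    gridSpacing = "numeric",
    sampleIds = "character",
    groupLabels = "character",
    normalized = "logical"
  )
)

setValidity("SmoothedSampleMatrix", function(object) {
  n <- length(object@gridGlobal)
  if (ncol(object@values) != n)
    return("values columns must match grid length")
  if (nrow(object@values) != length(object@sampleIds))
    return("one row per sample required")
  if (length(object@groupLabels) != length(object@sampleIds))
    return("one group label per sample required")
  if (is.unsorted(object@gridGlobal, strictly = TRUE))
    return("grid not strictly increasing")
  TRUE
})

#' SnrProfile: per-grid-point signal-to-noise with permutation FDR
#'
#' The differential-aberration statistic between two tumor groups: for each
#' grid point the ratio of the absolute difference of group means of the
#' per-tumor smoothed profiles to the sum of within-group standard
#' deviations, with label-permutation estimates of the false discovery rate
#' and the SNR thresholds attaining target FDR levels (1% and 5% by
#' default). An unattainable level has threshold \code{NA}.
#'
#' @aliases SnrProfile-class
#' @exportClass SnrProfile
setClass("SnrProfile",
  representation(
    gridChrom = "character",
    gridPos = "numeric",
    gridGlobal = "numeric",
    snr = "numeric",
    groupA = "character",
    groupB = "character",
    nPermutations = "integer",
    fdrCurve = "data.frame",
    thresholds = "numeric",
    gridSpacing = "numeric",
    kernelWidth = "numeric"
  )
)

setValidity("SnrProfile", function(object) {
  n <- length(object@gridGlobal)
  if (length(object@snr) != n)
    return("snr must match grid length")
  if (any(object@snr < 0, na.rm = TRUE))
    return("snr must be nonnegative")
  if (nrow(object@fdrCurve) &&
      !all(c("threshold", "fdr") %in% names(object@fdrCurve)))
    return("fdrCurve needs columns threshold, fdr")
  TRUE
})

#' NscModel: nearest shrunken centroids classifier
#'
#' A PAM-style shrunken-centroids model: per-class centroids soft-thresholded
#' toward the overall centroid in units of the standardized centroid
#' difference, retaining a sparse feature set. Slots hold everything needed
#' for prediction: shrunken centroids, per-feature pooled within-class
#' standard deviations \code{pooledSd}, the fudge constant \code{s0}, the
#' shrinkage level \code{delta} and class priors.
#'
#' @aliases NscModel-class
#' @exportClass NscModel
setClass("NscModel",
  representation(
    classLabels = "character",
    featureNames = "character",
    overallCentroid = "numeric",
    classCentroids = "matrix",
    shrunkenCentroids = "matrix",
    dik = "matrix",
    dikShrunk = "matrix",
    pooledSd = "numeric",
    s0 = "numeric",
    mk = "numeric",
    delta = "numeric",
    priors = "numeric",
    classSizes = "integer"
  )
)

setValidity("NscModel", function(object) {
  K <- length(object@classLabels)
  p <- length(object@featureNames)
  if (!all(dim(object@shrunkenCentroids) == c(p, K)))
    return("shrunkenCentroids must be features x classes")
  if (abs(sum(object@priors) - 1) > 1e-8)
    return("priors must sum to 1")
  if (object@delta < 0)
    return("delta must be nonnegative")
  TRUE
})

#' SyntheticSpec: parameters of the synthetic aCGH cohort generator
#'
#' Defines a simulated cohort: group sizes (default LM=36, PM=37, M0=25,
#' the study's design), aberration segments shared by all groups, segments
#' specific to target groups (e.g. a liver-metastasis-specific 20q gain),
#' per-clone Gaussian noise, per-sample baseline offsets, clone spacing and
#' the RNG seed. Segments are rows of a data.frame with columns
#' \code{chrom}, \code{startBp}, \code{endBp}, \code{amplitude} (log2 shift,
#' positive = gain), \code{penetrance} (carrier fraction in the target
#' groups) and \code{groups} (comma-separated labels, \code{"*"} = all).
#'
#' @aliases SyntheticSpec-class
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(
    groupSizes = "integer",
    sharedSegments = "data.frame",
    specificSegments = "data.frame",
    noiseSd = "numeric",
    sampleOffsetSd = "numeric",
    cloneSpacing = "numeric",
    arCoef = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  if (any(object@groupSizes <= 0) || is.null(names(object@groupSizes)))
    return("groupSizes must be positive and named")
  if (object@noiseSd <= 0)
    return("noiseSd must be > 0")
  if (object@cloneSpacing <= 0)
    return("cloneSpacing must be > 0")
  for (seg in list(object@sharedSegments, object@specificSegments)) {
    if (nrow(seg) == 0) next
    if (any(seg$startBp >= seg$endBp))
      return("segment startBp must be < endBp")
    if (any(seg$penetrance < 0 | seg$penetrance > 1))
      return("penetrance must be in [0, 1]")
  }
  TRUE
})
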