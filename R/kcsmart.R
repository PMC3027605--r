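# Gaussian kernel smoothing machinery shared by the single-group (KSE) and
# comparative (per-tumor) analyses. Smoothing never crosses chromosome
# boundaries; kernel evaluation is truncated beyond `truncMult` kernel widths
# (contract: truncation error < 1e-4 of the untruncated value at truncMult=4,
# since exp(-8) ~ 3.4e-4 relative to unit mass concentrated nearer).

# Grid points at multiples of gridSpacing within each chromosome, for the
# chromosomes the map declares (those with at least one clone can receive
# nonzero signal; empty ones smooth to zero).
.makeGrid <- function(map, gridSpacing) {
  lens <- chromLengths(map)
  chroms <- names(lens)
  pos <- lapply(chroms, function(ch) {
    n <- floor(lens[[ch]] / gridSpacing)
    if (n < 1) numeric(0) else gridSpacing * seq_len(n)
  })
  nper <- lengths(pos)
  offs <- c(0, cumsum(as.numeric(lens)))[seq_along(lens)]
  list(chrom = rep(chroms, nper),
       pos = unlist(pos, use.names = FALSE),
       global = unlist(pos, use.names = FALSE) + rep(offs, nper))
}

# Smooth clone-level values (clones x m matrix) onto the grid.
# normalize = FALSE: kernel-weighted sum (aggregate-mass interpretation,
#   linear in the values; NAs contribute zero).
# normalize = TRUE: kernel-weighted mean (Nadaraya-Watson), per column, with
#   NA cells excluded from the weight mass; 0/0 yields NA.
.kernelSmooth <- function(values, map, gridSpacing, kernelWidth,
                          normalize = FALSE, truncMult = 4) {
  stopifnot(gridSpacing > 0, kernelWidth > 0)
  values <- as.matrix(values)
  cl <- cloneTable(map)
  if (nrow(values) != nrow(cl))
    stop("values rows must match clone count")
  grid <- .makeGrid(map, gridSpacing)
  m <- ncol(values)
  out <- matrix(0, length(grid$global), m)
  den <- if (normalize) matrix(0, length(grid$global), m)
  naMask <- is.na(values)
  v0 <- values
  v0[naMask] <- 0
  gOff <- 0L
  for (ch in unique(grid$chrom)) {
    gIdx <- which(grid$chrom == ch)
    cIdx <- which(cl$chrom == ch)
    if (length(gIdx) == 0) next
    if (length(cIdx)) {
      d <- outer(grid$pos[gIdx], cl$pos[cIdx], "-")
      W <- exp(-(d * d) / (2 * kernelWidth^2))
      W[abs(d) > truncMult * kernelWidth] <- 0
      out[gIdx, ] <- W %*% v0[cIdx, , drop = FALSE]
      if (normalize)
        den[gIdx, ] <- W %*% (1 - naMask[cIdx, , drop = FALSE])
    }
  }
  if (normalize) {
    out <- out / den
    out[!is.finite(out)] <- NA_real_
  }
  list(chrom = grid$chrom, pos = grid$pos, global = grid$global,
       values = out)
}

#' Aggregate gain or loss profile across tumors
#'
#' Per clone, the sum over samples of the positive part (gains) or negative
#' part (losses) of the log2 ratios. Missing values contribute zero (absent
#' evidence). This is the raw material the KSE smooths.
#'
#' @param x \linkS4class{AcghSet}
#' @param sign \code{"gain"} or \code{"loss"}.
#' @return named numeric vector, one value per clone (nonnegative for gains,
#'   nonpositive for losses).
#' @export
aggregateProfile <- function(x, sign = c("gain", "loss")) {
  sign <- match.arg(sign)
  m <- log2Matrix(x)
  m[is.na(m)] <- 0
  if (sign == "gain") rowSums(pmax(m, 0)) else rowSums(pmin(m, 0))
}

#' Kernel Smoothed Estimate of an aggregate profile
#'
#' Evaluates, at every grid point x on the same chromosome,
#' \deqn{KSE(x) = \sum_c a_c \exp(-(x - p_c)^2 / (2 w^2))}
#' where a_c is the aggregate value of clone c at position p_c and w the
#' kernel width (Gaussian sd). The default is the unnormalized
#' kernel-weighted sum, which keeps the KSE linear in the aggregate;
#' \code{normalize = TRUE} gives the kernel-weighted mean instead.
#'
#' @param aggregate per-clone numeric vector (see
#'   \code{\link{aggregateProfile}}).
#' @param map \linkS4class{CloneMap}
#' @param gridSpacing grid spacing in bp (default 50 kb).
#' @param kernelWidth Gaussian kernel sd in bp (default 1 Mb, the array
#'   resolution).
#' @param normalize kernel-weighted mean instead of sum.
#' @param truncMult kernel truncation radius in kernel widths.
#' @return data.frame with columns \code{chrom}, \code{pos},
#'   \code{globalBp}, \code{kse}.
#' @export
kseSmooth <- function(aggregate, map, gridSpacing = 50000,
                      kernelWidth = 1e6, normalize = FALSE, truncMult = 4) {
  sm <- .kernelSmooth(matrix(aggregate, ncol = 1), map, gridSpacing,
                      kernelWidth, normalize = normalize,
                      truncMult = truncMult)
  data.frame(chrom = sm$chrom, pos = sm$pos, globalBp = sm$global,
             kse = sm$values[, 1], stringsAsFactors = FALSE)
}

#' Single-group recurrent-aberration profile (KC-SMART)
#'
#' Computes the gain and loss KSEs of a tumor group and, when
#' \code{nPermutations > 0}, randomization-null significance thresholds:
#' each randomized instance shuffles the clone-to-position assignment (one
#' shared permutation per instance, preserving the between-sample structure
#' at a locus), recomputes the KSE, and records its genome-wide maximum
#' (gains) / minimum (losses). With \code{correction = "maxstat"} the
#' threshold is the m-th largest null extreme with m = floor(alpha (B+1)),
#' a family-wise-error-corrected threshold that is exact under
#' exchangeability; \code{correction = "bonferroni"} instead computes
#' per-grid-point null quantiles at level alpha divided by the number of
#' grid points.
#'
#' @param x \linkS4class{AcghSet} (one group's samples).
#' @param gridSpacing,kernelWidth,normalize,truncMult see
#'   \code{\link{kseSmooth}}.
#' @param nPermutations number of randomized instances (0 = no thresholds).
#' @param alpha significance level for the corrected threshold.
#' @param correction \code{"maxstat"} (genome-wide max null, FWER) or
#'   \code{"bonferroni"} (per-point quantile at alpha/G).
#' @param shuffle \code{"shared"} (one clone-position permutation per
#'   instance, shared across samples) or \code{"perSample"} (independent
#'   shuffle per sample).
#' @param seed RNG seed for the randomization.
#' @return \linkS4class{KseProfile}
#' @export
kcsmartProfile <- function(x, gridSpacing = 50000, kernelWidth = 1e6,
                           nPermutations = 0, alpha = 0.05,
                           correction = c("maxstat", "bonferroni"),
                           shuffle = c("shared", "perSample"),
                           normalize = FALSE, truncMult = 4, seed = NULL) {
  correction <- match.arg(correction)
  shuffle <- match.arg(shuffle)
  if (ncol(x) < 1) stop("need at least one sample")
  aggG <- aggregateProfile(x, "gain")
  aggL <- aggregateProfile(x, "loss")
  map <- x@cloneMap
  smG <- .kernelSmooth(cbind(aggG), map, gridSpacing, kernelWidth,
                       normalize = normalize, truncMult = truncMult)
  smL <- .kernelSmooth(cbind(aggL), map, gridSpacing, kernelWidth,
                       normalize = normalize, truncMult = truncMult)
  thrG <- NA_real_
  thrL <- NA_real_
  if (nPermutations > 0) {
    thrG <- kseNullThreshold(x, "gain", gridSpacing, kernelWidth,
                             nPermutations, alpha, correction = correction,
                             shuffle = shuffle, normalize = normalize,
                             truncMult = truncMult, seed = seed)
    thrL <- kseNullThreshold(x, "loss", gridSpacing, kernelWidth,
                             nPermutations, alpha, correction = correction,
                             shuffle = shuffle, normalize = normalize,
                             truncMult = truncMult,
                             seed = if (is.null(seed)) NULL else seed + 1L)
  }
  kg <- smG$values[, 1]
  kl <- smL$values[, 1]
  kg[kg < 0] <- 0  # guard numerical noise; sign-split aggregates stay signed
  kl[kl > 0] <- 0
  new("KseProfile", gridChrom = smG$chrom, gridPos = smG$pos,
      gridGlobal = smG$global, kseGain = kg, kseLoss = kl,
      kernelWidth = kernelWidth, gridSpacing = gridSpacing,
      nSamples = ncol(x), thresholdGain = unname(thrG),
      thresholdLoss = unname(thrL),
      nPermutations = as.integer(nPermutations), alpha = alpha,
      correction = correction)
}

#' Randomization-null significance threshold for a KSE
#'
#' See \code{\link{kcsmartProfile}} for the null model and correction
#' modes. Errors when \code{nPermutations} is too small for the requested
#' alpha (the m-th largest with m = floor(alpha (B+1)) needs m >= 1).
#'
#' @inheritParams kcsmartProfile
#' @param sign \code{"gain"} or \code{"loss"}.
#' @return scalar threshold (maxstat) or per-grid-point threshold vector
#'   (bonferroni); for losses the threshold is negative and exceedance
#'   means falling below it.
#' @export
kseNullThreshold <- function(x, sign = c("gain", "loss"),
                             gridSpacing = 50000, kernelWidth = 1e6,
                             nPermutations = 100, alpha = 0.05,
                             correction = c("maxstat", "bonferroni"),
                             shuffle = c("shared", "perSample"),
                             normalize = FALSE, truncMult = 4, seed = NULL) {
  sign <- match.arg(sign)
  correction <- match.arg(correction)
  shuffle <- match.arg(shuffle)
  B <- as.integer(nPermutations)
  if (B < 20) stop("need at least 20 randomized instances")
  map <- x@cloneMap
  cl <- cloneTable(map)
  p <- nrow(cl)
  if (correction == "maxstat") {
    mRank <- min(B, floor(alpha * (B + 1)))  # alpha = 1 -> the null minimum
    if (mRank < 1)
      stop(sprintf(
        "nPermutations = %d too small for alpha = %g (needs >= %g)",
        B, alpha, ceiling(1 / alpha) - 1))
  }
  runSeeded(seed, {
    if (shuffle == "shared") {
      agg <- aggregateProfile(x, sign)
      V <- matrix(0, p, B)
      for (b in seq_len(B)) V[, b] <- agg[sample.int(p)]
    } else {
      m <- log2Matrix(x)
      m[is.na(m)] <- 0
      m <- if (sign == "gain") pmax(m, 0) else pmin(m, 0)
      V <- matrix(0, p, B)
      for (b in seq_len(B)) {
        perm <- apply(m, 2, function(col) col[sample.int(p)])
        V[, b] <- rowSums(perm)
      }
    }
    sm <- .kernelSmooth(V, map, gridSpacing, kernelWidth,
                        normalize = normalize, truncMult = truncMult)
    if (correction == "maxstat") {
      extremes <- if (sign == "gain") apply(sm$values, 2, max)
                  else apply(sm$values, 2, min)
      if (sign == "gain") sort(extremes, decreasing = TRUE)[mRank]
      else sort(extremes, decreasing = FALSE)[mRank]
    } else {
      G <- nrow(sm$values)
      prob <- if (sign == "gain") 1 - alpha / G else alpha / G
      apply(sm$values, 1, stats::quantile, probs = prob, names = FALSE,
            type = 1)
    }
  })
}

#' Significantly recurrent regions of a KSE profile
#'
#' Maximal runs of consecutive grid points whose gain KSE exceeds the gain
#' threshold (strictly), or whose loss KSE falls below the loss threshold,
#' reported as bp intervals with the peak KSE value of each run.
#'
#' @param profile \linkS4class{KseProfile} with thresholds (run
#'   \code{\link{kcsmartProfile}} with \code{nPermutations > 0}).
#' @return \linkS4class{GRanges} with metadata columns \code{sign}
#'   (\code{"gain"}/\code{"loss"}) and \code{peak}; regions are ordered by
#'   coordinate within sign.
#' @export
significantRegions <- function(profile) {
  if (all(is.na(profile@thresholdGain)) && all(is.na(profile@thresholdLoss)))
    stop("profile has no thresholds; rerun with nPermutations > 0")
  half <- profile@gridSpacing / 2
  collect <- function(exceed, values, sign) {
    exceed[is.na(exceed)] <- FALSE
    if (!any(exceed)) return(NULL)
    r <- rle(paste0(profile@gridChrom, "_", exceed))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(exceed[starts])
    do.call(rbind, lapply(keep, function(i) {
      idx <- starts[i]:ends[i]
      data.frame(chrom = profile@gridChrom[starts[i]],
                 start = max(1, profile@gridPos[starts[i]] - half),
                 end = profile@gridPos[ends[i]] + half,
                 sign = sign,
                 peak = if (sign == "gain") max(values[idx]) else min(values[idx]),
                 stringsAsFactors = FALSE)
    }))
  }
  regs <- rbind(
    if (!all(is.na(profile@thresholdGain)))
      collect(profile@kseGain > profile@thresholdGain, profile@kseGain, "gain"),
    if (!all(is.na(profile@thresholdLoss)))
      collect(profile@kseLoss < profile@thresholdLoss, profile@kseLoss, "loss")
  )
  if (is.null(regs) || nrow(regs) == 0)
    return(GRanges(seqnames = character(0), ranges = IRanges(),
                   sign = character(0), peak = numeric(0)))
  GRanges(seqnames = regs$chrom,
          ranges = IRanges(start = round(regs$start), end = round(regs$end)),
          sign = regs$sign, peak = regs$peak)
}

#' Pearson correlation between two KSE profiles
#'
#' Correlation of the chosen-sign KSE vectors of two groups over the shared
#' grid (the groups' overall aberration-landscape similarity). Errors on a
#' grid mismatch; a zero-variance profile has no defined correlation and
#' yields \code{NA} with a warning.
#'
#' @param a,b \linkS4class{KseProfile} objects on identical grids.
#' @param sign \code{"gain"} or \code{"loss"}.
#' @return Pearson correlation coefficient.
#' @export
kseCorrelation <- function(a, b, sign = c("gain", "loss")) {
  sign <- match.arg(sign)
  if (!isTRUE(all.equal(a@gridGlobal, b@gridGlobal)))
    stop("profiles are on different grids")
  va <- if (sign == "gain") a@kseGain else a@kseLoss
  vb <- if (sign == "gain") b@kseGain else b@kseLoss
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("zero-variance profile; correlation undefined")
    return(NA_real_)
  }
  stats::cor(va, vb)
}

setMethod("show", "KseProfile", function(object) {
  cat("KseProfile:", length(object@gridGlobal), "grid points,",
      object@nSamples, "samples\n")
  cat(sprintf("  kernel width %g bp, grid spacing %g bp\n",
              object@kernelWidth, object@gridSpacing))
  if (!all(is.na(object@thresholdGain)))
    cat(sprintf("  thresholds (%s, alpha=%g, B=%d): gain %s, loss %s\n",
                object@correction, object@alpha, object@nPermutations,
                format(object@thresholdGain[1], digits = 4),
                format(object@thresholdLoss[1], digits = 4)))
  else cat("  no significance thresholds (no null run)\n")
})

#' Export a KSE profile as a genome-track table
#'
#' @param profile \linkS4class{KseProfile}
#' @param path output path (tab-separated: chromosome, bp, kse_gain,
#'   kse_loss, thresholds).
#' @return invisibly, \code{path}.
#' @export
writeKseTrack <- function(profile, path) {
  out <- data.frame(chromosome = profile@gridChrom, bp = profile@gridPos,
                    global_bp = profile@gridGlobal,
                    kse_gain = profile@kseGain, kse_loss = profile@kseLoss,
                    threshold_gain = profile@thresholdGain,
                    threshold_loss = profile@thresholdLoss)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
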