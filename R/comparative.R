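#' Per-tumor smoothed profiles on a fixed grid
#'
#' Smooths each tumor's full signed log2 profile (gains and losses
#' together) with the Gaussian kernel used by \code{\link{kseSmooth}},
#' evaluated on a fixed grid (default spacing 50 kb). The default is the
#' kernel-weighted mean (normalized), so a constant profile smooths to that
#' constant and missing cells simply drop out of the local weight mass; the
#' unnormalized kernel-weighted sum is available for consistency checks
#' against the aggregate analysis.
#'
#' @param x \linkS4class{AcghSet}
#' @param gridSpacing grid spacing in bp (default 50,000).
#' @param kernelWidth Gaussian kernel sd in bp.
#' @param normalize kernel-weighted mean (default) vs sum.
#' @param truncMult kernel truncation radius in kernel widths.
#' @return \linkS4class{SmoothedSampleMatrix}
#' @export
smoothSamples <- function(x, gridSpacing = 50000, kernelWidth = 1e6,
                          normalize = TRUE, truncMult = 4) {
  sm <- .kernelSmooth(log2Matrix(x), x@cloneMap, gridSpacing, kernelWidth,
                      normalize = normalize, truncMult = truncMult)
  vals <- t(sm$values)
  rownames(vals) <- colnames(x)
  new("SmoothedSampleMatrix", gridChrom = sm$chrom, gridPos = sm$pos,
      gridGlobal = sm$global, values = vals, kernelWidth = kernelWidth,
      gridSpacing = gridSpacing, sampleIds = colnames(x),
      groupLabels = sampleGroups(x), normalized = normalize)
}

# Resolve a group specification ("LM" or c("PM","M0") or "PM+M0") to a
# logical sample selector.
.groupSelector <- function(labels, groupSpec) {
  wanted <- unlist(strsplit(groupSpec, "+", fixed = TRUE))
  miss <- setdiff(wanted, labels)
  if (length(miss))
    stop("group label(s) not present: ", paste(miss, collapse = ", "))
  labels %in% wanted
}

# Core SNR given the smoothed matrix and a logical selector for group A
# (group B = the rest of selB). Means and n-1 sds per grid point.
.snrCore <- function(V, selA, selB) {
  nA <- sum(selA); nB <- sum(selB)
  XA <- V[selA, , drop = FALSE]
  XB <- V[selB, , drop = FALSE]
  mA <- colMeans(XA); mB <- colMeans(XB)
  sdA <- sqrt(colSums(sweep(XA, 2, mA)^2) / (nA - 1))
  sdB <- sqrt(colSums(sweep(XB, 2, mB)^2) / (nB - 1))
  num <- abs(mA - mB)
  den <- sdA + sdB
  out <- num / den
  out[den == 0 & num == 0] <- 0
  out[den == 0 & num > 0] <- Inf
  out
}

#' Signal-to-noise ratio between two groups per grid point
#'
#' At each grid point g, \deqn{SNR(g) = |mean_A(g) - mean_B(g)| /
#' (sd_A(g) + sd_B(g)),} the ratio of the absolute difference of the group
#' means of the per-tumor smoothed profiles to the sum of the within-group
#' sample standard deviations (denominator n-1) — analogous to a
#' t-statistic. If both sds are zero the SNR is 0 for equal means and
#' \code{Inf} otherwise (the sentinel sorts above all finite values).
#'
#' @param smoothed \linkS4class{SmoothedSampleMatrix}
#' @param groupA,groupB group specifications; a union is written
#'   \code{"PM+M0"} or given as a character vector.
#' @return numeric vector of nonnegative SNR values, one per grid point.
#' @export
snrProfile <- function(smoothed, groupA, groupB) {
  labels <- smoothed@groupLabels
  selA <- .groupSelector(labels, groupA)
  selB <- .groupSelector(labels, groupB)
  if (any(selA & selB)) stop("groups overlap")
  if (sum(selA) < 2 || sum(selB) < 2)
    stop("each group needs at least 2 samples")
  .snrCore(smoothed@values, selA, selB)
}

#' Permutation-FDR thresholds for the comparative SNR
#'
#' Permutes the group labels (uniformly at random, preserving group sizes)
#' \code{nPermutations} times and, for every candidate threshold t taken
#' from the sorted observed SNR values, estimates
#' \deqn{FDR(t) = E_{perm}[\#\{g : SNR_{perm}(g) > t\}] /
#'   \max(1, \#\{g : SNR_{obs}(g) > t\}),}
#' capped at 1 and monotonized to be non-increasing in t. The threshold for
#' a target level q is the smallest observed SNR value whose estimated FDR
#' is at most q; an unattainable level gets threshold \code{NA} (not an
#' error). Reproducible from the seed.
#'
#' @inheritParams snrProfile
#' @param nPermutations number of label permutations (default 1000).
#' @param q target FDR levels.
#' @param seed RNG seed.
#' @return \linkS4class{SnrProfile}
#' @export
permutationFdr <- function(smoothed, groupA, groupB, nPermutations = 1000,
                           q = c(0.01, 0.05), seed = NULL) {
  B <- as.integer(nPermutations)
  if (B < 100) stop("need at least 100 permutations")
  labels <- smoothed@groupLabels
  selA <- .groupSelector(labels, groupA)
  selB <- .groupSelector(labels, groupB)
  if (any(selA & selB)) stop("groups overlap")
  nA <- sum(selA); nB <- sum(selB)
  if (nA < 2 || nB < 2) stop("each group needs at least 2 samples")
  V <- smoothed@values[selA | selB, , drop = FALSE]
  n <- nrow(V)
  obs <- .snrCore(smoothed@values, selA, selB)
  good <- !is.na(obs)                   # drop grid points with no kernel mass
  V <- V[, good, drop = FALSE]
  G <- sum(good)
  cand <- sort(obs[good])               # candidate thresholds (ascending)
  Robs <- G - seq_len(G)                # #{obs > cand_i}, strict
  totalFalse <- numeric(G)
  runSeeded(seed, {
    for (b in seq_len(B)) {
      permA <- logical(n)
      permA[sample.int(n, nA)] <- TRUE
      snrPerm <- .snrCore(V, permA, !permA)
      totalFalse <- totalFalse + (G - findInterval(cand, sort(snrPerm)))
    }
  })
  fdr <- pmin(1, (totalFalse / B) / pmax(1, Robs))
  # q-value convention: FDR attainable at cutoff t is the best (smallest)
  # plug-in estimate over cutoffs <= t; cummin over ascending candidates
  # makes the curve non-increasing in the threshold
  fdr <- cummin(fdr)
  thresholds <- vapply(q, function(qq) {
    ok <- which(fdr <= qq)
    if (!length(ok)) NA_real_ else cand[min(ok)]
  }, numeric(1))
  names(thresholds) <- as.character(q)
  new("SnrProfile", gridChrom = smoothed@gridChrom,
      gridPos = smoothed@gridPos, gridGlobal = smoothed@gridGlobal,
      snr = obs, groupA = unlist(strsplit(groupA, "+", fixed = TRUE)),
      groupB = unlist(strsplit(groupB, "+", fixed = TRUE)),
      nPermutations = B,
      fdrCurve = data.frame(threshold = cand, fdr = fdr),
      thresholds = thresholds, gridSpacing = smoothed@gridSpacing,
      kernelWidth = smoothed@kernelWidth)
}

#' Differentially aberrant regions at a target FDR
#'
#' Maximal runs of grid points whose observed SNR exceeds the threshold for
#' the requested FDR level, as bp intervals. Errors if the profile carries
#' no threshold for that level (an unattainable level has threshold NA and
#' yields an empty set).
#'
#' @param profile \linkS4class{SnrProfile}
#' @param q FDR level (must be one computed by \code{\link{permutationFdr}}).
#' @return \linkS4class{GRanges} with metadata columns \code{peakSnr} and
#'   \code{q}.
#' @export
differentialRegions <- function(profile, q = 0.01) {
  key <- as.character(q)
  if (!key %in% names(profile@thresholds))
    stop("no threshold computed for q = ", q)
  thr <- profile@thresholds[[key]]
  empty <- GRanges(seqnames = character(0), ranges = IRanges(),
                   peakSnr = numeric(0), q = numeric(0))
  if (is.na(thr)) return(empty)
  exceed <- profile@snr > thr
  exceed[is.na(exceed)] <- FALSE
  if (!any(exceed)) return(empty)
  half <- profile@gridSpacing / 2
  r <- rle(paste0(profile@gridChrom, "_", exceed))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(exceed[starts])
  regs <- do.call(rbind, lapply(keep, function(i) {
    idx <- starts[i]:ends[i]
    data.frame(chrom = profile@gridChrom[starts[i]],
               start = max(1, profile@gridPos[starts[i]] - half),
               end = profile@gridPos[ends[i]] + half,
               peak = max(profile@snr[idx]), stringsAsFactors = FALSE)
  }))
  GRanges(seqnames = regs$chrom,
          ranges = IRanges(start = round(regs$start), end = round(regs$end)),
          peakSnr = regs$peak, q = rep(q, nrow(regs)))
}

setMethod("show", "SnrProfile", function(object) {
  cat("SnrProfile:", paste(object@groupA, collapse = "+"), "vs",
      paste(object@groupB, collapse = "+"), "on",
      length(object@snr), "grid points\n")
  cat(sprintf("  %d permutations; thresholds: %s\n", object@nPermutations,
              paste(sprintf("FDR %s -> %s", names(object@thresholds),
                            format(object@thresholds, digits = 4)),
                    collapse = ", ")))
})

setMethod("show", "SmoothedSampleMatrix", function(object) {
  cat("SmoothedSampleMatrix:", nrow(object@values), "samples x",
      ncol(object@values), "grid points\n")
  cat(sprintf("  kernel width %g bp, grid spacing %g bp, %s\n",
              object@kernelWidth, object@gridSpacing,
              if (object@normalized) "normalized (kernel-weighted mean)"
              else "unnormalized (kernel-weighted sum)"))
})

#' Export an SNR profile as a genome-track table
#'
#' @param profile \linkS4class{SnrProfile}
#' @param path output path (tab-separated: chromosome, bp, snr, and one
#'   exceedance flag per FDR level).
#' @return invisibly, \code{path}.
#' @export
writeSnrTrack <- function(profile, path) {
  out <- data.frame(chromosome = profile@gridChrom, bp = profile@gridPos,
                    global_bp = profile@gridGlobal, snr = profile@snr)
  for (key in names(profile@thresholds)) {
    thr <- profile@thresholds[[key]]
    out[[paste0("flag_fdr", sub("^0\\.", "", key))]] <-
      if (is.na(thr)) FALSE else profile@snr > thr
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
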