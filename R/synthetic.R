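#' Define an aberration segment for the synthetic generator
#'
#' @param chrom chromosome label.
#' @param startBp,endBp segment bounds in bp (half-open interval, must
#'   satisfy startBp < endBp).
#' @param amplitude log2 shift added to carried clones (positive = gain).
#' @param penetrance fraction of samples in the target groups that carry the
#'   segment.
#' @param groups comma-separated target group labels, or \code{"*"} for all.
#' @return one-row data.frame; rbind rows to build segment lists.
#' @export
aberrationSegment <- function(chrom, startBp, endBp, amplitude,
                              penetrance = 1, groups = "*") {
  data.frame(chrom = as.character(chrom), startBp = startBp, endBp = endBp,
             amplitude = amplitude, penetrance = penetrance,
             groups = groups, stringsAsFactors = FALSE)
}

#' Baseline colorectal-cancer-like shared aberrations
#'
#' Qualitative mimic of the aberration landscape common to colorectal
#' tumors regardless of metastatic behaviour: gains of 7, 8q, 13q and
#' low-level 20q, losses of 8p, 17p and 18q. Amplitudes and penetrances are
#' package defaults chosen to make smoothed profiles look realistic; they
#' are configuration, not biological claims.
#'
#' @return segment data.frame (see \code{\link{aberrationSegment}}).
#' @export
crcSharedSegments <- function() {
  rbind(
    aberrationSegment("7", 1, 159138663, 0.18, 0.55),
    aberrationSegment("8", 45600000, 146364022, 0.20, 0.50),
    aberrationSegment("8", 1, 45600000, -0.22, 0.45),
    aberrationSegment("13", 17900000, 115169878, 0.18, 0.45),
    aberrationSegment("17", 1, 24000000, -0.22, 0.50),
    aberrationSegment("18", 17200000, 78077248, -0.25, 0.55),
    aberrationSegment("20", 27500000, 63025520, 0.15, 0.35)
  )
}

#' Construct a SyntheticSpec
#'
#' Defaults describe the study design the generator emulates: three patient
#' groups (liver metastases LM = 36, peritoneal metastases PM = 37,
#' metastasis-free M0 = 25), clones at 1 Mb spacing, per-clone Gaussian
#' noise of sd 0.1 on the log2 ratios, small per-sample baseline offsets,
#' a shared colorectal aberration baseline, and one LM-specific 20q gain
#' segment of amplitude 0.3 at penetrance 0.8.
#'
#' @param groupSizes named integer vector of samples per group.
#' @param sharedSegments segments applied to all groups
#'   (\code{\link{crcSharedSegments}} by default; pass a 0-row data.frame
#'   for none).
#' @param specificSegments group-specific segments; default one 20q gain
#'   targeting LM.
#' @param noiseSd per-clone Gaussian sd of the log2 ratio.
#' @param sampleOffsetSd sd of the per-sample baseline shift.
#' @param cloneSpacing clone spacing in bp.
#' @param arCoef optional AR(1) coefficient for along-genome noise
#'   autocorrelation (0 = independent noise, the default model).
#' @param seed integer RNG seed.
#' @return \linkS4class{SyntheticSpec}
#' @export
syntheticSpec <- function(groupSizes = c(LM = 36L, PM = 37L, M0 = 25L),
                          sharedSegments = crcSharedSegments(),
                          specificSegments = aberrationSegment(
                            "20", 27500000, 63025520, 0.3, 0.8, "LM"),
                          noiseSd = 0.1,
                          sampleOffsetSd = 0.02,
                          cloneSpacing = 1e6,
                          arCoef = 0,
                          seed = 1L) {
  gs <- as.integer(groupSizes)
  names(gs) <- names(groupSizes)
  if (is.null(specificSegments))
    specificSegments <- aberrationSegment("1", 1, 2, 0)[0, ]
  if (is.null(sharedSegments))
    sharedSegments <- aberrationSegment("1", 1, 2, 0)[0, ]
  new("SyntheticSpec", groupSizes = gs,
      sharedSegments = sharedSegments,
      specificSegments = specificSegments,
      noiseSd = noiseSd, sampleOffsetSd = sampleOffsetSd,
      cloneSpacing = cloneSpacing, arCoef = arCoef,
      seed = as.integer(seed))
}

#' Generate the clone map of a synthetic array
#'
#' Places clones at multiples of the clone spacing along each chromosome
#' (positions s, 2s, ..., floor(L/s)*s), emulating a genome-wide clone set
#' at ~1 Mb resolution. Deterministic: no randomness is consumed.
#'
#' @param spec \linkS4class{SyntheticSpec} (only \code{cloneSpacing} is used).
#' @param chromosomes chromosomes to cover; default the full packaged
#'   reference (1-22, X, Y).
#' @param chromLengths optional named lengths overriding the reference
#'   (chromosome order taken from this vector).
#' @return \linkS4class{CloneMap}
#' @export
generateCloneMap <- function(spec, chromosomes = c(as.character(1:22), "X", "Y"),
                             chromLengths = NULL) {
  if (is.null(chromLengths)) {
    info <- hsGenomeInfo(chromosomes)
    chromLengths <- info$lengths
    centromeres <- info$centromeres
  } else {
    centromeres <- pmin(hsGenomeInfo()[["centromeres"]][names(chromLengths)],
                        chromLengths, na.rm = TRUE)
    centromeres[is.na(centromeres)] <- chromLengths[is.na(centromeres)] / 2
    names(centromeres) <- names(chromLengths)
  }
  s <- spec@cloneSpacing
  rows <- lapply(names(chromLengths), function(ch) {
    n <- floor(chromLengths[[ch]] / s)
    if (n < 1) return(NULL)
    pos <- s * seq_len(n)
    data.frame(cloneId = sprintf("chr%s_%04d", ch, seq_len(n)),
               chrom = ch, pos = pos, stringsAsFactors = FALSE)
  })
  cloneMap(do.call(rbind, rows), chromLengths = chromLengths,
           centromeres = centromeres)
}

# Per-clone true mean contribution of segments for one group, given carriage.
# Returns clones x samples matrix of planted amplitudes.
.segmentEffects <- function(segments, carriage, map, groupOf) {
  cl <- cloneTable(map)
  p <- nrow(cl)
  n <- length(groupOf)
  eff <- matrix(0, p, n)
  if (!nrow(segments)) return(eff)
  for (k in seq_len(nrow(segments))) {
    seg <- segments[k, ]
    inSeg <- cl$chrom == seg$chrom & cl$pos >= seg$startBp & cl$pos < seg$endBp
    carriers <- which(carriage[k, ])
    if (length(carriers) && any(inSeg))
      eff[inSeg, carriers] <- eff[inSeg, carriers] + seg$amplitude
  }
  eff
}

.segmentTargets <- function(seg, groupOf) {
  if (seg$groups == "*") rep(TRUE, length(groupOf))
  else groupOf %in% strsplit(seg$groups, ",", fixed = TRUE)[[1]]
}

#' Generate a synthetic aCGH cohort with known truth
#'
#' The generative model: for sample s and clone c,
#' \deqn{log2_{cs} = \sum_{segments carried by s covering c} amplitude
#'   + offset_s + \epsilon_{cs},}
#' with \eqn{\epsilon ~ N(0, noiseSd^2)} independent per clone (optionally
#' AR(1) along each chromosome) and \eqn{offset_s ~ N(0, sampleOffsetSd^2)}.
#' Segment carriage is Bernoulli(penetrance) per sample within the target
#' groups. Fully reproducible from the spec seed; the random stream is
#' consumed in a documented order (sample offsets, then segment carriage
#' with segments in list order and samples in id order — shared segments
#' before specific ones — then the noise matrix sample by sample).
#'
#' @param spec \linkS4class{SyntheticSpec}
#' @param map optional \linkS4class{CloneMap}; default
#'   \code{generateCloneMap(spec, chromosomes = as.character(1:22))}
#'   (autosomes, the chromosomes downstream statistics use).
#' @return list with elements \code{acgh} (\linkS4class{AcghSet}) and
#'   \code{truth} (list: \code{carriage} segments x samples logical matrix,
#'   \code{segments} the combined segment table, \code{trueMean} clones x
#'   samples matrix of planted means, \code{offsets} per-sample baseline).
#' @export
generateCohort <- function(spec, map = NULL) {
  if (is.null(map))
    map <- generateCloneMap(spec, chromosomes = as.character(1:22))
  segs <- rbind(spec@sharedSegments, spec@specificSegments)
  cl <- cloneTable(map)
  if (nrow(segs)) {
    known <- names(map@chromLengths)
    bad <- !(segs$chrom %in% known) |
      segs$startBp > map@chromLengths[segs$chrom]
    if (any(bad))
      stop("segment outside any chromosome: row(s) ",
           paste(which(bad), collapse = ", "))
  }
  groupOf <- rep(names(spec@groupSizes), spec@groupSizes)
  n <- length(groupOf)
  p <- nrow(cl)
  sampleIds <- sprintf("S%03d", seq_len(n))

  runSeeded(spec@seed, {
    offsets <- stats::rnorm(n, 0, spec@sampleOffsetSd)
    carriage <- matrix(FALSE, max(1, nrow(segs)), n)
    if (nrow(segs)) {
      for (k in seq_len(nrow(segs))) {
        targ <- .segmentTargets(segs[k, ], groupOf)
        draw <- stats::runif(n) < segs$penetrance[k]
        carriage[k, ] <- targ & draw
      }
    }
    trueMean <- .segmentEffects(segs, carriage, map, groupOf)
    eps <- matrix(stats::rnorm(p * n, 0, spec@noiseSd), p, n)
    if (spec@arCoef != 0) {
      phi <- spec@arCoef
      sdInnov <- spec@noiseSd * sqrt(1 - phi^2)
      for (ch in unique(cl$chrom)) {
        idx <- which(cl$chrom == ch)
        if (length(idx) < 2) next
        e <- eps[idx, , drop = FALSE]
        for (i in 2:length(idx))
          e[i, ] <- phi * e[i - 1, ] + (sdInnov / spec@noiseSd) * e[i, ]
        eps[idx, ] <- e
      }
    }
    m <- trueMean + matrix(offsets, p, n, byrow = TRUE) + eps
    rownames(m) <- cl$cloneId
    acgh <- acghSet(m, map, group = groupOf, sampleIds = sampleIds,
                    samplesAsRows = FALSE)
    list(acgh = acgh,
         truth = list(carriage = carriage[seq_len(nrow(segs)), , drop = FALSE],
                      segments = segs, trueMean = trueMean,
                      offsets = offsets))
  })
}

#' Generate a null cohort (no group-specific aberrations)
#'
#' Identical to \code{\link{generateCohort}} with the specific segments
#' emptied: all groups share the same generative distribution, so group
#' labels are exchangeable by construction. The calibration input for the
#' permutation procedures.
#'
#' @inheritParams generateCohort
#' @return as \code{\link{generateCohort}}; the truth lists no specific
#'   segments.
#' @export
nullCohort <- function(spec, map = NULL) {
  spec@specificSegments <- spec@specificSegments[0, , drop = FALSE]
  generateCohort(spec, map = map)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so seeded
#' package operations do not disturb the session stream.
#'
#' @param seed integer seed, or NULL to leave the stream untouched.
#' @param expr expression.
#' @return value of \code{expr}.
#' @export
runSeeded <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:",
      paste(sprintf("%s=%d", names(object@groupSizes), object@groupSizes),
            collapse = ", "), "\n")
  cat("  shared segments:", nrow(object@sharedSegments),
      "; specific:", nrow(object@specificSegments), "\n")
  cat(sprintf("  noiseSd=%.3g offsetSd=%.3g spacing=%g seed=%d\n",
              object@noiseSd, object@sampleOffsetSd, object@cloneSpacing,
              object@seed))
})
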