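#' Construct an AcghSet
#'
#' @param log2 numeric matrix of log2 tumor/reference ratios, samples as rows
#'   and clones as columns (the orientation of the on-disk matrix format), or
#'   clones x samples if \code{samplesAsRows = FALSE}. Columns are reordered
#'   to clone-map order by clone id when column names are present; otherwise
#'   column order is assumed to already match the map.
#' @param map \linkS4class{CloneMap} for the array.
#' @param group per-sample group label (e.g. \code{"LM"}, \code{"PM"},
#'   \code{"M0"}); recycled if length 1.
#' @param sampleIds sample identifiers; default from rownames or S1..Sn.
#' @param samplesAsRows orientation of \code{log2}.
#' @return \linkS4class{AcghSet}
#' @export
acghSet <- function(log2, map, group, sampleIds = NULL, samplesAsRows = TRUE) {
  if (samplesAsRows) log2 <- t(log2)
  # now clones x samples
  ids <- cloneTable(map)$cloneId
  if (!is.null(rownames(log2))) {
    miss <- setdiff(rownames(log2), ids)
    if (length(miss))
      stop("clone(s) absent from map: ", paste(utils::head(miss, 10), collapse = ", "))
    miss <- setdiff(ids, rownames(log2))
    if (length(miss))
      stop("map clone(s) absent from matrix: ",
           paste(utils::head(miss, 10), collapse = ", "))
    log2 <- log2[ids, , drop = FALSE]
  } else {
    if (nrow(log2) != length(ids))
      stop("matrix clone dimension does not match clone map")
    rownames(log2) <- ids
  }
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(colnames(log2))) colnames(log2) else
      sprintf("S%03d", seq_len(ncol(log2)))
  colnames(log2) <- sampleIds
  group <- rep_len(as.character(group), ncol(log2))
  cl <- cloneTable(map)
  se <- SummarizedExperiment(
    assays = list(log2 = log2),
    rowData = DataFrame(chrom = cl$chrom, arm = cl$arm, pos = cl$pos,
                        globalBp = cl$globalBp, row.names = cl$cloneId),
    colData = DataFrame(group = group, row.names = sampleIds)
  )
  new("AcghSet", se, cloneMap = map)
}

#' @describeIn acghSet log2 matrix in clones x samples orientation.
#' @param x AcghSet.
#' @export
log2Matrix <- function(x) assay(x, "log2")

#' @describeIn acghSet logical matrix marking missing measurements.
#' @export
missingMask <- function(x) is.na(assay(x, "log2"))

#' @describeIn acghSet per-sample group labels.
#' @export
sampleGroups <- function(x) as.character(colData(x)$group)

#' @describeIn acghSet drop sex-chromosome clones (reference DNA sex
#'   confounds X/Y ratios; downstream statistics run on autosomes by default).
#' @export
keepAutosomes <- function(x) {
  map <- x@cloneMap
  keepCh <- setdiff(names(map@chromLengths), c("X", "Y"))
  keep <- map@clones$chrom %in% keepCh
  if (all(keep)) return(x)
  newMap <- new("CloneMap",
                clones = {
                  cl <- map@clones[keep, , drop = FALSE]
                  rownames(cl) <- NULL
                  # recompute global offsets over the reduced chromosome set
                  offs <- c(0, cumsum(as.numeric(map@chromLengths[keepCh])))
                  names(offs) <- c(keepCh, "_end")
                  cl$globalBp <- offs[cl$chrom] + cl$pos
                  cl
                },
                chromLengths = map@chromLengths[keepCh],
                centromeres = map@centromeres[keepCh])
  acghSet(log2Matrix(x)[keep, , drop = FALSE], newMap,
          group = sampleGroups(x), sampleIds = colnames(x),
          samplesAsRows = FALSE)
}

setMethod("show", "AcghSet", function(object) {
  cat("AcghSet:", ncol(object), "samples x", nrow(object), "clones\n")
  tab <- table(sampleGroups(object))
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  nmiss <- sum(missingMask(object))
  cat("  missing values:", nmiss,
      sprintf("(%.2f%%)\n", 100 * nmiss / length(missingMask(object))))
})

#' Read a log2-ratio matrix from disk
#'
#' Tab-separated, one sample per row: first column \code{sample_id}, then one
#' column per clone with clone ids as header. Blank or \code{NA} cells become
#' missing values. Columns are matched and reordered to clone-map order; a
#' clone in the file that the map does not know is an error listing the
#' offenders.
#'
#' @param path file path.
#' @param map \linkS4class{CloneMap}.
#' @param group per-sample group labels (vector, or name of a column holding
#'   them in a cohort table loaded separately). Default "unknown".
#' @return \linkS4class{AcghSet}
#' @export
loadLog2Matrix <- function(path, map, group = "unknown") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  if (names(tab)[1] != "sample_id")
    stop("first column must be sample_id")
  ids <- tab$sample_id
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  acghSet(m, map, group = group, sampleIds = ids, samplesAsRows = TRUE)
}

#' Write a log2-ratio matrix as a tab-separated table
#' @param x \linkS4class{AcghSet}
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeLog2Matrix <- function(x, path) {
  m <- t(log2Matrix(x))
  out <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort covariate table
#'
#' Tab-separated with a \code{sample_id} key column. Unknowns must be coded
#' explicitly (e.g. \code{"unknown"}); they are never dropped at load time.
#'
#' @param path file path.
#' @param sampleIds optional vector to validate against; an id mismatch is an
#'   error.
#' @return data.frame keyed by sample_id.
#' @export
loadCohortTable <- function(path, sampleIds = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(tab))
    stop("cohort table must have a sample_id column")
  if (!is.null(sampleIds)) {
    miss <- setdiff(sampleIds, tab$sample_id)
    if (length(miss))
      stop("cohort table missing sample(s): ", paste(miss, collapse = ", "))
    tab <- tab[match(sampleIds, tab$sample_id), , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Average replicate spot measurements per clone
#'
#' Arithmetic mean of the non-missing replicate log2 values of each clone
#' (arrays spot each clone in triplicate; the replicates are averaged before
#' analysis). A clone whose replicates are all missing yields \code{NA}.
#'
#' @param spots long-format data.frame with columns \code{cloneId} and
#'   \code{log2} (a replicate index column may be present but is not used).
#' @return named numeric vector of per-clone means, in first-appearance order.
#' @export
averageReplicates <- function(spots) {
  if (!all(c("cloneId", "log2") %in% names(spots)))
    stop("spot table must have columns cloneId, log2")
  ids <- unique(spots$cloneId)
  out <- vapply(split(spots$log2, factor(spots$cloneId, levels = ids)),
                function(v) {
                  v <- v[!is.na(v)]
                  if (!length(v)) NA_real_ else mean(v)
                }, numeric(1))
  out[ids]
}

#' Median-center each sample
#'
#' Removes the per-sample offset: after centering, the non-missing log2
#' values of every sample have median zero. Idempotent and
#' difference-preserving within a sample. This is the clone-level analogue
#' of the median subarray normalization applied to the physical arrays.
#'
#' @param x \linkS4class{AcghSet}
#' @return \linkS4class{AcghSet} with centered assay.
#' @export
medianCenter <- function(x) {
  m <- log2Matrix(x)
  med <- apply(m, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  assay(x, "log2") <- sweep(m, 2, med)
  x
}

#' Per-sample mean log2 over a genomic region
#'
#' Mean of the non-missing log2 values over the clones whose midpoint falls
#' in the region. A region is a chromosome, a chromosome arm, or a bp
#' interval treated half-open \code{[startBp, endBp)}. The mean 20q log2
#' used by the logistic-regression and ROC analyses is
#' \code{regionMeanLog2(x, "20", arm = "q")}.
#'
#' @param x \linkS4class{AcghSet}
#' @param chrom chromosome label.
#' @param arm optional \code{"p"} or \code{"q"}.
#' @param startBp,endBp optional interval bounds (half-open).
#' @return named numeric, one value per sample (NaN if a sample has no
#'   non-missing clone in the region).
#' @export
regionMeanLog2 <- function(x, chrom, arm = NULL, startBp = NULL, endBp = NULL) {
  cl <- cloneTable(x)
  sel <- cl$chrom == as.character(chrom)
  if (!is.null(arm)) sel <- sel & cl$arm == arm
  if (!is.null(startBp)) sel <- sel & cl$pos >= startBp
  if (!is.null(endBp)) sel <- sel & cl$pos < endBp
  if (!any(sel))
    stop("region contains no clones")
  colMeans(log2Matrix(x)[sel, , drop = FALSE], na.rm = TRUE)
}

#' Approximate absolute copy number from mean log2
#'
#' A region with mean log2 ratio r in a tumor of reference ploidy P has
#' approximate absolute copy number P * 2^r (so 0 maps to 2 copies, +1 to 4,
#' -1 to 1).
#'
#' @param meanLog2 numeric (vectorized).
#' @param referencePloidy reference copy number, default 2.
#' @return numeric copy-number estimates.
#' @export
copyNumberEstimate <- function(meanLog2, referencePloidy = 2) {
  referencePloidy * 2^meanLog2
}

#' Impute missing log2 values by chromosome-arm median
#'
#' Replaces each missing value by the sample's median over the non-missing
#' clones of the same chromosome arm (falling back to the chromosome, then
#' the whole sample), keeping local copy-number context. Used upstream of
#' the classifier, which requires complete data.
#'
#' @param x \linkS4class{AcghSet}
#' @return \linkS4class{AcghSet} without missing values.
#' @export
imputeArmMedian <- function(x) {
  m <- log2Matrix(x)
  if (!anyNA(m)) return(x)
  cl <- cloneTable(x)
  armKey <- paste0(cl$chrom, cl$arm)
  for (j in seq_len(ncol(m))) {
    nas <- which(is.na(m[, j]))
    if (!length(nas)) next
    armMed <- tapply(m[, j], armKey, stats::median, na.rm = TRUE)
    chrMed <- tapply(m[, j], cl$chrom, stats::median, na.rm = TRUE)
    fill <- armMed[armKey[nas]]
    fill[is.na(fill)] <- chrMed[cl$chrom[nas]][is.na(fill)]
    fill[is.na(fill)] <- stats::median(m[, j], na.rm = TRUE)
    fill[is.na(fill)] <- 0
    m[nas, j] <- fill
  }
  assay(x, "log2") <- m
  x
}
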