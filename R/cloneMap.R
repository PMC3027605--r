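#' Packaged human genome reference table
#'
#' Chromosome lengths and centromere positions (bp) for chromosomes 1-22, X
#' and Y, GRCh37-era assembly values. These drive arm assignment and the
#' head-to-tail genome layout; both tables can be overridden in
#' \code{\link{cloneMap}} and \code{\link{loadCloneMap}} when an array was
#' mapped to another build.
#'
#' @param chromosomes character vector of chromosome labels to keep, in the
#'   desired head-to-tail order. Default: 1-22, X, Y.
#' @return list with named numeric vectors \code{lengths} and
#'   \code{centromeres}.
#' @export
#' @examples
#' hsGenomeInfo(c("20"))$centromeres
hsGenomeInfo <- function(chromosomes = c(as.character(1:22), "X", "Y")) {
  lengths <- c(
    "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
    "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
    "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
    "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
    "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
    "21" = 48129895, "22" = 51304566, "X" = 155270560, "Y" = 59373566
  )
  centromeres <- c(
    "1" = 125000000, "2" = 93300000, "3" = 91000000, "4" = 50400000,
    "5" = 48400000, "6" = 61000000, "7" = 59900000, "8" = 45600000,
    "9" = 49000000, "10" = 40200000, "11" = 53700000, "12" = 35800000,
    "13" = 17900000, "14" = 17600000, "15" = 19000000, "16" = 36600000,
    "17" = 24000000, "18" = 17200000, "19" = 26500000, "20" = 27500000,
    "21" = 13200000, "22" = 14700000, "X" = 60600000, "Y" = 12500000
  )
  miss <- setdiff(chromosomes, names(lengths))
  if (length(miss))
    stop("unknown chromosome label(s): ", paste(miss, collapse = ", "))
  list(lengths = lengths[chromosomes], centromeres = centromeres[chromosomes])
}

#' Construct a CloneMap from a clone annotation table
#'
#' Assigns arms from the centromere table (position <= centromere is p, else
#' q), orders clones head-to-tail (chromosomes in reference order, positions
#' increasing) and computes the cumulative global coordinate. Unsorted input
#' is sorted with a notice; duplicate clone ids and unknown chromosome
#' labels are hard errors.
#'
#' @param clones data.frame with columns \code{cloneId}, \code{chrom},
#'   \code{pos} (clone midpoint, bp, 1-based).
#' @param chromLengths named numeric of chromosome lengths; defaults to the
#'   packaged reference restricted to the chromosomes present.
#' @param centromeres named numeric of centromere positions; same default.
#' @return \linkS4class{CloneMap}
#' @export
cloneMap <- function(clones, chromLengths = NULL, centromeres = NULL) {
  need <- c("cloneId", "chrom", "pos")
  if (!all(need %in% names(clones)))
    stop("clone table must have columns ", paste(need, collapse = ", "))
  clones$cloneId <- as.character(clones$cloneId)
  clones$chrom <- sub("^chr", "", as.character(clones$chrom))
  if (anyDuplicated(clones$cloneId))
    stop("duplicate clone id(s): ",
         paste(unique(clones$cloneId[duplicated(clones$cloneId)]), collapse = ", "))
  if (is.null(chromLengths) || is.null(centromeres)) {
    known <- hsGenomeInfo()
    order_ <- intersect(names(known$lengths), unique(clones$chrom))
    bad <- setdiff(unique(clones$chrom), names(known$lengths))
    if (length(bad))
      stop("unknown chromosome label(s): ", paste(bad, collapse = ", "))
    if (is.null(chromLengths)) chromLengths <- known$lengths[order_]
    if (is.null(centromeres)) centromeres <- known$centromeres[names(chromLengths)]
  }
  bad <- setdiff(unique(clones$chrom), names(chromLengths))
  if (length(bad))
    stop("unknown chromosome label(s): ", paste(bad, collapse = ", "))
  ord <- order(match(clones$chrom, names(chromLengths)), clones$pos)
  if (is.unsorted(ord)) {
    message("clone table not in head-to-tail order; sorting")
    clones <- clones[ord, , drop = FALSE]
  }
  offsets <- c(0, cumsum(as.numeric(chromLengths)))[seq_along(chromLengths)]
  names(offsets) <- names(chromLengths)
  clones$arm <- ifelse(clones$pos <= centromeres[clones$chrom], "p", "q")
  clones$globalBp <- offsets[clones$chrom] + clones$pos
  rownames(clones) <- NULL
  new("CloneMap",
      clones = clones[, c("cloneId", "chrom", "arm", "pos", "globalBp")],
      chromLengths = chromLengths, centromeres = centromeres)
}

#' Read a clone map from disk
#'
#' Accepts either a tab-separated table with columns \code{clone_id} (or
#' \code{cloneId}), \code{chromosome} (or \code{chrom}), \code{position_bp}
#' (or \code{pos}), or a headerless 4-column BED file (chrom, start, end,
#' name) whose interval midpoint becomes the clone position.
#'
#' @param path file path.
#' @param chromLengths,centromeres optional overrides, as in
#'   \code{\link{cloneMap}}.
#' @return \linkS4class{CloneMap}
#' @export
loadCloneMap <- function(path, chromLengths = NULL, centromeres = NULL) {
  first <- readLines(path, n = 1)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  headered <- any(c("clone_id", "cloneId") %in% fields)
  if (headered) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    ren <- c(clone_id = "cloneId", chromosome = "chrom",
             position_bp = "pos")
    for (nm in names(ren))
      if (nm %in% names(tab)) names(tab)[names(tab) == nm] <- ren[[nm]]
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 4)
      stop("headerless clone map must be 4-column BED (chrom, start, end, name)")
    tab <- data.frame(cloneId = as.character(tab[[4]]), chrom = tab[[1]],
                      pos = floor((tab[[2]] + tab[[3]]) / 2) + 1,
                      stringsAsFactors = FALSE)
  }
  cloneMap(tab, chromLengths = chromLengths, centromeres = centromeres)
}

#' Write a clone map as a tab-separated table
#' @param map \linkS4class{CloneMap}
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeCloneMap <- function(map, path) {
  tab <- map@clones[, c("cloneId", "chrom", "pos")]
  names(tab) <- c("clone_id", "chromosome", "position_bp")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn cloneMap clone annotation table (one row per clone, head-to-tail
#'   order) of a CloneMap or of the map embedded in an AcghSet.
#' @param x CloneMap or AcghSet.
#' @export
cloneTable <- function(x) {
  if (is(x, "AcghSet")) x <- x@cloneMap
  x@clones
}

#' @describeIn cloneMap number of clones.
#' @export
nClones <- function(x) nrow(cloneTable(x))

#' @describeIn cloneMap chromosome lengths used by the map.
#' @export
chromLengths <- function(x) {
  if (is(x, "AcghSet")) x <- x@cloneMap
  x@chromLengths
}

#' @describeIn cloneMap centromere positions used by the map.
#' @export
centromeres <- function(x) {
  if (is(x, "AcghSet")) x <- x@cloneMap
  x@centromeres
}

setMethod("show", "CloneMap", function(object) {
  cl <- object@clones
  cat("CloneMap with", nrow(cl), "clones on",
      length(unique(cl$chrom)), "chromosomes\n")
  cat("  arms: p =", sum(cl$arm == "p"), ", q =", sum(cl$arm == "q"), "\n")
  cat("  span:", names(object@chromLengths)[1], "..",
      names(object@chromLengths)[length(object@chromLengths)], "\n")
})
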