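# Packaged fixtures: transcriptions of the cohort's published
# patient-characteristics counts and of the chromosome-20 clone table
# (with the classifier-membership markup as a logical flag). The clone
# positions in the chromosome-20 fixture are nominal — evenly spaced on
# the correct arm — because the publication states clone order and arm,
# not build coordinates.

#' Parse decimal-comma numerals
#'
#' The transcribed tables print p-values with decimal commas ("0,027");
#' this accepts both comma and point decimals.
#'
#' @param x character vector.
#' @return numeric vector.
#' @export
parseDecimal <- function(x) {
  as.numeric(sub(",", ".", as.character(x), fixed = TRUE))
}

#' Packaged patient-characteristics contingency tables
#'
#' Counts of the three patient groups (M0, PM, LM) over the published
#' clinicopathological covariates, with explicitly coded "unknown"
#' categories, plus the printed p-value per covariate (decimal-comma
#' numerals parsed).
#'
#' @return list: \code{counts} (data.frame variable, category, M0, PM, LM)
#'   and \code{printedP} (named numeric).
#' @export
table1Fixture <- function() {
  counts <- utils::read.delim(
    system.file("extdata", "table1_counts.tsv", package = "acghMet"),
    stringsAsFactors = FALSE, check.names = FALSE)
  pv <- utils::read.delim(
    system.file("extdata", "table1_pvalues.tsv", package = "acghMet"),
    stringsAsFactors = FALSE)
  printedP <- parseDecimal(pv$printed_p)
  names(printedP) <- pv$variable
  list(counts = counts, printedP = printedP)
}

#' Contingency table of one covariate from the packaged counts
#'
#' @param variable covariate name (e.g. \code{"location"}).
#' @param dropUnknown exclude explicitly coded unknown categories.
#' @return categories x groups count matrix.
#' @export
table1Contingency <- function(variable, dropUnknown = TRUE) {
  fx <- table1Fixture()
  sub <- fx$counts[fx$counts$variable == variable, , drop = FALSE]
  if (!nrow(sub)) stop("unknown variable: ", variable)
  if (dropUnknown)
    sub <- sub[!tolower(sub$category) %in% "unknown", , drop = FALSE]
  m <- as.matrix(sub[, c("M0", "PM", "LM")])
  rownames(m) <- sub$category
  m
}

#' Packaged chromosome-20 clone table
#'
#' The 65 chromosome-20 clones of the array with arm assignment and a
#' logical \code{in_lm_pam} flag transcribing the classifier-membership
#' markup (34 of the 44 q-arm clones are flagged). Positions are nominal:
#' evenly spaced within the correct arm.
#'
#' @return data.frame: clone_id, chromosome, arm, position_bp, in_lm_pam.
#' @export
table2Fixture <- function() {
  utils::read.delim(
    system.file("extdata", "table2_chr20_clones.tsv", package = "acghMet"),
    stringsAsFactors = FALSE)
}
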