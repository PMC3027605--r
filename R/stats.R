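# Cohort statistics: contingency-table comparisons of the patient groups
# and the logistic-regression odds-ratio analysis of regional copy number
# (mean 20q log2) as a predictor of liver metastasis.

#' Pearson chi-square test of independence
#'
#' Pearson chi-square without continuity correction on an r x c count
#' table, after dropping all-zero rows and columns; p-value from the
#' chi-square upper tail with (r-1)(c-1) degrees of freedom. The group
#' comparisons of the patient-characteristics table reproduce under
#' exactly this test, with "unknown" categories excluded by the caller.
#' A warning (not an error) is emitted when any expected cell count is
#' below 5.
#'
#' @param tab matrix of nonnegative integer counts (rows and columns may
#'   carry labels).
#' @return list: \code{observed} (table after dropping zero margins),
#'   \code{expected}, \code{statistic}, \code{df}, \code{p.value},
#'   \code{warnings} (character vector).
#' @export
chiSquareIndependence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("degenerate table after dropping all-zero margins")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  warns <- character(0)
  if (any(res$expected < 5))
    warns <- sprintf("%d expected cell(s) below 5; chi-square approximation is rough",
                     sum(res$expected < 5))
  for (w in warns) warning(w, call. = FALSE)
  list(observed = tab, expected = res$expected,
       statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = unname(res$p.value), warnings = warns)
}

#' Logistic regression with Wald confidence intervals
#'
#' Maximum-likelihood logistic fit (IRLS; convergence when the relative
#' deviance change drops below 1e-8, at most 100 iterations) with Wald
#' standard errors, p-values and confidence intervals at a configurable
#' level (default 90%, the reporting convention of the 20q odds-ratio
#' analysis). Perfect separation is detected and reported as an error
#' naming the offending covariate rather than returned as a divergent fit.
#'
#' @param outcome binary vector (logical, 0/1, or two-level factor; the
#'   second level is the event).
#' @param covariates data.frame (or named list) of per-sample covariates.
#' @param ciLevel confidence level for the Wald intervals.
#' @return list of class fields: \code{coefficients}, \code{se}, \code{z},
#'   \code{p.value}, \code{ci} (matrix with lower/upper), \code{ciLevel},
#'   \code{n}, \code{converged}, \code{fit} (the glm object).
#' @export
logisticFit <- function(outcome, covariates, ciLevel = 0.90) {
  if (is.factor(outcome)) outcome <- as.integer(outcome) - 1L
  outcome <- as.numeric(outcome)
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary")
  if (length(unique(outcome)) < 2)
    stop("both outcome classes must be present")
  covariates <- as.data.frame(covariates)
  dat <- cbind(data.frame(.y = outcome), covariates)
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged)
    stop("IRLS did not converge in 100 iterations; last deviance ",
         format(fit$deviance))
  sm <- summary(fit)$coefficients
  beta <- stats::setNames(sm[, "Estimate"], rownames(sm))
  se <- stats::setNames(sm[, "Std. Error"], rownames(sm))
  big <- which(abs(beta[-1]) > 15 | se[-1] > 1e3)
  if (length(big)) {
    # huge coefficient/SE on the logit scale: separation diagnostics
    fitted <- stats::fitted(fit)
    if (all(abs(fitted - outcome) < 1e-4))
      stop("perfect separation on covariate(s): ",
           paste(names(beta[-1])[big], collapse = ", "))
  }
  z <- stats::qnorm(1 - (1 - ciLevel) / 2)
  ci <- cbind(lower = beta - z * se, upper = beta + z * se)
  rownames(ci) <- rownames(sm)
  list(coefficients = beta, se = se,
       z = stats::setNames(sm[, "z value"], rownames(sm)),
       p.value = stats::setNames(sm[, "Pr(>|z|)"], rownames(sm)),
       ci = ci, ciLevel = ciLevel,
       n = length(outcome), converged = fit$converged, fit = fit)
}

#' Odds ratio per unit change of a covariate
#'
#' For a logistic coefficient beta, the odds ratio for a change of
#' \code{unit} in the covariate is exp(unit * beta), with Wald CI endpoints
#' exp(unit * (beta +/- z * SE)). The default unit 0.1 expresses the odds
#' ratio per 0.1 increase in mean regional log2 ratio, the scale on which
#' the 20q-amplification risk is reported.
#'
#' @param fit result of \code{\link{logisticFit}}.
#' @param covariate coefficient name.
#' @param unit covariate change the OR refers to.
#' @param ciLevel confidence level; default the fit's level.
#' @return list: \code{or}, \code{ci} (length-2), \code{unit},
#'   \code{ciLevel}.
#' @export
oddsRatioPerUnit <- function(fit, covariate, unit = 0.1, ciLevel = NULL) {
  if (!covariate %in% names(fit$coefficients))
    stop("covariate not in fit: ", covariate)
  if (is.null(ciLevel)) ciLevel <- fit$ciLevel
  beta <- fit$coefficients[[covariate]]
  se <- fit$se[[covariate]]
  z <- stats::qnorm(1 - (1 - ciLevel) / 2)
  list(or = exp(unit * beta),
       ci = c(lower = exp(unit * (beta - z * se)),
              upper = exp(unit * (beta + z * se))),
       unit = unit, ciLevel = ciLevel)
}

#' Group-comparison tests over a cohort covariate table
#'
#' Cross-tabulates each requested categorical covariate against the group
#' label, excludes rows whose value is in \code{excludeValues} (unknowns
#' are coded explicitly, never silently dropped at load time — they are
#' excluded here, at test time), and runs
#' \code{\link{chiSquareIndependence}}.
#'
#' @param cohort data.frame with a group column and covariate columns.
#' @param covariates character vector of covariate column names; default
#'   all columns except \code{sample_id} and the group column.
#' @param groupCol name of the group column.
#' @param excludeValues values treated as unknown.
#' @return data.frame: covariate, statistic, df, p.value, note.
#' @export
cohortComparisons <- function(cohort, covariates = NULL, groupCol = "group",
                              excludeValues = c("unknown", "Unknown", "", NA)) {
  if (is.null(covariates))
    covariates <- setdiff(names(cohort), c("sample_id", groupCol))
  rows <- lapply(covariates, function(cv) {
    val <- cohort[[cv]]
    keep <- !(val %in% excludeValues) & !is.na(val)
    tab <- table(val[keep], cohort[[groupCol]][keep])
    res <- tryCatch(suppressWarnings(chiSquareIndependence(tab)),
                    error = function(e) NULL)
    if (is.null(res))
      return(data.frame(covariate = cv, statistic = NA, df = NA,
                        p.value = NA, note = "degenerate table"))
    data.frame(covariate = cv, statistic = res$statistic, df = res$df,
               p.value = res$p.value,
               note = if (length(res$warnings)) res$warnings[1] else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
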