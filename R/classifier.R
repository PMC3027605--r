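# Nearest shrunken centroids (PAM-style) classification of metastasis site
# from clone-level log2 profiles.
#
# Training statistics for class k and feature i:
#   d_ik  = (xbar_ik - xbar_i) / (m_k (s_i + s0)),   m_k = sqrt(1/n_k - 1/n)
#   d'_ik = sign(d_ik) max(|d_ik| - delta, 0)        (soft thresholding)
#   xbar'_ik = xbar_i + m_k (s_i + s0) d'_ik         (shrunken centroid)
# with s_i the pooled within-class sd and s0 the median of the s_i.
# Prediction: discriminant
#   delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log prior_k,
# class = argmin, probabilities proportional to exp(-delta_k / 2).

# Shrinkage-independent training statistics.
.nscStats <- function(X, y, priors = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (anyNA(X)) stop("missing values; impute upstream (imputeArmMedian)")
  classes <- sort(unique(y))
  K <- length(classes)
  if (K < 2) stop("need at least 2 classes")
  n <- nrow(X); p <- ncol(X)
  nk <- vapply(classes, function(k) sum(y == k), integer(1))
  if (any(nk < 2))
    stop("class with fewer than 2 samples: ",
         paste(classes[nk < 2], collapse = ", "))
  cent <- vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]),
                 numeric(p))
  overall <- colMeans(X)
  ssw <- numeric(p)
  for (j in seq_len(K)) {
    Xi <- X[y == classes[j], , drop = FALSE]
    ssw <- ssw + colSums(sweep(Xi, 2, cent[, j])^2)
  }
  si <- sqrt(ssw / (n - K))
  s0 <- stats::median(si)
  mk <- sqrt(1 / nk - 1 / n)
  if (is.null(priors)) priors <- nk / n else {
    priors <- priors[classes]
    priors <- priors / sum(priors)
  }
  dik <- sweep(cent - overall, 1, si + s0, "/")
  dik <- sweep(dik, 2, mk, "/")
  feat <- if (!is.null(colnames(X))) colnames(X) else
    sprintf("f%05d", seq_len(p))
  list(classes = classes, featureNames = feat, overall = overall,
       cent = cent, si = si, s0 = s0, mk = mk, nk = nk,
       priors = priors, dik = dik)
}

.nscShrink <- function(st, delta) {
  if (delta < 0) stop("delta must be nonnegative")
  dShr <- sign(st$dik) * pmax(abs(st$dik) - delta, 0)
  shrunk <- st$overall +
    sweep(sweep(dShr, 2, st$mk, "*"), 1, st$si + st$s0, "*")
  dimnames(shrunk) <- list(st$featureNames, st$classes)
  dimnames(dShr) <- dimnames(shrunk)
  rawCent <- st$cent
  dimnames(rawCent) <- dimnames(shrunk)
  pr <- as.numeric(st$priors)
  names(pr) <- st$classes
  new("NscModel", classLabels = st$classes, featureNames = st$featureNames,
      overallCentroid = unname(st$overall), classCentroids = rawCent,
      shrunkenCentroids = shrunk, dik = st$dik, dikShrunk = dShr,
      pooledSd = unname(st$si), s0 = st$s0, mk = unname(st$mk),
      delta = delta, priors = pr,
      classSizes = {
        ns <- as.integer(st$nk); names(ns) <- st$classes; ns
      })
}

#' Train a nearest shrunken centroids classifier
#'
#' @param X samples x features numeric matrix (no missing values; see
#'   \code{\link{imputeArmMedian}}).
#' @param y class label per sample.
#' @param delta shrinkage threshold (>= 0; 0 = plain nearest centroid with
#'   pooled standardization).
#' @param priors optional named class priors; default empirical class
#'   frequencies.
#' @return \linkS4class{NscModel}
#' @export
trainNsc <- function(X, y, delta = 0, priors = NULL) {
  .nscShrink(.nscStats(X, y, priors), delta)
}

#' @describeIn trainNsc features with at least one nonzero shrunken
#'   centroid difference (the model's selected feature set).
#' @param model \linkS4class{NscModel}
#' @export
selectedFeatures <- function(model) {
  model@featureNames[rowSums(abs(model@dikShrunk) > 0) > 0]
}

#' Predict with a nearest shrunken centroids model
#'
#' @param model \linkS4class{NscModel}
#' @param X feature vector or samples x features matrix, columns in model
#'   feature order.
#' @return list with \code{label} (character vector) and \code{prob}
#'   (samples x classes matrix, rows summing to 1). Discriminant ties are
#'   broken toward the larger prior, then label order.
#' @export
predictNsc <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  p <- length(model@featureNames)
  if (ncol(X) != p)
    stop("feature dimension mismatch: got ", ncol(X), ", expected ", p)
  s <- model@pooledSd + model@s0
  K <- length(model@classLabels)
  disc <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    d <- sweep(X, 2, model@shrunkenCentroids[, k])
    disc[, k] <- rowSums(sweep(d, 2, s, "/")^2) - 2 * log(model@priors[k])
  }
  colnames(disc) <- model@classLabels
  # probabilities with a stability shift
  e <- exp(-(disc - apply(disc, 1, min)) / 2)
  prob <- e / rowSums(e)
  ord <- order(-model@priors, model@classLabels)  # tie-break preference
  label <- apply(disc, 1, function(d) {
    best <- which(d == min(d))
    model@classLabels[ord[ord %in% best][1]]
  })
  list(label = unname(label), prob = prob)
}

#' Cross-validate the shrinkage level of an NSC classifier
#'
#' Stratified k-fold cross-validation over a grid of shrinkage levels.
#' Reports the mean misclassification error per delta and chooses, by the
#' one-standard-error parsimony rule, the largest delta (most shrinkage,
#' fewest features) whose error is within one standard error of the
#' minimum.
#'
#' @param X samples x features matrix.
#' @param y class labels.
#' @param deltaGrid numeric vector of candidate shrinkage levels.
#' @param nFolds number of folds (default 10; capped at the smallest class
#'   size so every fold's training set keeps all classes).
#' @param seed RNG seed for fold assignment.
#' @param priors optional class priors passed to training.
#' @return list: \code{delta} (grid), \code{cvError}, \code{se} (per-delta
#'   standard error over folds), \code{bestDelta}, \code{folds} (fold id
#'   per sample).
#' @export
crossValidateNsc <- function(X, y, deltaGrid, nFolds = 10, seed = NULL,
                             priors = NULL) {
  if (!length(deltaGrid)) stop("empty delta grid")
  X <- as.matrix(X)
  y <- as.character(y)
  n <- nrow(X)
  minClass <- min(table(y))
  nFolds <- max(2, min(nFolds, minClass))
  deltaGrid <- sort(deltaGrid)
  runSeeded(seed, {
    fold <- integer(n)
    for (k in unique(y)) {
      idx <- sample(which(y == k))
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
    errs <- matrix(NA_real_, nFolds, length(deltaGrid))
    for (f in seq_len(nFolds)) {
      tr <- fold != f
      st <- .nscStats(X[tr, , drop = FALSE], y[tr], priors)
      for (j in seq_along(deltaGrid)) {
        mod <- .nscShrink(st, deltaGrid[j])
        pred <- predictNsc(mod, X[!tr, , drop = FALSE])$label
        errs[f, j] <- mean(pred != y[!tr])
      }
    }
    cvError <- colMeans(errs)
    se <- apply(errs, 2, stats::sd) / sqrt(nFolds)
    iMin <- which.min(cvError)
    ok <- which(cvError <= cvError[iMin] + se[iMin])
    bestDelta <- max(deltaGrid[ok])
    list(delta = deltaGrid, cvError = cvError, se = se,
         bestDelta = bestDelta, folds = fold)
  })
}

#' ROC curve and AUC from a real-valued score
#'
#' Ranks samples by score (higher = more positive-like), groups ties, and
#' walks the grouped thresholds from (0,0) to (1,1); AUC by the trapezoid
#' rule, which under tied scores equals the Mann-Whitney statistic with the
#' usual tie correction.
#'
#' @param scores numeric score per sample.
#' @param truth true labels.
#' @param positiveLabel label counted as positive.
#' @return list: \code{points} data.frame (fpr, tpr, one row per distinct
#'   score plus the origin) and \code{auc}.
#' @export
rocFromScore <- function(scores, truth, positiveLabel) {
  truth <- as.character(truth)
  if (!positiveLabel %in% truth) stop("no positive samples in truth")
  pos <- truth == positiveLabel
  if (all(pos)) stop("no negative samples in truth")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(!duplicated(s))
  tpG <- tapply(p, grp, sum)
  fpG <- tapply(!p, grp, sum)
  tpr <- c(0, cumsum(tpG)) / sum(pos)
  fpr <- c(0, cumsum(fpG)) / sum(!pos)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate classifier predictions
#'
#' Confusion matrix and derived rates for a declared positive class, plus
#' the ROC curve and AUC from the positive-class probabilities.
#'
#' @param predictions predicted labels.
#' @param probabilities samples x classes probability matrix (as returned
#'   by \code{\link{predictNsc}}), or a numeric vector of positive-class
#'   probabilities.
#' @param truth true labels.
#' @param positiveLabel the positive class.
#' @return list: \code{confusion} (truth x prediction table),
#'   \code{accuracy}, \code{sensitivity}, \code{specificity}, \code{roc},
#'   \code{auc}.
#' @export
evaluateClassifier <- function(predictions, probabilities, truth,
                               positiveLabel) {
  truth <- as.character(truth)
  predictions <- as.character(predictions)
  labs <- sort(unique(c(truth, predictions)))
  if (!positiveLabel %in% labs)
    stop("unknown positive label: ", positiveLabel)
  conf <- table(truth = factor(truth, labs),
                prediction = factor(predictions, labs))
  acc <- sum(diag(conf)) / sum(conf)
  isPos <- truth == positiveLabel
  predPos <- predictions == positiveLabel
  sens <- sum(isPos & predPos) / sum(isPos)
  spec <- sum(!isPos & !predPos) / sum(!isPos)
  score <- if (is.matrix(probabilities)) probabilities[, positiveLabel]
           else as.numeric(probabilities)
  roc <- rocFromScore(score, truth, positiveLabel)
  list(confusion = conf, accuracy = acc, sensitivity = sens,
       specificity = spec, roc = roc$points, auc = roc$auc)
}

#' Annotated feature report with chromosome-arm enrichment
#'
#' Lists the selected clones of a trained model with their chromosome and
#' arm, and tests each arm for enrichment among the selected features by a
#' one-sided hypergeometric tail (drawing |selected| clones from the array
#' without replacement; p = P(X >= observed count on the arm)).
#'
#' @param model \linkS4class{NscModel} trained on clone-level features.
#' @param map \linkS4class{CloneMap} (feature names must be clone ids).
#' @return list: \code{features} (data.frame cloneId, chrom, arm,
#'   maxAbsDik) and \code{enrichment} (data.frame arm, nArray, nSelected,
#'   pHypergeom, ordered by p).
#' @export
featureReport <- function(model, map) {
  cl <- cloneTable(map)
  sel <- selectedFeatures(model)
  idx <- match(sel, cl$cloneId)
  if (anyNA(idx))
    stop("model features are not clone ids of this map")
  feats <- data.frame(cloneId = sel, chrom = cl$chrom[idx],
                      arm = cl$arm[idx],
                      maxAbsDik = apply(abs(
                        model@dikShrunk[match(sel, model@featureNames), ,
                                        drop = FALSE]), 1, max),
                      stringsAsFactors = FALSE)
  armKeyAll <- paste0(cl$chrom, cl$arm)
  armsOnArray <- unique(armKeyAll)
  nSel <- length(sel)
  N <- nrow(cl)
  enr <- do.call(rbind, lapply(armsOnArray, function(a) {
    K <- sum(armKeyAll == a)
    k <- sum(paste0(feats$chrom, feats$arm) == a)
    p <- if (nSel == 0) 1 else
      stats::phyper(k - 1, K, N - K, nSel, lower.tail = FALSE)
    data.frame(arm = a, nArray = K, nSelected = k, pHypergeom = p,
               stringsAsFactors = FALSE)
  }))
  enr <- enr[order(enr$pHypergeom), ]
  rownames(enr) <- NULL
  if (nSel == 0) feats <- feats[0, , drop = FALSE]
  list(features = feats, enrichment = enr)
}

setMethod("show", "NscModel", function(object) {
  cat("NscModel:", length(object@classLabels), "classes (",
      paste(object@classLabels, collapse = ", "), ")\n")
  cat(sprintf("  delta = %g, s0 = %.4g, selected features: %d / %d\n",
              object@delta, object@s0, length(selectedFeatures(object)),
              length(object@featureNames)))
  cat("  priors:", paste(sprintf("%s=%.3f", names(object@priors),
                                 object@priors), collapse = ", "), "\n")
})

#' Serialize / restore an NSC model as a flat text file
#'
#' Header lines (key=value: labels, delta, s0, priors, class sizes, mk)
#' followed by a tab-separated centroid table (feature, pooledSd, overall,
#' one raw and one shrunken centroid column per class).
#'
#' @param model \linkS4class{NscModel}
#' @param path file path.
#' @return \code{writeNscModel}: invisibly, \code{path};
#'   \code{readNscModel}: \linkS4class{NscModel}.
#' @export
writeNscModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("#nsc labels=", paste(model@classLabels, collapse = ","))
  w("#nsc delta=", format(model@delta, digits = 17))
  w("#nsc s0=", format(model@s0, digits = 17))
  w("#nsc priors=", paste(format(model@priors, digits = 17), collapse = ","))
  w("#nsc classSizes=", paste(model@classSizes, collapse = ","))
  tab <- data.frame(feature = model@featureNames,
                    pooledSd = model@pooledSd,
                    overall = model@overallCentroid,
                    check.names = FALSE)
  for (k in model@classLabels) {
    tab[[paste0("raw.", k)]] <- model@classCentroids[, k]
    tab[[paste0("shrunk.", k)]] <- model@shrunkenCentroids[, k]
  }
  utils::write.table(format(tab, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNscModel
#' @export
readNscModel <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#nsc ", lines, value = TRUE)
  getv <- function(key) sub(paste0("^#nsc ", key, "="), "",
                            grep(paste0("^#nsc ", key, "="), hdr, value = TRUE))
  labels <- strsplit(getv("labels"), ",")[[1]]
  delta <- as.numeric(getv("delta"))
  s0 <- as.numeric(getv("s0"))
  priors <- as.numeric(strsplit(getv("priors"), ",")[[1]])
  names(priors) <- labels
  classSizes <- as.integer(strsplit(getv("classSizes"), ",")[[1]])
  names(classSizes) <- labels
  tab <- utils::read.delim(textConnection(lines[!grepl("^#nsc ", lines)]),
                           stringsAsFactors = FALSE)
  p <- nrow(tab)
  n <- sum(classSizes)
  mk <- sqrt(1 / classSizes - 1 / n)
  raw <- as.matrix(tab[, paste0("raw.", labels), drop = FALSE])
  shrunk <- as.matrix(tab[, paste0("shrunk.", labels), drop = FALSE])
  dimnames(raw) <- dimnames(shrunk) <- list(tab$feature, labels)
  si <- as.numeric(tab$pooledSd)
  overall <- as.numeric(tab$overall)
  dik <- sweep(sweep(raw - overall, 1, si + s0, "/"), 2, mk, "/")
  dikShrunk <- sweep(sweep(shrunk - overall, 1, si + s0, "/"), 2, mk, "/")
  new("NscModel", classLabels = labels, featureNames = tab$feature,
      overallCentroid = overall, classCentroids = raw,
      shrunkenCentroids = shrunk, dik = dik, dikShrunk = dikShrunk,
      pooledSd = si, s0 = s0, mk = unname(mk), delta = delta,
      priors = priors, classSizes = classSizes)
}
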