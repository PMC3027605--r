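test_that("training matches the brute-force shrunken-centroid formulas", {
  d <- toyXy()
  for (delta in c(0, 0.4, 1.3)) {
    mod <- trainNsc(d$X, d$y, delta = delta)
    br <- bruteNsc(d$X, d$y, delta)
    expect_equal(unname(mod@shrunkenCentroids), unname(br$shrunk),
                 tolerance = 1e-12)
    expect_equal(unname(mod@pooledSd), br$si, tolerance = 1e-12)
    expect_equal(mod@s0, br$s0, tolerance = 1e-12)
  }
})

test_that("zero shrinkage keeps raw centroids; full shrinkage removes all
           features", {
  d <- toyXy(2)
  mod0 <- trainNsc(d$X, d$y, delta = 0)
  rawU <- colMeans(d$X[d$y == "u", ])
  expect_equal(unname(mod0@shrunkenCentroids[, "u"]), rawU,
               tolerance = 1e-12)
  dMax <- max(abs(mod0@dik))
  modFull <- trainNsc(d$X, d$y, delta = dMax + 0.01)
  expect_equal(length(selectedFeatures(modFull)), 0L)
  expect_equal(unname(modFull@shrunkenCentroids[, "u"]),
               unname(modFull@overallCentroid), tolerance = 1e-12)
  # fully shrunken model predicts the larger prior everywhere
  pred <- predictNsc(modFull, d$X)
  expect_true(all(pred$label == "v"))  # n2 > n1
})

test_that("the selected feature set shrinks monotonically with delta", {
  d <- toyXy(3, p = 30)
  sizes <- sapply(seq(0, 3, by = 0.25), function(dd)
    length(selectedFeatures(trainNsc(d$X, d$y, dd))))
  expect_true(all(diff(sizes) <= 0))
})

test_that("prediction follows the penalized discriminant and returns
           normalized, equivariant probabilities", {
  d <- toyXy(4)
  mod <- trainNsc(d$X, d$y, delta = 0.3)
  br <- bruteNsc(d$X, d$y, 0.3)
  pred <- predictNsc(mod, d$X)
  for (i in c(1, 5, 10)) {
    disc <- bruteDiscriminant(br, d$X[i, ], br$priors)
    expect_equal(pred$label[i], br$classes[which.min(disc)])
    pr <- exp(-(disc - min(disc)) / 2)
    expect_equal(unname(pred$prob[i, ]), unname(pr / sum(pr)),
                 tolerance = 1e-12)
  }
  expect_equal(unname(rowSums(pred$prob)), rep(1, nrow(d$X)),
               tolerance = 1e-12)
  # a sample placed at a class's shrunken centroid is assigned that class
  # under equal priors
  modEq <- trainNsc(d$X, d$y, delta = 0.3, priors = c(u = 0.5, v = 0.5))
  expect_equal(predictNsc(modEq, modEq@shrunkenCentroids[, "u"])$label, "u")
  expect_error(predictNsc(mod, d$X[, 1:3]), "dimension mismatch")
})

test_that("delta = 0 with equal priors and s0 forced to zero reduces to
           diagonal-covariance nearest centroid", {
  d <- toyXy(5)
  mod <- trainNsc(d$X, d$y, delta = 0, priors = c(u = 0.5, v = 0.5))
  mod@s0 <- 0
  pred <- predictNsc(mod, d$X)$label
  cent <- sapply(c("u", "v"), function(k)
    colMeans(d$X[d$y == k, , drop = FALSE]))
  si <- mod@pooledSd
  oracle <- apply(d$X, 1, function(x) {
    dists <- colSums((x - cent)^2 / si^2)
    c("u", "v")[which.min(dists)]
  })
  expect_equal(pred, unname(oracle))
})

test_that("cross-validation finds separable data, degenerates to the prior
           classifier, and is seeded", {
  set.seed(6)
  X <- rbind(matrix(rnorm(20 * 10, mean = 0), 20, 10),
             matrix(rnorm(20 * 10, mean = 4), 20, 10))
  y <- rep(c("a", "b"), each = 20)
  cv <- crossValidateNsc(X, y, deltaGrid = c(0, 0.5, 1), nFolds = 5,
                         seed = 41)
  expect_equal(cv$cvError[1], 0)
  cvHuge <- crossValidateNsc(X, c(rep("a", 30), rep("b", 10)),
                             deltaGrid = 1e6, nFolds = 5, seed = 42)
  expect_equal(cvHuge$cvError, 1 - 30 / 40, tolerance = 0.05)
  cv2 <- crossValidateNsc(X, y, deltaGrid = c(0, 0.5, 1), nFolds = 5,
                          seed = 41)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$cvError, cv2$cvError)
  expect_error(crossValidateNsc(X, y, numeric(0)), "empty")
})

test_that("ROC construction matches its closed forms and the Mann-Whitney
           identity", {
  truth <- rep(c("pos", "neg"), c(4, 6))
  sep <- c(4, 3.5, 3, 2.9, 1, 0.9, 0.5, 0.4, 0.2, 0.1)
  expect_equal(rocFromScore(sep, truth, "pos")$auc, 1)
  rev_ <- rocFromScore(-sep, truth, "pos")$auc
  expect_equal(rev_, 0)
  # constant scores tie everything: AUC 1/2
  expect_equal(rocFromScore(rep(1, 10), truth, "pos")$auc, 0.5)
  # random scores with ties: AUC equals U / (n+ n-)
  set.seed(7)
  for (r in 1:5) {
    sc <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)
    tr <- sample(c("pos", "neg"), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(tr)) < 2) next
    auc <- rocFromScore(sc, tr, "pos")$auc
    w <- stats::wilcox.test(sc[tr == "pos"], sc[tr == "neg"],
                            exact = FALSE, correct = FALSE)
    U <- unname(w$statistic)
    expect_equal(auc, U / (sum(tr == "pos") * sum(tr == "neg")),
                 tolerance = 1e-12)
  }
  expect_error(rocFromScore(sep, rep("pos", 10), "pos"), "negative")
})

test_that("ROC agrees with an independent implementation (pROC)", {
  skip_if_not_installed("pROC")
  set.seed(17)
  sc <- rnorm(40)
  tr <- sample(c("pos", "neg"), 40, replace = TRUE)
  ours <- rocFromScore(sc, tr, "pos")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = tr, predictor = sc,
                                        levels = c("neg", "pos"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("classifier evaluation computes confusion-derived rates", {
  truth <- c("p", "p", "p", "n", "n", "n")
  pred <- c("p", "p", "n", "n", "n", "p")
  prob <- c(0.9, 0.8, 0.4, 0.2, 0.1, 0.6)
  ev <- evaluateClassifier(pred, prob, truth, "p")
  expect_equal(ev$accuracy, 4 / 6)
  expect_equal(ev$sensitivity, 2 / 3)
  expect_equal(ev$specificity, 2 / 3)
  evPerf <- evaluateClassifier(truth, c(1, 1, 1, 0, 0, 0), truth, "p")
  expect_equal(evPerf$accuracy, 1)
  expect_equal(evPerf$auc, 1)
  expect_error(evaluateClassifier(pred, prob, truth, "zz"), "unknown")
})

test_that("the mean-20q score separates planted cohorts (AUC above chance)", {
  spec <- syntheticSpec(noiseSd = 0.2,
                        specificSegments = aberrationSegment(
                          "20", 27500000, 63025520, 0.3, 0.8, "LM"),
                        seed = 44)
  sim <- generateCohort(spec)
  score <- regionMeanLog2(sim$acgh, "20", arm = "q")
  auc <- rocFromScore(score, sampleGroups(sim$acgh), "LM")$auc
  expect_gt(auc, 0.75)
})

test_that("feature reports annotate arms and match a brute-force
           hypergeometric tail", {
  map <- toyMap(c(A = 6e6, B = 4e6), spacing = 1e6,
                centromeres = c(A = 2.5e6, B = 2.5e6))
  ids <- cloneTable(map)$cloneId
  set.seed(10)
  X <- matrix(rnorm(12 * 10, sd = 0.1), 12, 10, dimnames = list(NULL, ids))
  # make the A-q clones (positions 3..6 Mb) strongly class-separating
  aq <- which(cloneTable(map)$chrom == "A" & cloneTable(map)$arm == "q")
  X[1:6, aq] <- X[1:6, aq] + 2
  y <- rep(c("g1", "g2"), each = 6)
  mod <- trainNsc(X, y, delta = 3)
  rep_ <- featureReport(mod, map)
  expect_true(all(rep_$features$arm == "q" & rep_$features$chrom == "A"))
  expect_equal(rep_$enrichment$arm[1], "Aq")
  # brute-force tail: P(X >= k) enumerated from the hypergeometric pmf
  k <- rep_$enrichment$nSelected[1]
  K <- rep_$enrichment$nArray[1]
  n <- nrow(rep_$features)
  N <- nClones(map)
  tail_ <- sum(sapply(k:min(K, n), function(i)
    choose(K, i) * choose(N - K, n - i) / choose(N, n)))
  expect_equal(rep_$enrichment$pHypergeom[1], tail_, tolerance = 1e-12)
  # no selected features: empty report, p-values 1
  modFull <- trainNsc(X, y, delta = 1e6)
  repEmpty <- featureReport(modFull, map)
  expect_equal(nrow(repEmpty$features), 0L)
  expect_true(all(repEmpty$enrichment$pHypergeom == 1))
})

test_that("NSC models survive a round trip through the flat-file format", {
  d <- toyXy(11)
  colnames(d$X) <- sprintf("cl%02d", seq_len(ncol(d$X)))
  mod <- trainNsc(d$X, d$y, delta = 0.5)
  f <- tempfile(fileext = ".txt")
  writeNscModel(mod, f)
  mod2 <- readNscModel(f)
  expect_equal(mod2@shrunkenCentroids, mod@shrunkenCentroids,
               tolerance = 1e-12)
  expect_equal(mod2@priors, mod@priors, tolerance = 1e-12)
  p1 <- predictNsc(mod, d$X)
  p2 <- predictNsc(mod2, d$X)
  expect_equal(p1$label, p2$label)
  expect_equal(p1$prob, p2$prob, tolerance = 1e-10)
})
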