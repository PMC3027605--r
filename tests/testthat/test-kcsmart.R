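test_that("aggregate profiles sum sign-split values and match brute force", {
  map <- toyMap(c(A = 4e6), spacing = 1e6)
  m <- matrix(c(0.5, -0.3, 0.2, NA,
                -0.1, 0.4, -0.2, 0.3), 2, 4, byrow = TRUE,
              dimnames = list(NULL, cloneTable(map)$cloneId))
  x <- toyAcgh(m, map)
  g <- aggregateProfile(x, "gain")
  l <- aggregateProfile(x, "loss")
  expect_equal(unname(g[1]), 0.5)
  expect_equal(unname(l[1]), -0.1)
  # missing contributes zero
  expect_equal(unname(g[4]), 0.3)
  # brute-force loop oracle on a random matrix
  set.seed(1)
  m2 <- matrix(rnorm(20), 5, 4,
               dimnames = list(NULL, cloneTable(map)$cloneId))
  x2 <- toyAcgh(m2, map)
  brute <- sapply(seq_len(4), function(j) sum(pmax(m2[, j], 0)))
  expect_equal(unname(aggregateProfile(x2, "gain")), brute)
  # an all-negative clone has zero gain aggregate
  m3 <- m2; m3[, 2] <- -abs(m3[, 2])
  expect_equal(unname(aggregateProfile(toyAcgh(m3, map), "gain"))[2], 0)
})

test_that("the KSE has the Gaussian closed form at and near a single clone", {
  w <- 1e6
  map <- toyMap(c(A = 8e6), spacing = 1e6)
  agg <- c(0, 0, 0, 1, 0, 0, 0, 0)  # unit mass at 4 Mb
  ks <- kseSmooth(agg, map, gridSpacing = 1e6, kernelWidth = w)
  at <- ks$kse[ks$pos == 4e6]
  # neighbours at 3 and 5 Mb contribute nothing here (agg zero), so the
  # kernel at lag 0 gives exactly 1
  expect_equal(at, 1)
  oneWidth <- ks$kse[ks$pos == 3e6]
  expect_equal(oneWidth, exp(-0.5), tolerance = 1e-12)
})

test_that("KSE matches the untruncated brute-force double loop", {
  set.seed(42)
  map <- toyMap(c(A = 30e6, B = 20e6), spacing = 1e6)
  agg <- rexp(nClones(map))
  for (w in c(5e5, 1e6, 2e6)) {
    ours <- kseSmooth(agg, map, gridSpacing = 1e6, kernelWidth = w)$kse
    brute <- bruteKse(agg, map, 1e6, w)
    expect_lt(max(abs(ours - brute) / pmax(abs(brute), 1e-12)), 1e-4)
  }
})

test_that("KSE is linear in the aggregate and scales with duplicated samples", {
  map <- toyMap(c(A = 20e6), spacing = 1e6)
  set.seed(3)
  a <- rexp(20); b <- rexp(20)
  ka <- kseSmooth(a, map, 1e6, 1e6)$kse
  kb <- kseSmooth(b, map, 1e6, 1e6)$kse
  kab <- kseSmooth(a + b, map, 1e6, 1e6)$kse
  expect_equal(kab, ka + kb, tolerance = 1e-12)

  m <- matrix(rnorm(3 * 20, sd = 0.3), 3, 20,
              dimnames = list(NULL, cloneTable(map)$cloneId))
  x1 <- toyAcgh(m, map)
  x2 <- toyAcgh(rbind(m, m), map)
  k1 <- kcsmartProfile(x1, gridSpacing = 1e6)
  k2 <- kcsmartProfile(x2, gridSpacing = 1e6)
  expect_equal(k2@kseGain, 2 * k1@kseGain, tolerance = 1e-12)
  expect_equal(k2@kseLoss, 2 * k1@kseLoss, tolerance = 1e-12)
})

test_that("gain KSE is nonnegative and loss KSE nonpositive everywhere", {
  sim <- generateCohort(smallSpec(seed = 11), smallMap())
  pr <- kcsmartProfile(sim$acgh, gridSpacing = 1e6)
  expect_true(all(pr@kseGain >= 0))
  expect_true(all(pr@kseLoss <= 0))
})

test_that("no smoothing leaks across chromosome boundaries", {
  map <- toyMap(c(A = 5e6, B = 5e6), spacing = 1e6)
  agg <- c(rep(10, 5), rep(0, 5))
  ks <- kseSmooth(agg, map, gridSpacing = 1e6, kernelWidth = 2e6)
  expect_true(all(ks$kse[ks$chrom == "B"] == 0))
})

test_that("null thresholds are seeded, ranked correctly, and degenerate
           at alpha = 1", {
  sim <- generateCohort(smallSpec(seed = 12), smallMap())
  x <- sim$acgh
  t1 <- kseNullThreshold(x, "gain", 1e6, 1e6, nPermutations = 39,
                         alpha = 0.05, seed = 5)
  t2 <- kseNullThreshold(x, "gain", 1e6, 1e6, nPermutations = 39,
                         alpha = 0.05, seed = 5)
  expect_identical(t1, t2)
  expect_error(kseNullThreshold(x, "gain", 1e6, 1e6, nPermutations = 20,
                                alpha = 0.01), "too small")
  # alpha = 1: the threshold is the smallest null maximum; a profile with
  # real spatial structure exceeds it somewhere
  spec <- syntheticSpec(groupSizes = c(G = 15L),
                        sharedSegments = aberrationSegment(
                          "1", 5e6, 25e6, 0.6, 1, "*"),
                        specificSegments = NULL, noiseSd = 0.1,
                        sampleOffsetSd = 0, seed = 12)
  xs <- generateCohort(spec, smallMap())$acgh
  tAll <- kseNullThreshold(xs, "gain", 1e6, 1e6, nPermutations = 25,
                           alpha = 1, seed = 6)
  pr <- kcsmartProfile(xs, gridSpacing = 1e6)
  expect_gt(max(pr@kseGain), tAll)
})

test_that("planted gains become significant regions in coordinate order", {
  segs <- rbind(aberrationSegment("1", 5e6, 15e6, 0.8, 1, "*"),
                aberrationSegment("3", 30e6, 45e6, 0.8, 1, "*"))
  spec <- syntheticSpec(groupSizes = c(G = 20L), sharedSegments = segs,
                        specificSegments = NULL, noiseSd = 0.1,
                        sampleOffsetSd = 0, seed = 13)
  sim <- generateCohort(spec, smallMap())
  pr <- kcsmartProfile(sim$acgh, gridSpacing = 1e6, nPermutations = 79,
                       alpha = 0.05, seed = 7)
  regs <- significantRegions(pr)
  gains <- regs[S4Vectors::mcols(regs)$sign == "gain"]
  expect_equal(length(gains), 2L)
  expect_equal(as.character(GenomicRanges::seqnames(gains)), c("1", "3"))
  expect_true(GenomicRanges::start(gains)[1] < 15e6 &&
              GenomicRanges::end(gains)[1] > 5e6)
  # a profile below threshold yields an empty set
  prHigh <- pr
  prHigh@thresholdGain <- max(pr@kseGain) + 1
  prHigh@thresholdLoss <- min(pr@kseLoss) - 1
  expect_equal(length(significantRegions(prHigh)), 0L)
})

test_that("KSE correlations behave at the extremes and across replicate
           cohorts", {
  sim <- generateCohort(smallSpec(seed = 14,
                                  groupSizes = c(G = 12L)), smallMap())
  pr <- kcsmartProfile(sim$acgh, gridSpacing = 1e6)
  expect_equal(kseCorrelation(pr, pr, "gain"), 1.0)
  # affine negation of the gain profile correlates at exactly -1
  neg <- pr
  neg@kseGain <- max(pr@kseGain) - pr@kseGain
  expect_equal(kseCorrelation(pr, neg, "gain"), -1.0)
  # grid mismatch errors
  prB <- kcsmartProfile(sim$acgh, gridSpacing = 2e6)
  expect_error(kseCorrelation(pr, prB, "gain"), "grids")
  # zero variance is undefined, reported as NA with a warning
  flat <- pr
  flat@kseGain <- rep(0, length(flat@kseGain))
  expect_warning(r <- kseCorrelation(pr, flat, "gain"), "undefined")
  expect_true(is.na(r))

  # two cohorts from one generative spec (different seeds) share their
  # aberration landscape: high KSE correlation at default noise
  spec <- syntheticSpec(seed = 15)
  map <- generateCohort(spec)$acgh@cloneMap
  prA <- kcsmartProfile(generateCohort(spec, map)$acgh, gridSpacing = 1e6)
  spec@seed <- 16L
  prB2 <- kcsmartProfile(generateCohort(spec, map)$acgh, gridSpacing = 1e6)
  expect_gt(kseCorrelation(prA, prB2, "gain"), 0.8)
  expect_gt(kseCorrelation(prA, prB2, "loss"), 0.8)
})
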