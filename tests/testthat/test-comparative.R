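test_that("per-sample smoothing preserves constants in normalized mode and
           matches brute force", {
  map <- toyMap(c(A = 30e6), spacing = 1e6)
  n <- nClones(map)
  m <- rbind(rep(0.7, n), rnorm(n, sd = 0.4))
  colnames(m) <- cloneTable(map)$cloneId
  x <- toyAcgh(m, map)
  sm <- smoothSamples(x, gridSpacing = 1e6, kernelWidth = 1e6)
  expect_equal(unname(sm@values[1, ]),
               rep(0.7, ncol(sm@values)), tolerance = 1e-6)
  brute <- bruteKse(m[2, ], map, 1e6, 1e6, normalize = TRUE)
  expect_lt(max(abs(sm@values[2, ] - brute)) / max(abs(brute)), 1e-4)

  # a single clone smooths to a Gaussian bump around the clone
  m1 <- matrix(0, 1, n, dimnames = list(NULL, cloneTable(map)$cloneId))
  m1[1, 15] <- 1
  smU <- smoothSamples(toyAcgh(m1, map), gridSpacing = 1e6,
                       kernelWidth = 1e6, normalize = FALSE)
  v <- smU@values[1, ]
  expect_equal(which.max(v), 15L)
  expect_equal(unname(v[14] / v[15]), exp(-0.5), tolerance = 1e-12)
})

test_that("the SNR follows its defining formula and handles degenerate
           variances", {
  map <- toyMap(c(A = 10e6), spacing = 1e6)
  ids <- cloneTable(map)$cloneId
  mk <- function(m) {
    colnames(m) <- ids
    smoothSamples(toyAcgh(m, map, group = c(rep("A", nrow(m) / 2),
                                            rep("B", nrow(m) / 2))),
                  gridSpacing = 1e6, kernelWidth = 1e5)
  }
  # identical groups: SNR 0 everywhere
  base <- matrix(rnorm(40), 4, 10)
  smEq <- mk(rbind(base[1:2, ], base[1:2, ]))
  expect_equal(unname(snrProfile(smEq, "A", "B")), rep(0, 10))
  # means 1 vs 0, both sds 0.5 -> SNR 1 (constructed exactly)
  g <- c(1.5, 0.5, 1.5, 0.5)  # mean 1, sd 0.577 -> use explicit values
  a <- rbind(rep(1.5, 10), rep(0.5, 10))   # mean 1, sd = 0.7071
  b <- rbind(rep(0.5, 10), rep(-0.5, 10))  # mean 0, sd = 0.7071
  smAb <- mk(rbind(a, b))
  expect_equal(unname(snrProfile(smAb, "A", "B")),
               rep(1 / (2 * sd(c(1.5, 0.5))), 10), tolerance = 1e-10)
  # zero variance, equal means -> 0; zero variance, different means -> Inf
  smZero <- mk(rbind(matrix(1, 2, 10), matrix(0, 2, 10)))
  expect_true(all(is.infinite(snrProfile(smZero, "A", "B"))))
  smSame <- mk(matrix(1, 4, 10))
  expect_equal(unname(snrProfile(smSame, "A", "B")), rep(0, 10))

  # random groups match the brute-force formula
  set.seed(8)
  m <- matrix(rnorm(20 * 10), 20, 10)
  smR <- mk(m)
  ours <- snrProfile(smR, "A", "B")
  V <- smR@values
  brute <- sapply(seq_len(ncol(V)), function(g) {
    a <- V[1:10, g]; b <- V[11:20, g]
    abs(mean(a) - mean(b)) / (sd(a) + sd(b))
  })
  expect_equal(unname(ours), brute, tolerance = 1e-12)
})

test_that("the SNR is symmetric, shift-invariant and scale-invariant", {
  map <- toyMap(c(A = 15e6), spacing = 1e6)
  set.seed(9)
  m <- matrix(rnorm(12 * 15), 12, 15,
              dimnames = list(NULL, cloneTable(map)$cloneId))
  grp <- rep(c("A", "B"), each = 6)
  sm <- smoothSamples(toyAcgh(m, map, group = grp), gridSpacing = 1e6)
  s1 <- snrProfile(sm, "A", "B")
  expect_equal(s1, snrProfile(sm, "B", "A"))
  smShift <- smoothSamples(toyAcgh(m + 5, map, group = grp),
                           gridSpacing = 1e6)
  expect_equal(snrProfile(smShift, "A", "B"), s1, tolerance = 1e-8)
  smScale <- smoothSamples(toyAcgh(m * 3.7, map, group = grp),
                           gridSpacing = 1e6)
  expect_equal(snrProfile(smScale, "A", "B"), s1, tolerance = 1e-8)
})

test_that("permutation FDR is seeded, monotone and nested across levels", {
  seg <- aberrationSegment("2", 10e6, 40e6, 0.5, 1, "A")
  spec <- syntheticSpec(groupSizes = c(A = 10L, B = 12L),
                        sharedSegments = NULL, specificSegments = seg,
                        noiseSd = 0.1, seed = 21)
  sim <- generateCohort(spec, smallMap())
  sm <- smoothSamples(sim$acgh, gridSpacing = 1e6)
  p1 <- permutationFdr(sm, "A", "B", nPermutations = 150, seed = 31)
  p2 <- permutationFdr(sm, "A", "B", nPermutations = 150, seed = 31)
  expect_identical(p1@thresholds, p2@thresholds)
  # FDR curve non-increasing in the threshold
  expect_true(all(diff(p1@fdrCurve$fdr) <= 1e-12))
  # the 5% threshold sits at or below the 1% threshold, so 1% regions are
  # a subset of 5% regions as point sets
  thr <- p1@thresholds
  if (!anyNA(thr)) expect_lte(thr[["0.05"]], thr[["0.01"]])
  r01 <- differentialRegions(p1, 0.01)
  r05 <- differentialRegions(p1, 0.05)
  if (length(r01))
    expect_true(all(GenomicRanges::countOverlaps(r01, r05) > 0))
  expect_error(differentialRegions(p1, 0.2), "no threshold")
})

test_that("a planted group-specific gain is recovered as a differential
           region, and an all-zero SNR yields none", {
  seg <- aberrationSegment("2", 10e6, 40e6, 0.6, 1, "A")
  spec <- syntheticSpec(groupSizes = c(A = 12L, B = 12L),
                        sharedSegments = NULL, specificSegments = seg,
                        noiseSd = 0.1, seed = 22)
  sim <- generateCohort(spec, smallMap())
  sm <- smoothSamples(sim$acgh, gridSpacing = 1e6)
  prof <- permutationFdr(sm, "A", "B", nPermutations = 200, seed = 32)
  regs <- differentialRegions(prof, 0.01)
  expect_gt(length(regs), 0)
  planted <- GenomicRanges::GRanges("2", IRanges::IRanges(10e6, 40e6))
  expect_true(any(GenomicRanges::countOverlaps(planted, regs) > 0))

  flat <- prof
  flat@snr <- rep(0, length(prof@snr))
  expect_equal(length(differentialRegions(flat, 0.01)), 0L)
})

test_that("label permutation of an exchangeable cohort leaves the SNR
           distribution unchanged", {
  nul <- nullCohort(smallSpec(seed = 23,
                              groupSizes = c(A = 10L, B = 10L)), smallMap())
  sm <- smoothSamples(nul$acgh, gridSpacing = 1e6)
  obs <- snrProfile(sm, "A", "B")
  perm <- runSeeded(33, {
    lab <- sample(sm@groupLabels)
    smP <- sm
    smP@groupLabels <- lab
    snrProfile(smP, "A", "B")
  })
  ks <- suppressWarnings(stats::ks.test(obs, perm))
  expect_gt(ks$p.value, 0.001)
})
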