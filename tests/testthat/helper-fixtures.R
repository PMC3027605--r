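# Shared builders for small in-code fixtures.

# A toy clone map: chromosomes of the given lengths (bp), clones at
# `spacing` intervals, arms split at the chromosome midpoint unless a
# centromere table is given.
toyMap <- function(lengths = c(A = 10e6, B = 8e6), spacing = 1e6,
                   centromeres = NULL) {
  rows <- do.call(rbind, lapply(names(lengths), function(ch) {
    pos <- seq(spacing, lengths[[ch]], by = spacing)
    data.frame(cloneId = sprintf("%s_%02d", ch, seq_along(pos)),
               chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  if (is.null(centromeres)) centromeres <- lengths / 2
  cloneMap(rows, chromLengths = lengths, centromeres = centromeres)
}

# A toy AcghSet with the given clone-level matrix (samples x clones).
toyAcgh <- function(m, map, group = "G") {
  acghSet(m, map, group = group, samplesAsRows = TRUE)
}

# Small synthetic spec on a reduced genome for fast simulation tests.
smallSpec <- function(..., groupSizes = c(LM = 10L, PM = 10L, M0 = 6L),
                      seed = 1L) {
  syntheticSpec(groupSizes = groupSizes, sharedSegments = NULL,
                specificSegments = NULL, seed = seed, ...)
}

smallLengths <- c("1" = 50e6, "2" = 50e6, "3" = 50e6, "4" = 50e6)

smallMap <- function(spec = smallSpec()) {
  generateCloneMap(spec, chromLengths = smallLengths)
}

# Untruncated brute-force Gaussian-kernel smoother (the independent oracle
# for the kernel machinery): double loop over grid points and clones of the
# same chromosome.
bruteKse <- function(values, map, gridSpacing, kernelWidth,
                     normalize = FALSE) {
  cl <- cloneTable(map)
  lens <- chromLengths(map)
  out <- NULL
  for (ch in names(lens)) {
    n <- floor(lens[[ch]] / gridSpacing)
    if (n < 1) next
    gpos <- gridSpacing * seq_len(n)
    idx <- which(cl$chrom == ch)
    for (g in gpos) {
      num <- 0; den <- 0
      for (i in idx) {
        w <- exp(-(g - cl$pos[i])^2 / (2 * kernelWidth^2))
        if (!is.na(values[i])) {
          num <- num + w * values[i]
          den <- den + w
        }
      }
      out <- c(out, if (normalize) num / den else num)
    }
  }
  out
}

# Independent re-implementation of the shrunken-centroids formulas used as
# the oracle: centroid shrinkage d_ik = (xbar_ik - xbar_i)/(m_k (s_i + s0)),
# soft thresholding, reconstruction, and the penalized discriminant.
bruteNsc <- function(X, y, delta) {
  classes <- sort(unique(y))
  n <- nrow(X); p <- ncol(X); K <- length(classes)
  nk <- sapply(classes, function(k) sum(y == k))
  xbar <- colMeans(X)
  cent <- sapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]))
  s2 <- rep(0, p)
  for (k in classes)
    s2 <- s2 + colSums((X[y == k, , drop = FALSE] -
                        matrix(cent[, k], nk[[k]], p, byrow = TRUE))^2)
  si <- sqrt(s2 / (n - K))
  s0 <- median(si)
  mk <- sqrt(1 / nk - 1 / n)
  dik <- matrix(0, p, K)
  for (k in seq_len(K))
    dik[, k] <- (cent[, k] - xbar) / (mk[k] * (si + s0))
  dshr <- sign(dik) * pmax(abs(dik) - delta, 0)
  shrunk <- matrix(0, p, K)
  for (k in seq_len(K))
    shrunk[, k] <- xbar + mk[k] * (si + s0) * dshr[, k]
  list(classes = classes, si = si, s0 = s0, shrunk = shrunk, dik = dik,
       priors = nk / n)
}

bruteDiscriminant <- function(br, x, priors) {
  sapply(seq_along(br$classes), function(k)
    sum((x - br$shrunk[, k])^2 / (br$si + br$s0)^2) - 2 * log(priors[k]))
}

toyXy <- function(seed = 1, n1 = 6, n2 = 8, p = 5, shift = 1.5) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n1 * p), n1, p),
             matrix(rnorm(n2 * p), n2, p))
  X[seq_len(n1), 1:2] <- X[seq_len(n1), 1:2] + shift
  list(X = X, y = rep(c("u", "v"), c(n1, n2)))
}

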