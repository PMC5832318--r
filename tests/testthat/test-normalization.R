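test_that("GC correction flattens constant and noiseless biased counts", {
  b <- smallGenome(seed = 3)
  n <- length(b)

  # constant counts: corrected ratio ~ 1 everywhere
  v <- gcNormalize(rep(100L, n), b)
  r <- v / median(v, na.rm = TRUE)
  expect_lt(max(abs(r - 1), na.rm = TRUE), 0.02)

  # noiseless smooth unimodal bias: corrected nearly constant
  bias <- gcBiasBeta()
  cnt <- as.integer(round(100 * bias(b$gc)))
  v <- gcNormalize(cnt, b)
  expect_lt(sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE), 0.05)

  expect_error(gcNormalize(rep(0L, n), b), "empty sample")
})

test_that("GC correction decorrelates Poisson counts from GC", {
  set.seed(21)
  b <- smallGenome(chromLength = 62.5e6, seed = 5) # 500 bins
  bias <- gcBiasBeta()
  cnt <- rpois(length(b), 200 * bias(b$gc))
  v <- gcNormalize(cnt, b)
  u <- !is.na(v)
  expect_lt(abs(cor(v[u], b$gc[u], method = "spearman")), 0.1)
})

test_that("normalization is scale-equivariant", {
  b <- smallGenome(seed = 6)
  cc <- simulateCellCounts(b, 2L, totalReads = 300000, seed = 61)
  r1 <- ratios(normalizeProfile(counts(cc), b))
  r2 <- ratios(normalizeProfile(counts(cc) * 7L, b))
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("mappability correction divides and floors usability", {
  b <- smallGenome(seed = 7)
  mcols(b)$mappability <- rep(1, length(b))
  expect_equal(mappabilityNormalize(rep(50, length(b)), b),
               rep(50, length(b)))
  mcols(b)$mappability <- c(0.5, 0.2, rep(1, length(b) - 2))
  # with the floor lowered, division is plain arithmetic: 50 / 0.5 = 100
  v <- mappabilityNormalize(rep(50, length(b)), b, minMappability = 0.3)
  expect_equal(v[1], 100)
  expect_true(is.na(v[2])) # 0.2 is below even the lowered floor
  # at the default floor both low-mappability bins are unusable
  v <- mappabilityNormalize(rep(50, length(b)), b)
  expect_true(all(is.na(v[1:2])))
})

test_that("median centering produces a valid unit-median profile", {
  b <- makeBins(c(c1 = 1.5e6), 5e5)
  p <- medianCenter(c(2, 4, 6), b)
  expect_equal(ratios(p), c(0.5, 1, 1.5))
  expect_equal(median(ratios(p)[usableBins(p)]), 1)

  # unusable bins are excluded from the median
  p <- medianCenter(c(2, 4, NA), b)
  expect_equal(ratios(p)[1:2], c(2, 4) / 3)
  expect_false(usableBins(p)[3])
})

test_that("quality metrics match hand-derived values", {
  b <- makeBins(c(c1 = 2e6), 5e5)
  p <- medianCenter(c(10, 10, 10, 1), b)
  qm <- qualityMetrics(p)
  # mean 7.75; 20% threshold 1.55 -> 3 of 4 bins above
  expect_equal(qm$uniformity, 0.75)
  expect_equal(qm$coverageFraction, 0.75)

  # constant profile
  p <- medianCenter(rep(5, 4), b)
  qm <- qualityMetrics(p)
  expect_equal(qm$uniformity, 1)
  expect_equal(qm$coverageFraction, 1)
  expect_equal(qm$dlrs, 0)

  # dlrs closed form: log2 ratios (0, .2, 0, .2) -> sd(diffs)/sqrt(2)
  p <- medianCenter(2^c(0, 0.2, 0, 0.2), b)
  expect_equal(qualityMetrics(p)$dlrs, 0.1633, tolerance = 1e-4)
})

test_that("dlrs approaches the population closed form for alternating signals", {
  # deterministic alternating +-d/2 log-ratio signal: population sd of the
  # consecutive differences is |d|, so population dlrs = |d|/sqrt(2); the
  # sample-sd variant converges to it as n grows
  d <- 0.3
  b <- makeBins(c(c1 = 200 * 5e5), 5e5)
  p <- medianCenter(2^(rep(c(-d / 2, d / 2), 100)), b)
  expect_equal(qualityMetrics(p)$dlrs, d / sqrt(2), tolerance = 0.01)
})

test_that("dlrs excludes chromosome-boundary pairs", {
  b <- makeBins(c(c1 = 1e6, c2 = 1e6), 5e5)
  # within-chromosome pairs are flat; the only variation crosses chromosomes
  p <- medianCenter(c(1, 1, 2, 2), b)
  expect_equal(qualityMetrics(p)$dlrs, 0)
})

test_that("problematic-region detection follows the strict median rule", {
  b <- makeBins(c(c1 = 2e6), 5e5)
  mkProf <- function(vals) medianCenter(vals, b)

  # flat panel -> empty blacklist
  bl <- detectProblematicRegions(list(mkProf(rep(1, 4)), mkProf(rep(1, 4)),
                                      mkProf(rep(1, 4))))
  expect_equal(length(bl), 0L)
  expect_equal(metadata(bl)$totalBp, 0)

  # per-bin medians (1.0, 1.5, 0.5, 1.0): bins 2-3 flagged, merged
  panel <- list(mkProf(c(1, 1.5, 0.5, 1)), mkProf(c(1, 1.5, 0.5, 1)),
                mkProf(c(1, 1.5, 0.5, 1)))
  # median-centering rescales; build directly instead
  panel <- lapply(1:3, function(i) {
    methods::new("CNProfile", bins = b, raw = rep(NA_integer_, 4),
                 ratio = c(1, 1.5, 0.5, 1), usable = rep(TRUE, 4))
  })
  bl <- detectProblematicRegions(panel)
  expect_equal(length(bl), 1L)
  expect_equal(start(bl), 5e5 + 1)
  expect_equal(end(bl), 1.5e6)
  expect_equal(metadata(bl)$nRegions, 1L)
  expect_equal(metadata(bl)$totalBp, 1e6)

  # boundary: a median of exactly 1.4 is NOT flagged (strict inequality)
  panel <- lapply(1:3, function(i)
    methods::new("CNProfile", bins = b, raw = rep(NA_integer_, 4),
                 ratio = c(1, 1.4, 0.6, 1), usable = rep(TRUE, 4)))
  expect_equal(length(detectProblematicRegions(panel)), 0L)

  expect_error(detectProblematicRegions(panel[1]), "at least 2")
})

test_that("a panel of normals recovers systematically biased bins", {
  b <- smallGenome(seed = 8)
  bad <- c(30, 31, 32, 200, 201, 420, 421, 422, 600, 601)
  panel <- simulateNormalPanel(b, nCells = 20, totalReads = 500000,
                               badBins = bad, badFactor = 1.6, seed = 81)
  profs <- lapply(panel, normalizeProfile, bins = b)
  bl <- detectProblematicRegions(profs)
  hit <- countOverlaps(b[bad], bl) > 0
  expect_gte(mean(hit), 0.95)
  # and a deflated factor is recovered as loss-direction regions
  panel <- simulateNormalPanel(b, nCells = 20, totalReads = 500000,
                               badBins = bad, badFactor = 0.5, seed = 82)
  profs <- lapply(panel, normalizeProfile, bins = b)
  bl <- detectProblematicRegions(profs)
  expect_gte(mean(countOverlaps(b[bad], bl) > 0), 0.95)
  expect_true(all(bl$direction == "loss"))
})

test_that("flat GC-biased cells normalize to high uniformity", {
  b <- smallGenome(chromLength = 125e6, seed = 9)
  cc <- simulateCellCounts(b, 2L, totalReads = 500000, seed = 91)
  p <- normalizeProfile(cc, b)
  qm <- qualityMetrics(p)
  expect_gt(qm$uniformity, 0.99)
  u <- usableBins(p)
  expect_lt(abs(cor(ratios(p)[u], bins(p)$gc[u], method = "spearman")), 0.1)
})
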