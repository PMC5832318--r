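flatProfile <- function(n, chrom = "c1", ratio = NULL, seed = 1) {
  b <- makeBins(setNames(n * 5e5, chrom), 5e5)
  if (is.null(ratio)) ratio <- rep(1, n)
  methods::new("CNProfile", bins = b, raw = rep(NA_integer_, n),
               ratio = ratio / median(ratio), usable = rep(TRUE, n))
}

test_that("a flat ratio vector yields a single segment per chromosome", {
  p <- flatProfile(100)
  segs <- segmentProfile(p)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$nBins, 100L)
})

test_that("a noiseless step is split exactly at the breakpoint", {
  r <- c(rep(1, 50), rep(1.5, 50))
  p <- flatProfile(100, ratio = r)
  segs <- segmentProfile(p)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$binEnd[1], 50L)
  expect_equal(segs$binStart[2], 51L)
})

test_that("noisy step breakpoints land within 2 bins in >=95% of replicates", {
  hits <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    r <- c(rep(1, 50), rep(1.5, 50)) + rnorm(100, 0, 0.1)
    segs <- segmentProfile(flatProfile(100, ratio = r))
    any(abs(segs$binStart - 51L) <= 2L)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("segmentation is deterministic and unmoved by a masked chromosome", {
  x <- aberrantProfile(2, seed = 301, totalReads = 500000)
  s1 <- segmentProfile(x$profile)
  s2 <- segmentProfile(x$profile)
  expect_identical(s1, s2)

  # appending an all-unusable chromosome changes nothing
  b2 <- makeBins(setNames(c(rep(80e6, 4), 5e6), c(paste0("chr", 1:4), "chrU")),
                 5e5)
  n2 <- length(b2)
  pad <- n2 - length(bins(x$profile))
  p2 <- methods::new("CNProfile", bins = b2,
                     raw = c(rawCounts(x$profile), rep(NA_integer_, pad)),
                     ratio = c(ratios(x$profile), rep(NA_real_, pad)),
                     usable = c(usableBins(x$profile), rep(FALSE, pad)))
  s3 <- segmentProfile(p2)
  expect_equal(s3$meanRatio, s1$meanRatio)
})

test_that("copy numbers round half away from zero and classify correctly", {
  segs <- data.frame(meanRatio = c(1.5, 0.5, 1.02, 1.25))
  out <- assignCopyNumbers(segs, 2L)
  expect_equal(out$copyNumber, c(3L, 1L, 2L, 3L)) # 2.5 -> 3, away from zero
  expect_equal(out$class, c("gain", "loss", "neutral", "gain"))

  out <- assignCopyNumbers(data.frame(meanRatio = 0.5), 6L)
  expect_equal(out$copyNumber, 3L)
  expect_equal(out$class, "loss")
})

test_that("segment significance needs both tests below alpha", {
  set.seed(77)
  n <- 220
  r <- c(rep(1, 200), rep(1.5, 20)) + rnorm(n, 0, 0.05)
  p <- flatProfile(n, ratio = r)
  segs <- data.frame(chrom = "c1",
                     binStart = c(1L, 201L), binEnd = c(200L, n),
                     start = c(1, 200 * 5e5 + 1), end = c(200 * 5e5, n * 5e5),
                     nBins = c(200L, 20L), meanRatio = c(1, 1.5))
  segs <- assignCopyNumbers(segs, 2L)
  segs <- testSegmentSignificance(segs, p)
  expect_true(segs$significant[2])
  expect_lt(segs$pWilcoxon[2], 0.01)
  expect_lt(segs$pKS[2], 0.01)
  expect_false(segs$significant[1]) # neutral background itself

  # a 2-bin segment cannot reach p < 0.01 in the rank test
  segs2 <- segs
  segs2$binStart[2] <- 219L
  segs2$nBins[2] <- 2L
  segs2 <- testSegmentSignificance(segs2, p)
  expect_false(segs2$significant[2])
})

test_that("blacklist filtering uses a strict overlap fraction and is idempotent", {
  b <- makeBins(c(c1 = 10e6), 5e5)
  gr <- GRanges("c1", IRanges(1, 1e6),
                class = "gain", copyNumber = 3L, meanRatio = 1.5,
                pWilcoxon = 1e-5, pKS = 1e-5, blacklistedFraction = 0,
                seqlengths = c(c1 = 10e6))
  cs <- methods::new("CNACallSet", cellId = "x", mainPloidy = 2L, calls = gr,
                     mbpGained = 1, mbpLost = 0)

  # empty blacklist: identity
  expect_equal(length(calls(filterCalls(cs, GRanges()))), 1L)

  # 800 kb of a 1 Mb call blacklisted: fraction 0.8 > 0.5 -> removed
  bl <- GRanges("c1", IRanges(1, 8e5))
  expect_equal(length(calls(filterCalls(cs, bl))), 0L)

  # exactly half: retained (strict >)
  bl <- GRanges("c1", IRanges(1, 5e5))
  kept <- filterCalls(cs, bl)
  expect_equal(length(calls(kept)), 1L)
  expect_equal(calls(kept)$blacklistedFraction, 0.5)
  expect_equal(length(calls(filterCalls(kept, bl))), 1L) # idempotent
})

test_that("planted CNAs are recovered with high recall and low FPR", {
  recalls <- c(); fprs <- c()
  for (s in 1:5) {
    x <- aberrantProfile(2, seed = 400 + s)
    cs <- callCNAs(x$profile, 2L)
    altered <- x$cn != 2L
    hit <- suppressWarnings(countOverlaps(x$bins, calls(cs))) > 0
    recalls <- c(recalls, sum(hit & altered) / sum(altered))
    fprs <- c(fprs, sum(hit & !altered) / sum(!altered))
  }
  expect_gte(mean(recalls), 0.9)
  expect_lte(mean(fprs), 0.01)
})

test_that("megabase accounting partitions the usable genome", {
  x <- aberrantProfile(2, seed = 411)
  cs <- callCNAs(x$profile, 2L)
  segs <- attr(cs, "segments")
  segBp <- sum(segs$end - segs$start + 1)
  # segments cover the span from first to last usable bin of each chromosome
  expect_equal(cs@mbpGained,
               sum(width(calls(cs)[calls(cs)$class == "gain"])) / 1e6)
  expect_equal(cs@mbpLost,
               sum(width(calls(cs)[calls(cs)$class == "loss"])) / 1e6)
  expect_lte((cs@mbpGained + cs@mbpLost) * 1e6, segBp)
})

test_that("call sets intersect into cores and private lengths", {
  sl <- c(c1 = 20e6)
  mkCS <- function(id, st, en, cls) {
    gr <- GRanges("c1", IRanges(st, en), class = cls, copyNumber = 3L,
                  meanRatio = 1.5, pWilcoxon = 0, pKS = 0,
                  blacklistedFraction = 0, seqlengths = sl)
    methods::new("CNACallSet", cellId = id, mainPloidy = 2L, calls = gr,
                 mbpGained = sum(width(gr[gr$class == "gain"])) / 1e6,
                 mbpLost = sum(width(gr[gr$class == "loss"])) / 1e6)
  }
  # single cell: core equals its own calls
  a <- mkCS("a", 1, 10e6, "loss")
  out <- summarizeAndIntersect(list(a))
  expect_equal(sum(width(out$coreLoss)), 10e6)

  # loss 0-10Mb vs loss 5-15Mb: core loss 5-10 Mb
  b2 <- mkCS("b", 5e6 + 1, 15e6, "loss")
  out <- summarizeAndIntersect(list(a, b2))
  expect_equal(sum(width(out$coreLoss)), 5e6)
  expect_equal(start(out$coreLoss), 5e6 + 1)
  # private: 5 Mb each
  expect_equal(out$perCell$privateMbp, c(5, 5))

  # disjoint calls: empty core, full private lengths
  c2 <- mkCS("c", 12e6 + 1, 15e6, "gain")
  out <- summarizeAndIntersect(list(a, c2))
  expect_equal(sum(width(out$coreGain)) + sum(width(out$coreLoss)), 0)
  expect_equal(out$perCell$privateMbp, c(10, 3))
})
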