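#' LOWESS GC-bias correction of binned counts
#'
#' Fits a robustified locally weighted regression of per-bin read count on
#' per-bin GC fraction over usable bins and divides each count by the fitted
#' value at its GC. Bins with undefined GC, masked bins, or bins where the
#' fit is non-positive are marked unusable (`NA`).
#'
#' The curve is fitted to per-GC-stratum *medians* (usable bins are split
#' into `nStrata` GC quantile strata) rather than to the raw per-bin counts:
#' in a heavily aberrant cell a large fraction of bins sits at non-neutral
#' copy numbers, and a direct fit of count on GC absorbs copy number into
#' the correction wherever copy-number states and GC strata are unevenly
#' mixed; the stratum median tracks the modal (neutral) count level as long
#' as no stratum is majority-aberrant. The fit runs on the log of the
#' stratum medians — representation and amplification biases are
#' multiplicative and near-exponential in GC, which local linear fits track
#' far better in log space — and extrapolates linearly (in log space) beyond
#' the outermost stratum medians, where representation changes fastest.
#'
#' Bins whose fitted expectation falls below `minRelFit` of the median fitted
#' expectation are also marked unusable: at low pass such bins hold a handful
#' of reads at best, so dividing by the tiny fitted value only amplifies
#' shot noise into extreme ratio outliers, and they carry no usable
#' copy-number signal.
#'
#' @param counts A [BinnedCounts-class] or integer vector aligned with `bins`.
#' @param bins Annotated bin `GRanges` (needs `gc`, and `masked` if present).
#' @param span LOWESS neighbourhood fraction (default 0.3).
#' @param iterations Robustifying reweighting passes (default 3).
#' @param minRelFit Representation floor as a fraction of the median fitted
#'   expectation (default 0.1).
#' @param nStrata Number of GC quantile strata for the median curve
#'   (default 51; reduced automatically for small bin tables).
#' @return Numeric vector of corrected values (`NA` where unusable).
#' @export
gcNormalize <- function(counts, bins, span = 0.3, iterations = 3L,
                        minRelFit = 0.1, nStrata = 51L) {
  x <- if (methods::is(counts, "BinnedCounts")) counts(counts) else counts
  if (length(x) != length(bins)) stop("counts must align with bins")
  if (all(x == 0)) stop("empty sample: all bin counts are zero")
  gc <- mcols(bins)$gc
  if (is.null(gc)) stop("bins lack GC annotation; run annotateBins() first")
  masked <- mcols(bins)$masked
  if (is.null(masked)) masked <- rep(FALSE, length(bins))
  usable <- !masked & !is.na(gc)
  if (sum(usable) < 50)
    stop("need at least 50 usable bins with defined GC for the LOWESS fit")
  nStrata <- min(as.integer(nStrata), max(5L, sum(usable) %/% 10L))
  qs <- unique(quantile(gc[usable], probs = seq(0, 1, length.out = nStrata + 1)))
  strat <- cut(gc, qs, include.lowest = TRUE)
  med <- tapply(x[usable], strat[usable], median)
  gcm <- tapply(gc[usable], strat[usable], median)
  keep <- !is.na(med) & med > 0
  if (sum(keep) < 3) stop("too few informative GC strata")
  fit <- lowess(gcm[keep], log(med[keep]), f = span, iter = iterations)
  pred <- exp(approx(fit$x, fit$y, xout = gc, rule = 2, ties = mean)$y)
  nf <- length(fit$x)
  if (nf >= 2) {
    lo <- !is.na(gc) & gc < fit$x[1]
    hi <- !is.na(gc) & gc > fit$x[nf]
    sl1 <- (fit$y[2] - fit$y[1]) / (fit$x[2] - fit$x[1])
    sl2 <- (fit$y[nf] - fit$y[nf - 1]) / (fit$x[nf] - fit$x[nf - 1])
    pred[lo] <- exp(fit$y[1] + sl1 * (gc[lo] - fit$x[1]))
    pred[hi] <- exp(fit$y[nf] + sl2 * (gc[hi] - fit$x[nf]))
  }
  ok <- usable & !is.na(pred) & pred > 0
  floorFit <- minRelFit * median(pred[ok])
  ok <- ok & pred >= floorFit
  out <- rep(NA_real_, length(x))
  out[ok] <- x[ok] / pred[ok]
  out
}

#' Mappability correction
#'
#' Divides each value by the bin's mappability; bins below the mappability
#' floor are marked unusable, mirroring unique-match filtering: counts in
#' poorly mappable bins are artifactually distorted rather than rescalable.
#'
#' @param values Numeric per-bin values (`NA` allowed).
#' @param bins Annotated bin `GRanges` with a `mappability` column.
#' @param minMappability Usability floor (default 0.85).
#' @return Numeric vector (`NA` where unusable). If mappability was never
#'   annotated (all `NA`), values pass through unchanged.
#' @export
mappabilityNormalize <- function(values, bins, minMappability = 0.85) {
  m <- mcols(bins)$mappability
  if (is.null(m) || all(is.na(m))) return(values)
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values) & !is.na(m) & m >= minMappability
  out[ok] <- values[ok] / m[ok]
  out
}

#' Median-center corrected values into a copy-number profile
#'
#' Divides by the median over usable (non-`NA`) bins so a karyotypically flat
#' genome sits at ratio 1.
#'
#' @param values Numeric per-bin values (`NA` = unusable).
#' @param bins Bin `GRanges`.
#' @param raw Optional integer vector of raw counts to carry along.
#' @param cellId Optional cell label.
#' @return A [CNProfile-class].
#' @export
medianCenter <- function(values, bins, raw = NULL, cellId = NA_character_) {
  usable <- !is.na(values)
  if (!any(usable)) stop("no usable bins")
  med <- median(values[usable])
  if (med <= 0) stop("median of usable values is not positive")
  ratio <- values / med
  if (is.null(raw)) raw <- rep(NA_integer_, length(values))
  methods::new("CNProfile", bins = bins, raw = as.integer(raw),
               ratio = ratio, usable = usable, cellId = cellId)
}

#' Full normalization of one cell's binned counts
#'
#' Applies the corrections in the order GC, then mappability, then median
#' centering, producing the normalized ratio profile used everywhere
#' downstream.
#'
#' @inheritParams gcNormalize
#' @inheritParams mappabilityNormalize
#' @param cellId Optional cell label.
#' @return A [CNProfile-class].
#' @export
normalizeProfile <- function(counts, bins, span = 0.3, iterations = 3L,
                             minMappability = 0.85, minRelFit = 0.1,
                             cellId = NA_character_) {
  raw <- if (methods::is(counts, "BinnedCounts")) counts(counts) else counts
  v <- gcNormalize(raw, bins, span = span, iterations = iterations,
                   minRelFit = minRelFit)
  v <- mappabilityNormalize(v, bins, minMappability = minMappability)
  medianCenter(v, bins, raw = raw, cellId = cellId)
}

#' Per-profile quality metrics
#'
#' * **uniformity** — fraction of usable bins whose ratio is at least
#'   `uniformityThreshold` (default 20%) of the mean ratio;
#' * **coverageFraction** — fraction of usable bins whose ratio exceeds
#'   `coverageThreshold` (default 60%) of the mean ratio;
#' * **dlrs** — derivative log-ratio spread: the sample standard deviation of
#'   consecutive differences of log2 ratio over usable bins in genome order
#'   (pairs spanning a chromosome boundary excluded), divided by sqrt(2);
#' * **outlierFraction3sd** — diagnostic only: fraction of usable bins whose
#'   ratio deviates from the median by more than 3 standard deviations (no
#'   filtering is applied on this flag).
#'
#' @param profile A [CNProfile-class].
#' @param uniformityThreshold,coverageThreshold Fractions of the mean ratio.
#' @return Named list with the four metrics.
#' @export
qualityMetrics <- function(profile, uniformityThreshold = 0.2,
                           coverageThreshold = 0.6) {
  u <- usableBins(profile)
  if (sum(u) < 3) stop("need at least 3 usable bins")
  r <- ratios(profile)[u]
  m <- mean(r)
  lr <- log2(r)
  ch <- .chromFactor(bins(profile))[u]
  d <- diff(lr)
  d <- d[as.integer(ch[-1]) == as.integer(ch[-length(ch)])]
  list(uniformity = mean(r >= uniformityThreshold * m),
       coverageFraction = mean(r > coverageThreshold * m),
       dlrs = if (length(d) >= 2) sd(d) / sqrt(2) else NA_real_,
       outlierFraction3sd = mean(abs(r - median(r)) > 3 * sd(r)))
}

#' Detect problematic genome regions from a panel of normal cells
#'
#' For every bin evaluable in more than half of the panel, the median
#' normalized ratio across the panel is computed; bins with median strictly
#' above `hi` (default 1.4) or strictly below `lo` (default 0.6) are flagged,
#' and maximal runs of adjacent flagged bins on a chromosome are merged into
#' blacklist regions. These regions systematically mis-report copy number in
#' karyotypically normal cells and are used to filter false-positive calls.
#'
#' @param panel List of [CNProfile-class] objects on an identical bin table.
#' @param hi,lo Median fold-change flags (strict inequalities).
#' @return A `GRanges` of blacklist regions with metadata columns `medianFC`
#'   (median across panel of the region's bin medians) and `direction`
#'   (`"gain"`/`"loss"`); `metadata()` carries `nRegions` and `totalBp`.
#' @export
detectProblematicRegions <- function(panel, hi = 1.4, lo = 0.6) {
  if (length(panel) < 2) stop("need at least 2 panel profiles")
  b0 <- bins(panel[[1]])
  for (p in panel[-1])
    if (!identical(granges(bins(p)), granges(b0)))
      stop("panel profiles must share an identical bin table")
  R <- vapply(panel, ratios, numeric(length(b0)))
  evaluable <- rowSums(!is.na(R)) > length(panel) / 2
  med <- rep(NA_real_, length(b0))
  med[evaluable] <- apply(R[evaluable, , drop = FALSE], 1, median,
                          na.rm = TRUE)
  flagged <- !is.na(med) & (med > hi | med < lo)

  bl <- GRanges(seqlengths = seqlengths(b0))
  mcols(bl)$medianFC <- numeric(0)
  mcols(bl)$direction <- character(0)
  if (any(flagged)) {
    ch <- .chromFactor(b0)
    # runs of adjacent flagged bins within a chromosome
    grp <- cumsum(c(TRUE, diff(as.integer(flagged)) != 0 |
                      as.integer(ch[-1]) != as.integer(ch[-length(ch)])))
    idx <- which(flagged)
    runs <- split(idx, grp[idx])
    rows <- lapply(runs, function(ii) {
      mfc <- median(med[ii])
      data.frame(chrom = as.character(ch[ii[1]]),
                 start = start(b0)[ii[1]], end = end(b0)[ii[length(ii)]],
                 medianFC = mfc,
                 direction = if (mfc > 1) "gain" else "loss")
    })
    rows <- do.call(rbind, rows)
    bl <- GRanges(rows$chrom, IRanges(rows$start, rows$end),
                  medianFC = rows$medianFC, direction = rows$direction,
                  seqlengths = seqlengths(b0))
    bl <- sort(bl)
  }
  metadata(bl)$nRegions <- length(bl)
  metadata(bl)$totalBp <- sum(width(bl))
  bl
}
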