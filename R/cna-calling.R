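# recursive binary RSS splitting of one numeric vector; returns sorted vector
# of segment start positions (1-based within x)
.segmentVector <- function(x, penalty, minBins, sigma2) {
  n <- length(x)
  starts <- 1L
  if (n < 2L * minBins) return(starts)
  thresh <- penalty * sigma2 * log(n)
  eps <- 1e-10 * (sum((x - mean(x))^2) + 1)
  queue <- list(c(1L, n))
  while (length(queue)) {
    rg <- queue[[1]]; queue <- queue[-1]
    lo <- rg[1]; hi <- rg[2]
    m <- hi - lo + 1L
    if (m < 2L * minBins) next
    xi <- x[lo:hi]
    cs <- cumsum(xi)
    tot <- cs[m]
    rssAll <- sum(xi^2) - tot^2 / m
    k <- seq.int(minBins, m - minBins) # last index of the left part
    sL <- cs[k]
    gain <- sL^2 / k + (tot - sL)^2 / (m - k) - tot^2 / m
    best <- which.max(gain)
    if (gain[best] > thresh + eps) {
      cut <- lo + k[best] - 1L
      starts <- c(starts, cut + 1L)
      queue <- c(queue, list(c(lo, cut)), list(c(cut + 1L, hi)))
    }
  }
  sort(unique(starts))
}

#' Segment a normalized profile into piecewise-constant regions
#'
#' Deterministic recursive binary splitting per chromosome: the split
#' maximizing the residual-sum-of-squares reduction is accepted only when the
#' gain exceeds `penalty * sigma2 * log(n)`, where `sigma2` is a robust noise
#' variance estimated genome-wide from the median absolute consecutive
#' difference of the ratio and `n` is the chromosome's usable bin count — a
#' BIC-style stopping rule. Splits always leave at least `minBins` bins on
#' each side; a chromosome with fewer than `minBins` usable bins becomes a
#' single segment with a warning.
#'
#' @param profile A [CNProfile-class].
#' @param penalty Penalty multiplier on the BIC-style threshold (default 3).
#' @param minBins Minimum segment length in usable bins (default 3).
#' @return Data frame of segments: `chrom`, `binStart`/`binEnd` (inclusive
#'   indices into the full bin table), `start`/`end` (bp), `nBins` (usable
#'   bins), `meanRatio`.
#' @export
segmentProfile <- function(profile, penalty = 3, minBins = 3L) {
  b <- bins(profile)
  u <- usableBins(profile)
  r <- ratios(profile)
  ch <- .chromFactor(b)

  # robust genome-wide noise from consecutive usable-bin differences
  dAll <- unlist(lapply(levels(ch), function(cc) {
    xi <- r[u & ch == cc]
    if (length(xi) > 1) diff(xi) else numeric(0)
  }), use.names = FALSE)
  sigma2 <- if (length(dAll)) (median(abs(dAll)) / (0.6745 * sqrt(2)))^2 else 0

  segs <- lapply(levels(ch), function(cc) {
    idx <- which(u & ch == cc) # full-table indices of usable bins
    if (!length(idx)) return(NULL)
    if (length(idx) < minBins)
      warning("chromosome ", cc, " has fewer than ", minBins,
              " usable bins; single segment")
    st <- .segmentVector(r[idx], penalty, minBins, sigma2)
    en <- c(st[-1] - 1L, length(idx))
    data.frame(chrom = cc,
               binStart = idx[st], binEnd = idx[en],
               start = start(b)[idx[st]], end = end(b)[idx[en]],
               nBins = en - st + 1L,
               meanRatio = vapply(seq_along(st), function(i)
                 mean(r[idx[st[i]:en[i]][u[idx[st[i]:en[i]]]]]), numeric(1)))
  })
  do.call(rbind, segs)
}

#' Assign integer copy numbers to segments
#'
#' Absolute copy number is `round(meanRatio * mainPloidy)` (half away from
#' zero), floored at 0; segments above the main ploidy are gains, below are
#' losses, at it neutral.
#'
#' @param segments Segment data frame from [segmentProfile()].
#' @param mainPloidy Integer main ploidy (>= 1).
#' @return `segments` with `copyNumber` and `class` columns added.
#' @export
assignCopyNumbers <- function(segments, mainPloidy) {
  mainPloidy <- as.integer(mainPloidy)
  if (mainPloidy < 1L) stop("mainPloidy must be >= 1")
  cn <- pmax(0, roundHalfAway(segments$meanRatio * mainPloidy))
  segments$copyNumber <- as.integer(cn)
  segments$class <- ifelse(cn > mainPloidy, "gain",
                           ifelse(cn < mainPloidy, "loss", "neutral"))
  segments
}

# per-segment usable-bin ratios
.segmentRatios <- function(segments, profile) {
  u <- usableBins(profile); r <- ratios(profile)
  lapply(seq_len(nrow(segments)), function(i) {
    ii <- segments$binStart[i]:segments$binEnd[i]
    r[ii[u[ii]]]
  })
}

#' Test segment significance against the neutral background
#'
#' Each non-neutral segment's per-bin ratios are compared with the ratios of
#' all neutral-segment bins genome-wide using both a two-sample Wilcoxon
#' rank-sum test and a two-sample Kolmogorov-Smirnov test. A segment is a
#' significant call only when it is non-neutral and both p-values fall below
#' `alpha` (default 0.01). Segments with fewer than 2 usable bins, or tested
#' when no neutral background exists, are untestable and never significant.
#'
#' @param segments Classified segment data frame (after
#'   [assignCopyNumbers()]).
#' @param profile The [CNProfile-class] the segments came from.
#' @param alpha Two-test significance threshold (default 0.01).
#' @return `segments` with `pWilcoxon`, `pKS`, `significant` and `untestable`
#'   columns added.
#' @export
testSegmentSignificance <- function(segments, profile, alpha = 0.01) {
  segRatios <- .segmentRatios(segments, profile)
  bg <- unlist(segRatios[segments$class == "neutral"], use.names = FALSE)
  n <- nrow(segments)
  pW <- pK <- rep(NA_real_, n)
  untestable <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (segments$class[i] == "neutral") next
    x <- segRatios[[i]]
    if (length(x) < 2L || length(bg) < 2L) {
      untestable[i] <- TRUE
      next
    }
    pW[i] <- suppressWarnings(wilcox.test(x, bg, exact = FALSE)$p.value)
    pK[i] <- suppressWarnings(ks.test(x, bg)$p.value)
  }
  segments$pWilcoxon <- pW
  segments$pKS <- pK
  segments$untestable <- untestable
  segments$significant <- segments$class != "neutral" & !untestable &
    !is.na(pW) & !is.na(pK) & pW < alpha & pK < alpha
  segments
}

# build a CNACallSet from significant segments
.makeCallSet <- function(segments, profile, mainPloidy) {
  sig <- segments[segments$significant, , drop = FALSE]
  gr <- if (nrow(sig)) {
    GRanges(sig$chrom, IRanges(sig$start, sig$end),
            class = sig$class, copyNumber = sig$copyNumber,
            meanRatio = sig$meanRatio, pWilcoxon = sig$pWilcoxon,
            pKS = sig$pKS, blacklistedFraction = 0,
            seqlengths = seqlengths(bins(profile)))
  } else {
    g <- GRanges(seqlengths = seqlengths(bins(profile)))
    mcols(g) <- DataFrame(class = character(0), copyNumber = integer(0),
                          meanRatio = numeric(0), pWilcoxon = numeric(0),
                          pKS = numeric(0), blacklistedFraction = numeric(0))
    g
  }
  methods::new("CNACallSet", cellId = cellId(profile),
               mainPloidy = as.integer(mainPloidy), calls = sort(gr),
               mbpGained = sum(width(gr[gr$class == "gain"])) / 1e6,
               mbpLost = sum(width(gr[gr$class == "loss"])) / 1e6)
}

#' Call copy-number alterations in one cell
#'
#' Convenience wrapper: segments the profile, assigns copy numbers at the
#' given main ploidy, tests significance and (optionally) filters against a
#' blacklist of problematic regions.
#'
#' @inheritParams segmentProfile
#' @inheritParams assignCopyNumbers
#' @inheritParams testSegmentSignificance
#' @param blacklist Optional blacklist `GRanges` from
#'   [detectProblematicRegions()].
#' @param maxOverlap Maximum tolerated blacklist-overlap fraction of a call
#'   (default 0.5, strict).
#' @return A [CNACallSet-class] of significant, filtered calls. The full
#'   segment table is attached as `attr(, "segments")`.
#' @export
callCNAs <- function(profile, mainPloidy, penalty = 3, minBins = 3L,
                     alpha = 0.01, blacklist = NULL, maxOverlap = 0.5) {
  segs <- segmentProfile(profile, penalty = penalty, minBins = minBins)
  segs <- assignCopyNumbers(segs, mainPloidy)
  segs <- testSegmentSignificance(segs, profile, alpha = alpha)
  cs <- .makeCallSet(segs, profile, mainPloidy)
  if (!is.null(blacklist)) cs <- filterCalls(cs, blacklist, maxOverlap)
  attr(cs, "segments") <- segs
  cs
}

#' Filter calls against a blacklist of problematic regions
#'
#' Removes calls whose fraction of length overlapping blacklist regions is
#' strictly greater than `maxOverlap`; retained calls carry their
#' `blacklistedFraction`.
#'
#' @param callset A [CNACallSet-class].
#' @param blacklist Blacklist `GRanges`.
#' @param maxOverlap Maximum tolerated overlap fraction (default 0.5).
#' @return The filtered [CNACallSet-class].
#' @export
filterCalls <- function(callset, blacklist, maxOverlap = 0.5) {
  gr <- calls(callset)
  if (length(gr) == 0L || length(blacklist) == 0L) return(callset)
  ov <- suppressWarnings(findOverlaps(gr, blacklist))
  w <- width(pintersect(gr[queryHits(ov)], blacklist[subjectHits(ov)]))
  bp <- as.numeric(tapply(w, factor(queryHits(ov), levels = seq_along(gr)),
                          sum))
  bp[is.na(bp)] <- 0
  frac <- bp / width(gr)
  gr$blacklistedFraction <- frac
  keep <- gr[frac <= maxOverlap]
  methods::new("CNACallSet", cellId = callset@cellId,
               mainPloidy = callset@mainPloidy, calls = keep,
               mbpGained = sum(width(keep[keep$class == "gain"])) / 1e6,
               mbpLost = sum(width(keep[keep$class == "loss"])) / 1e6)
}

#' Summarize and intersect calls across cells
#'
#' Computes, per alteration class, the genomic core shared by every cell (the
#' intersection of the cells' call footprints), each cell's fraction of the
#' core it carries, and each cell's private call length (genome called in
#' exactly one cell).
#'
#' @param callsets List of [CNACallSet-class] objects on a shared genome.
#' @return List with `coreGain` and `coreLoss` (`GRanges`), and `perCell`, a
#'   data frame with per-cell megabase tallies, `sharedFraction` (of the
#'   combined core) and `privateMbp`.
#' @export
summarizeAndIntersect <- function(callsets) {
  if (!length(callsets)) stop("need at least one callset")
  foot <- function(cs, cls) reduce(calls(cs)[calls(cs)$class == cls])
  core <- function(cls)
    Reduce(function(a, b) suppressWarnings(intersect(a, b)),
           lapply(callsets, foot, cls))
  coreGain <- core("gain")
  coreLoss <- core("loss")
  coreAll <- reduce(c(coreGain, coreLoss))

  allCalls <- lapply(callsets, function(cs) reduce(calls(cs)))
  cov <- coverage(do.call(c, unname(allCalls)))
  once <- methods::as(cov, "GRanges")
  once <- once[once$score == 1]

  perCell <- do.call(rbind, lapply(seq_along(callsets), function(i) {
    cs <- callsets[[i]]
    shared <- if (sum(width(coreAll)) > 0)
      sum(width(suppressWarnings(intersect(coreAll, allCalls[[i]])))) /
        sum(width(coreAll))
    else NA_real_
    priv <- sum(width(suppressWarnings(intersect(once, allCalls[[i]])))) / 1e6
    data.frame(cellId = cellId(cs), mbpGained = cs@mbpGained,
               mbpLost = cs@mbpLost, sharedFraction = shared,
               privateMbp = priv)
  }))
  list(coreGain = coreGain, coreLoss = coreLoss, perCell = perCell)
}
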