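# windows tiling the genome of a bin table; keeps windows with >= 50% of
# their length covered by usable bins
.makeWindows <- function(profile, windowSize) {
  b <- bins(profile)
  sl <- seqlengths(b)
  if (any(is.na(sl)))
    sl[is.na(sl)] <- vapply(names(sl)[is.na(sl)], function(cc)
      max(end(b[seqnames(b) == cc])), numeric(1))
  win <- makeBins(sl, windowSize)
  ub <- b[usableBins(profile)]
  ov <- suppressWarnings(findOverlaps(win, ub))
  covBp <- rep(0, length(win))
  if (length(ov)) {
    w <- width(pintersect(win[queryHits(ov)], ub[subjectHits(ov)]))
    agg <- tapply(w, factor(queryHits(ov), levels = seq_along(win)), sum)
    covBp <- as.numeric(agg)
    covBp[is.na(covBp)] <- 0
  }
  win[covBp / width(win) >= 0.5]
}

# per-window index of the longest-overlap segment; NA when none
.windowSegment <- function(win, segGR) {
  ov <- suppressWarnings(findOverlaps(win, segGR))
  if (!length(ov)) return(rep(NA_integer_, length(win)))
  w <- width(pintersect(win[queryHits(ov)], segGR[subjectHits(ov)]))
  o <- base::order(queryHits(ov), -w, subjectHits(ov))
  first <- !duplicated(queryHits(ov)[o])
  idx <- rep(NA_integer_, length(win))
  idx[queryHits(ov)[o][first]] <- subjectHits(ov)[o][first]
  idx
}

# rank-statistic AUC (equivalent to the Mann-Whitney normalization)
.rankAUC <- function(score, truth) {
  nPos <- sum(truth); nNeg <- sum(!truth)
  if (nPos == 0 || nNeg == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[truth]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Windowed ROC/AUC of CNA detection against reference calls
#'
#' Tiles the genome into fixed-size windows (windows with under half their
#' length in usable bins are excluded), marks a window altered when any
#' reference call overlaps it (type and actual copy number are not compared),
#' scores each window with `-log10` of the Wilcoxon p-value of its
#' longest-overlap segment (neutral or untested windows score 0), and
#' computes the AUC by the rank statistic over all thresholds.
#'
#' @param segments Segment table of the test cell (from [callCNAs()]'s
#'   `attr(, "segments")` or [testSegmentSignificance()]).
#' @param profile The test cell's [CNProfile-class] (defines usable windows).
#' @param referenceCalls `GRanges` of reference alteration calls.
#' @param windowSize Window size in bp (default 500000).
#' @return List with `auc`, `nWindows`, `nAltered` and the per-window
#'   `windows` GRanges carrying `truth` and `score`.
#' @export
rocAucWindows <- function(segments, profile, referenceCalls,
                          windowSize = 500000L) {
  win <- .makeWindows(profile, windowSize)
  truth <- suppressWarnings(countOverlaps(win, referenceCalls)) > 0
  segGR <- GRanges(segments$chrom, IRanges(segments$start, segments$end))
  idx <- .windowSegment(win, segGR)
  score <- rep(0, length(win))
  hit <- !is.na(idx)
  p <- segments$pWilcoxon[idx[hit]]
  cls <- segments$class[idx[hit]]
  s <- ifelse(cls != "neutral" & !is.na(p), -log10(pmax(p, 1e-300)), 0)
  score[hit] <- s
  auc <- .rankAUC(score, truth)
  if (is.na(auc))
    warning("degenerate truth: all windows in one class; AUC undefined")
  mcols(win)$truth <- truth
  mcols(win)$score <- score
  list(auc = auc, nWindows = length(win), nAltered = sum(truth),
       windows = win)
}

#' Specificity on an expected-flat profile
#'
#' For a profile whose truth is all-neutral by construction, every window
#' overlapped by a call is a false positive; specificity is the fraction of
#' windows not called altered.
#'
#' @param callset A [CNACallSet-class] (calls are the false positives).
#' @param profile The cell's [CNProfile-class].
#' @param windowSize Window size in bp (default 200000).
#' @return List with `specificity`, `nWindows`, `falsePositiveWindows`.
#' @export
specificityFlat <- function(callset, profile, windowSize = 200000L) {
  win <- .makeWindows(profile, windowSize)
  fp <- sum(suppressWarnings(countOverlaps(win, calls(callset))) > 0)
  list(specificity = 1 - fp / length(win), nWindows = length(win),
       falsePositiveWindows = fp)
}

#' Squared correlation between two copy-number profiles
#'
#' Averages each profile's ratios within shared fixed-size windows (usable
#' bins only; windows usable in both profiles) and returns the squared
#' Pearson correlation — the profile-stability statistic used to compare the
#' same cell at different read depths.
#'
#' @param profileA,profileB [CNProfile-class] objects on the same genome.
#' @param windowSize Window size in bp (default 500000).
#' @return Squared Pearson correlation (scalar), or `NA` with a warning if
#'   fewer than 3 shared windows exist.
#' @export
profileR2 <- function(profileA, profileB, windowSize = 500000L) {
  winMeans <- function(p) {
    win <- .makeWindows(p, windowSize)
    ub <- bins(p)[usableBins(p)]
    r <- ratios(p)[usableBins(p)]
    ov <- suppressWarnings(findOverlaps(win, ub))
    m <- tapply(r[subjectHits(ov)],
                factor(queryHits(ov), levels = seq_along(win)), mean)
    mcols(win)$m <- as.numeric(m)
    win
  }
  a <- winMeans(profileA)
  b <- winMeans(profileB)
  key <- function(w) paste0(seqnames(w), ":", start(w))
  shared <- base::intersect(key(a), key(b))
  if (length(shared) < 3) {
    warning("fewer than 3 shared windows; R2 undefined")
    return(NA_real_)
  }
  ma <- mcols(a)$m[match(shared, key(a))]
  mb <- mcols(b)$m[match(shared, key(b))]
  ok <- !is.na(ma) & !is.na(mb)
  cor(ma[ok], mb[ok])^2
}
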