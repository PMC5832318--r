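#' Scale and smooth a profile for ploidy testing
#'
#' Multiplies the median-centered ratio of each usable bin by the candidate
#' main ploidy and smooths along genome order within each chromosome with a
#' running median of width `smoothWindow` followed by a running mean of the
#' same width. The median pass removes isolated spikes, the mean pass reduces
#' residual noise; steps are preserved to within the window width.
#' Chromosomes with fewer usable bins than the window pass through unsmoothed.
#'
#' @param profile A [CNProfile-class] (median-centered).
#' @param ploidy Candidate main ploidy (>= 1).
#' @param smoothWindow Odd window width in bins (default 5).
#' @return Numeric vector of smoothed scaled values, one per usable bin, in
#'   genome order.
#' @export
prepareSignal <- function(profile, ploidy, smoothWindow = 5L) {
  if (ploidy < 1) stop("ploidy must be >= 1")
  smoothWindow <- as.integer(smoothWindow)
  if (smoothWindow %% 2L == 0L) stop("smoothWindow must be odd")
  u <- usableBins(profile)
  ch <- .chromFactor(bins(profile))[u]
  v <- ratios(profile)[u] * ploidy
  unlist(lapply(levels(ch), function(cc) {
    xi <- v[ch == cc]
    if (length(xi) < smoothWindow) return(xi)
    runningMean(runmed(xi, smoothWindow, endrule = "median"), smoothWindow)
  }), use.names = FALSE)
}

#' Kernel density estimate of scaled copy-number values
#'
#' Gaussian-kernel density with bandwidth chosen by Silverman's rule of thumb
#' `0.9 * min(sd, IQR/1.34) * n^(-1/5)` (the [stats::bw.nrd0()] rule), with a
#' manual override for cases where visual inspection suggests a different
#' smoothing. A zero-variance input yields a flagged degenerate density with
#' a single point mass.
#'
#' @param values Numeric vector (>= 10 values unless degenerate).
#' @param bandwidth Numeric bandwidth, or `NULL` for Silverman's rule.
#' @param n Grid size (default 512).
#' @return List with `x`, `y`, `bw` and logical `degenerate`.
#' @export
estimateDensity <- function(values, bandwidth = NULL, n = 512L) {
  values <- values[!is.na(values)]
  if (var(values) == 0 || length(values) < 2L)
    return(list(x = values[1], y = 1, bw = 0, degenerate = TRUE))
  if (length(values) < 10L) stop("need at least 10 values for a KDE")
  bw <- if (is.null(bandwidth)) bw.nrd0(values) else bandwidth
  d <- density(values, bw = bw, n = n)
  list(x = d$x, y = d$y, bw = bw, degenerate = FALSE)
}

# Mexican-hat (Ricker) wavelet sampled at integer offsets for a given scale
.ricker <- function(scale, len) {
  t <- seq(-len, len)
  a <- t / scale
  (1 - a^2) * exp(-a^2 / 2)
}

# continuous-wavelet-transform ridge detection of local maxima: CWT maxima
# are linked into ridge lines from the coarsest scale down, and ridges
# persisting over at least half the scale ladder are kept. Returns grid
# indices of the ridge positions at their finest reached scale.
.cwtPeaks <- function(y, scales = NULL, bwGrid = NULL) {
  n <- length(y)
  if (is.null(scales)) {
    # ladder matched to the kernel width when known (peaks in a KDE are at
    # least one bandwidth wide), else spanning ~1-10% of the grid
    if (is.null(bwGrid)) {
      smin <- max(2L, round(0.01 * n))
      smax <- max(smin + 1L, round(0.1 * n))
    } else {
      smin <- max(2L, round(bwGrid / 3))
      smax <- max(smin + 4L, round(2 * bwGrid))
    }
    scales <- unique(round(seq(smin, smax, length.out = 10)))
  }
  localMax <- function(v) which(diff(sign(diff(v))) < 0) + 1L
  maxima <- lapply(scales, function(s) {
    half <- min(n - 1L, ceiling(4 * s))
    k <- .ricker(s, half)
    cwt <- as.numeric(stats::filter(y, k / sum(abs(k)), sides = 2))
    cwt[is.na(cwt)] <- 0
    m <- localMax(cwt)
    m[cwt[m] > 0]
  })
  nS <- length(scales)
  ridges <- data.frame(pos = maxima[[nS]], len = 1L)
  for (i in rev(seq_len(nS - 1L))) {
    m <- maxima[[i]]
    used <- logical(length(m))
    if (nrow(ridges)) for (j in seq_len(nrow(ridges))) {
      if (!length(m)) next
      d <- abs(m - ridges$pos[j])
      k <- which.min(d)
      if (d[k] <= scales[i + 1L] && !used[k]) {
        ridges$pos[j] <- m[k]
        ridges$len[j] <- ridges$len[j] + 1L
        used[k] <- TRUE
      }
    }
    if (any(!used)) # unmatched maxima seed new ridges at this scale
      ridges <- rbind(ridges, data.frame(pos = m[!used], len = 1L))
  }
  sort(unique(ridges$pos[ridges$len >= max(3L, ceiling(nS / 3))]))
}

#' Find peaks of a density and their probability masses
#'
#' Candidate peaks are local maxima of the density persistent across a ladder
#' of continuous-wavelet-transform scales (Mexican-hat kernel, scales spanning
#' roughly 1-10% of the grid); a plain local-maxima finder is available as
#' `method = "localmax"`. Each peak's mass is the integral of the density
#' over its basin, delimited by the density minima between adjacent peaks
#' (grid ends for the outer peaks); peaks contributing less than `minMass`
#' (default 2%) of the total probability are excluded as potential false
#' positives.
#'
#' @param dens Density list from [estimateDensity()].
#' @param minMass Minimum relative probability contribution (default 0.02).
#' @param method `"cwt"` (default) or `"localmax"`.
#' @return List with `peaks` (positions, increasing) and `masses`.
#' @export
findDensityPeaks <- function(dens, minMass = 0.02,
                             method = c("cwt", "localmax")) {
  method <- match.arg(method)
  if (isTRUE(dens$degenerate))
    return(list(peaks = dens$x[1], masses = 1))
  x <- dens$x; y <- dens$y
  n <- length(y)
  idx <- if (method == "cwt")
    .cwtPeaks(y, bwGrid = if (dens$bw > 0) dens$bw / (x[2] - x[1]) else NULL)
  else which(diff(sign(diff(y))) < 0) + 1L
  # refine each candidate to the nearest local maximum of the raw density
  if (length(idx)) {
    idx <- vapply(idx, function(i) {
      lo <- max(1L, i - 5L); hi <- min(n, i + 5L)
      lo + which.max(y[lo:hi]) - 1L
    }, integer(1))
    idx <- sort(unique(idx))
  }
  if (!length(idx)) stop("uninterpretable density: no peaks found")
  total <- .trapz(x, y)
  repeat {
    # basin boundaries: minima between adjacent peaks, grid ends outside
    bounds <- c(1L, vapply(seq_len(length(idx) - 1L), function(i) {
      lo <- idx[i]; hi <- idx[i + 1L]
      lo + which.min(y[lo:hi]) - 1L
    }, integer(1)), n)
    masses <- vapply(seq_along(idx), function(i)
      .trapz(x[bounds[i]:bounds[i + 1L]], y[bounds[i]:bounds[i + 1L]]) / total,
      numeric(1))
    if (all(masses >= minMass) || length(idx) == 1L) break
    idx <- idx[-which.min(masses)] # drop weakest, re-derive basins
  }
  if (length(idx) == 1L && masses[1] < minMass)
    stop("uninterpretable density: no peaks above the mass threshold")
  list(peaks = x[idx], masses = masses)
}

#' Linear regression of KDE peaks on putative integer copy numbers
#'
#' Rounds each peak position to the nearest integer — the putative underlying
#' copy number — and fits an ordinary least-squares line of peak position on
#' putative copy number, with an intercept term. On a correctly scaled
#' profile the peak positions increase linearly with the underlying copy
#' number, so a good candidate ploidy yields a near-perfect fit.
#'
#' @param peaks Numeric vector of peak positions (>= 2 for a fit).
#' @param r2Min R-squared threshold recorded in `passesR2` (default 0.98).
#' @param weights Optional non-negative weights (e.g. peak masses) for a
#'   weighted fit; `NULL` (the default) fits ordinary least squares.
#' @return List with `putativeCN`, `slope`, `intercept`, `r2`, `ssr`,
#'   `passesR2`. Fewer than 2 peaks, or all peaks rounding to the same copy
#'   number, give an undefined fit (`passesR2 = FALSE`). A 2-peak fit is
#'   computed but never passes: a line through two points is saturated and
#'   carries no evidence about the scaling, so at least 3 peaks (3 distinct
#'   copy-number levels in the genome) are required to support a ploidy.
#' @examples
#' fitPloidyRegression(c(1.0, 1.97, 2.94, 3.82, 4.67))$ssr # ~0.008
#' @export
fitPloidyRegression <- function(peaks, r2Min = 0.98, weights = NULL) {
  cn <- as.integer(roundHalfAway(peaks))
  und <- list(putativeCN = cn, slope = NA_real_, intercept = NA_real_,
              r2 = NA_real_, ssr = NA_real_, passesR2 = FALSE)
  if (length(peaks) < 2L || length(unique(cn)) < 2L) return(und)
  w <- if (is.null(weights)) rep(1, length(peaks)) else weights
  f <- lm(peaks ~ cn, weights = w)
  ssr <- sum(w * resid(f)^2)
  tss <- sum(w * (peaks - sum(w * peaks) / sum(w))^2)
  r2 <- 1 - ssr / tss
  list(putativeCN = cn, slope = unname(coef(f)[2]),
       intercept = unname(coef(f)[1]), r2 = r2, ssr = ssr,
       passesR2 = r2 > r2Min && length(peaks) >= 3L)
}

#' Select the main ploidy from candidate fits
#'
#' Candidates failing the goodness-of-fit filter (`r2 <= r2Min`, or fewer
#' than 3 peaks) are discarded. Because the regression carries an intercept,
#' a candidate one off from the true ploidy can produce a deceptively good
#' line — scaling by `P/p` shifts every rounded copy number by the same
#' amount, and its SSR is then *smaller* than the true ploidy's by
#' `(P/p)^2` — so a candidate is only *plausible* when its peaks are
#' actually centered on the putative integer copy numbers: slope within
#' `slopeTolerance` of 1 and intercept within `interceptTolerance` of 0
#' (an affine off-by-one alias has intercept `±P/p`, at least `(p-1)/p`).
#'
#' Among plausible candidates the minimum-SSR candidate is found; a ploidy
#' multiple of the truth fits equally well with residuals scaled by the
#' multiple, so the *smallest plausible divisor* of the best candidate whose
#' SSR is within the expected `(best/P)^2` scaling (times
#' `1 + ssrTolerance`) is preferred over it — the automated counterpart of
#' manually reviewing ploidy multiples and taking the lowest plausible
#' ploidy with similar fit quality.
#'
#' @param fits List of fit lists, each with `ploidy`, `r2`, `ssr`, `slope`,
#'   `intercept`, `passesR2` (see [ploidyScan()]).
#' @param r2Min R-squared filter (default 0.98, strict).
#' @param ssrTolerance Relative SSR slack in the scaled divisor comparison
#'   (default 0.5).
#' @param slopeTolerance,interceptTolerance Centering window around the
#'   identity line (defaults 0.15 and 0.5).
#' @return A [PloidyScan-class].
#' @export
selectPloidy <- function(fits, r2Min = 0.98, ssrTolerance = 0.5,
                         slopeTolerance = 0.15, interceptTolerance = 0.5) {
  summ <- do.call(rbind, lapply(fits, function(f)
    data.frame(ploidy = f$ploidy, nPeaks = length(f$peaks),
               slope = f$slope, intercept = f$intercept,
               r2 = f$r2, ssr = f$ssr, passesR2 = f$passesR2)))
  ok <- summ$passesR2 & !is.na(summ$ssr) &
    abs(summ$slope - 1) <= slopeTolerance &
    abs(summ$intercept) <= interceptTolerance
  if (!any(ok)) {
    return(methods::new("PloidyScan", fits = fits, summary = summ,
                        selected = NA_integer_,
                        rationale = paste0(
                          "no candidate ploidy reached R2 > ", r2Min,
                          " with peaks centered on integer copy numbers")))
  }
  best <- summ$ploidy[ok][which.min(summ$ssr[ok])]
  bestSSR <- min(summ$ssr[ok])
  sel <- best
  note <- ""
  divs <- sort(summ$ploidy[ok & summ$ploidy < best & best %% summ$ploidy == 0])
  for (P in divs) {
    if (summ$ssr[summ$ploidy == P] <=
        (best / P)^2 * (1 + ssrTolerance) * bestSSR) {
      sel <- P
      note <- paste0("; ", best, " is a multiple of ", P,
                     " with comparable scaled fit - lowest plausible taken")
      break
    }
  }
  rationale <- paste0(
    "plausible candidates (R2 > ", r2Min, ", slope ~1, intercept ~0): ",
    paste(summ$ploidy[ok], collapse = ", "),
    "; min SSR ", signif(bestSSR, 3), " at ploidy ", best, note)
  methods::new("PloidyScan", fits = fits, summary = summ,
               selected = as.integer(sel), rationale = rationale)
}

#' Scan candidate main ploidies for one cell
#'
#' For each candidate ploidy the normalized profile is scaled and smoothed
#' ([prepareSignal()]), a kernel density is estimated ([estimateDensity()]),
#' its peaks are detected and mass-filtered ([findDensityPeaks()]) and the
#' peak positions are regressed on their rounded copy numbers
#' ([fitPloidyRegression()]); [selectPloidy()] then picks the lowest
#' plausible candidate.
#'
#' On the scaled signal the modes of a correct candidate sit at consecutive
#' integers, so the useful bandwidth range is known a priori: with
#' `bandwidth = NULL` Silverman's rule is clamped to `[0.06, 0.25]`
#' copy-number units — the automated counterpart of tweaking the bandwidth
#' after visual inspection, needed because the rule-of-thumb both
#' under-smooths strongly multimodal data (its IQR term sees mostly the
#' dominant mode) and over-smooths at high candidate ploidies (its scale
#' term grows with the ploidy).
#'
#' @param profile A [CNProfile-class].
#' @param ploidies Candidate main ploidies (default 2:8).
#' @param smoothWindow Smoothing window (default 5 bins).
#' @param bandwidth KDE bandwidth override, or `NULL` for Silverman's rule
#'   clamped to `[0.06, 0.25]`.
#' @param minMass Peak mass filter (default 0.02).
#' @param r2Min,ssrTolerance Selection parameters (see [selectPloidy()]).
#' @param peakMethod Peak detection method (see [findDensityPeaks()]).
#' @return A [PloidyScan-class].
#' @export
ploidyScan <- function(profile, ploidies = 2:8, smoothWindow = 5L,
                       bandwidth = NULL, minMass = 0.02, r2Min = 0.98,
                       ssrTolerance = 0.5, peakMethod = "cwt") {
  fits <- lapply(ploidies, function(p) {
    v <- prepareSignal(profile, p, smoothWindow = smoothWindow)
    bw <- if (is.null(bandwidth) && var(v) > 0)
      min(max(bw.nrd0(v), 0.06), 0.25) else bandwidth
    fit <- tryCatch({
      dens <- estimateDensity(v, bandwidth = bw)
      pk <- findDensityPeaks(dens, minMass = minMass, method = peakMethod)
      c(list(ploidy = as.integer(p), peaks = pk$peaks,
             peakMasses = pk$masses),
        fitPloidyRegression(pk$peaks, r2Min = r2Min, weights = pk$masses))
    }, error = function(e)
      list(ploidy = as.integer(p), peaks = numeric(0),
           peakMasses = numeric(0), putativeCN = integer(0),
           slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
           ssr = NA_real_, passesR2 = FALSE, error = conditionMessage(e)))
    fit
  })
  selectPloidy(fits, r2Min = r2Min, ssrTolerance = ssrTolerance)
}
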