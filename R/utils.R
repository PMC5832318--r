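#' Round half away from zero
#'
#' Copy-number assignment rounds ratios to the nearest integer with ties at
#' .5 rounded away from zero (so 2.5 -> 3, -0.5 -> -1), unlike [base::round()]
#' which rounds half to even.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @export
roundHalfAway <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Running mean with shrinking edge windows
#'
#' Mean filter of odd width `k`; near the ends the window is truncated to the
#' available positions so the output has the same length as the input and no
#' NA padding.
#'
#' @param x Numeric vector.
#' @param k Odd integer window width.
#' @return Numeric vector, same length as `x`.
#' @keywords internal
runningMean <- function(x, k) {
  n <- length(x)
  if (n == 0L || k <= 1L) return(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# genome-order chromosome factor of a GRanges, in seqlevels order
.chromFactor <- function(gr) {
  factor(as.character(seqnames(gr)), levels = seqlevels(gr))
}

# stop unless bins are a sorted, non-overlapping GRanges
.checkBins <- function(bins) {
  if (!methods::is(bins, "GRanges")) stop("'bins' must be a GRanges")
  n <- length(bins)
  if (n > 1L) {
    ord <- order(bins)
    if (any(ord != seq_len(n))) stop("bin table is not sorted")
    ch <- .chromFactor(bins)
    same <- as.integer(ch[-1]) == as.integer(ch[-n])
    if (any(start(bins)[-1][same] <= end(bins)[-n][same]))
      stop("bins overlap")
  }
  invisible(TRUE)
}

# trapezoidal integral on a uniform or non-uniform grid
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Derive a reproducible sub-seed
#'
#' Deterministically expands one master seed into a stream of 32-bit seeds so
#' independent simulation stages do not share random state.
#'
#' @param seed Master seed (integer).
#' @param index Positive index of the sub-seed.
#' @return A single integer seed.
#' @export
subSeed <- function(seed, index) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, index)
  s[index]
}
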