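#' @import methods
#' @importFrom stats approx cor density dlnorm ks.test lm lowess mad median
#'   quantile rbinom resid rgamma rmultinom rnorm runif sd setNames var
#'   wilcox.test runmed IQR bw.nrd0 coef dbeta rpois
#' @importFrom utils read.delim write.table head tail
#' @importFrom GenomicRanges GRanges start end width sort order findOverlaps
#'   countOverlaps pintersect reduce intersect setdiff union coverage seqnames
#'   mcols mcols<- tileGenome strand score granges
#' @importFrom IRanges IRanges Views subsetByOverlaps ranges
#' @importFrom GenomeInfoDb seqlevels seqlengths seqlengths<- seqinfo
#'   keepSeqlevels
#' @importFrom S4Vectors queryHits subjectHits metadata metadata<- DataFrame
#'   Rle runValue
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   matchPattern letterFrequency
#' @importFrom BiocGenerics counts
NULL

#' Per-bin read counts for one cell
#'
#' Container for the result of assigning a stream of aligned reads (or a
#' simulated count draw) to the units of a bin table or fragment set. The
#' accounting invariant `sum(counts) == nAssigned` is enforced by the
#' validity method.
#'
#' @slot counts Integer vector, one non-negative count per unit.
#' @slot nAssigned Total reads assigned to exactly one unit.
#' @slot nDiscarded Reads discarded (low mapping quality, unknown chromosome,
#'   outside all units, or ambiguous fragment match).
#'
#' @export
setClass("BinnedCounts",
  representation(counts = "integer", nAssigned = "integer",
                 nDiscarded = "integer"),
  prototype(counts = integer(0), nAssigned = 0L, nDiscarded = 0L))

setValidity("BinnedCounts", function(object) {
  msg <- NULL
  if (any(object@counts < 0L)) msg <- c(msg, "negative counts")
  if (sum(as.numeric(object@counts)) != object@nAssigned)
    msg <- c(msg, "sum(counts) != nAssigned")
  if (object@nDiscarded < 0L) msg <- c(msg, "negative nDiscarded")
  if (is.null(msg)) TRUE else msg
})

#' Normalized copy-number profile of one cell
#'
#' Per-bin raw counts and GC-/mappability-corrected, median-centered ratios
#' for a single cell. The ratio of a usable bin is positive and the median
#' ratio over usable bins is 1; unusable bins carry `NA` ratios.
#'
#' @slot bins A `GRanges` bin table (see [makeBins()], [annotateBins()]).
#' @slot raw Integer vector of raw per-bin counts.
#' @slot ratio Numeric vector of normalized ratios (`NA` where not usable).
#' @slot usable Logical vector marking bins that survived masking,
#'   GC-fit support and the mappability floor.
#' @slot cellId Character label for the cell.
#'
#' @export
setClass("CNProfile",
  representation(bins = "GRanges", raw = "integer", ratio = "numeric",
                 usable = "logical", cellId = "character"),
  prototype(cellId = NA_character_))

setValidity("CNProfile", function(object) {
  n <- length(object@bins)
  msg <- NULL
  if (length(object@raw) != n || length(object@ratio) != n ||
      length(object@usable) != n)
    msg <- c(msg, "raw, ratio and usable must align 1:1 with bins")
  if (any(object@usable & is.na(object@ratio)))
    msg <- c(msg, "usable bins must have defined ratios")
  if (any(!object@usable & !is.na(object@ratio)))
    msg <- c(msg, "unusable bins must have NA ratios")
  if (any(object@usable)) {
    m <- median(object@ratio[object@usable])
    if (abs(m - 1) > 1e-9)
      msg <- c(msg, "median ratio over usable bins must be 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' Ploidy scan over candidate main ploidies
#'
#' Result of fitting the KDE-peak linear-regression model at each candidate
#' main ploidy and selecting the lowest plausible one.
#'
#' @slot fits List with one element per candidate ploidy, each a list with
#'   components `ploidy`, `peaks`, `peakMasses`, `putativeCN`, `slope`,
#'   `intercept`, `r2`, `ssr`, `passesR2`.
#' @slot summary Data frame summarising the fits (one row per candidate).
#' @slot selected Integer: the selected main ploidy, or `NA` if no candidate
#'   passed the goodness-of-fit filter.
#' @slot rationale Character description of the selection.
#'
#' @export
setClass("PloidyScan",
  representation(fits = "list", summary = "data.frame",
                 selected = "integer", rationale = "character"),
  prototype(selected = NA_integer_, rationale = ""))

setValidity("PloidyScan", function(object) {
  if (!is.na(object@selected)) {
    ok <- vapply(object@fits, function(f)
      f$ploidy == object@selected && isTRUE(f$passesR2), logical(1))
    if (!any(ok)) return("selected ploidy must be a candidate passing the R2 filter")
  }
  TRUE
})

#' Copy-number alteration calls for one cell
#'
#' Significant non-neutral segments of a cell at its main ploidy, with
#' per-cell megabase tallies of gained and lost genome.
#'
#' @slot cellId Character label.
#' @slot mainPloidy Integer main ploidy used for absolute copy numbers.
#' @slot calls `GRanges` of significant non-neutral calls with metadata
#'   columns `class`, `copyNumber`, `meanRatio`, `pWilcoxon`, `pKS`,
#'   `blacklistedFraction`.
#' @slot mbpGained,mbpLost Megabases gained/lost (sums of call widths).
#'
#' @export
setClass("CNACallSet",
  representation(cellId = "character", mainPloidy = "integer",
                 calls = "GRanges", mbpGained = "numeric",
                 mbpLost = "numeric"))

setValidity("CNACallSet", function(object) {
  cls <- object@calls$class
  g <- sum(GenomicRanges::width(object@calls[cls == "gain"])) / 1e6
  l <- sum(GenomicRanges::width(object@calls[cls == "loss"])) / 1e6
  msg <- NULL
  if (abs(g - object@mbpGained) > 1e-6) msg <- c(msg, "mbpGained mismatch")
  if (abs(l - object@mbpLost) > 1e-6) msg <- c(msg, "mbpLost mismatch")
  if (is.null(msg)) TRUE else msg
})
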