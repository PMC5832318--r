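#' @rdname BinnedCounts-class
#' @param object,x A `BinnedCounts`, `CNProfile`, `PloidyScan` or
#'   `CNACallSet` object, as appropriate.
#' @export
BiocGenerics::counts

#' @rdname BinnedCounts-class
#' @export
setGeneric("nAssigned", function(x) standardGeneric("nAssigned"))

#' @rdname BinnedCounts-class
#' @export
setGeneric("nDiscarded", function(x) standardGeneric("nDiscarded"))

#' @rdname CNProfile-class
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))

#' @rdname CNProfile-class
#' @export
setGeneric("ratios", function(x) standardGeneric("ratios"))

#' @rdname CNProfile-class
#' @export
setGeneric("rawCounts", function(x) standardGeneric("rawCounts"))

#' @rdname CNProfile-class
#' @export
setGeneric("usableBins", function(x) standardGeneric("usableBins"))

#' @rdname CNProfile-class
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))

#' @rdname PloidyScan-class
#' @export
setGeneric("selectedPloidy", function(x) standardGeneric("selectedPloidy"))

#' @rdname PloidyScan-class
#' @export
setGeneric("ploidyFits", function(x) standardGeneric("ploidyFits"))

#' @rdname CNACallSet-class
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname BinnedCounts-class
#' @export
setMethod("counts", "BinnedCounts", function(object, ...) object@counts)
setMethod("nAssigned", "BinnedCounts", function(x) x@nAssigned)
setMethod("nDiscarded", "BinnedCounts", function(x) x@nDiscarded)
setMethod("show", "BinnedCounts", function(object) {
  cat("BinnedCounts:", length(object@counts), "units,",
      object@nAssigned, "assigned,", object@nDiscarded, "discarded\n")
})

setMethod("bins", "CNProfile", function(x) x@bins)
setMethod("ratios", "CNProfile", function(x) x@ratio)
setMethod("rawCounts", "CNProfile", function(x) x@raw)
setMethod("usableBins", "CNProfile", function(x) x@usable)
setMethod("cellId", "CNProfile", function(x) x@cellId)
setMethod("show", "CNProfile", function(object) {
  cat("CNProfile", if (!is.na(object@cellId)) paste0("'", object@cellId, "'"),
      "\n ", length(object@bins), "bins on",
      length(GenomeInfoDb::seqlevels(object@bins)), "chromosomes;",
      sum(object@usable), "usable\n")
  if (any(object@usable))
    cat("  ratio range:",
        paste(signif(range(object@ratio[object@usable]), 4), collapse = " - "),
        "\n")
})

setMethod("selectedPloidy", "PloidyScan", function(x) x@selected)
setMethod("ploidyFits", "PloidyScan", function(x) x@fits)
setMethod("show", "PloidyScan", function(object) {
  cat("PloidyScan over candidate ploidies",
      paste(range(object@summary$ploidy), collapse = "-"), "\n")
  print(object@summary, digits = 4)
  cat("selected:", ifelse(is.na(object@selected), "none", object@selected),
      "\n", object@rationale, "\n")
})

setMethod("calls", "CNACallSet", function(x) x@calls)
setMethod("cellId", "CNACallSet", function(x) x@cellId)
setMethod("show", "CNACallSet", function(object) {
  cat("CNACallSet", if (!is.na(object@cellId)) paste0("'", object@cellId, "'"),
      "- main ploidy", object@mainPloidy, "\n ",
      length(object@calls), "calls:",
      round(object@mbpGained, 1), "Mbp gained,",
      round(object@mbpLost, 1), "Mbp lost\n")
})
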