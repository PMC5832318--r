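#' Default pipeline parameters
#'
#' All printed thresholds of the workflow surfaced as one named list:
#' 500 kb bins, LOWESS span 0.3 with 3 robustifying passes, mappability floor
#' 0.85, blacklist flags 1.4/0.6, test level 0.01, uniformity/coverage
#' thresholds 0.2/0.6, peak-mass filter 0.02, R-squared filter 0.98 over
#' candidate ploidies 2-8.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of parameters.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(binSize = 500000L, span = 0.3, iterations = 3L,
              minMappability = 0.85, blacklistHi = 1.4, blacklistLo = 0.6,
              alpha = 0.01, uniformityThreshold = 0.2,
              coverageThreshold = 0.6, peakMass = 0.02, r2Min = 0.98,
              ssrTolerance = 0.25, ploidies = 2:8, penalty = 3,
              minBins = 3L, maxBlacklistOverlap = 0.5, smoothWindow = 5L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run the full per-cell workflow
#'
#' Counting (if reads rather than counts are supplied), normalization, QC,
#' ploidy scan and CNA calling at the selected (or forced) main ploidy, with
#' optional blacklist filtering — the per-cell orchestration of the whole
#' pipeline.
#'
#' @param input A [BinnedCounts-class], or a `GRanges` of reads to count.
#' @param bins Annotated bin `GRanges`.
#' @param blacklist Optional blacklist `GRanges`.
#' @param mainPloidy `"auto"` (default) to use the ploidy scan, or an integer
#'   to force a main ploidy.
#' @param config Parameter list from [pipelineConfig()].
#' @param cellId Cell label.
#' @return List with `profile`, `qc`, `ploidy` (a [PloidyScan-class] or
#'   `NULL` when forced), `mainPloidy`, `callset`, `segments` and `log` (one
#'   line per stage).
#' @export
runCell <- function(input, bins, blacklist = NULL, mainPloidy = "auto",
                    config = pipelineConfig(), cellId = NA_character_) {
  log <- character(0)
  counts <- if (methods::is(input, "GRanges")) {
    bc <- countReadsInBins(input, bins)
    log <- c(log, sprintf("counting: %d assigned, %d discarded",
                          nAssigned(bc), nDiscarded(bc)))
    bc
  } else input
  profile <- normalizeProfile(counts, bins, span = config$span,
                              iterations = config$iterations,
                              minMappability = config$minMappability,
                              cellId = cellId)
  log <- c(log, sprintf("normalization: %d/%d bins usable",
                        sum(usableBins(profile)), length(bins)))
  qc <- qualityMetrics(profile,
                       uniformityThreshold = config$uniformityThreshold,
                       coverageThreshold = config$coverageThreshold)
  log <- c(log, sprintf("qc: uniformity %.4f, coverage %.4f, dlrs %.4f%s",
                        qc$uniformity, qc$coverageFraction, qc$dlrs,
                        if (qc$uniformity < 0.9) " [WARN low uniformity]"
                        else ""))
  scan <- NULL
  if (identical(mainPloidy, "auto")) {
    scan <- ploidyScan(profile, ploidies = config$ploidies,
                       smoothWindow = config$smoothWindow,
                       minMass = config$peakMass, r2Min = config$r2Min,
                       ssrTolerance = config$ssrTolerance)
    mainPloidy <- selectedPloidy(scan)
    if (is.na(mainPloidy)) {
      warning("ploidy scan inconclusive; falling back to ploidy 2")
      mainPloidy <- 2L
    }
    log <- c(log, sprintf("ploidy: selected %d", mainPloidy))
  }
  cs <- callCNAs(profile, mainPloidy, penalty = config$penalty,
                 minBins = config$minBins, alpha = config$alpha,
                 blacklist = blacklist,
                 maxOverlap = config$maxBlacklistOverlap)
  segs <- attr(cs, "segments")
  log <- c(log, sprintf("calling: %d segments, %d calls (%.1f Mbp gained, %.1f Mbp lost)",
                        nrow(segs), length(calls(cs)), cs@mbpGained,
                        cs@mbpLost))
  list(profile = profile, qc = qc, ploidy = scan,
       mainPloidy = as.integer(mainPloidy), callset = cs, segments = segs,
       log = log)
}

#' Build a panel-of-normals blacklist
#'
#' Normalizes each control cell, computes per-bin medians across the panel
#' and derives the problematic-region blacklist, together with a per-cell QC
#' table.
#'
#' @param inputs List of [BinnedCounts-class] (or read `GRanges`) for the
#'   control cells (>= 2).
#' @param bins Annotated bin `GRanges`.
#' @param config Parameter list from [pipelineConfig()].
#' @return List with `blacklist` (`GRanges`), `panelQC` (data frame) and
#'   `profiles`.
#' @export
buildPanel <- function(inputs, bins, config = pipelineConfig()) {
  if (length(inputs) < 2) stop("need at least 2 control cells")
  profiles <- lapply(seq_along(inputs), function(i) {
    x <- inputs[[i]]
    if (methods::is(x, "GRanges")) x <- countReadsInBins(x, bins)
    normalizeProfile(x, bins, span = config$span,
                     iterations = config$iterations,
                     minMappability = config$minMappability,
                     cellId = paste0("control", i))
  })
  bl <- detectProblematicRegions(profiles, hi = config$blacklistHi,
                                 lo = config$blacklistLo)
  qc <- do.call(rbind, lapply(profiles, function(p) {
    m <- qualityMetrics(p, config$uniformityThreshold,
                        config$coverageThreshold)
    data.frame(cellId = cellId(p), uniformity = m$uniformity,
               coverageFraction = m$coverageFraction, dlrs = m$dlrs)
  }))
  list(blacklist = bl, panelQC = qc, profiles = profiles)
}
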