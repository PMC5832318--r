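#' In-silico restriction digestion of a genome
#'
#' Scans each sequence for every (possibly overlapping) occurrence of a
#' restriction-site motif on the forward strand of the uppercased sequence and
#' cuts at `start + cutOffset` within each occurrence. The fragments are the
#' intervals between consecutive cuts plus the two terminal intervals, so they
#' tile each sequence exactly. The default site is the MseI recognition
#' sequence TTAA, cut between the first T and the TAA overhang (`cutOffset =
#' 1`): shifting the cut inside the site moves fragment ends by at most 3 bp,
#' immaterial at bin scale, but the convention is fixed for reproducibility.
#'
#' Ligation-mediated whole-genome amplification of restriction fragments makes
#' the fragment set a deterministic function of the genome, which is what lets
#' per-bin representation be modelled in silico.
#'
#' @param sequences A named [Biostrings::DNAStringSet] (or named character
#'   vector) of reference sequences.
#' @param site Restriction-site motif over A/C/G/T (default `"TTAA"`).
#' @param cutOffset Cut position within the site, `0 <= cutOffset <=
#'   nchar(site)` (default 1, the MseI convention T^TAA).
#' @return A `GRanges` of fragments with metadata column `fragLength`;
#'   `seqlengths` are set from the input sequences. Zero-length sequences
#'   yield no fragments.
#' @examples
#' frags <- digestGenome(Biostrings::DNAStringSet(c(chrA = "AATTAACCTTAAGG")))
#' width(frags) # 3 6 5
#' @export
digestGenome <- function(sequences, site = "TTAA", cutOffset = 1L) {
  if (is.character(sequences)) sequences <- DNAStringSet(sequences)
  if (is.null(names(sequences)) || anyNA(names(sequences)))
    stop("sequences must be named")
  if (!nzchar(site) || grepl("[^ACGTacgt]", site))
    stop("site must be a non-empty motif over A/C/G/T")
  site <- toupper(site)
  cutOffset <- as.integer(cutOffset)
  if (cutOffset < 0L || cutOffset > nchar(site))
    stop("cutOffset must lie within the site")

  lens <- setNames(Biostrings::width(sequences), names(sequences))
  out <- lapply(names(sequences), function(nm) {
    L <- lens[[nm]]
    if (L == 0L) return(NULL)
    # DNAString storage is case-normalized, so matching is case-insensitive
    hits <- if (L >= nchar(site))
      start(matchPattern(site, sequences[[nm]], fixed = TRUE))
    else integer(0)
    # 0-based cut positions strictly inside (0, L); cuts at the boundary
    # would create empty terminal fragments
    cuts <- sort(unique(hits - 1L + cutOffset))
    cuts <- cuts[cuts > 0L & cuts < L]
    starts0 <- c(0L, cuts)
    ends0 <- c(cuts, L)
    data.frame(chrom = nm, start0 = starts0, end0 = ends0)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    gr <- GRanges(seqlengths = lens)
    mcols(gr)$fragLength <- integer(0)
    return(gr)
  }
  gr <- GRanges(out$chrom, IRanges(out$start0 + 1L, out$end0),
                seqlengths = lens)
  mcols(gr)$fragLength <- width(gr)
  gr
}

#' Divide a genome into fixed-size, non-overlapping bins
#'
#' Each chromosome is tiled with `floor(length / binSize)` complete bins;
#' a trailing partial bin is dropped so every retained bin has exactly the
#' configured size (no per-bin length corrections are then needed
#' downstream). The workflow's default resolution is 500 kb.
#'
#' @param chromLengths Named numeric vector of chromosome lengths (bp), or a
#'   `DNAStringSet` whose widths are used.
#' @param binSize Bin size in bp (> 0); default 500000.
#' @return A sorted `GRanges` of bins with `seqlengths` set.
#' @examples
#' makeBins(c(chr1 = 1050), binSize = 500) # 2 bins
#' @export
makeBins <- function(chromLengths, binSize = 500000L) {
  if (methods::is(chromLengths, "DNAStringSet"))
    chromLengths <- setNames(Biostrings::width(chromLengths),
                             names(chromLengths))
  if (is.null(names(chromLengths))) stop("chromLengths must be named")
  binSize <- as.integer(binSize)
  if (binSize <= 0L) stop("binSize must be positive")
  nbin <- floor(chromLengths / binSize)
  if (any(nbin == 0L))
    warning("chromosome(s) shorter than one bin dropped: ",
            paste(names(chromLengths)[nbin == 0], collapse = ", "))
  rows <- lapply(names(chromLengths), function(nm) {
    k <- nbin[[nm]]
    if (k == 0L) return(NULL)
    s <- (seq_len(k) - 1L) * binSize
    data.frame(chrom = nm, start0 = s, end0 = s + binSize)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(GRanges(seqlengths = chromLengths))
  GRanges(rows$chrom, IRanges(rows$start0 + 1L, rows$end0),
          seqlengths = chromLengths)
}

#' Annotate bins with GC content, N fraction and mappability
#'
#' GC is computed as (G+C)/(A+C+G+T) over the bin (undefined when the
#' denominator is 0, i.e. an all-N bin); `nFraction` is the fraction of
#' undetermined bases. Mappability is the length-weighted mean of an
#' interval-value track over the bin, with positions missing from the track
#' treated as 0 — the same averaging a bigWig summary over bins performs.
#' Bins with `nFraction` above `maxNFraction` are masked from all downstream
#' statistics.
#'
#' @param bins `GRanges` from [makeBins()].
#' @param sequences Named `DNAStringSet` covering all bin coordinates.
#' @param mappability Optional track: a `GRanges` with a numeric `score`
#'   column, or a data frame with columns `chrom`, `start` (0-based), `end`,
#'   `value`. `NULL` leaves mappability as `NA`.
#' @param maxNFraction Masking threshold on the fraction of N bases
#'   (default 0.5).
#' @return `bins` with metadata columns `gc`, `nFraction`, `mappability`,
#'   `masked` added.
#' @export
annotateBins <- function(bins, sequences, mappability = NULL,
                         maxNFraction = 0.5) {
  .checkBins(bins)
  if (is.character(sequences)) sequences <- DNAStringSet(sequences)
  slen <- setNames(Biostrings::width(sequences), names(sequences))
  ch <- as.character(seqnames(bins))
  if (!all(ch %in% names(slen)))
    stop("sequences missing for chromosome(s): ",
         paste(setdiff(unique(ch), names(slen)), collapse = ", "))
  if (any(end(bins) > slen[ch]))
    stop("bin coordinates extend beyond sequence end")

  gc <- nfrac <- numeric(length(bins))
  for (nm in unique(ch)) {
    idx <- which(ch == nm)
    v <- Views(sequences[[nm]], start = start(bins)[idx], end = end(bins)[idx])
    lf <- letterFrequency(v, c("A", "C", "G", "T", "N"))
    denom <- rowSums(lf[, c("A", "C", "G", "T"), drop = FALSE])
    gc[idx] <- ifelse(denom > 0, (lf[, "C"] + lf[, "G"]) / denom, NA_real_)
    nfrac[idx] <- lf[, "N"] / width(bins)[idx]
  }
  mapp <- rep(NA_real_, length(bins))
  if (!is.null(mappability)) {
    track <- if (methods::is(mappability, "GRanges")) {
      GRanges(seqnames(mappability), ranges(mappability),
              value = mcols(mappability)$score)
    } else {
      GRanges(mappability$chrom,
              IRanges(mappability$start + 1L, mappability$end),
              value = mappability$value)
    }
    ov <- findOverlaps(bins, track)
    w <- width(pintersect(bins[queryHits(ov)], track[subjectHits(ov)]))
    contrib <- w * track$value[subjectHits(ov)]
    mapp <- as.numeric(tapply(contrib, factor(queryHits(ov),
                                              levels = seq_along(bins)), sum))
    mapp[is.na(mapp)] <- 0
    mapp <- mapp / width(bins) # missing positions count as 0
  }
  mcols(bins)$gc <- gc
  mcols(bins)$nFraction <- nfrac
  mcols(bins)$mappability <- mapp
  mcols(bins)$masked <- nfrac > maxNFraction
  bins
}

#' Fragment-length weight functions
#'
#' The amplified library is size-selected, so a fragment's chance of being
#' represented depends on its length. The weight function maps fragment
#' length to a non-negative representation weight, zero outside its support.
#' `lengthWeightLognormal()` builds the default parametric family — a
#' log-normal density, matching the unimodal right-skewed fragment-length
#' distribution such libraries show — and `lengthWeightTable()` builds a
#' tabulated map (linear interpolation between tabulated lengths).
#'
#' @param meanlog,sdlog Log-normal parameters (defaults `log(400)`, 0.6).
#' @param support Length support in bp; weight is 0 outside (default
#'   `c(50, 3000)`, the selectable size range).
#' @return A function mapping numeric lengths to weights.
#' @examples
#' lw <- lengthWeightLognormal()
#' lw(c(10, 400, 5000)) # zero outside the support
#' @export
lengthWeightLognormal <- function(meanlog = log(400), sdlog = 0.6,
                                  support = c(50, 3000)) {
  force(meanlog); force(sdlog); force(support)
  function(len) {
    w <- dlnorm(len, meanlog = meanlog, sdlog = sdlog)
    w[len < support[1] | len > support[2]] <- 0
    w
  }
}

#' @rdname lengthWeightLognormal
#' @param lengths,weights Tabulated lengths (bp) and their weights.
#' @export
lengthWeightTable <- function(lengths, weights) {
  if (length(lengths) != length(weights) || any(weights < 0))
    stop("lengths and weights must align and weights be non-negative")
  ord <- order(lengths)
  lengths <- lengths[ord]; weights <- weights[ord]
  function(len) {
    w <- approx(lengths, weights, xout = len, rule = 1)$y
    w[is.na(w)] <- 0
    w
  }
}

#' Size-selection-weighted fragment counts per bin
#'
#' Each restriction fragment is assigned to the single bin containing its
#' midpoint (fragments whose midpoint falls outside all retained bins, e.g.
#' in a dropped partial-bin tail, are ignored), and the bin accumulates the
#' fragment's length weight. The resulting per-bin weighted fragment count is
#' the genome-representation expectation against which read counts are
#' compared.
#'
#' @param fragments Fragment `GRanges` from [digestGenome()].
#' @param bins Bin `GRanges`.
#' @param lw Length-weight function (default [lengthWeightLognormal()]).
#' @return `bins` with a `weightedFragments` metadata column added.
#' @export
weightedFragmentCount <- function(fragments, bins,
                                  lw = lengthWeightLognormal()) {
  .checkBins(bins)
  if (length(fragments) == 0L) {
    mcols(bins)$weightedFragments <- 0
    return(bins)
  }
  mid0 <- start(fragments) - 1L + floor(width(fragments) / 2) # 0-based midpoint
  mids <- GRanges(as.character(seqnames(fragments)),
                  IRanges(mid0 + 1L, mid0 + 1L))
  ov <- suppressWarnings(findOverlaps(mids, bins))
  w <- lw(width(fragments))[queryHits(ov)]
  tot <- as.numeric(tapply(w, factor(subjectHits(ov),
                                     levels = seq_along(bins)), sum))
  tot[is.na(tot)] <- 0
  mcols(bins)$weightedFragments <- tot
  bins
}
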