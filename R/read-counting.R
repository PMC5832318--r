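#' Read aligned reads from BED or BAM
#'
#' `readReadsBed()` reads the lightweight BED3+1 dialect (chrom, start
#' 0-based, end, mapq) so the whole pipeline can run without alignment-format
#' dependencies; `readReadsBam()` reads primary alignments from a BAM file via
#' Rsamtools (secondary and supplementary alignments are excluded).
#'
#' @param path Path to the file.
#' @return A `GRanges` of read intervals with a `mapq` metadata column.
#' @export
readReadsBed <- function(path) {
  d <- read.delim(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop("BED reads need at least 3 columns")
  mapq <- if (ncol(d) >= 4) as.integer(d[[4]]) else 0L
  GRanges(d[[1]], IRanges(d[[2]] + 1L, d[[3]]), mapq = mapq)
}

#' @rdname readReadsBed
#' @export
readReadsBam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required for BAM input; use BED reads otherwise")
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flag,
                               what = c("rname", "pos", "qwidth", "mapq"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$pos)
  GRanges(as.character(b$rname[keep]),
          IRanges(b$pos[keep], width = b$qwidth[keep]),
          mapq = ifelse(is.na(b$mapq[keep]), 0L, b$mapq[keep]))
}

#' Count reads in genomic bins by longest overlap
#'
#' Each retained read increments exactly one bin: the bin it overlaps the
#' most, with ties broken deterministically towards the leftmost bin. Reads
#' with mapping quality below `minMapq`, on chromosomes absent from the bin
#' table, or falling entirely outside all bins (e.g. in a dropped partial-bin
#' tail) are discarded and tallied.
#'
#' @param reads `GRanges` of read intervals with an optional `mapq` column
#'   (absent means 0).
#' @param bins Sorted, non-overlapping bin `GRanges`.
#' @param minMapq Minimum mapping quality (default 0, keeping everything the
#'   aligner reported).
#' @return A [BinnedCounts-class] with one count per bin.
#' @export
countReadsInBins <- function(reads, bins, minMapq = 0L) {
  .checkBins(bins)
  nIn <- length(reads)
  mapq <- mcols(reads)$mapq
  if (is.null(mapq)) mapq <- rep(0L, nIn)
  keep <- mapq >= minMapq &
    as.character(seqnames(reads)) %in% seqlevels(bins)
  reads <- reads[keep]
  # strip read seqinfo so unknown-chromosome bookkeeping cannot conflict
  reads <- GRanges(as.character(seqnames(reads)), ranges(reads))
  ov <- suppressWarnings(findOverlaps(reads, bins))
  # reads may extend past the last bin or the chromosome end; the overlap
  # width is unaffected
  olap <- suppressWarnings(
    width(pintersect(reads[queryHits(ov)], bins[subjectHits(ov)])))
  # longest overlap, ties to the leftmost bin: order hits so the best hit per
  # read comes first (bins are sorted, so smaller subjectHits = leftmost)
  o <- base::order(queryHits(ov), -olap, subjectHits(ov))
  first <- !duplicated(queryHits(ov)[o])
  hitBin <- subjectHits(ov)[o][first]
  cnt <- tabulate(hitBin, nbins = length(bins))
  assigned <- length(hitBin)
  methods::new("BinnedCounts", counts = as.integer(cnt),
               nAssigned = as.integer(assigned),
               nDiscarded = as.integer(nIn - assigned))
}

#' Count reads on restriction fragments with ambiguity filtering
#'
#' A read overlapping exactly one fragment increments that fragment; a read
#' overlapping two or more fragments is discarded (filtering out reads with
#' more than one fragment match), as is a read overlapping none.
#'
#' @param reads `GRanges` of read intervals.
#' @param fragments Fragment `GRanges` from [digestGenome()].
#' @return A [BinnedCounts-class] with one count per fragment.
#' @export
countReadsOnFragments <- function(reads, fragments) {
  nIn <- length(reads)
  reads <- GRanges(as.character(seqnames(reads)), ranges(reads))
  nhit <- suppressWarnings(countOverlaps(reads, fragments))
  unique1 <- nhit == 1L
  ov <- suppressWarnings(findOverlaps(reads[unique1], fragments))
  cnt <- tabulate(subjectHits(ov), nbins = length(fragments))
  methods::new("BinnedCounts", counts = as.integer(cnt),
               nAssigned = as.integer(sum(unique1)),
               nDiscarded = as.integer(nIn - sum(unique1)))
}
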