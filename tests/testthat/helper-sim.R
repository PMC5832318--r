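# Shared fixture builders. Everything is generated in code under fixed seeds.

library(GenomicRanges)
library(Biostrings)

# peak vectors of the printed ploidy worked example (main ploidy 2 and 3)
peaksPloidy2 <- c(1.0, 1.97, 2.94, 3.82, 4.67)
peaksPloidy3 <- c(1.58, 2.98, 4.49, 5.79, 6.52, 7.12)

# small annotated four-chromosome genome at bin level
smallGenome <- function(chromLength = 80e6, nChroms = 4, binSize = 500000,
                        seed = 1) {
  sl <- setNames(rep(chromLength, nChroms), paste0("chr", seq_len(nChroms)))
  simulateBinAnnotations(sl, binSize = binSize, seed = seed)
}

# an aberrant single cell: eight CNA regions at copy-number levels around the
# main ploidy, placed at random non-overlapping positions per chromosome
aberrantProfile <- function(p, seed, totalReads = 800000,
                            chromLength = 80e6, binSize = 500000) {
  b <- smallGenome(chromLength, 4, binSize, seed = seed)
  set.seed(seed + 1)
  lv <- unique(pmax(1L, c(p - 1L, p + 1L, p + 2L, p - 2L)))
  st <- unlist(lapply(1:4, function(i) {
    s1 <- sample(seq(2e6, 20e6, 5e5), 1)
    c(s1, s1 + 16e6 + sample(seq(4e6, 25e6, 5e5), 1))
  }))
  regs <- GRanges(rep(paste0("chr", 1:4), each = 2),
                  IRanges(start = st + 1, width = rep(c(15e6, 18e6), 4)),
                  copyNumber = sample(rep(lv, length.out = 8)))
  cn <- binCopyNumbers(b, regs, basePloidy = p)
  cc <- simulateCellCounts(b, cn, totalReads = totalReads, seed = seed + 2)
  list(bins = b, regions = regs, cn = cn, counts = cc,
       profile = normalizeProfile(cc, b))
}

# brute-force longest-overlap read assignment (oracle for countReadsInBins)
bruteCountBins <- function(reads, bins, minMapq = 0) {
  cnt <- integer(length(bins))
  discarded <- 0L
  bch <- as.character(seqnames(bins))
  for (i in seq_along(reads)) {
    mq <- reads$mapq[i]
    if (is.null(mq)) mq <- 0L
    if (mq < minMapq) { discarded <- discarded + 1L; next }
    ov <- pmin(end(bins), end(reads)[i]) - pmax(start(bins), start(reads)[i]) + 1L
    ov[bch != as.character(seqnames(reads))[i]] <- 0L
    if (max(ov) <= 0) { discarded <- discarded + 1L; next }
    cnt[which.max(ov)] <- cnt[which.max(ov)] + 1L # which.max = leftmost tie
  }
  list(counts = cnt, discarded = discarded)
}

# brute-force overlap-aware motif occurrence count (oracle for digestGenome)
bruteMotifCount <- function(seqchar, motif) {
  n <- nchar(seqchar); m <- nchar(motif)
  if (n < m) return(0L)
  hits <- 0L
  for (i in seq_len(n - m + 1L))
    if (substr(seqchar, i, i + m - 1L) == motif) hits <- hits + 1L
  hits
}
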