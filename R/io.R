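#' Read and write profile, bin, fragment and blacklist tables
#'
#' Plain-text interchange for the pipeline's objects. Tables are TSV with a
#' header and 0-based half-open coordinates (the BED convention); profile
#' round-trips preserve raw counts, ratios and usability to full stored
#' precision.
#'
#' @param profile A [CNProfile-class].
#' @param path File path.
#' @name profile-io
#' @return `readProfileTsv()` returns a [CNProfile-class]; the writers return
#'   `path` invisibly.
#' @export
writeProfileTsv <- function(profile, path) {
  b <- bins(profile)
  d <- data.frame(chrom = as.character(seqnames(b)),
                  start = start(b) - 1L, end = end(b),
                  gc = mcols(b)$gc,
                  mappability = mcols(b)$mappability,
                  raw = rawCounts(profile),
                  ratio = ratios(profile),
                  usable = usableBins(profile))
  sl <- seqlengths(b)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seqlengths: ",
                    paste(names(sl), sl, sep = "=", collapse = ";"),
                    "; cellId=", cellId(profile)), con)
  write.table(format(d, digits = 15, scientific = FALSE, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname profile-io
#' @export
readProfileTsv <- function(path) {
  hdr <- readLines(path, n = 1)
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  sl <- NULL
  cellId <- NA_character_
  if (startsWith(hdr, "# seqlengths: ")) {
    body <- sub("^# seqlengths: ", "", hdr)
    parts <- strsplit(body, "; cellId=", fixed = TRUE)[[1]]
    kv <- strsplit(strsplit(parts[1], ";")[[1]], "=")
    sl <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                   vapply(kv, `[`, "", 1))
    if (length(parts) > 1 && parts[2] != "NA") cellId <- parts[2]
  }
  b <- GRanges(d$chrom, IRanges(d$start + 1L, d$end), seqlengths = sl)
  mcols(b)$gc <- suppressWarnings(as.numeric(d$gc))
  mcols(b)$mappability <- suppressWarnings(as.numeric(d$mappability))
  usable <- as.logical(d$usable)
  ratio <- suppressWarnings(as.numeric(d$ratio))
  ratio[!usable] <- NA_real_
  methods::new("CNProfile", bins = b,
               raw = suppressWarnings(as.integer(d$raw)),
               ratio = ratio, usable = usable, cellId = cellId)
}

#' @rdname profile-io
#' @param gr A `GRanges` (blacklist regions or fragments).
#' @export
writeBlacklistBed <- function(gr, path) {
  d <- data.frame(chrom = as.character(seqnames(gr)),
                  start = start(gr) - 1L, end = end(gr),
                  medianFC = round(gr$medianFC, 6),
                  direction = gr$direction)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname profile-io
#' @export
readBlacklistBed <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  gr <- GRanges(d[[1]], IRanges(d[[2]] + 1L, d[[3]]),
                medianFC = d[[4]], direction = d[[5]])
  metadata(gr)$nRegions <- length(gr)
  metadata(gr)$totalBp <- sum(width(gr))
  gr
}

#' @rdname profile-io
#' @param callset A [CNACallSet-class].
#' @export
writeCallsTsv <- function(callset, path) {
  gr <- calls(callset)
  d <- data.frame(chrom = as.character(seqnames(gr)),
                  start = start(gr) - 1L, end = end(gr),
                  class = gr$class, copyNumber = gr$copyNumber,
                  meanRatio = gr$meanRatio, pWilcoxon = gr$pWilcoxon,
                  pKS = gr$pKS,
                  blacklistedFraction = gr$blacklistedFraction)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# cellId=", callset@cellId,
                    " mainPloidy=", callset@mainPloidy), con)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname profile-io
#' @export
readBedGraph <- function(path) {
  d <- read.delim(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  GRanges(d[[1]], IRanges(d[[2]] + 1L, d[[3]]), score = as.numeric(d[[4]]))
}
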