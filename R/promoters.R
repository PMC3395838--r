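## Promoter-window extraction. External tables use 0-based half-open
## coordinates (BED convention); internally windows are kept as GRanges
## (1-based closed) and converted at the boundaries.

#' Define promoter scan windows around transcription start sites
#'
#' For every transcript, the window `[tss - flank, tss + flank)` is taken,
#' clipped at position 0 (and at the chromosome end when sizes are given),
#' the union of all coding intervals is subtracted, and the windows of each
#' gene are merged. The result is the set of non-coding promoter intervals
#' eligible for footprint scanning.
#'
#' @param tssTable data.frame with columns `chrom`, `tss` (0-based
#'   position), `gene_id`, `gene_symbol`; one row per transcript.
#' @param cdsTable data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open coding intervals), or `NULL`.
#' @param flank Bases taken on each side of the TSS (default 3000).
#' @param chromSizes Optional named vector of chromosome lengths; a TSS on
#'   a chromosome missing from it is an error.
#' @return A [GenomicRanges::GRanges] of promoter intervals with metadata
#'   columns `gene_id` and `gene_symbol` (1-based closed coordinates, as
#'   usual for GRanges).
#' @examples
#' tss <- data.frame(chrom = "chr1", tss = 10000,
#'                   gene_id = "g1", gene_symbol = "G1")
#' promoterWindows(tss, NULL)
#' @export
promoterWindows <- function(tssTable, cdsTable = NULL, flank = 3000,
                            chromSizes = NULL) {
  stopifnot2(flank > 0, "flank must be positive")
  need <- c("chrom", "tss", "gene_id", "gene_symbol")
  stopifnot2(all(need %in% names(tssTable)),
             sprintf("tssTable must have columns %s", paste(need, collapse = ", ")))
  if (!is.null(chromSizes)) {
    unknown <- setdiff(unique(tssTable$chrom), names(chromSizes))
    if (length(unknown)) {
      stop(sprintf("TSS on unknown chromosome(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
  }
  start0 <- pmax(tssTable$tss - flank, 0)
  end0 <- tssTable$tss + flank  # half-open end
  if (!is.null(chromSizes)) {
    end0 <- pmin(end0, unname(chromSizes[tssTable$chrom]))
  }
  win <- GenomicRanges::GRanges(
    tssTable$chrom,
    IRanges::IRanges(start = start0 + 1, end = end0),
    gene_id = tssTable$gene_id, gene_symbol = tssTable$gene_symbol)
  cdsU <- if (!is.null(cdsTable) && nrow(cdsTable) > 0) {
    GenomicRanges::reduce(GenomicRanges::GRanges(
      cdsTable$chrom,
      IRanges::IRanges(start = cdsTable$start + 1, end = cdsTable$end)))
  } else {
    GenomicRanges::GRanges()
  }
  genes <- unique(tssTable$gene_id)
  pieces <- lapply(genes, function(g) {
    gw <- GenomicRanges::reduce(win[win$gene_id == g])
    res <- GenomicRanges::setdiff(gw, cdsU)
    if (length(res)) {
      res$gene_id <- g
      res$gene_symbol <- tssTable$gene_symbol[match(g, tssTable$gene_id)]
    }
    res
  })
  out <- suppressWarnings(do.call(c, pieces))
  sort(out, ignore.strand = TRUE)
}

#' Read a TSS table
#'
#' Tab-separated, BED6-like: `chrom`, `tss` (0-based), `gene_id`,
#' `gene_symbol`, `strand`. A header line is optional.
#'
#' @param file Path.
#' @return data.frame with those columns.
#' @export
readTssTable <- function(file) {
  first <- readLines(file, n = 1L)
  hasHeader <- grepl("chrom", first, ignore.case = TRUE)
  df <- read.delim(file, header = hasHeader, stringsAsFactors = FALSE)
  if (!hasHeader) {
    names(df)[1:5] <- c("chrom", "tss", "gene_id", "gene_symbol", "strand")
  }
  df
}

#' Read a coding-interval table
#'
#' BED3-like TSV: `chrom`, `start`, `end` (0-based half-open); extra
#' columns are ignored. A header line is optional.
#'
#' @param file Path.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
readCdsTable <- function(file) {
  first <- readLines(file, n = 1L)
  hasHeader <- grepl("chrom|start", first, ignore.case = TRUE)
  df <- read.delim(file, header = hasHeader, stringsAsFactors = FALSE)
  if (!hasHeader) names(df)[1:3] <- c("chrom", "start", "end")
  df[c("chrom", "start", "end")]
}
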