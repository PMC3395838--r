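## Minimal MAF (Multiple Alignment Format) block reader/writer.
##
## Each block is a list with elements:
##   rows  - data.frame(species, chrom, start, size, strand, src_size, text)
##           start is 0-based on the row's own strand (MAF semantics);
##           species is the part of the MAF src field before the first '.'
##           and chrom the remainder.
##   ncols - number of alignment columns.
## The reference species of a block is its first row.

#' Read MAF alignment blocks
#'
#' Parses `a`/`s` lines of a MAF file. Rows of unequal gapped length, rows
#' whose ungapped length disagrees with their size field, and blocks
#' without rows raise errors naming the offending block.
#'
#' @param file Path to a MAF file.
#' @return List of alignment blocks (see Details).
#' @details Each block is a list with `rows` (data.frame of `species`,
#'   `chrom`, `start`, `size`, `strand`, `src_size`, `text`) and `ncols`.
#'   Negative-strand rows keep MAF coordinate semantics (start counted on
#'   their own strand).
#' @seealso [writeMaf()], [scanConservedSites()]
#' @export
readMaf <- function(file) {
  lines <- readLines(file)
  blocks <- list()
  cur <- NULL
  nblock <- 0L
  flush <- function() {
    if (is.null(cur)) return()
    rows <- do.call(rbind, cur)
    rows <- as.data.frame(rows, stringsAsFactors = FALSE)
    if (nrow(rows) == 0L) stop(sprintf("MAF block %d has no sequence rows", nblock), call. = FALSE)
    nc <- nchar(rows$text)
    if (length(unique(nc)) != 1L) {
      stop(sprintf("MAF block %d: rows of unequal gapped length", nblock), call. = FALSE)
    }
    ung <- nchar(gsub("-", "", rows$text, fixed = TRUE))
    if (any(ung != rows$size)) {
      stop(sprintf("MAF block %d: ungapped length disagrees with size field", nblock),
           call. = FALSE)
    }
    blocks[[length(blocks) + 1L]] <<- list(rows = rows, ncols = nc[1L])
    cur <<- NULL
  }
  for (ln in lines) {
    t <- trimws(ln)
    if (!nzchar(t) || startsWith(t, "#")) { if (!nzchar(t)) flush(); next }
    if (startsWith(t, "a")) {
      flush()
      nblock <- nblock + 1L
      cur <- list()
    } else if (startsWith(t, "s ") || startsWith(t, "s\t")) {
      if (is.null(cur)) { nblock <- nblock + 1L; cur <- list() }
      tok <- strsplit(t, "\\s+")[[1L]]
      if (length(tok) < 7L) {
        stop(sprintf("MAF block %d: malformed s line '%s'", nblock, substr(t, 1, 50)),
             call. = FALSE)
      }
      src <- tok[2L]
      dot <- regexpr(".", src, fixed = TRUE)
      species <- if (dot > 0) substr(src, 1, dot - 1) else src
      chrom <- if (dot > 0) substr(src, dot + 1, nchar(src)) else ""
      cur[[length(cur) + 1L]] <- data.frame(
        species = species, chrom = chrom,
        start = as.numeric(tok[3L]), size = as.numeric(tok[4L]),
        strand = tok[5L], src_size = as.numeric(tok[6L]),
        text = tok[7L], stringsAsFactors = FALSE)
    }
    ## i/e/q lines are ignored
  }
  flush()
  blocks
}

#' Write MAF alignment blocks
#'
#' Inverse of [readMaf()]; coordinates and sequences round-trip exactly.
#'
#' @param blocks List of alignment blocks.
#' @param file Output path.
#' @return Invisibly, the path written.
#' @export
writeMaf <- function(blocks, file) {
  out <- c("##maf version=1")
  for (b in blocks) {
    out <- c(out, "a score=0")
    r <- b$rows
    src <- ifelse(nzchar(r$chrom), paste(r$species, r$chrom, sep = "."), r$species)
    out <- c(out, sprintf("s %s %d %d %s %d %s",
                          src, as.integer(r$start), as.integer(r$size),
                          r$strand, as.integer(r$src_size), r$text), "")
  }
  writeLines(out, file)
  invisible(file)
}

blockSpecies <- function(block) block$rows$species
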