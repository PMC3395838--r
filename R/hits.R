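## Hit export (extended BED dialect), target-set construction and per-gene
## regulator statistics.

#' Write hits in the extended BED dialect
#'
#' Eight tab-separated fields per hit: `chrom`, `chromStart`, `chromEnd`,
#' `name` (matrix id and factor names, pipe-separated), `score`, `strand`,
#' `gene id`, `geneSymbol`. Coordinates are 0-based half-open. Scores are
#' printed with enough digits to round-trip exactly.
#'
#' @param hits Hit data.frame from [scanConservedSites()].
#' @param file Output path.
#' @return Invisibly, the path written.
#' @seealso [readHitsBed()]
#' @export
writeHitsBed <- function(hits, file) {
  name <- ifelse(nzchar(hits$names),
                 paste(hits$pwm_id, hits$names, sep = "|"),
                 hits$pwm_id)
  lines <- sprintf("%s\t%d\t%d\t%s\t%.17g\t%s\t%s\t%s",
                   hits$chrom, as.integer(hits$start), as.integer(hits$end),
                   name, hits$score, hits$strand, hits$gene_id,
                   hits$gene_symbol)
  writeLines(lines, file)
  invisible(file)
}

#' Read hits from the extended BED dialect
#'
#' Inverse of [writeHitsBed()]. The pipe-separated `name` field is split
#' back into `pwm_id` (first token) and `names` (remainder).
#'
#' @param file Path.
#' @return Hit data.frame with columns `chrom`, `start`, `end`, `pwm_id`,
#'   `names`, `score`, `strand`, `gene_id`, `gene_symbol`.
#' @export
readHitsBed <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    df <- emptyHits(character(0))
    return(df[setdiff(names(df), character(0))])
  }
  tok <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(tok) != 8L)
  if (length(bad)) {
    stop(sprintf("line %d does not have 8 tab-separated fields", bad[1L]),
         call. = FALSE)
  }
  m <- do.call(rbind, tok)
  nameParts <- strsplit(m[, 4L], "|", fixed = TRUE)
  data.frame(
    chrom = m[, 1L],
    start = as.numeric(m[, 2L]), end = as.numeric(m[, 3L]),
    pwm_id = vapply(nameParts, `[`, character(1), 1L),
    names = vapply(nameParts, function(p) paste(p[-1L], collapse = "|"),
                   character(1)),
    score = as.numeric(m[, 5L]),
    strand = m[, 6L], gene_id = m[, 7L], gene_symbol = m[, 8L],
    stringsAsFactors = FALSE)
}

#' Build target sets from hits
#'
#' Collapses hit multiplicity: each matrix maps to its set of distinct
#' target genes and each gene to its set of distinct matrices
#' ("non-redundant" regulators).
#'
#' @param hits Hit data.frame.
#' @return List with `byPwm` (matrix id -> character vector of gene ids)
#'   and `byGene` (gene id -> character vector of matrix ids).
#' @export
targetSets <- function(hits) {
  if (nrow(hits) == 0L) return(list(byPwm = list(), byGene = list()))
  byPwm <- lapply(split(hits$gene_id, hits$pwm_id), function(g) sort(unique(g)))
  byGene <- lapply(split(hits$pwm_id, hits$gene_id), function(m) sort(unique(m)))
  list(byPwm = byPwm, byGene = byGene)
}

#' Per-gene regulator-count summary and top fraction
#'
#' Counts the distinct matrices hitting each gene, summarizes the
#' distribution, and returns the genes in the requested top fraction of
#' regulator counts. The cut keeps `ceiling(topFraction * n)` genes; ties
#' at the boundary count are all included.
#'
#' @param byGene Named list gene -> matrix ids (from [targetSets()]).
#' @param topFraction Fraction in (0, 1] (default 0.01, the "top 1%" of
#'   most-regulated genes).
#' @return List with `counts` (named integer vector), `summary`
#'   (median/mean/min/max) and `top_genes`.
#' @export
regulatorCounts <- function(byGene, topFraction = 0.01) {
  stopifnot2(topFraction > 0 && topFraction <= 1,
             "topFraction must lie in (0, 1]")
  counts <- vapply(byGene, length, integer(1))
  if (length(counts) == 0L) {
    return(list(counts = integer(0), summary = list(), top_genes = character(0)))
  }
  counts <- sort(counts, decreasing = TRUE)
  k <- ceiling(topFraction * length(counts))
  boundary <- counts[k]
  list(
    counts = counts,
    summary = list(median = median(counts), mean = mean(counts),
                   min = min(counts), max = max(counts)),
    top_genes = names(counts)[counts >= boundary]
  )
}

#' Per-matrix hit counts joined with matrix descriptors
#'
#' One row per matrix: number of distinct target genes together with GC and
#' information content, the inputs of the hits-versus-GC diagnostic plot.
#'
#' @param byPwm Named list matrix id -> gene ids (from [targetSets()]).
#' @param statsTable data.frame with columns `pwm_id`,
#'   `information_content`, `gc_content` (one row per matrix; see
#'   [pwmStats()]).
#' @return data.frame `pwm_id`, `n_hits`, `gc_content`,
#'   `information_content`.
#' @export
hitCountStats <- function(byPwm, statsTable = NULL) {
  df <- data.frame(pwm_id = names(byPwm),
                   n_hits = vapply(byPwm, length, integer(1)),
                   row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(statsTable) && nrow(df) > 0L) {
    i <- match(df$pwm_id, statsTable$pwm_id)
    df$gc_content <- statsTable$gc_content[i]
    df$information_content <- statsTable$information_content[i]
  } else {
    df$gc_content <- numeric(nrow(df))
    df$information_content <- numeric(nrow(df))
  }
  df
}
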