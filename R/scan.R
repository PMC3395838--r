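## Phylogenetic-footprint scanning of MAF blocks.
##
## A window of W consecutive reference bases is a putative site when every
## required species scores at or above the calibrated threshold at the SAME
## alignment columns. Scores are computed on the calibration's integer bin
## grid, so "score >= t" is an exact integer comparison. A gap or
## unscoreable character (N, ambiguity code) in any required species
## disqualifies the window. Both strands are scanned independently, the
## reverse strand with the reverse-complemented matrix at the same
## reference coordinates.

hitColumns <- function(requiredSpecies) {
  c("chrom", "start", "end", "pwm_id", "names", "score", "strand",
    "gene_id", "gene_symbol", paste0("score_", requiredSpecies))
}

emptyHits <- function(requiredSpecies) {
  cols <- hitColumns(requiredSpecies)
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  num <- c("start", "end", "score", paste0("score_", requiredSpecies))
  for (n in num) df[[n]] <- numeric(0)
  df
}

#' Scan alignment blocks for conserved PWM sites
#'
#' For each window of W consecutive reference-species bases lying fully
#' inside a promoter region, and for each strand, the characters of every
#' required species at the same alignment columns are scored; the window is
#' emitted as a hit iff all required species reach the calibrated
#' threshold. Hit coordinates are 0-based half-open reference coordinates;
#' a window inside the promoter windows of several genes is emitted once
#' per gene. Blocks missing a required species are skipped with a message.
#'
#' @param blocks List of alignment blocks from [readMaf()] (or a single
#'   block).
#' @param lom A [LogOddsMatrix-class].
#' @param threshold The matching [CalibratedThreshold-class]; its bin grid
#'   is reused for scoring.
#' @param requiredSpecies Character vector of species that must all pass;
#'   must include the reference (first-row) species of the blocks.
#' @param regions Promoter [GenomicRanges::GRanges] from
#'   [promoterWindows()], with `gene_id`/`gene_symbol` metadata.
#' @return data.frame of hits: `chrom`, `start`, `end`, `pwm_id`, `names`,
#'   `score` (reference-species bits), `strand`, `gene_id`, `gene_symbol`,
#'   plus one `score_<species>` column per required species.
#' @seealso [footprintScan()] for scanning a whole matrix collection,
#'   [writeHitsBed()]
#' @export
scanConservedSites <- function(blocks, lom, threshold, requiredSpecies,
                               regions) {
  if (!is.null(blocks$rows)) blocks <- list(blocks)
  out <- lapply(blocks, scanBlock, lom = lom, threshold = threshold,
                requiredSpecies = requiredSpecies, regions = regions)
  out <- do.call(rbind, c(out, list(emptyHits(requiredSpecies))))
  rownames(out) <- NULL
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

scanBlock <- function(block, lom, threshold, requiredSpecies, regions) {
  rows <- block$rows
  refSp <- rows$species[1L]
  stopifnot2(refSp %in% requiredSpecies,
             "the reference (first-row) species must be among requiredSpecies")
  if (!all(requiredSpecies %in% rows$species)) {
    message(sprintf("block on %s:%d missing species %s; skipped",
                    rows$chrom[1L], rows$start[1L],
                    paste(setdiff(requiredSpecies, rows$species), collapse = ",")))
    return(emptyHits(requiredSpecies))
  }
  if (rows$strand[1L] != "+") {
    message("reference row on '-' strand; block skipped")
    return(emptyHits(requiredSpecies))
  }
  if (!threshold@attainable) return(emptyHits(requiredSpecies))
  W <- pwmWidth(lom)
  bin <- threshold@binWidth
  kthr <- as.integer(round(threshold@threshold / bin))
  refChars <- strsplit(rows$text[1L], "", fixed = TRUE)[[1L]]
  refcols <- which(refChars != "-")
  nref <- length(refcols)
  if (nref < W) return(emptyHits(requiredSpecies))
  nsp <- length(requiredSpecies)
  codes <- matrix(NA_integer_, nsp, nref)
  for (i in seq_len(nsp)) {
    ch <- strsplit(rows$text[match(requiredSpecies[i], rows$species)], "",
                   fixed = TRUE)[[1L]]
    codes[i, ] <- nucCodes(ch[refcols])
  }
  nwin <- nref - W + 1L
  kF <- snapWeightsToGrid(lomWeights(lom), bin)
  kR <- snapWeightsToGrid(lomWeights(reverseComplement(lom)), bin)
  SF <- matrix(0L, nsp, nwin)
  SR <- matrix(0L, nsp, nwin)
  for (w in seq_len(W)) {
    cw <- codes[, w:(w + nwin - 1L), drop = FALSE]
    SF <- SF + matrix(kF[cbind(as.vector(cw), w)], nsp, nwin)
    SR <- SR + matrix(kR[cbind(as.vector(cw), w)], nsp, nwin)
  }
  refRow <- match(refSp, requiredSpecies)
  gstart <- rows$start[1L] + seq_len(nwin) - 1L  # 0-based window starts
  collect <- function(S, strand) {
    tot <- colSums(S)
    pass <- !is.na(tot) & colSums(S >= kthr) == nsp
    j <- which(pass)
    if (length(j) == 0L) return(emptyHits(requiredSpecies))
    q <- GenomicRanges::GRanges(rows$chrom[1L],
                                IRanges::IRanges(gstart[j] + 1L, gstart[j] + W))
    ov <- GenomicRanges::findOverlaps(q, regions, type = "within")
    if (length(ov) == 0L) return(emptyHits(requiredSpecies))
    qi <- S4Vectors::queryHits(ov)
    ri <- S4Vectors::subjectHits(ov)
    df <- data.frame(
      chrom = rows$chrom[1L],
      start = gstart[j][qi], end = gstart[j][qi] + W,
      pwm_id = pwmId(lom),
      names = paste(factorNames(lom), collapse = "|"),
      score = S[refRow, j][qi] * bin,
      strand = strand,
      gene_id = regions$gene_id[ri],
      gene_symbol = regions$gene_symbol[ri],
      stringsAsFactors = FALSE)
    for (i in seq_len(nsp)) {
      df[[paste0("score_", requiredSpecies[i])]] <- S[i, j][qi] * bin
    }
    df
  }
  rbind(collect(SF, "+"), collect(SR, "-"))
}

#' Scan a matrix collection over alignment blocks
#'
#' Convenience driver over [scanConservedSites()]: scans every matrix with
#' its own calibrated threshold and concatenates the hits.
#'
#' @param blocks List of alignment blocks from [readMaf()].
#' @param loms List of [LogOddsMatrix-class] objects.
#' @param thresholds Named list of [CalibratedThreshold-class], keyed by
#'   matrix id (as produced by [calibrateThresholds()]).
#' @inheritParams scanConservedSites
#' @return Combined hit data.frame (see [scanConservedSites()]).
#' @export
footprintScan <- function(blocks, loms, thresholds, requiredSpecies, regions) {
  out <- lapply(loms, function(l) {
    thr <- thresholds[[pwmId(l)]]
    stopifnot2(!is.null(thr), sprintf("no calibrated threshold for matrix '%s'", pwmId(l)))
    scanConservedSites(blocks, l, thr, requiredSpecies, regions)
  })
  out <- do.call(rbind, c(out, list(emptyHits(requiredSpecies))))
  rownames(out) <- NULL
  out
}
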