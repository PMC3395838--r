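## Shared builders for small deterministic test objects.

## A PWM built directly from a probability matrix (columns = positions).
probPwm <- function(probs, id = "toy") {
  newPwm(id, probs)
}

flatPwm <- function(width, id = "flat") {
  newPwm(id, matrix(0.25, 4, width))
}

## Deterministic (zero-pseudocount) PWM spelling out a consensus string.
consensusPwm <- function(consensus, id = "cons") {
  chars <- strsplit(consensus, "")[[1]]
  probs <- vapply(chars, function(ch) {
    p <- numeric(4)
    p[match(ch, c("A", "C", "G", "T"))] <- 1
    p
  }, numeric(4))
  newPwm(id, probs)
}

fourSpecies <- c("hg", "mm", "rn", "cf")

## Promoter region covering a whole block interval [start0, start0 + len).
regionCovering <- function(chrom, start0, len, gene = "g1", symbol = "G1") {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1, start0 + len))
  gr$gene_id <- gene
  gr$gene_symbol <- symbol
  gr
}

## Replace reference-offset window [pos, pos+width) of one species' row
## with the given characters (no gaps in any row assumed).
editBlockWindow <- function(block, species, pos, replacement) {
  i <- match(species, block$rows$species)
  txt <- strsplit(block$rows$text[i], "")[[1]]
  idx <- (pos + 1):(pos + nchar(replacement))
  txt[idx] <- strsplit(replacement, "")[[1]]
  block$rows$text[i] <- paste(txt, collapse = "")
  block$rows$size[i] <- nchar(gsub("-", "", block$rows$text[i]))
  block
}

bcSets <- function(bcs) lapply(bcs, function(b) b[c("rows", "cols")])
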