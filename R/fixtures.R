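## Deterministic synthetic-data generators. Every generator is a pure
## function of its arguments and seed (byte-identical reruns) and restores
## the caller's RNG state. Species rows of generated alignments are drawn
## independently: no phylogenetic substitution model is attempted, which
## makes planted-signal truth tables exact.

#' Random PWM from a symmetric Dirichlet
#'
#' Columns are independent draws from a symmetric Dirichlet with the given
#' concentration: small concentrations give near-deterministic,
#' high-information columns (IC -> 2 bits/column), large ones flat columns
#' (IC -> 0).
#'
#' @param width Motif width (>= 1).
#' @param concentration Dirichlet concentration parameter (> 0).
#' @param seed Integer seed.
#' @param id Matrix identifier.
#' @return A [PositionWeightMatrix-class].
#' @export
randomPwm <- function(width, concentration = 0.3, seed = 1,
                      id = sprintf("SYN%04d", seed)) {
  stopifnot2(isCount(width) && width >= 1, "width must be a positive integer")
  stopifnot2(concentration > 0, "concentration must be positive")
  probs <- withSeed(seed, {
    ## Dirichlet via log-gamma draws: log G(a) = log G(a+1) + log(U)/a,
    ## which stays finite for tiny concentrations where rgamma underflows.
    lg <- matrix(log(rgamma(4L * width, shape = concentration + 1)) +
                   log(runif(4L * width)) / concentration, nrow = 4L)
    g <- exp(sweep(lg, 2, apply(lg, 2, max), "-"))
    g <- g + 1e-12
    sweep(g, 2, colSums(g), "/")
  })
  newPwm(id, probs, factorNames = paste0("synth_", id), dialect = "generic")
}

pwmConsensus <- function(pwm) {
  paste(NUC[apply(pwmProbs(pwm), 2, which.max)], collapse = "")
}

randomSeq <- function(n) sample(NUC, n, replace = TRUE)

#' Multi-species alignment with planted conserved motif sites
#'
#' Background columns are drawn independently per species (uniform
#' A/C/G/T). At each planted position the PWM consensus is written into
#' every species, then each species' copy is independently mutated at rate
#' `perSpeciesMutation`. Gaps are introduced at rate `gapRate` in
#' non-reference species. The first species is the reference row.
#'
#' @param species Character vector of species names; default
#'   `c("hg","mm","rn","cf")`, the four-genome conservation requirement.
#' @param length Alignment length in columns.
#' @param pwm The [PositionWeightMatrix-class] whose consensus is planted.
#' @param plantPositions Integer vector of 0-based reference offsets; the
#'   planted windows must fit inside the block and not overlap.
#' @param perSpeciesMutation Per-base mutation probability of planted
#'   copies; a scalar, or one value per species (default 0).
#' @param gapRate Per-base gap probability in non-reference species
#'   (default 0).
#' @param seed Integer seed.
#' @param chrom Reference chromosome name.
#' @param refStart 0-based reference start of the block.
#' @return List with `block` (an alignment block as from [readMaf()]) and
#'   `truth` (data.frame `chrom`, `start`, `end`, `strand` of the planted
#'   sites, reference coordinates).
#' @export
plantedAlignment <- function(species = c("hg", "mm", "rn", "cf"), length,
                             pwm, plantPositions = integer(0),
                             perSpeciesMutation = 0, gapRate = 0, seed = 1,
                             chrom = "chr1", refStart = 0) {
  W <- pwmWidth(pwm)
  plantPositions <- sort(as.integer(plantPositions))
  stopifnot2(all(plantPositions >= 0 & plantPositions + W <= length),
             "planted windows must fit inside the block")
  if (length(plantPositions) > 1L &&
      any(diff(plantPositions) < W)) {
    stop("planted windows must not overlap", call. = FALSE)
  }
  cons <- strsplit(pwmConsensus(pwm), "")[[1L]]
  perSpeciesMutation <- rep_len(perSpeciesMutation, length(species))
  mats <- withSeed(seed, {
    m <- vapply(species, function(s) randomSeq(length), character(length))
    for (p in plantPositions) {
      idx <- (p + 1L):(p + W)
      for (si in seq_along(species)) {
        copy <- cons
        mut <- runif(W) < perSpeciesMutation[si]
        if (any(mut)) copy[mut] <- randomSeq(sum(mut))
        m[idx, si] <- copy
      }
    }
    if (gapRate > 0 && length(species) > 1L) {
      for (si in seq_along(species)[-1L]) {
        g <- runif(length) < gapRate
        m[g, si] <- "-"
      }
    }
    m
  })
  rows <- do.call(rbind, lapply(seq_along(species), function(si) {
    txt <- paste(mats[, si], collapse = "")
    ung <- nchar(gsub("-", "", txt, fixed = TRUE))
    data.frame(species = species[si],
               chrom = if (si == 1L) chrom else paste0("chr", si),
               start = if (si == 1L) refStart else 0,
               size = ung, strand = "+",
               src_size = refStart + length + 1000,
               text = txt, stringsAsFactors = FALSE)
  }))
  truth <- data.frame(chrom = rep(chrom, length(plantPositions)),
                      start = refStart + plantPositions,
                      end = refStart + plantPositions + W,
                      strand = rep("+", length(plantPositions)),
                      stringsAsFactors = FALSE)
  list(block = list(rows = rows, ncols = length), truth = truth)
}

#' Synthetic annotation universe with planted enrichments
#'
#' Random gene-term memberships at `backgroundRate`, plus planted term
#' memberships given explicitly. Gene ids are `g0001`... and background
#' term ids `T001`...
#'
#' @param nGenes Universe size.
#' @param nTerms Number of background terms.
#' @param planted Named list term id -> character vector of member genes
#'   (subsets of the universe); terms may be new or background ids.
#' @param backgroundRate Membership probability per (gene, term) pair.
#' @param seed Integer seed.
#' @return An [AnnotationUniverse-class].
#' @export
syntheticAnnotationUniverse <- function(nGenes, nTerms, planted = list(),
                                        backgroundRate = 0.02, seed = 1) {
  genes <- sprintf("g%04d", seq_len(nGenes))
  for (p in planted) {
    stopifnot2(all(p %in% genes), "planted gene sets must lie in the universe")
  }
  tg <- withSeed(seed, {
    out <- lapply(seq_len(nTerms), function(i) {
      genes[runif(nGenes) < backgroundRate]
    })
    names(out) <- sprintf("T%03d", seq_len(nTerms))
    out
  })
  for (nm in names(planted)) {
    tg[[nm]] <- sort(unique(c(tg[[nm]], planted[[nm]])))
  }
  tg <- tg[lengths(tg) > 0L | names(tg) %in% names(planted)]
  annotationUniverse(tg, universe = genes, source = "synthetic")
}

#' Synthetic binary matrix with planted all-ones blocks
#'
#' Independent noise ones at `noiseDensity`, then the planted blocks are
#' overwritten with ones.
#'
#' @param nrow,ncol Matrix shape.
#' @param plantedBlocks List of blocks, each a list with integer vectors
#'   `rows` and `cols`.
#' @param noiseDensity Probability of a background 1.
#' @param seed Integer seed.
#' @return List with `matrix` (0/1) and `truth` (the planted blocks,
#'   sorted).
#' @export
syntheticBinaryMatrix <- function(nrow, ncol, plantedBlocks = list(),
                                  noiseDensity = 0.1, seed = 1) {
  for (b in plantedBlocks) {
    stopifnot2(all(b$rows >= 1 & b$rows <= nrow) &&
               all(b$cols >= 1 & b$cols <= ncol),
               "planted blocks must lie inside the matrix")
  }
  m <- withSeed(seed, matrix(as.integer(runif(nrow * ncol) < noiseDensity),
                             nrow, ncol))
  for (b in plantedBlocks) m[b$rows, b$cols] <- 1L
  list(matrix = m,
       truth = lapply(plantedBlocks, function(b) {
         list(rows = sort(as.integer(b$rows)), cols = sort(as.integer(b$cols)))
       }))
}

#' Synthetic interaction flat file
#'
#' Random typed interactions over `gene1`...`geneN`. For each category the
#' expected number of records is `density * nGenes`. Signs are drawn for
#' transcription-factor categories, left empty for miRNA records (the
#' loader defaults them to repression) and omitted for protein-protein
#' records.
#'
#' @param nGenes Number of genes.
#' @param densities Named numeric vector, category -> density in \[0, 1\].
#' @param seed Integer seed.
#' @return List with `lines` (TSV lines including header) and `records`
#'   (the parsed data.frame, equal to
#'   `readInteractionTable(lines)`).
#' @export
syntheticInteractionTable <- function(nGenes,
                                      densities = c(tf_target_curated = 0.3,
                                                    mirna_target = 0.2,
                                                    kinase_substrate = 0.1,
                                                    ppi = 0.4),
                                      seed = 1) {
  stopifnot2(all(densities >= 0 & densities <= 1), "densities must lie in [0, 1]")
  stopifnot2(all(names(densities) %in% INTERACTION_CATEGORIES),
             "unknown interaction category in densities")
  genes <- paste0("gene", seq_len(nGenes))
  body <- withSeed(seed, {
    out <- character(0)
    for (cat. in names(densities)) {
      k <- round(densities[[cat.]] * nGenes)
      if (k == 0L) next
      src <- sample(genes, k, replace = TRUE)
      tgt <- vapply(src, function(s) sample(setdiff(genes, s), 1L), character(1))
      sign <- if (cat. %in% c("tf_target_curated", "tf_target_chip",
                              "tf_target_predicted")) {
        sample(c("activation", "repression", "ambiguous"), k, replace = TRUE)
      } else {
        rep("", k)
      }
      out <- c(out, sprintf("%s\t%s\t%s\t%s\t%s", src, tgt, cat., sign,
                            paste0("synthetic:", cat.)))
    }
    out
  })
  lines <- c("source\ttarget\tcategory\tsign\tprovenance", body)
  list(lines = lines, records = readInteractionTable(lines))
}
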