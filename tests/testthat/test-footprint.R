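test_that("promoter windows flank the TSS, subtract CDS and clip at zero", {
  tss <- data.frame(chrom = "chr1", tss = 10000, gene_id = "g1",
                    gene_symbol = "G1")
  w <- promoterWindows(tss, NULL)
  expect_equal(GenomicRanges::start(w) - 1, 7000)  # 0-based start
  expect_equal(GenomicRanges::end(w), 13000)       # half-open end
  cds <- data.frame(chrom = "chr1", start = 9000, end = 9500)
  w2 <- promoterWindows(tss, cds)
  expect_equal(GenomicRanges::start(w2) - 1, c(7000, 9500))
  expect_equal(GenomicRanges::end(w2), c(9000, 13000))
  expect_equal(unique(w2$gene_id), "g1")
  w3 <- promoterWindows(data.frame(chrom = "chr1", tss = 1000,
                                   gene_id = "g2", gene_symbol = "G2"), NULL)
  expect_equal(GenomicRanges::start(w3) - 1, 0)
  expect_equal(GenomicRanges::end(w3), 4000)
  expect_error(promoterWindows(tss, NULL, chromSizes = c(chr2 = 1e6)),
               "unknown chromosome")
  ## two transcripts of one gene merge
  tss2 <- data.frame(chrom = "chr1", tss = c(10000, 10500),
                     gene_id = "g1", gene_symbol = "G1")
  w4 <- promoterWindows(tss2, NULL)
  expect_length(w4, 1)
  expect_equal(GenomicRanges::end(w4), 13500)
})

test_that("MAF blocks round-trip and malformed blocks are rejected", {
  pwm <- randomPwm(8, 0.1, seed = 3)
  blocks <- list(plantedAlignment(length = 60, pwm = pwm, seed = 1)$block,
                 plantedAlignment(length = 80, pwm = pwm, seed = 2,
                                  refStart = 500)$block)
  f <- withr::local_tempfile()
  writeMaf(blocks, f)
  back <- readMaf(f)
  expect_length(back, 2)
  for (i in 1:2) {
    expect_equal(back[[i]]$rows$text, blocks[[i]]$rows$text)
    expect_equal(back[[i]]$rows$start, blocks[[i]]$rows$start)
    expect_equal(back[[i]]$rows$species, blocks[[i]]$rows$species)
    expect_equal(back[[i]]$ncols, blocks[[i]]$ncols)
  }
  bad <- c("a score=0", "s hg.chr1 0 4 + 100 ACGT", "s mm.chr2 0 3 + 100 ACG")
  fb <- withr::local_tempfile(lines = bad)
  expect_error(readMaf(fb), "unequal gapped length")
  bad2 <- c("a score=0", "s hg.chr1 0 5 + 100 ACGT")
  expect_error(readMaf(withr::local_tempfile(lines = bad2)),
               "size field")
})

test_that("conserved-site scanning requires every species at the same columns", {
  pwm <- randomPwm(10, 0.05, seed = 7)
  lom <- logOdds(pwm)
  thr <- thresholdForPvalue(scoreDistribution(lom), 5e-5)
  expect_true(isAttainable(thr))
  fx <- plantedAlignment(length = 400, pwm = pwm, plantPositions = 100,
                         seed = 11, refStart = 7000)
  reg <- regionCovering("chr1", 7000, 400)
  hits <- scanConservedSites(fx$block, lom, thr, fourSpecies, reg)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 7100)
  expect_equal(hits$end, 7110)
  expect_equal(hits$strand, "+")
  expect_equal(hits$gene_id, "g1")
  ## every species' score clears the threshold
  spCols <- paste0("score_", fourSpecies)
  expect_true(all(hits[spCols] >= thresholdScore(thr)))
  ## scramble the site in one species: the conservation requirement fails
  scr <- editBlockWindow(fx$block, "rn", 100,
                         chartr("ACGT", "TGCA", phyloFootprint:::pwmConsensus(pwm)))
  expect_equal(nrow(scanConservedSites(scr, lom, thr, fourSpecies, reg)), 0)
  ## a gap inside the window disqualifies the position
  gapped <- editBlockWindow(fx$block, "mm", 104, "-")
  expect_equal(nrow(scanConservedSites(gapped, lom, thr, fourSpecies, reg)), 0)
})

test_that("reverse-strand sites are reported with '-' and forward coordinates", {
  pwm <- randomPwm(10, 0.05, seed = 17)
  lom <- logOdds(pwm)
  thr <- thresholdForPvalue(scoreDistribution(lom), 5e-5)
  fx <- plantedAlignment(length = 300, pwm = reverseComplement(pwm),
                         plantPositions = 120, seed = 23)
  reg <- regionCovering("chr1", 0, 300)
  hits <- scanConservedSites(fx$block, lom, thr, fourSpecies, reg)
  minus <- hits[hits$strand == "-", ]
  expect_equal(nrow(minus), 1)
  expect_equal(minus$start, 120)
  expect_equal(minus$end, 130)
})

test_that("hits rescore exactly and never overlap coding-masked intervals", {
  pwm <- randomPwm(10, 0.05, seed = 31)
  lom <- logOdds(pwm)
  thr <- thresholdForPvalue(scoreDistribution(lom), 5e-5)
  fx <- plantedAlignment(length = 600, pwm = pwm,
                         plantPositions = c(50, 300, 500), seed = 37,
                         refStart = 8000)
  tss <- data.frame(chrom = "chr1", tss = 8300, gene_id = "g1",
                    gene_symbol = "G1")
  cds <- data.frame(chrom = "chr1", start = 8290, end = 8320)
  reg <- promoterWindows(tss, cds, flank = 3000)
  hits <- scanConservedSites(fx$block, lom, thr, fourSpecies, reg)
  ## the site planted at 8300 falls in the masked interval and is dropped
  expect_equal(sort(hits$start), c(8050, 8500))
  cdsGr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(8291, 8320))
  hitGr <- GenomicRanges::GRanges(hits$chrom,
                                  IRanges::IRanges(hits$start + 1, hits$end))
  expect_equal(length(GenomicRanges::findOverlaps(hitGr, cdsGr)), 0L)
  ## coordinate soundness: re-extract each window and rescore on the grid
  kF <- phyloFootprint:::snapWeightsToGrid(lomWeights(lom), thr@binWidth)
  refTxt <- strsplit(fx$block$rows$text[1], "")[[1]]
  for (i in seq_len(nrow(hits))) {
    off <- hits$start[i] - 8000
    win <- paste(refTxt[(off + 1):(off + 10)], collapse = "")
    codes <- match(strsplit(win, "")[[1]], c("A", "C", "G", "T"))
    rescore <- sum(kF[cbind(codes, 1:10)]) * thr@binWidth
    expect_equal(rescore, hits$score[i], tolerance = 1e-12)
  }
})

test_that("blocks missing a required species are skipped with a notice", {
  pwm <- randomPwm(8, 0.1, seed = 41)
  lom <- logOdds(pwm)
  thr <- thresholdForPvalue(scoreDistribution(lom), 0.01)
  fx <- plantedAlignment(species = c("hg", "mm"), length = 100, pwm = pwm,
                         seed = 1)
  reg <- regionCovering("chr1", 0, 100)
  expect_message(
    hits <- scanConservedSites(fx$block, lom, thr, fourSpecies, reg),
    "missing species")
  expect_equal(nrow(hits), 0)
})

test_that("hit BED export round-trips all eight fields", {
  pwm <- randomPwm(10, 0.05, seed = 7)
  lom <- logOdds(pwm)
  thr <- thresholdForPvalue(scoreDistribution(lom), 5e-5)
  fx <- plantedAlignment(length = 500, pwm = pwm,
                         plantPositions = c(40, 200, 420), seed = 47)
  reg <- regionCovering("chr1", 0, 500)
  hits <- scanConservedSites(fx$block, lom, thr, fourSpecies, reg)
  expect_gte(nrow(hits), 3)
  f <- withr::local_tempfile()
  writeHitsBed(hits, f)
  raw <- readLines(f)
  expect_true(all(lengths(strsplit(raw, "\t")) == 8))
  expect_true(all(grepl("\\|", vapply(strsplit(raw, "\t"), `[`, "", 4))))
  back <- readHitsBed(f)
  for (col in c("chrom", "start", "end", "pwm_id", "names", "score",
                "strand", "gene_id", "gene_symbol")) {
    expect_identical(back[[col]], hits[[col]], label = col)
  }
  ## empty hit set writes an empty file
  f2 <- withr::local_tempfile()
  writeHitsBed(hits[0, ], f2)
  expect_equal(nrow(readHitsBed(f2)), 0)
})

test_that("target sets collapse duplicates in both directions", {
  hits <- data.frame(pwm_id = c("m1", "m1", "m2"),
                     gene_id = c("geneA", "geneA", "geneA"))
  ts <- targetSets(hits)
  expect_equal(ts$byGene$geneA, c("m1", "m2"))
  expect_equal(ts$byPwm$m1, "geneA")
  expect_equal(ts$byPwm$m2, "geneA")
  empty <- targetSets(data.frame(pwm_id = character(0),
                                 gene_id = character(0)))
  expect_identical(empty$byPwm, list())
})

test_that("regulator counts summarize and cut the top fraction with ties", {
  byGene <- list(A = paste0("m", 1:5), B = paste0("m", 1:3), C = "m1")
  rc <- regulatorCounts(byGene, 1 / 3)
  expect_equal(rc$top_genes, "A")
  tied <- regulatorCounts(list(A = paste0("m", 1:5), B = paste0("m", 6:10),
                               C = "m1"), 1 / 3)
  expect_setequal(tied$top_genes, c("A", "B"))
  expect_equal(regulatorCounts(list(a = paste0("m", 1:1),
                                    b = paste0("m", 1:8),
                                    c = paste0("m", 1:318))[c(3, 2, 1)],
                               1)$summary$median, 8)
  expect_identical(regulatorCounts(list())$top_genes, character(0))
})

test_that("hit-count statistics join matrix descriptors", {
  byPwm <- list(m1 = c("a", "b", "c"), m2 = letters[1:5])
  st <- data.frame(pwm_id = c("m1", "m2"), information_content = c(10, 4),
                   gc_content = c(0.6, 0.4))
  tab <- hitCountStats(byPwm, st)
  expect_equal(tab$n_hits, c(3, 5))
  expect_equal(tab$gc_content, c(0.6, 0.4))
  expect_equal(median(tab$n_hits), 4)
  expect_equal(nrow(hitCountStats(list())), 0)
})
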