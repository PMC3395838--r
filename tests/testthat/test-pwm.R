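test_that("TRANSFAC records parse with ids, names and counts", {
  txt <- c("ID M00001", "NA Sp1", "P0 A C G T",
           "01 2 1 1 0", "02 0 4 0 0", "03 1 1 1 1", "04 4 0 0 0", "//")
  pwms <- readPwmCollection(txt, dialect = "transfac")
  expect_length(pwms, 1)
  expect_equal(pwmId(pwms[[1]]), "M00001")
  expect_equal(factorNames(pwms[[1]]), "Sp1")
  expect_equal(pwmWidth(pwms[[1]]), 4)
  ## counts (2,1,1,0) + uniform pseudocount 1
  expect_equal(pwmProbs(pwms[[1]])[, 1],
               c(A = 2.25, C = 1.25, G = 1.25, T = 0.25) / 5)
  expect_true(all(abs(colSums(pwmProbs(pwms[[1]])) - 1) < 1e-9))
})

test_that("JASPAR records parse and auto-detection picks the dialect", {
  txt <- c(">MA0001.1 NAME",
           "A [ 0 3 79 40 66 48 ]", "C [ 94 75 4 3 1 2 ]",
           "G [ 1 0 3 4 1 0 ]", "T [ 2 19 11 50 29 47 ]")
  pwms <- readPwmCollection(txt, dialect = "jaspar")
  expect_length(pwms, 1)
  expect_equal(pwmWidth(pwms[[1]]), 6)
  expect_true("NAME" %in% factorNames(pwms[[1]]))
  expect_equal(readPwmCollection(txt, dialect = "auto")[[1]]@probs,
               pwms[[1]]@probs)
})

test_that("UNIPROBE and generic dialects parse; empty stream gives empty list", {
  up <- c("UP00001 Zfp161", "A: 0.25 0.1", "C: 0.25 0.2",
          "G: 0.25 0.3", "T: 0.25 0.4")
  pwms <- readPwmCollection(up, dialect = "uniprobe")
  expect_length(pwms, 1)
  ## probability rows with no zeros: renormalized only
  expect_equal(unname(pwmProbs(pwms[[1]])[, 2]), c(0.1, 0.2, 0.3, 0.4))
  gen <- c(">G1 foo", "1 0 0 3", "0 2 2 0")
  expect_equal(pwmWidth(readPwmCollection(gen, dialect = "generic")[[1]]), 2)
  expect_identical(readPwmCollection(character(0)), list())
})

test_that("malformed records and unknown dialects raise informative errors", {
  expect_error(readPwmCollection(c("ID M1", "01 1 2 3"), dialect = "transfac"),
               "record 1.*4 numeric")
  expect_error(readPwmCollection(c(">m", "A [ 1 2 ]", "C [ 1 ]",
                                   "G [ 1 2 ]", "T [ 1 2 ]"),
                                 dialect = "jaspar"),
               "unequal length")
  expect_error(readPwmCollection(">x", dialect = "meme"), "unknown PWM dialect")
})

test_that("count-to-probability conversion follows the pseudocount rule", {
  p <- countsToProbabilities(matrix(c(0, 0, 10, 0), nrow = 1))
  expect_equal(unname(p[, 1]), c(0.25, 0.25, 10.25, 0.25) / 11)
  p2 <- countsToProbabilities(matrix(c(5, 5, 5, 5), nrow = 1), pseudocount = 7)
  expect_equal(unname(p2[, 1]), rep(0.25, 4))
  expect_error(countsToProbabilities(matrix(0, 1, 4), pseudocount = 0),
               "zero total")
})

test_that("log-odds weights are log2(p/bg) and reject zero probabilities", {
  lom <- logOdds(probPwm(matrix(c(0.25, 0.5, 0.125, 0.125), 4, 1)))
  expect_equal(unname(lomWeights(lom)[, 1]), c(0, 1, -1, -1))
  expect_error(logOdds(consensusPwm("A")), "pseudocount")
})

test_that("window scoring sums per-position weights and flags unscoreable windows", {
  expect_equal(scoreWindow(logOdds(flatPwm(5)), "ACGTT"), 0)
  twoCol <- probPwm(matrix(c(0.5, 0.25, 0.125, 0.125), 4, 2))
  lom <- logOdds(twoCol)
  expect_equal(scoreWindow(lom, "AG"), 1 + (-1))
  expect_equal(scoreWindow(lom, "ag"), 0)  # case-insensitive
  expect_true(is.na(scoreWindow(lom, "AN")))
  expect_true(is.na(scoreWindow(lom, "A-")))
  expect_true(is.na(scoreWindow(lom, "AR")))  # ambiguity codes unscoreable
  expect_error(scoreWindow(lom, "AGG"), "width")
  ## near-deterministic consensus: 3 columns of probability 1 -> 3 x 2 bits
  cons <- consensusPwm("ACG")
  p <- pwmProbs(cons); p[p == 0] <- 1e-12; p <- sweep(p, 2, colSums(p), "/")
  expect_equal(scoreWindow(logOdds(newPwm("c", p)), "ACG"), 6, tolerance = 1e-6)
})

test_that("reverse complement is an involution and preserves scores on the opposite strand", {
  pwm <- randomPwm(7, 0.5, seed = 42)
  expect_equal(pwmProbs(reverseComplement(reverseComplement(pwm))),
               pwmProbs(pwm))
  w1 <- probPwm(matrix(c(0.7, 0.1, 0.1, 0.1), 4, 1))
  expect_equal(unname(pwmProbs(reverseComplement(w1))[, 1]),
               c(0.1, 0.1, 0.1, 0.7))
  ## strand symmetry over random (pwm, window) pairs
  set.seed(99)
  for (i in 1:250) {
    pwm <- randomPwm(sample(3:8, 1), 0.8, seed = i)
    lom <- logOdds(pwm)
    win <- paste(sample(c("A", "C", "G", "T"), pwmWidth(pwm), TRUE),
                 collapse = "")
    rcwin <- chartr("ACGT", "TGCA", paste(rev(strsplit(win, "")[[1]]),
                                          collapse = ""))
    expect_equal(scoreWindow(lom, win),
                 scoreWindow(reverseComplement(lom), rcwin),
                 tolerance = 1e-9)
  }
})

test_that("information and GC content match their definitions", {
  s <- pwmStats(flatPwm(6))
  expect_equal(s$information_content, 0)
  expect_equal(s$gc_content, 0.5)
  expect_equal(pwmStats(consensusPwm("ACGT"))$information_content, 8)
  ## half A / half C column with a tiny floor; expected value from the
  ## definition evaluated directly
  eps <- 1e-6
  p <- c(0.5 - eps, 0.5 - eps, eps, eps)
  expected <- sum(p * log2(p / 0.25))
  got <- pwmStats(probPwm(matrix(p, 4, 1)))
  expect_equal(got$information_content, expected, tolerance = 1e-12)
  expect_equal(got$gc_content, 0.5, tolerance = 1e-5)
})

test_that("collections round-trip through every dialect", {
  pwms <- lapply(1:3, function(i) randomPwm(3 + i, 0.7, seed = i,
                                            id = sprintf("RT%d", i)))
  for (d in c("transfac", "jaspar", "uniprobe", "generic")) {
    f <- withr::local_tempfile()
    writePwmCollection(pwms, f, dialect = d)
    back <- readPwmCollection(f, dialect = d)
    expect_length(back, 3)
    for (i in 1:3) {
      expect_equal(pwmId(back[[i]]), pwmId(pwms[[i]]))
      expect_equal(factorNames(back[[i]]), factorNames(pwms[[i]]))
      expect_equal(pwmProbs(back[[i]]), pwmProbs(pwms[[i]]), tolerance = 1e-9)
      expect_true(all(abs(colSums(pwmProbs(back[[i]])) - 1) < 1e-9))
    }
  }
})
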