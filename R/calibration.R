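## Exact p-value calibration of PWM score thresholds.
##
## All scores live on an integer bin grid: weight w (bits) is represented
## by the integer round(w / binWidth). The null distribution, the
## thresholds and the scanner all use the same grid, so "score >= t" is a
## pure integer comparison and bit-reproducible. The discretization error
## of a window score is bounded by W * binWidth / 2.

snapWeightsToGrid <- function(weights, binWidth) {
  k <- round(weights / binWidth)
  storage.mode(k) <- "integer"
  k
}

#' Exact background distribution of window scores
#'
#' Computes the exact distribution of the log-odds score of a random
#' background window by column-wise convolution: starting from unit mass at
#' score 0, each motif position adds its four (grid-rounded) nucleotide
#' weights with their background probabilities. Positions are independent
#' under the zero-order background.
#'
#' @param lom A [LogOddsMatrix-class].
#' @param background A [BackgroundModel-class] (defaults to the matrix's
#'   own).
#' @param binWidth Score-grid resolution in bits (default 0.01).
#' @return A [ScoreDistribution-class].
#' @seealso [thresholdForPvalue()], [bruteForceScoreDistribution()]
#' @examples
#' lom <- logOdds(newPwm("flat", matrix(0.25, 4, 4)))
#' scoreDistribution(lom)  # unit mass at 0
#' @export
scoreDistribution <- function(lom, background = lom@background,
                              binWidth = 0.01) {
  stopifnot2(binWidth > 0, "binWidth must be positive")
  k <- snapWeightsToGrid(lomWeights(lom), binWidth)
  bg <- bgProbs(background)
  W <- ncol(k)
  ## mass vector indexed by offset from the running minimum bin
  lo <- 0L
  mass <- 1
  for (w in seq_len(W)) {
    kw <- k[, w]
    newLo <- lo + min(kw)
    newHi <- (lo + length(mass) - 1L) + max(kw)
    acc <- numeric(newHi - newLo + 1L)
    for (n in 1:4) {
      off <- lo + kw[n] - newLo
      idx <- seq_along(mass) + off
      acc[idx] <- acc[idx] + mass * bg[n]
    }
    mass <- acc
    lo <- newLo
  }
  keep <- mass > 0
  bins <- (lo + which(keep) - 1L)
  m <- mass[keep]
  newScoreDistribution(pwmId(lom), binWidth, bins, m)
}

newScoreDistribution <- function(id, binWidth, bins, m) {
  new("ScoreDistribution", pwmId = id, binWidth = binWidth,
      support = bins * binWidth, mass = m,
      survival = rev(cumsum(rev(m))))
}

#' Brute-force background score distribution
#'
#' Enumerates all `4^W` windows and accumulates the exact background
#' probability of each (grid-rounded) score. Serves as an independent
#' oracle for [scoreDistribution()]; refuses widths above 10.
#'
#' @inheritParams scoreDistribution
#' @return A [ScoreDistribution-class].
#' @export
bruteForceScoreDistribution <- function(lom, background = lom@background,
                                        binWidth = 0.01) {
  k <- snapWeightsToGrid(lomWeights(lom), binWidth)
  W <- ncol(k)
  stopifnot2(W <= 10L, "brute-force enumeration limited to width <= 10")
  bg <- bgProbs(background)
  codes <- as.matrix(expand.grid(rep(list(1:4), W)))
  scores <- integer(nrow(codes))
  probs <- rep(1, nrow(codes))
  for (w in seq_len(W)) {
    scores <- scores + k[codes[, w], w]
    probs <- probs * bg[codes[, w]]
  }
  agg <- tapply(probs, scores, sum)
  bins <- as.integer(names(agg))
  o <- order(bins)
  newScoreDistribution(pwmId(lom), binWidth, bins[o], as.numeric(agg)[o])
}

#' Calibrate the score threshold at a target p-value
#'
#' Returns the smallest grid score whose background tail probability
#' `P(SCORE >= s)` does not exceed `alpha`. When `alpha` is smaller than
#' the mass of the maximum achievable score no window can qualify: the
#' threshold is `+Inf`, the achieved p-value 0, and `attainable` is
#' `FALSE`.
#'
#' @param dist A [ScoreDistribution-class].
#' @param alpha Target p-value in (0, 1].
#' @return A [CalibratedThreshold-class].
#' @examples
#' lom <- logOdds(newPwm("m", countsToProbabilities(diag(4)[, c(1, 2)] * 50)))
#' thresholdForPvalue(scoreDistribution(lom), 0.05)
#' @export
thresholdForPvalue <- function(dist, alpha) {
  stopifnot2(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha <= 1,
             "alpha must lie in (0, 1]")
  ok <- which(dist@survival <= alpha)
  if (length(ok) == 0L) {
    return(new("CalibratedThreshold", pwmId = dist@pwmId, threshold = Inf,
               achievedPvalue = 0, targetPvalue = alpha,
               binWidth = dist@binWidth, attainable = FALSE))
  }
  i <- ok[1L]
  new("CalibratedThreshold", pwmId = dist@pwmId,
      threshold = dist@support[i], achievedPvalue = dist@survival[i],
      targetPvalue = alpha, binWidth = dist@binWidth, attainable = TRUE)
}

#' Tail p-value of a score
#'
#' `P(SCORE >= s)` under the background, read from the survival table with
#' `s` snapped down to the score grid.
#'
#' @param dist A [ScoreDistribution-class].
#' @param s Score in bits.
#' @return Tail probability.
#' @export
pvalueOfScore <- function(dist, s) {
  kq <- floor(s / dist@binWidth + 1e-9)
  ks <- round(dist@support / dist@binWidth)
  vapply(kq, function(k) {
    j <- which(ks >= k)
    if (length(j) == 0L) 0 else dist@survival[j[1L]]
  }, numeric(1))
}

#' Calibrate thresholds for a collection of matrices
#'
#' Convenience wrapper: computes each matrix's exact score distribution and
#' threshold at the target p-value (default `5e-5`, the stringency used for
#' promoter footprinting).
#'
#' @param loms List of [LogOddsMatrix-class] objects.
#' @param alpha Target p-value.
#' @param binWidth Score-grid resolution in bits.
#' @return Named list of [CalibratedThreshold-class] objects, keyed by
#'   matrix id.
#' @export
calibrateThresholds <- function(loms, alpha = 5e-5, binWidth = 0.01) {
  out <- lapply(loms, function(l) {
    thresholdForPvalue(scoreDistribution(l, binWidth = binWidth), alpha)
  })
  names(out) <- vapply(loms, pwmId, character(1))
  out
}

#' Export calibration results as TSV
#'
#' One row per matrix: `pwm_id`, `width`, `threshold_bits`,
#' `achieved_pvalue`, `target_pvalue`. Unattainable thresholds are written
#' as `Inf`.
#'
#' @param thresholds Named list of [CalibratedThreshold-class].
#' @param loms The matching list of [LogOddsMatrix-class] (for widths).
#' @param file Output path.
#' @return Invisibly, the data.frame written.
#' @export
writeCalibrationTsv <- function(thresholds, loms, file) {
  widths <- setNames(vapply(loms, pwmWidth, integer(1)),
                     vapply(loms, pwmId, character(1)))
  df <- data.frame(
    pwm_id = vapply(thresholds, pwmId, character(1)),
    width = widths[vapply(thresholds, pwmId, character(1))],
    threshold_bits = vapply(thresholds, thresholdScore, numeric(1)),
    achieved_pvalue = vapply(thresholds, achievedPvalue, numeric(1)),
    target_pvalue = vapply(thresholds, function(t) t@targetPvalue, numeric(1)),
    row.names = NULL
  )
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
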