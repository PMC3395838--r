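#' Construct a uniform or custom background model
#'
#' @param probs Numeric vector of length 4 (A, C, G, T order) summing to 1.
#'   The default is the uniform background (0.25 per base) used for promoter
#'   scanning.
#' @return A [BackgroundModel-class].
#' @examples
#' uniformBackground()
#' @export
uniformBackground <- function(probs = rep(0.25, 4)) {
  new("BackgroundModel", probs = setNames(as.numeric(probs), NUC))
}

#' Build a PositionWeightMatrix from a probability matrix
#'
#' Low-level constructor. `probs` may be given as 4 x W (rows A,C,G,T) or
#' W x 4 (columns A,C,G,T); it is stored as 4 x W.
#'
#' @param id Matrix identifier.
#' @param probs Numeric probability matrix.
#' @param factorNames Character vector of factor names.
#' @param dialect Source dialect tag.
#' @return A [PositionWeightMatrix-class].
#' @export
newPwm <- function(id, probs, factorNames = character(0), dialect = "generic") {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L && ncol(probs) == 4L) probs <- t(probs)
  rownames(probs) <- NUC
  colnames(probs) <- NULL
  new("PositionWeightMatrix", id = as.character(id), probs = probs,
      factorNames = as.character(factorNames), dialect = dialect)
}

#' Convert count columns to regularized probabilities
#'
#' Each position's counts are converted to probabilities with a pseudocount
#' distributed proportionally to the background:
#' `p = (count + pseudocount * bg) / (total + pseudocount)`. With a positive
#' pseudocount every probability is strictly positive, which keeps log-odds
#' weights finite.
#'
#' @param counts W x 4 (or 4 x W) matrix of non-negative counts, A,C,G,T
#'   order.
#' @param pseudocount Non-negative pseudocount mass added per position
#'   (default 1).
#' @param background A [BackgroundModel-class]; defaults to uniform.
#' @return 4 x W probability matrix (rows A,C,G,T), columns summing to 1.
#' @examples
#' countsToProbabilities(matrix(c(0, 0, 10, 0), nrow = 1))
#' @export
countsToProbabilities <- function(counts, pseudocount = 1,
                                  background = uniformBackground()) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L && ncol(counts) == 4L) counts <- t(counts)
  stopifnot2(nrow(counts) == 4L, "counts must have 4 nucleotide rows/columns")
  stopifnot2(all(counts >= 0), "counts must be non-negative")
  stopifnot2(pseudocount >= 0, "pseudocount must be non-negative")
  tot <- colSums(counts) + pseudocount
  if (any(tot <= 0)) {
    stop("column with zero total count and zero pseudocount: probabilities undefined",
         call. = FALSE)
  }
  bg <- bgProbs(background)
  p <- sweep(counts + outer(bg, rep(pseudocount, ncol(counts))), 2, tot, "/")
  rownames(p) <- NUC
  p
}

#' Log2-odds transform of a PWM
#'
#' Weights are `log2(p[n, w] / bg[n])` in bits; a window is scored as the
#' sum of the weights of its observed bases.
#'
#' @param pwm A [PositionWeightMatrix-class] with strictly positive
#'   probabilities.
#' @param background A [BackgroundModel-class].
#' @return A [LogOddsMatrix-class].
#' @examples
#' pwm <- newPwm("m1", matrix(0.25, 4, 5))
#' lomWeights(logOdds(pwm))
#' @export
logOdds <- function(pwm, background = uniformBackground()) {
  p <- pwmProbs(pwm)
  if (any(p <= 0)) {
    stop("PWM contains zero probabilities; apply a pseudocount (countsToProbabilities) first",
         call. = FALSE)
  }
  w <- log2(p / bgProbs(background))
  new("LogOddsMatrix", pwmId = pwmId(pwm), factorNames = factorNames(pwm),
      weights = w, background = background)
}

#' Score one sequence window against a log-odds matrix
#'
#' Returns the summed log2-odds of the window's bases in bits. Windows
#' containing `N`, gaps or any IUPAC ambiguity character are unscoreable and
#' yield `NA_real_`.
#'
#' @param lom A [LogOddsMatrix-class].
#' @param window Character string of length equal to the matrix width
#'   (case-insensitive).
#' @return Score in bits, or `NA_real_` if unscoreable.
#' @examples
#' lom <- logOdds(newPwm("m1", matrix(0.25, 4, 3)))
#' scoreWindow(lom, "ACG")  # 0 bits
#' @export
scoreWindow <- function(lom, window) {
  w <- lomWeights(lom)
  chars <- strsplit(window, "", fixed = TRUE)[[1L]]
  stopifnot2(length(chars) == ncol(w),
             sprintf("window length %d does not match matrix width %d",
                     length(chars), ncol(w)))
  codes <- nucCodes(chars)
  if (anyNA(codes)) return(NA_real_)
  sum(w[cbind(codes, seq_along(codes))])
}

#' @describeIn reverseComplementPwm Reverse complement of a log-odds matrix.
#' @export
setMethod("reverseComplement", "LogOddsMatrix", function(x, ...) {
  new("LogOddsMatrix", pwmId = x@pwmId, factorNames = x@factorNames,
      weights = revcompMatrix(x@weights), background = x@background)
})

#' Reverse complement of a motif matrix
#'
#' Reverses the column order and swaps A with T and C with G, giving the
#' matrix that scores the opposite strand. Applying it twice returns the
#' original matrix. Methods are provided on the `Biostrings`
#' [Biostrings::reverseComplement()] generic for both
#' [PositionWeightMatrix-class] and [LogOddsMatrix-class].
#'
#' @param x A [PositionWeightMatrix-class] or [LogOddsMatrix-class].
#' @param ... Ignored.
#' @return An object of the same class on the opposite strand.
#' @aliases reverseComplement,PositionWeightMatrix-method
#'   reverseComplement,LogOddsMatrix-method
#' @importMethodsFrom Biostrings reverseComplement
#' @name reverseComplementPwm
#' @examples
#' pwm <- newPwm("m1", matrix(c(.7, .1, .1, .1), nrow = 4))
#' pwmProbs(Biostrings::reverseComplement(pwm))
NULL

#' @describeIn reverseComplementPwm Reverse complement of a PWM.
#' @export
setMethod("reverseComplement", "PositionWeightMatrix", function(x, ...) {
  new("PositionWeightMatrix", id = x@id, factorNames = x@factorNames,
      probs = revcompMatrix(x@probs), dialect = x@dialect)
})

revcompMatrix <- function(m) {
  out <- m[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(m))), drop = FALSE]
  rownames(out) <- NUC
  colnames(out) <- NULL
  out
}

#' Information content and GC content of a PWM
#'
#' Information content is the Kullback-Leibler divergence from the
#' background summed over positions,
#' `sum_w sum_n p[n,w] * log2(p[n,w] / bg[n])` in bits (terms with
#' `p = 0` contribute 0). GC content is the mean over positions of
#' `p[C,w] + p[G,w]`. Both are the axes of the standard hits-versus-GC
#' diagnostic: GC-rich matrices accumulate hits in GC-rich promoters and
#' high-information matrices match fewer windows.
#'
#' @param pwm A [PositionWeightMatrix-class].
#' @param background A [BackgroundModel-class].
#' @return Named list with `information_content` (bits) and `gc_content`
#'   (fraction).
#' @examples
#' pwmStats(newPwm("flat", matrix(0.25, 4, 6)))
#' @export
pwmStats <- function(pwm, background = uniformBackground()) {
  p <- pwmProbs(pwm)
  bg <- bgProbs(background)
  term <- p * log2(sweep(p, 1, bg, "/"))
  term[p == 0] <- 0
  list(information_content = sum(term),
       gc_content = mean(colSums(p[c("C", "G"), , drop = FALSE])))
}
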