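#' @import methods
#' @importFrom stats runif rgamma fisher.test p.adjust phyper median setNames
#' @importFrom utils read.delim write.table head
#' @importFrom grDevices hcl.colors
#' @importFrom Biostrings reverseComplement
NULL

NUC <- c("A", "C", "G", "T")

## Evaluate `code` under a local RNG state seeded with `seed`; the caller's
## .Random.seed is restored afterwards so generators never perturb global state.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  code
}

## Map nucleotide characters to 1..4 (A,C,G,T); anything else (N, gaps,
## IUPAC ambiguity) becomes NA and marks the position unscoreable.
nucCodes <- function(chars) {
  match(toupper(chars), NUC)
}

stopifnot2 <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

isCount <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)
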