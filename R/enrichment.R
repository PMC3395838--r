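## Functional-enrichment scoring of predicted target sets.

#' Construct an annotation universe
#'
#' @param termGenes Named list: term id -> character vector of gene ids.
#' @param universe Character vector of all annotated genes; defaults to the
#'   union of the term gene sets.
#' @param source Free-text source label.
#' @return An [AnnotationUniverse-class].
#' @export
annotationUniverse <- function(termGenes, universe = NULL, source = "custom") {
  termGenes <- lapply(termGenes, function(g) sort(unique(as.character(g))))
  if (is.null(universe)) universe <- sort(unique(unlist(termGenes)))
  new("AnnotationUniverse", source = source, termGenes = termGenes,
      universe = sort(unique(as.character(universe))))
}

#' Read a gene-to-term annotation table
#'
#' Three-column TSV: `gene_id`, `term_id`, `source`; a header line is
#' optional. The universe defaults to all genes in the table, or can be
#' supplied explicitly (e.g. all genes with any promoter alignment).
#'
#' @param file Path.
#' @param universe Optional explicit universe.
#' @return An [AnnotationUniverse-class].
#' @export
readAnnotationTable <- function(file, universe = NULL) {
  first <- readLines(file, n = 1L)
  hasHeader <- grepl("gene_id|term_id", first)
  df <- read.delim(file, header = hasHeader, stringsAsFactors = FALSE)
  if (!hasHeader) names(df)[1:3] <- c("gene_id", "term_id", "source")
  annotationUniverse(split(df$gene_id, df$term_id), universe = universe,
                     source = paste(sort(unique(df$source)), collapse = "+"))
}

#' One-sided Fisher enrichment test of a target set against a term
#'
#' Tests over-representation of an annotation term among a matrix's target
#' genes with a one-sided (greater) Fisher exact test on the 2x2 table
#' (targets in term, targets not in term; non-targets in term, non-targets
#' not in term). Targets are intersected with the universe first. The
#' p-value equals the hypergeometric upper tail.
#'
#' @param targets Character vector of target gene ids.
#' @param termGenes Character vector of the term's gene ids (subset of the
#'   universe).
#' @param universe Character vector of all genes.
#' @return List with `table` (2x2 integer matrix) and `p_value`.
#' @export
fisherEnrichment <- function(targets, termGenes, universe) {
  stopifnot2(length(universe) > 0L, "universe must be non-empty")
  universe <- unique(universe)
  stopifnot2(all(termGenes %in% universe),
             "term gene set must be a subset of the universe")
  targets <- intersect(unique(targets), universe)
  termGenes <- unique(termGenes)
  k <- length(intersect(targets, termGenes))
  tab <- matrix(c(k, length(targets) - k,
                  length(termGenes) - k,
                  length(universe) - length(targets) - length(termGenes) + k),
                nrow = 2,
                dimnames = list(c("target", "nontarget"), c("term", "nonterm")))
  p <- fisher.test(tab, alternative = "greater")$p.value
  list(table = tab, p_value = min(p, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate q-values; monotone, each q >= its p, capped
#' at 1, invariant to input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values in input order.
#' @export
bhAdjust <- function(pvalues) {
  stopifnot2(all(pvalues >= 0 & pvalues <= 1, na.rm = FALSE),
             "p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Build the term-by-matrix enrichment score matrix
#'
#' For every (term, matrix) pair the one-sided Fisher p-value `f` is
#' computed and the cell filled with `-log10(f)`. Rows are terms, columns
#' matrices.
#'
#' @param byPwm Named list matrix id -> target gene ids (from
#'   [targetSets()]).
#' @param annos An [AnnotationUniverse-class].
#' @return Numeric matrix of scores with an attribute `pvalues` holding the
#'   raw p-value matrix of the same shape.
#' @seealso [binarizeMatrix()], [bimaxBiclusters()]
#' @export
enrichmentMatrix <- function(byPwm, annos) {
  terms <- names(termGenes(annos))
  pwms <- names(byPwm)
  P <- matrix(1, length(terms), length(pwms), dimnames = list(terms, pwms))
  for (j in seq_along(pwms)) {
    tg <- byPwm[[j]]
    for (i in seq_along(terms)) {
      P[i, j] <- fisherEnrichment(tg, termGenes(annos)[[i]],
                                  geneUniverse(annos))$p_value
    }
  }
  S <- -log10(P)
  attr(S, "pvalues") <- P
  S
}

#' Binarize an enrichment score matrix
#'
#' A cell is 1 iff its p-value is strictly below `pThreshold`, i.e. its
#' score is strictly above `-log10(pThreshold)`.
#'
#' @param scores Score matrix from [enrichmentMatrix()] (or any `-log10 p`
#'   matrix).
#' @param pThreshold p-value cutoff in (0, 1) (default 1e-3).
#' @return Binary 0/1 matrix of the same shape.
#' @export
binarizeMatrix <- function(scores, pThreshold = 1e-3) {
  stopifnot2(pThreshold > 0 && pThreshold < 1, "pThreshold must lie in (0, 1)")
  out <- (scores > -log10(pThreshold)) + 0L
  dimnames(out) <- dimnames(scores)
  out
}
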