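#' Position weight matrix
#'
#' A probability model of a transcription-factor binding motif: one
#' probability distribution over A, C, G, T per motif position. Columns are
#' positions; rows are nucleotides in fixed A, C, G, T order. Matrices
#' obtained from count data are regularized with a background-proportional
#' pseudocount (see [countsToProbabilities()]) so that log-odds scores stay
#' finite.
#'
#' @slot id Matrix identifier (accession).
#' @slot factorNames Character vector of associated transcription-factor
#'   names (may be empty).
#' @slot probs 4 x W numeric matrix of per-position nucleotide
#'   probabilities, rownames `A,C,G,T`; every column sums to 1.
#' @slot dialect Origin dialect, one of `"transfac"`, `"jaspar"`,
#'   `"uniprobe"`, `"generic"`.
#'
#' @seealso [readPwmCollection()], [logOdds()], [pwmStats()]
#' @export
setClass("PositionWeightMatrix",
  representation(
    id = "character",
    factorNames = "character",
    probs = "matrix",
    dialect = "character"
  )
)

setValidity("PositionWeightMatrix", function(object) {
  p <- object@probs
  if (!is.numeric(p) || nrow(p) != 4L) {
    return("probs must be a numeric 4 x W matrix (rows A,C,G,T)")
  }
  if (ncol(p) < 1L) return("matrix width must be >= 1")
  if (!identical(rownames(p), NUC)) return("probs rownames must be A,C,G,T")
  if (any(p < 0)) return("probabilities must be non-negative")
  if (any(abs(colSums(p) - 1) > 1e-9)) {
    return("every column must sum to 1 within 1e-9")
  }
  if (length(object@id) != 1L || is.na(object@id)) return("id must be a single string")
  TRUE
})

#' Background nucleotide model
#'
#' A zero-order background distribution over A, C, G, T. The default used
#' throughout is uniform (0.25 per base).
#'
#' @slot probs Named numeric vector of length 4 (A,C,G,T) summing to 1.
#' @export
setClass("BackgroundModel", representation(probs = "numeric"))

setValidity("BackgroundModel", function(object) {
  p <- object@probs
  if (length(p) != 4L || !identical(names(p), NUC)) {
    return("probs must be length-4 named A,C,G,T")
  }
  if (any(p <= 0)) return("background probabilities must be positive")
  if (abs(sum(p) - 1) > 1e-12) return("background must sum to 1 within 1e-12")
  TRUE
})

#' Log-odds scoring matrix
#'
#' The scoring form of a [PositionWeightMatrix-class]: per position and
#' nucleotide, `log2(p / bg)` in bits. A window of width W is scored as the
#' sum of the weights of its observed bases.
#'
#' @slot pwmId Identifier of the source matrix.
#' @slot factorNames Factor names carried over from the source matrix.
#' @slot weights 4 x W numeric matrix of log2-odds weights (bits),
#'   rownames `A,C,G,T`.
#' @slot background The [BackgroundModel-class] the weights were computed
#'   against.
#' @export
setClass("LogOddsMatrix",
  representation(
    pwmId = "character",
    factorNames = "character",
    weights = "matrix",
    background = "BackgroundModel"
  )
)

setValidity("LogOddsMatrix", function(object) {
  w <- object@weights
  if (!is.numeric(w) || nrow(w) != 4L || !identical(rownames(w), NUC)) {
    return("weights must be a numeric 4 x W matrix with rownames A,C,G,T")
  }
  if (any(!is.finite(w))) return("weights must be finite; regularize the PWM with a pseudocount")
  TRUE
})

#' Exact null distribution of window scores
#'
#' The distribution of the log-odds score of a random background window,
#' discretized on a fixed score grid of width `binWidth` bits. Computed
#' either exactly by column-wise convolution ([scoreDistribution()]) or by
#' enumeration of all 4^W windows ([bruteForceScoreDistribution()]).
#'
#' @slot pwmId Identifier of the scored matrix.
#' @slot binWidth Grid resolution in bits.
#' @slot support Ascending vector of achievable grid scores (bits).
#' @slot mass Probability mass per support point (sums to 1).
#' @slot survival Tail probability `P(SCORE >= s)` per support point
#'   (non-increasing, 1 at the minimum).
#' @export
setClass("ScoreDistribution",
  representation(
    pwmId = "character",
    binWidth = "numeric",
    support = "numeric",
    mass = "numeric",
    survival = "numeric"
  )
)

setValidity("ScoreDistribution", function(object) {
  if (length(object@support) != length(object@mass) ||
      length(object@mass) != length(object@survival)) {
    return("support, mass and survival must have equal length")
  }
  if (is.unsorted(object@support, strictly = TRUE)) return("support must be strictly ascending")
  if (abs(sum(object@mass) - 1) > 1e-9) return("mass must sum to 1 within 1e-9")
  if (any(diff(object@survival) > 1e-12)) return("survival must be non-increasing")
  if (abs(object@survival[1L] - 1) > 1e-9) return("survival at the minimum support must be 1")
  TRUE
})

#' Calibrated score threshold
#'
#' The per-matrix score cutoff at a target p-value: the smallest grid score
#' whose background tail probability does not exceed the target. When even
#' the maximum achievable score has tail probability above the target, the
#' threshold is `+Inf` and `attainable` is `FALSE` (no window can ever be
#' called).
#'
#' @slot pwmId Identifier of the calibrated matrix.
#' @slot threshold Score cutoff in bits (`+Inf` when unattainable).
#' @slot achievedPvalue Tail probability actually achieved at the cutoff.
#' @slot targetPvalue The requested p-value.
#' @slot binWidth Score-grid resolution the calibration was computed on;
#'   scanning uses the same grid so comparisons are bit-reproducible.
#' @slot attainable Whether any score meets the target.
#' @export
setClass("CalibratedThreshold",
  representation(
    pwmId = "character",
    threshold = "numeric",
    achievedPvalue = "numeric",
    targetPvalue = "numeric",
    binWidth = "numeric",
    attainable = "logical"
  )
)

setValidity("CalibratedThreshold", function(object) {
  if (object@achievedPvalue > object@targetPvalue + 1e-15) {
    return("achievedPvalue must not exceed targetPvalue")
  }
  TRUE
})

#' Annotation term universe
#'
#' A collection of annotation terms (e.g. GO biological process, KEGG,
#' PANTHER) with their gene memberships, together with the universe of
#' annotated genes used for enrichment testing.
#'
#' @slot source Free-text label of the annotation source.
#' @slot termGenes Named list: term id -> character vector of gene ids.
#' @slot universe Character vector of all genes under consideration.
#' @export
setClass("AnnotationUniverse",
  representation(
    source = "character",
    termGenes = "list",
    universe = "character"
  )
)

setValidity("AnnotationUniverse", function(object) {
  if (length(object@universe) == 0L) return("universe must be non-empty")
  if (length(object@termGenes) > 0L && is.null(names(object@termGenes))) {
    return("termGenes must be a named list")
  }
  bad <- vapply(object@termGenes, function(g) !all(g %in% object@universe), logical(1))
  if (any(bad)) {
    return(sprintf("term gene sets must be subsets of the universe (offending: %s)",
                   paste(names(object@termGenes)[bad], collapse = ", ")))
  }
  TRUE
})

#' Cellular-compartment hierarchy
#'
#' A rooted tree over a pruned subset of cellular-component terms, used both
#' to place gene-product instances into compartments and to derive the
#' nested layout zones of a [MixedGraph-class].
#'
#' @slot nodes data.frame with columns `term_id`, `label`, `parent`
#'   (`NA` for the root), `depth`, `color`.
#' @slot root term id of the whole-cell root.
#' @seealso [defaultCompartmentTree()], [readCompartmentTree()]
#' @export
setClass("CompartmentTree",
  representation(nodes = "data.frame", root = "character")
)

setValidity("CompartmentTree", function(object) {
  nd <- object@nodes
  need <- c("term_id", "label", "parent", "depth", "color")
  if (!all(need %in% names(nd))) {
    return(sprintf("nodes must have columns %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(nd$term_id)) return("duplicate term ids in tree")
  if (!(object@root %in% nd$term_id)) return("root must be a tree node")
  nonroot <- nd[nd$term_id != object@root, , drop = FALSE]
  if (any(is.na(nonroot$parent)) || !all(nonroot$parent %in% nd$term_id)) {
    return("every non-root node must name an existing parent")
  }
  ## walk each node to the root to reject cycles
  for (t in nd$term_id) {
    seen <- character(0)
    cur <- t
    while (!is.na(cur) && cur != object@root) {
      if (cur %in% seen) return("cycle in compartment tree")
      seen <- c(seen, cur)
      cur <- nd$parent[match(cur, nd$term_id)]
    }
  }
  TRUE
})

#' Compartment-annotated mixed interaction graph
#'
#' A graph over gene-product instances. Each gene may be instantiated once
#' per annotated compartment; edges connect instances and can be directed
#' (transcriptional regulation, miRNA targeting, kinase-substrate) or
#' undirected (physical protein-protein interaction), carrying a sign
#' (activation / repression / ambiguous / none). Zones are nested
#' rectangles derived from the compartment tree and used by
#' [layoutGraph()].
#'
#' @slot instances data.frame: `instance_id`, `gene_id`, `compartment`,
#'   `x`, `y`, `has_regulatory_info`.
#' @slot edges data.frame: `from`, `to` (instance ids), `source_id`,
#'   `target_id` (gene ids), `category`, `sign`, `directed`, `provenance`.
#' @slot zones data.frame: `term_id`, `xmin`, `xmax`, `ymin`, `ymax`,
#'   `anchor_x`, `anchor_y`.
#' @slot tree The [CompartmentTree-class] the zones were derived from.
#' @export
setClass("MixedGraph",
  representation(
    instances = "data.frame",
    edges = "data.frame",
    zones = "data.frame",
    tree = "CompartmentTree"
  )
)

setValidity("MixedGraph", function(object) {
  ins <- object@instances
  ed <- object@edges
  if (anyDuplicated(ins[c("gene_id", "compartment")])) {
    return("at most one instance per (gene, compartment) pair")
  }
  if (nrow(ed) > 0L &&
      (!all(ed$from %in% ins$instance_id) || !all(ed$to %in% ins$instance_id))) {
    return("edge endpoints must be existing instances")
  }
  TRUE
})
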