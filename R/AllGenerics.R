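#' @rdname PositionWeightMatrix-class
#' @param x A package object.
#' @aliases pwmId,PositionWeightMatrix-method pwmId,LogOddsMatrix-method
#'   pwmId,ScoreDistribution-method pwmId,CalibratedThreshold-method
#'   factorNames,PositionWeightMatrix-method factorNames,LogOddsMatrix-method
#'   pwmWidth,PositionWeightMatrix-method pwmWidth,LogOddsMatrix-method
#'   pwmProbs,PositionWeightMatrix-method
#' @export
setGeneric("pwmId", function(x) standardGeneric("pwmId"))

#' @rdname PositionWeightMatrix-class
#' @export
setGeneric("factorNames", function(x) standardGeneric("factorNames"))

#' @rdname PositionWeightMatrix-class
#' @export
setGeneric("pwmWidth", function(x) standardGeneric("pwmWidth"))

#' @rdname PositionWeightMatrix-class
#' @export
setGeneric("pwmProbs", function(x) standardGeneric("pwmProbs"))

#' @rdname BackgroundModel-class
#' @param x A package object.
#' @aliases bgProbs,BackgroundModel-method
#' @export
setGeneric("bgProbs", function(x) standardGeneric("bgProbs"))

#' @rdname LogOddsMatrix-class
#' @param x A package object.
#' @aliases lomWeights,LogOddsMatrix-method
#' @export
setGeneric("lomWeights", function(x) standardGeneric("lomWeights"))

#' @export
setMethod("pwmId", "PositionWeightMatrix", function(x) x@id)
#' @export
setMethod("pwmId", "LogOddsMatrix", function(x) x@pwmId)
#' @export
setMethod("pwmId", "ScoreDistribution", function(x) x@pwmId)
#' @export
setMethod("pwmId", "CalibratedThreshold", function(x) x@pwmId)
#' @export
setMethod("factorNames", "PositionWeightMatrix", function(x) x@factorNames)
#' @export
setMethod("factorNames", "LogOddsMatrix", function(x) x@factorNames)
#' @export
setMethod("pwmWidth", "PositionWeightMatrix", function(x) ncol(x@probs))
#' @export
setMethod("pwmWidth", "LogOddsMatrix", function(x) ncol(x@weights))
#' @export
setMethod("pwmProbs", "PositionWeightMatrix", function(x) x@probs)
#' @export
setMethod("bgProbs", "BackgroundModel", function(x) x@probs)
#' @export
setMethod("lomWeights", "LogOddsMatrix", function(x) x@weights)

#' @rdname ScoreDistribution-class
#' @param x A `ScoreDistribution`.
#' @export
scoreSupport <- function(x) x@support
#' @rdname ScoreDistribution-class
#' @export
scoreMass <- function(x) x@mass
#' @rdname ScoreDistribution-class
#' @export
scoreSurvival <- function(x) x@survival

#' @rdname CalibratedThreshold-class
#' @param x A `CalibratedThreshold`.
#' @export
thresholdScore <- function(x) x@threshold
#' @rdname CalibratedThreshold-class
#' @export
achievedPvalue <- function(x) x@achievedPvalue
#' @rdname CalibratedThreshold-class
#' @export
isAttainable <- function(x) x@attainable

#' @rdname AnnotationUniverse-class
#' @param x An `AnnotationUniverse`.
#' @export
termGenes <- function(x) x@termGenes
#' @rdname AnnotationUniverse-class
#' @export
geneUniverse <- function(x) x@universe

#' @rdname MixedGraph-class
#' @param x A `MixedGraph`.
#' @export
graphInstances <- function(x) x@instances
#' @rdname MixedGraph-class
#' @export
graphEdges <- function(x) x@edges
#' @rdname MixedGraph-class
#' @export
graphZones <- function(x) x@zones
#' @rdname CompartmentTree-class
#' @param x A `CompartmentTree`.
#' @export
treeNodes <- function(x) x@nodes

setMethod("show", "PositionWeightMatrix", function(object) {
  cat(sprintf("PositionWeightMatrix %s (%s), width %d",
              object@id, object@dialect, ncol(object@probs)))
  if (length(object@factorNames)) {
    cat(sprintf(" [%s]", paste(object@factorNames, collapse = ", ")))
  }
  cat("\n")
  print(round(object@probs, 3))
  invisible(NULL)
})

setMethod("show", "LogOddsMatrix", function(object) {
  cat(sprintf("LogOddsMatrix %s, width %d, max score %.3f bits\n",
              object@pwmId, ncol(object@weights),
              sum(apply(object@weights, 2, max))))
  invisible(NULL)
})

setMethod("show", "ScoreDistribution", function(object) {
  cat(sprintf(
    "ScoreDistribution %s: %d support points in [%.3f, %.3f] bits (bin %.3g)\n",
    object@pwmId, length(object@support),
    min(object@support), max(object@support), object@binWidth))
  invisible(NULL)
})

setMethod("show", "CalibratedThreshold", function(object) {
  if (object@attainable) {
    cat(sprintf("CalibratedThreshold %s: t = %.3f bits (tail %.3g <= target %.3g)\n",
                object@pwmId, object@threshold, object@achievedPvalue,
                object@targetPvalue))
  } else {
    cat(sprintf("CalibratedThreshold %s: unattainable at target %.3g\n",
                object@pwmId, object@targetPvalue))
  }
  invisible(NULL)
})

setMethod("show", "AnnotationUniverse", function(object) {
  cat(sprintf("AnnotationUniverse [%s]: %d terms over %d genes\n",
              object@source, length(object@termGenes), length(object@universe)))
  invisible(NULL)
})

setMethod("show", "CompartmentTree", function(object) {
  cat(sprintf("CompartmentTree: %d compartments, root '%s'\n",
              nrow(object@nodes), object@root))
  invisible(NULL)
})

setMethod("show", "MixedGraph", function(object) {
  nd <- sum(object@edges$directed)
  cat(sprintf("MixedGraph: %d instances (%d genes), %d edges (%d directed / %d undirected), %d zones\n",
              nrow(object@instances), length(unique(object@instances$gene_id)),
              nrow(object@edges), nd, nrow(object@edges) - nd,
              nrow(object@zones)))
  invisible(NULL)
})
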