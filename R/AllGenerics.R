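#' @name accessors
#' @title Accessors for velofate containers
#' @description Slot access for the S4 containers without reaching into
#'   internals.
#' @param object a velofate S4 object.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(object) standardGeneric("exprMatrix"))
#' @rdname accessors
#' @export
setGeneric("velocityMatrix", function(object) standardGeneric("velocityMatrix"))
#' @rdname accessors
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("missingGenes", function(object) standardGeneric("missingGenes"))
#' @rdname accessors
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setGeneric("nGenes", function(object) standardGeneric("nGenes"))
#' @rdname accessors
#' @export
setGeneric("transitionProbs", function(object) standardGeneric("transitionProbs"))
#' @rdname accessors
#' @export
setGeneric("isBackward", function(object) standardGeneric("isBackward"))
#' @rdname accessors
#' @export
setGeneric("memberships", function(object) standardGeneric("memberships"))
#' @rdname accessors
#' @export
setGeneric("coarseTransition", function(object) standardGeneric("coarseTransition"))
#' @rdname accessors
#' @export
setGeneric("stabilityIndex", function(object) standardGeneric("stabilityIndex"))
#' @rdname accessors
#' @export
setGeneric("fateProbs", function(object) standardGeneric("fateProbs"))
#' @rdname accessors
#' @export
setGeneric("lineageNames", function(object) standardGeneric("lineageNames"))
#' @rdname accessors
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setGeneric("neighborLists", function(object) standardGeneric("neighborLists"))

#' @rdname accessors
#' @export
setMethod("exprMatrix", "VelocityData", function(object) object@expr)
#' @rdname accessors
#' @export
setMethod("velocityMatrix", "VelocityData", function(object) object@velocity)
#' @rdname accessors
#' @export
setMethod("cellIds", "VelocityData", function(object) object@cellIds)
#' @rdname accessors
#' @export
setMethod("geneIds", "VelocityData", function(object) object@geneIds)
#' @rdname accessors
#' @export
setMethod("missingGenes", "VelocityData", function(object) object@missingGenes)
#' @rdname accessors
#' @export
setMethod("nCells", "VelocityData", function(object) nrow(object@expr))
#' @rdname accessors
#' @export
setMethod("nGenes", "VelocityData", function(object) ncol(object@expr))
#' @rdname accessors
#' @export
setMethod("transitionProbs", "TransitionMatrix", function(object) object@probs)
#' @rdname accessors
#' @export
setMethod("isBackward", "TransitionMatrix", function(object) object@backward)
#' @rdname accessors
#' @export
setMethod("memberships", "GPCCAResult", function(object) object@chi)
#' @rdname accessors
#' @export
setMethod("coarseTransition", "GPCCAResult", function(object) object@Pc)
#' @rdname accessors
#' @export
setMethod("stabilityIndex", "GPCCAResult", function(object) diag(object@Pc))
#' @rdname accessors
#' @export
setMethod("stabilityIndex", "StateClassification",
          function(object) object@stabilityIndex)
#' @rdname accessors
#' @export
setMethod("fateProbs", "FateMatrix", function(object) object@probs)
#' @rdname accessors
#' @export
setMethod("lineageNames", "FateMatrix", function(object) object@lineageNames)
#' @rdname accessors
#' @export
setMethod("adjacency", "NeighborGraph", function(object) object@adjacency)
#' @rdname accessors
#' @export
setMethod("neighborLists", "NeighborGraph", function(object) object@neighbors)

setMethod("show", "VelocityData", function(object) {
  cat(sprintf("VelocityData: %d cells x %d genes (%d genes without velocity)\n",
              nrow(object@expr), ncol(object@expr), sum(object@missingGenes)))
})

setMethod("show", "NeighborGraph", function(object) {
  deg <- lengths(object@neighbors)
  cat(sprintf("NeighborGraph: %d cells, K = %d (symmetrized degree %d-%d)%s\n",
              length(object@neighbors), object@K, min(deg), max(deg),
              if (nzchar(object@similarityMethod))
                sprintf(", %s similarities", object@similarityMethod)
              else ", similarities not computed"))
})

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix: %d states, %s chain\n  recipe: %s\n",
              nrow(object@probs),
              if (object@backward) "backward" else "forward",
              object@provenance))
})

setMethod("show", "GPCCAResult", function(object) {
  cat(sprintf(
    "GPCCAResult: %d cells -> %d macrostates\n  crispness %.4f, minChi %.4g\n",
    nrow(object@chi), object@nStates, object@crispness, object@minChi))
  cat("  stability indices:",
      paste(sprintf("%.3f", diag(object@Pc)), collapse = " "), "\n")
})

setMethod("show", "StateClassification", function(object) {
  nm <- object@macrostateNames
  lab <- function(ix) if (length(ix)) paste(nm[ix], collapse = ", ") else "none"
  cat("StateClassification\n",
      sprintf("  terminal (SI >= %.2f): %s\n", object@siThreshold,
              lab(object@terminal)),
      sprintf("  initial: %s\n", lab(object@initial)),
      sprintf("  intermediate: %s\n", lab(object@intermediate)),
      sprintf("  outlier: %s\n", lab(object@outlier)), sep = "")
})

setMethod("show", "FateMatrix", function(object) {
  cat(sprintf("FateMatrix: %d cells x %d lineages (%s)\n",
              nrow(object@probs), ncol(object@probs),
              paste(object@lineageNames, collapse = ", ")))
})

setMethod("show", "TrendFit", function(object) {
  cat(sprintf(
    "TrendFit: %d cells fitted on %d-point grid, lambda = %.3g\n",
    length(object@tau), length(object@testGrid), object@lambda))
})
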