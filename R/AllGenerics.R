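#' @name accessors
#' @title Accessors for gatddi classes
#' @description Accessor generics for the core classes: `drugId()`,
#'   `numAtoms()`, `atomFeatures()`, `graphEdges()`, `atomElements()`,
#'   `layerVectors()`, `embeddingVector()`, `atomWeights()`, `drugTable()`,
#'   `positivePairs()`, `scoreMatrix()`.
#' @param object an object of the documented classes.
#' @return the slot contents; see each class for details.
NULL

#' @rdname accessors
#' @export
setGeneric("drugId", function(object) standardGeneric("drugId"))
#' @rdname accessors
#' @export
setGeneric("numAtoms", function(object) standardGeneric("numAtoms"))
#' @rdname accessors
#' @export
setGeneric("atomFeatures", function(object) standardGeneric("atomFeatures"))
#' @rdname accessors
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setGeneric("atomElements", function(object) standardGeneric("atomElements"))
#' @rdname accessors
#' @export
setGeneric("layerVectors", function(object) standardGeneric("layerVectors"))
#' @rdname accessors
#' @export
setGeneric("embeddingVector", function(object) standardGeneric("embeddingVector"))
#' @rdname accessors
#' @export
setGeneric("atomWeights", function(object) standardGeneric("atomWeights"))
#' @rdname accessors
#' @export
setGeneric("drugTable", function(object) standardGeneric("drugTable"))
#' @rdname accessors
#' @export
setGeneric("positivePairs", function(object) standardGeneric("positivePairs"))
#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(object) standardGeneric("scoreMatrix"))

#' @rdname accessors
setMethod("drugId", "MolecularGraph", function(object) object@drugId)
#' @rdname accessors
setMethod("drugId", "DrugEmbedding", function(object) object@drugId)
#' @rdname accessors
setMethod("numAtoms", "MolecularGraph", function(object) nrow(object@atomFeatures))
#' @rdname accessors
setMethod("atomFeatures", "MolecularGraph", function(object) object@atomFeatures)
#' @rdname accessors
setMethod("graphEdges", "MolecularGraph", function(object) object@edges)
#' @rdname accessors
setMethod("atomElements", "MolecularGraph", function(object) object@elements)
#' @rdname accessors
setMethod("layerVectors", "DrugEmbedding", function(object) object@layerVectors)
#' @rdname accessors
setMethod("embeddingVector", "DrugEmbedding", function(object) object@z)
#' @rdname accessors
setMethod("atomWeights", "DrugEmbedding", function(object) object@atomWeights)
#' @rdname accessors
setMethod("drugTable", "DDIDataset", function(object) object@drugs)
#' @rdname accessors
setMethod("positivePairs", "DDIDataset", function(object) object@positives)
#' @rdname accessors
setMethod("scoreMatrix", "AttributionResult", function(object) object@scoreMatrix)

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph '%s': %d atoms, %d bonds\n  SMILES: %s\n",
              object@drugId, nrow(object@atomFeatures), nrow(object@edges),
              object@smiles))
})

setMethod("show", "DrugEmbedding", function(object) {
  cat(sprintf("DrugEmbedding '%s': %d layers x %d dims (Z length %d)\n",
              object@drugId, nrow(object@layerVectors),
              ncol(object@layerVectors), length(object@z)))
})

setMethod("show", "DDIDataset", function(object) {
  cat(sprintf("DDIDataset: %d drugs, %d positive interactions\n",
              nrow(object@drugs), nrow(object@positives)))
})

setMethod("show", "AttributionResult", function(object) {
  cat(sprintf(
    "AttributionResult %s ~ %s\n  best layer pair: (%d, %d), score %.4f\n",
    object@drugX, object@drugY, object@bestPair[1L], object@bestPair[2L],
    object@bestScore))
})

setMethod("show", "DDIModel", function(object) {
  cat(sprintf("DDIModel (version %s): %d encoder layers, %d heads, head dim %d\n",
              object@version, object@config$numLayers, object@config$heads,
              object@config$headDim))
})
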