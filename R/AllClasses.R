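#' MolecularGraph: a featurized molecular graph
#'
#' Heavy atoms are nodes (hydrogens are implicit), covalent bonds between
#' heavy atoms are undirected edges, and every atom carries a 78-dimensional
#' feature vector: element symbol one-hot (44 slots, 43 named elements plus a
#' catch-all), heavy-atom degree one-hot (0-10), implicit valence one-hot
#' (0-6), formal charge (signed integer), radical electron count (integer),
#' hybridization one-hot (SP, SP2, SP3, SP3D, SP3D2), total hydrogen count
#' one-hot (0-7) and an aromaticity flag.
#'
#' @slot drugId character(1), identifier of the drug.
#' @slot smiles character(1), the source SMILES string.
#' @slot atomFeatures numeric matrix, one 78-column row per heavy atom.
#' @slot edges integer matrix with two columns holding 0-based atom indices,
#'   one row per bond, each unordered pair stored once.
#' @slot elements character vector of element symbols, one per atom.
#'
#' @exportClass MolecularGraph
setClass("MolecularGraph",
  representation(
    drugId = "character",
    smiles = "character",
    atomFeatures = "matrix",
    edges = "matrix",
    elements = "character"
  )
)

setValidity("MolecularGraph", function(object) {
  msgs <- character(0)
  p <- nrow(object@atomFeatures)
  if (p < 1L) msgs <- c(msgs, "graph must contain at least one atom")
  if (ncol(object@atomFeatures) != 78L)
    msgs <- c(msgs, "atom feature rows must have length 78")
  if (length(object@elements) != p)
    msgs <- c(msgs, "one element symbol required per atom")
  symSums <- rowSums(object@atomFeatures[, 1:44, drop = FALSE])
  if (p >= 1L && any(abs(symSums - 1) > 1e-12))
    msgs <- c(msgs, "symbol one-hot block must sum to 1 in every row")
  e <- object@edges
  if (nrow(e) > 0) {
    if (ncol(e) != 2L) msgs <- c(msgs, "edges must have two columns")
    else {
      if (any(e < 0L) || any(e >= p))
        msgs <- c(msgs, "edge endpoints must be valid 0-based atom indices")
      if (any(e[, 1L] == e[, 2L])) msgs <- c(msgs, "self-loop edges forbidden")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' DrugEmbedding: per-layer pooled drug vectors and their concatenation
#'
#' Holds the attention-pooled graph vector of every encoder layer (each of
#' length heads x headDim), the concatenated k-hop embedding used by the pair
#' classifier, and the per-layer atom weights produced by the pooling readout
#' (softmax-normalized, one weight per atom, summing to 1 per layer).
#'
#' @slot drugId character(1).
#' @slot layerVectors numeric matrix, one row per encoder layer.
#' @slot z numeric vector, the row-wise concatenation of `layerVectors`.
#' @slot atomWeights numeric matrix, layers x atoms; each row sums to 1.
#'
#' @exportClass DrugEmbedding
setClass("DrugEmbedding",
  representation(
    drugId = "character",
    layerVectors = "matrix",
    z = "numeric",
    atomWeights = "matrix"
  )
)

setValidity("DrugEmbedding", function(object) {
  msgs <- character(0)
  K <- nrow(object@layerVectors)
  if (length(object@z) != K * ncol(object@layerVectors))
    msgs <- c(msgs, "z must be the concatenation of the per-layer vectors")
  if (nrow(object@atomWeights) != K)
    msgs <- c(msgs, "one atom-weight row required per layer")
  ws <- rowSums(object@atomWeights)
  if (K >= 1L && any(abs(ws - 1) > 1e-8))
    msgs <- c(msgs, "atom weights must sum to 1 within each layer")
  if (length(msgs)) msgs else TRUE
})

#' DDIDataset: a drug table plus a positive interaction edge list
#'
#' @slot drugs data.frame with columns `drug_id` and `smiles`.
#' @slot positives data.frame with columns `drug_a` and `drug_b`; unordered
#'   pairs, each stored once, no self pairs, endpoints present in `drugs`.
#'
#' @exportClass DDIDataset
setClass("DDIDataset",
  representation(
    drugs = "data.frame",
    positives = "data.frame"
  )
)

setValidity("DDIDataset", function(object) {
  msgs <- character(0)
  if (!all(c("drug_id", "smiles") %in% names(object@drugs)))
    msgs <- c(msgs, "drugs must have columns drug_id and smiles")
  if (!all(c("drug_a", "drug_b") %in% names(object@positives)))
    msgs <- c(msgs, "positives must have columns drug_a and drug_b")
  else {
    pa <- object@positives$drug_a; pb <- object@positives$drug_b
    if (any(pa == pb)) msgs <- c(msgs, "self pairs are not allowed")
    known <- object@drugs$drug_id
    if (!all(c(pa, pb) %in% known))
      msgs <- c(msgs, "every pair endpoint must reference a known drug")
    if (anyDuplicated(.pairKey(pa, pb)))
      msgs <- c(msgs, "duplicate unordered pairs in positives")
  }
  if (length(msgs)) msgs else TRUE
})

#' AttributionResult: layer-pair contribution scores for one drug pair
#'
#' @slot drugX,drugY character(1) drug identifiers.
#' @slot scoreMatrix K x K matrix of inner products between the per-layer
#'   pooled vectors of the two drugs.
#' @slot bestPair integer(2), 1-based (layer of x, layer of y) maximizing the
#'   score, ties broken toward the smallest indices.
#' @slot bestScore numeric(1), the maximum score.
#' @slot atomsX,atomsY data.frame with columns `atom_index` (0-based),
#'   `element`, `weight`: the pooling weights of the selected layer.
#'
#' @exportClass AttributionResult
setClass("AttributionResult",
  representation(
    drugX = "character",
    drugY = "character",
    scoreMatrix = "matrix",
    bestPair = "integer",
    bestScore = "numeric",
    atomsX = "data.frame",
    atomsY = "data.frame"
  )
)

setValidity("AttributionResult", function(object) {
  msgs <- character(0)
  if (abs(object@bestScore - max(object@scoreMatrix)) > 1e-9)
    msgs <- c(msgs, "bestScore must equal the maximum of scoreMatrix")
  for (nm in c("atomsX", "atomsY")) {
    df <- slot(object, nm)
    if (!all(c("atom_index", "element", "weight") %in% names(df)))
      msgs <- c(msgs, sprintf("%s needs atom_index, element, weight", nm))
    else if (abs(sum(df$weight) - 1) > 1e-8)
      msgs <- c(msgs, sprintf("%s weights must sum to 1", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' DDIModel: a trained encoder + pair-classifier checkpoint
#'
#' @slot encoder nested list of graph-attention layer parameters (per layer:
#'   per-head weight matrices and attention vectors, plus the pooling scorer).
#' @slot mlp list of affine-layer weights and biases of the pair classifier.
#' @slot config list echoing the architecture and training configuration.
#' @slot version character(1) checkpoint format version.
#'
#' @exportClass DDIModel
setClass("DDIModel",
  representation(
    encoder = "list",
    mlp = "list",
    config = "list",
    version = "character"
  )
)
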