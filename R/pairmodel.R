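# Drug-pair feature construction, the MLP pair classifier and the binary
# cross-entropy objective.

#' Concatenate two drug embeddings into a pair feature vector
#'
#' @param zx,zy numeric drug embedding vectors of equal length.
#' @return numeric vector `c(zx, zy)` (length 640 at default architecture).
#' @export
pairFeatures <- function(zx, zy) {
  if (length(zx) != length(zy))
    stop("drug embeddings must have equal length")
  c(zx, zy)
}

#' Initialize the pair-classifier parameters (Glorot-uniform, seeded)
#'
#' The classifier is a five-layer perceptron: the pair feature input, three
#' hidden layers (128, 64 and 32 units by default, each followed by ReLU)
#' and a 2-unit softmax output whose positive-class component is the
#' interaction probability.
#'
#' @param inputDim length of the pair feature vector (640 at defaults).
#' @param hidden integer vector of hidden layer sizes.
#' @param seed integer seed.
#' @return list of affine layers, each with weight matrix `W` and bias `b`.
#' @export
initMlpParams <- function(inputDim = 640L, hidden = c(128L, 64L, 32L),
                          seed = 1L) {
  withr::with_seed(seed, {
    dims <- c(inputDim, hidden, 2L)
    lapply(seq_len(length(dims) - 1L), function(i) {
      list(W = .glorot(dims[i], dims[i + 1L]), b = numeric(dims[i + 1L]))
    })
  })
}

#' MLP forward pass over a batch of pair features.
#' Returns the activations needed for backpropagation.
#' @keywords internal
.mlpForwardBatch <- function(X, params) {
  nl <- length(params)
  acts <- vector("list", nl + 1L)
  acts[[1L]] <- X
  A <- X
  for (i in seq_len(nl)) {
    A <- sweep(A %*% params[[i]]$W, 2L, params[[i]]$b, `+`)
    if (i < nl) A <- .relu(A)
    acts[[i + 1L]] <- A
  }
  # row-wise softmax over the 2-unit output
  M <- apply(A, 1L, max)
  EZ <- exp(A - M)
  P <- EZ / rowSums(EZ)
  list(acts = acts, probs = P[, 2L], P = P)
}

#' Pair-classifier forward pass
#'
#' Applies the affine layers with ReLU activations and a softmax over the
#' 2-unit output; the returned probability is the positive-class component.
#'
#' @param feature numeric pair feature vector (or a matrix with one pair per
#'   row) matching the input layer width.
#' @param params list from [initMlpParams()] (or the `mlp` slot of a trained
#'   [DDIModel-class]).
#' @return numeric vector of interaction probabilities in `[0, 1]`.
#' @export
mlpForward <- function(feature, params) {
  X <- if (is.matrix(feature)) feature else matrix(feature, nrow = 1L)
  if (ncol(X) != nrow(params[[1L]]$W))
    stop("pair feature length does not match the classifier input layer")
  .mlpForwardBatch(X, params)$probs
}

#' Binary cross-entropy loss
#'
#' Mean over the batch of `-(y log p + (1 - y) log(1 - p))`, with
#' probabilities clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param predictions numeric vector of predicted probabilities.
#' @param labels numeric vector of 0/1 labels.
#' @return numeric(1), non-negative.
#' @export
bceLoss <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length")
  p <- pmin(pmax(predictions, 1e-7), 1 - 1e-7)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' MLP backward pass: combined softmax + cross-entropy gradient.
#' Returns the parameter gradients and the gradient w.r.t. the input rows.
#' @keywords internal
.mlpBackwardBatch <- function(fw, params, labels) {
  n <- length(labels)
  Y <- cbind(1 - labels, labels)
  dA <- (fw$P - Y) / n
  nl <- length(params)
  grads <- vector("list", nl)
  for (i in rev(seq_len(nl))) {
    Ain <- fw$acts[[i]]
    grads[[i]] <- list(W = crossprod(Ain, dA), b = colSums(dA))
    dA <- dA %*% t(params[[i]]$W)
    if (i > 1L) dA <- dA * (Ain > 0)
  }
  list(grads = grads, dX = dA)
}

#' Predict the interaction probability of a drug pair
#'
#' Encodes both drugs, concatenates their embeddings and applies the
#' classifier. Because interaction is symmetric while concatenation is
#' ordered, the default symmetrizes by averaging the probabilities of both
#' orientations, making the prediction invariant under argument swap.
#'
#' @param graphX,graphY [MolecularGraph-class] objects.
#' @param model a [DDIModel-class] checkpoint.
#' @param symmetrize logical; average over both pair orientations (default
#'   taken from the model configuration, `TRUE` if unset).
#' @return numeric(1) interaction probability.
#' @export
predictPair <- function(graphX, graphY, model, symmetrize = NULL) {
  cfg <- model@config
  if (is.null(symmetrize))
    symmetrize <- if (is.null(cfg$symmetrize)) TRUE else cfg$symmetrize
  enc <- encoderConfigFromModel(model)
  zx <- embeddingVector(encodeDrug(graphX, model@encoder, enc))
  zy <- embeddingVector(encodeDrug(graphY, model@encoder, enc))
  pxy <- mlpForward(pairFeatures(zx, zy), model@mlp)
  if (!symmetrize) return(unname(pxy))
  pyx <- mlpForward(pairFeatures(zy, zx), model@mlp)
  unname((pxy + pyx) / 2)
}

#' Extract the encoder configuration stored in a model checkpoint.
#' @keywords internal
encoderConfigFromModel <- function(model) {
  cfg <- model@config
  encoderConfig(numLayers = cfg$numLayers, heads = cfg$heads,
                headDim = cfg$headDim, leakyReluSlope = cfg$leakyReluSlope,
                seed = if (is.null(cfg$seed)) 1L else cfg$seed)
}
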