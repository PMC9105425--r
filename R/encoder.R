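# Multi-layer multi-head graph-attention encoder with a per-layer
# attention-pooled readout and k-hop concatenation.
#
# All tensors are dense per-molecule matrices: drug molecular graphs are
# small (tens of atoms), so dense masked attention is both simple and fast.

#' Encoder configuration
#'
#' @param numLayers number of graph-attention layers (the receptive field in
#'   bond hops); default 5.
#' @param heads number of attention heads per layer; default 2.
#' @param headDim output dimension of each head; default 32, so each layer
#'   emits `heads * headDim` = 64 features per atom and the concatenated
#'   drug embedding has length `numLayers * heads * headDim` = 320.
#' @param leakyReluSlope negative slope of the LeakyReLU in the attention
#'   logits; default 0.2.
#' @param seed integer seed used for parameter initialization.
#' @return a list with the validated settings.
#' @export
encoderConfig <- function(numLayers = 5L, heads = 2L, headDim = 32L,
                          leakyReluSlope = 0.2, seed = 1L) {
  stopifnot(numLayers >= 1L, heads >= 1L, headDim >= 1L)
  list(numLayers = as.integer(numLayers), heads = as.integer(heads),
       headDim = as.integer(headDim), leakyReluSlope = leakyReluSlope,
       seed = as.integer(seed))
}

#' Initialize encoder parameters (Glorot-uniform, seeded)
#'
#' @param config list from [encoderConfig()].
#' @param inputDim width of the atom feature rows entering layer 1.
#' @return nested parameter list: per layer, `heads` (each with projection
#'   `W` and attention vector halves `a1`, `a2`) and the pooling scorer
#'   (`theta`, `b`).
#' @export
initEncoderParams <- function(config, inputDim = 78L) {
  withr::with_seed(config$seed, {
    layerDim <- config$heads * config$headDim
    dims <- c(inputDim, rep(layerDim, config$numLayers - 1L))
    layers <- lapply(seq_len(config$numLayers), function(k) {
      d <- dims[k]
      heads <- lapply(seq_len(config$heads), function(l) {
        list(W = .glorot(d, config$headDim),
             a1 = stats::runif(config$headDim, -sqrt(6 / (2 * config$headDim + 1)),
                               sqrt(6 / (2 * config$headDim + 1))),
             a2 = stats::runif(config$headDim, -sqrt(6 / (2 * config$headDim + 1)),
                               sqrt(6 / (2 * config$headDim + 1))))
      })
      score <- list(theta = drop(.glorot(layerDim, 1L)), b = 0)
      list(heads = heads, score = score)
    })
    list(layers = layers)
  })
}

#' Dense helper matrices for one molecular graph
#'
#' `mask` is the neighbor indicator (no self loops; attention softmaxes run
#' over it) and `anorm` the symmetrically normalized adjacency with self
#' loops used by the pooling scorer.
#' @keywords internal
.graphMats <- function(graph) {
  H0 <- atomFeatures(graph)
  p <- nrow(H0)
  e <- graphEdges(graph)
  A <- matrix(0, p, p)
  if (nrow(e)) {
    A[e + 1L] <- 1
    A[e[, 2:1, drop = FALSE] + 1L] <- 1
  }
  Ahat <- A + diag(p)
  dinv <- 1 / sqrt(rowSums(Ahat))
  anorm <- Ahat * tcrossprod(dinv)
  list(H0 = H0, mask = A > 0, anorm = anorm, p = p,
       drugId = drugId(graph), elements = atomElements(graph))
}

#' Attention logit between two atoms
#'
#' `e_ij = LeakyReLU( a' [W h_i || W h_j] )` where the attention vector `a`
#' is split into its two halves `a1`, `a2`.
#'
#' @param hi,hj numeric input feature vectors of atoms i and j.
#' @param W projection matrix (input dim x head dim).
#' @param a attention vector of length `2 * headDim`.
#' @param slope LeakyReLU negative slope.
#' @return numeric(1).
#' @export
attentionLogit <- function(hi, hj, W, a, slope = 0.2) {
  if (length(hi) != nrow(W) || length(hj) != nrow(W))
    stop("input vectors do not match the projection's input dimension")
  if (length(a) != 2L * ncol(W))
    stop("attention vector must have length 2 * headDim")
  ui <- drop(crossprod(W, hi))
  uj <- drop(crossprod(W, hj))
  .leakyRelu(sum(a * c(ui, uj)), slope)
}

#' Attention coefficients over a neighborhood
#'
#' Softmax of the attention logits, numerically stabilized by maximum
#' subtraction. An empty neighborhood yields a zero-length vector (the
#' encoder then keeps only the atom's self term).
#'
#' @param logits numeric vector of attention logits over the neighborhood.
#' @return numeric vector of non-negative weights summing to 1 (or
#'   `numeric(0)` for an empty neighborhood).
#' @export
attentionCoefficients <- function(logits) {
  .softmax(logits)
}

#' Masked row-wise softmax; rows with no neighbors become all-zero.
#' @keywords internal
.maskedSoftmax <- function(E, mask) {
  Em <- E
  Em[!mask] <- -Inf
  rmax <- Em[cbind(seq_len(nrow(Em)), max.col(Em, ties.method = "first"))]
  W <- exp(Em - rmax)
  W[is.nan(W)] <- 0          # rows with no neighbors
  rs <- rowSums(W)
  W / pmax(rs, .Machine$double.xmin)
}

#' One head of one attention layer (forward).
#' @keywords internal
.headForward <- function(H, mask, head, slope) {
  U <- H %*% head$W
  f <- drop(U %*% head$a1)
  g <- drop(U %*% head$a2)
  Zl <- outer(f, g, function(x, y) x + y)   # Zl[i, j] = f_i + g_j
  E <- .leakyRelu(Zl, slope)
  A <- .maskedSoftmax(E, mask)
  S <- A %*% U + U
  list(U = U, Zl = Zl, A = A, S = S, out = .relu(S))
}

#' One graph-attention layer: multi-head aggregation and update
#'
#' Per head, each atom's representation is updated as
#' `h_i' = ReLU( sum_j alpha_ij W h_j + W h_i )` with attention weights
#' `alpha` over the atom's bonded neighbors; the head outputs are
#' concatenated.
#'
#' @param H numeric matrix of atom features (atoms x input dim).
#' @param graph a [MolecularGraph-class] (or prepared graph data).
#' @param params one layer's parameter list (`heads`).
#' @param config list from [encoderConfig()].
#' @return numeric matrix (atoms x heads*headDim).
#' @export
layerForward <- function(H, graph, params, config = encoderConfig()) {
  gd <- if (is(graph, "MolecularGraph")) .graphMats(graph) else graph
  if (nrow(H) != gd$p) stop("feature row count does not match atom count")
  outs <- lapply(params$heads, function(head) {
    if (nrow(head$W) != ncol(H))
      stop("layer parameters do not match the input dimension")
    .headForward(H, gd$mask, head, config$leakyReluSlope)$out
  })
  do.call(cbind, outs)
}

#' Attention-pooled graph readout
#'
#' A one-channel graph-convolution scorer assigns each atom a scalar score
#' from its own and its neighbors' features; the softmax of the scores gives
#' per-atom weights `gamma` (summing to 1), and the pooled graph vector is
#' the gamma-weighted sum of the atom features. The weights are retained for
#' interpretability.
#'
#' @param H numeric matrix of atom features (atoms x dim).
#' @param graph a [MolecularGraph-class] (or prepared graph data).
#' @param scoreParams list with `theta` (length dim) and scalar `b`.
#' @return list with `pooled` (numeric vector of length dim) and `weights`
#'   (numeric vector over atoms, summing to 1).
#' @export
sagReadout <- function(H, graph, scoreParams) {
  gd <- if (is(graph, "MolecularGraph")) .graphMats(graph) else graph
  if (nrow(H) != gd$p) stop("feature row count does not match atom count")
  q <- drop(gd$anorm %*% (H %*% scoreParams$theta)) + scoreParams$b
  gamma <- .softmax(q)
  list(pooled = drop(crossprod(H, gamma)), weights = gamma, scores = q)
}

#' Full encoder forward pass over prepared graph data.
#'
#' Returns the per-layer pooled vectors, atom weights and (optionally) the
#' caches needed for backpropagation.
#' @keywords internal
.encodeForward <- function(gd, params, config, keepCache = FALSE) {
  K <- config$numLayers
  layerDim <- config$heads * config$headDim
  H <- gd$H0
  pooled <- matrix(0, K, layerDim)
  gammas <- matrix(0, K, gd$p)
  cache <- if (keepCache) vector("list", K) else NULL
  for (k in seq_len(K)) {
    lay <- params$layers[[k]]
    hc <- lapply(lay$heads, function(head)
      .headForward(H, gd$mask, head, config$leakyReluSlope))
    Hout <- do.call(cbind, lapply(hc, `[[`, "out"))
    ro <- sagReadout(Hout, gd, lay$score)
    pooled[k, ] <- ro$pooled
    gammas[k, ] <- ro$weights
    if (keepCache) cache[[k]] <- list(Hin = H, heads = hc, Hout = Hout, ro = ro)
    H <- Hout
  }
  list(pooled = pooled, gammas = gammas, z = as.vector(t(pooled)),
       cache = cache)
}

#' Encode a drug's molecular graph into its k-hop embedding
#'
#' Runs the multi-layer attention encoder and concatenates the per-layer
#' pooled vectors into the drug embedding `Z` (length
#' `numLayers * heads * headDim`, 320 at defaults). The per-layer pooling
#' weights are retained in the result for attribution.
#'
#' @param graph a [MolecularGraph-class] object.
#' @param params encoder parameters from [initEncoderParams()] (or the
#'   `encoder` slot of a trained [DDIModel-class]).
#' @param config list from [encoderConfig()].
#' @return a [DrugEmbedding-class] object.
#' @examples
#' cfg <- encoderConfig(seed = 7)
#' par <- initEncoderParams(cfg)
#' emb <- encodeDrug(buildGraph("benzene", "c1ccccc1"), par, cfg)
#' length(embeddingVector(emb))  # 320
#' @export
encodeDrug <- function(graph, params, config = encoderConfig()) {
  gd <- .graphMats(graph)
  fw <- .encodeForward(gd, params, config)
  methods::new("DrugEmbedding",
    drugId = drugId(graph),
    layerVectors = fw$pooled,
    z = fw$z,
    atomWeights = fw$gammas
  )
}
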