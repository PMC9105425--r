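# Backpropagation through the encoder, the Adam optimizer, the training
# loop and checkpoint IO.

#' Backward pass through the encoder for one drug.
#'
#' `gPooled` is the loss gradient w.r.t. the per-layer pooled vectors
#' (layers x layerDim). Returns a gradient tree with the same shape as the
#' encoder parameters.
#' @keywords internal
.encodeBackward <- function(gd, fw, params, config, gPooled) {
  K <- config$numLayers
  Fp <- config$headDim
  slope <- config$leakyReluSlope
  grads <- vector("list", K)
  layerDim <- config$heads * Fp
  gH <- matrix(0, gd$p, layerDim)   # gradient flowing into layer K's output
  for (k in rev(seq_len(K))) {
    ck <- fw$cache[[k]]
    lay <- params$layers[[k]]
    # --- readout backward: HG = Hout' gamma, q = anorm Hout theta + b
    gHG <- gPooled[k, ]
    gamma <- ck$ro$weights
    Hout <- ck$Hout
    gGamma <- drop(Hout %*% gHG)
    gH <- gH + outer(gamma, gHG)
    gq <- gamma * (gGamma - sum(gamma * gGamma))
    aq <- drop(gd$anorm %*% gq)               # anorm is symmetric
    gtheta <- drop(crossprod(Hout, aq))
    gb <- sum(gq)
    gH <- gH + outer(aq, lay$score$theta)
    # --- multi-head attention backward
    gHin <- NULL
    headGrads <- vector("list", config$heads)
    for (l in seq_len(config$heads)) {
      cols <- ((l - 1L) * Fp + 1L):(l * Fp)
      hc <- ck$heads[[l]]
      head <- lay$heads[[l]]
      gOut <- gH[, cols, drop = FALSE]
      gS <- gOut * (hc$S > 0)
      gU <- crossprod(hc$A, gS) + gS
      gA <- (gS %*% t(hc$U)) * gd$mask
      dE <- hc$A * (gA - rowSums(hc$A * gA))
      dZ <- dE * .leakyReluGrad(hc$Zl, slope)
      rr <- rowSums(dZ)
      cc <- colSums(dZ)
      ga1 <- drop(crossprod(hc$U, rr))
      ga2 <- drop(crossprod(hc$U, cc))
      gU <- gU + outer(rr, head$a1) + outer(cc, head$a2)
      headGrads[[l]] <- list(W = crossprod(ck$Hin, gU), a1 = ga1, a2 = ga2)
      gHinL <- gU %*% t(head$W)
      gHin <- if (is.null(gHin)) gHinL else gHin + gHinL
    }
    grads[[k]] <- list(heads = headGrads, score = list(theta = gtheta, b = gb))
    gH <- gHin
  }
  list(layers = grads)
}

#' Adam optimizer over a parameter tree.
#' @keywords internal
.adamInit <- function(params) {
  list(m = .treeZero(params), v = .treeZero(params), t = 0L)
}

#' @keywords internal
.adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .treeMap(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- .treeMap(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- .treeMap(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                     params, state$m, state$v)
  list(params = params, state = state)
}

#' Training configuration
#'
#' @param epochs number of passes over the training pairs (default 400; the
#'   desk-scale profile uses 50).
#' @param learningRate Adam step size (default 0.001).
#' @param batchSize mini-batch size in drug pairs (default 1024; the
#'   desk-scale profile uses 128).
#' @param seed integer seed controlling initialization and batch order.
#' @param symmetrize average both pair orientations at inference.
#' @param augmentSwapped also train on the swapped orientation of every pair.
#' @param verbose print per-epoch losses.
#' @return list of validated settings.
#' @export
trainConfig <- function(epochs = 400L, learningRate = 1e-3, batchSize = 1024L,
                        seed = 1L, symmetrize = TRUE, augmentSwapped = FALSE,
                        verbose = FALSE) {
  stopifnot(epochs >= 1L, learningRate > 0, batchSize >= 1L)
  list(epochs = as.integer(epochs), learningRate = learningRate,
       batchSize = as.integer(batchSize), seed = as.integer(seed),
       symmetrize = isTRUE(symmetrize), augmentSwapped = isTRUE(augmentSwapped),
       verbose = isTRUE(verbose))
}

#' Encode a set of drugs and score labeled pairs (no caches kept).
#' @keywords internal
.scorePairs <- function(gds, encParams, mlpParams, config, pairs) {
  ids <- unique(c(pairs$drug_x, pairs$drug_y))
  Z <- lapply(gds[ids], function(gd) .encodeForward(gd, encParams, config)$z)
  X <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    c(Z[[pairs$drug_x[i]]], Z[[pairs$drug_y[i]]])))
  .mlpForwardBatch(X, mlpParams)$probs
}

#' Train the drug-pair interaction model
#'
#' Mini-batch Adam on the binary cross-entropy of the pair classifier, with
#' gradients backpropagated through the pair MLP into the graph-attention
#' encoder. After every epoch the validation loss is evaluated and the best
#' parameter set is retained (checkpoint selection); training always runs
#' for the configured number of epochs.
#'
#' @param graphs named list of [MolecularGraph-class] objects covering every
#'   drug referenced by the pairs.
#' @param trainPairs,valPairs data.frames with columns `drug_x`, `drug_y`,
#'   `label` (0/1).
#' @param encConfig list from [encoderConfig()].
#' @param fitConfig list from [trainConfig()].
#' @param hidden hidden layer sizes of the pair classifier.
#' @return a [DDIModel-class] holding the selected parameters, the full
#'   configuration and the per-epoch loss history (`config$history`).
#' @export
trainModel <- function(graphs, trainPairs, valPairs = NULL,
                       encConfig = encoderConfig(),
                       fitConfig = trainConfig(),
                       hidden = c(128L, 64L, 32L)) {
  stopifnot(all(c("drug_x", "drug_y", "label") %in% names(trainPairs)))
  gds <- lapply(graphs, .graphMats)
  layerDim <- encConfig$heads * encConfig$headDim
  zLen <- encConfig$numLayers * layerDim
  if (isTRUE(fitConfig$augmentSwapped)) {
    sw <- trainPairs
    names(sw)[match(c("drug_x", "drug_y"), names(sw))] <- c("drug_y", "drug_x")
    trainPairs <- rbind(trainPairs, sw[names(trainPairs)])
  }
  encCfg <- encConfig
  encCfg$seed <- fitConfig$seed
  params <- list(
    encoder = initEncoderParams(encCfg, inputDim = .ATOM_FEATURE_DIM),
    mlp = initMlpParams(inputDim = 2L * zLen, hidden = hidden,
                        seed = fitConfig$seed + 1L)
  )
  state <- .adamInit(params)
  n <- nrow(trainPairs)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(params = params, valLoss = Inf)
  withr::with_seed(fitConfig$seed, {
    for (epoch in seq_len(fitConfig$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = fitConfig$batchSize)
      epochLoss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + fitConfig$batchSize - 1L, n)]
        batch <- trainPairs[idx, ]
        ids <- unique(c(batch$drug_x, batch$drug_y))
        fws <- lapply(gds[ids], .encodeForward, params = params$encoder,
                      config = encCfg, keepCache = TRUE)
        X <- do.call(rbind, lapply(seq_len(nrow(batch)), function(i)
          c(fws[[batch$drug_x[i]]]$z, fws[[batch$drug_y[i]]]$z)))
        fwm <- .mlpForwardBatch(X, params$mlp)
        epochLoss <- epochLoss + bceLoss(fwm$probs, batch$label) * length(idx)
        bw <- .mlpBackwardBatch(fwm, params$mlp, batch$label)
        # accumulate embedding gradients per drug over the batch
        gz <- lapply(ids, function(id) numeric(zLen))
        names(gz) <- ids
        for (i in seq_len(nrow(batch))) {
          gz[[batch$drug_x[i]]] <- gz[[batch$drug_x[i]]] + bw$dX[i, 1:zLen]
          gz[[batch$drug_y[i]]] <- gz[[batch$drug_y[i]]] +
            bw$dX[i, (zLen + 1L):(2L * zLen)]
        }
        encGrads <- NULL
        for (id in ids) {
          gPooled <- matrix(gz[[id]], encCfg$numLayers, layerDim, byrow = TRUE)
          g <- .encodeBackward(gds[[id]], fws[[id]], params$encoder, encCfg,
                               gPooled)
          encGrads <- if (is.null(encGrads)) g else .treeAdd(encGrads, g)
        }
        upd <- .adamStep(params, list(encoder = encGrads, mlp = bw$grads),
                         state, lr = fitConfig$learningRate)
        params <- upd$params
        state <- upd$state
      }
      trainLoss <- epochLoss / n
      valLoss <- NA_real_
      if (!is.null(valPairs) && nrow(valPairs) > 0) {
        vp <- .scorePairs(gds, params$encoder, params$mlp, encCfg, valPairs)
        valLoss <- bceLoss(vp, valPairs$label)
        if (valLoss < best$valLoss)
          best <- list(params = params, valLoss = valLoss)
      }
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = trainLoss,
                                           val_loss = valLoss))
      if (fitConfig$verbose)
        message(sprintf("epoch %3d  train %.4f  val %s", epoch, trainLoss,
                        ifelse(is.na(valLoss), "-", sprintf("%.4f", valLoss))))
    }
  })
  final <- if (is.finite(best$valLoss)) best$params else params
  cfg <- c(encCfg, list(hidden = hidden, symmetrize = fitConfig$symmetrize,
                        augmentSwapped = fitConfig$augmentSwapped,
                        fit = fitConfig, history = history,
                        bestValLoss = best$valLoss))
  methods::new("DDIModel", encoder = final$encoder, mlp = final$mlp,
               config = cfg, version = "1")
}

#' Score many labeled pairs with a trained model
#'
#' Encodes each distinct drug once and applies the classifier to every pair;
#' with `symmetrize` (the model default) both orientations are averaged.
#'
#' @param model a [DDIModel-class].
#' @param graphs named list of [MolecularGraph-class] objects.
#' @param pairs data.frame with columns `drug_x`, `drug_y`.
#' @return numeric vector of interaction probabilities, one per row.
#' @export
predictPairs <- function(model, graphs, pairs) {
  enc <- encoderConfigFromModel(model)
  gds <- lapply(graphs, .graphMats)
  ids <- unique(c(pairs$drug_x, pairs$drug_y))
  missing <- setdiff(ids, names(gds))
  if (length(missing))
    stop("no molecular graph for drug(s): ", paste(missing, collapse = ", "))
  Z <- lapply(gds[ids], function(gd) .encodeForward(gd, model@encoder, enc)$z)
  X <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    c(Z[[pairs$drug_x[i]]], Z[[pairs$drug_y[i]]])))
  p <- .mlpForwardBatch(X, model@mlp)$probs
  sym <- if (is.null(model@config$symmetrize)) TRUE else model@config$symmetrize
  if (sym) {
    Xs <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
      c(Z[[pairs$drug_y[i]]], Z[[pairs$drug_x[i]]])))
    p <- (p + .mlpForwardBatch(Xs, model@mlp)$probs) / 2
  }
  unname(p)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single versioned RDS file carrying the encoder and
#' classifier parameters plus the full configuration (echoed for
#' reproducibility).
#'
#' @param model a [DDIModel-class].
#' @param path file path.
#' @return `loadCheckpoint` returns the [DDIModel-class].
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(version = model@version, encoder = model@encoder,
               mlp = model@mlp, config = model@config), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  if (is.null(x$version))
    stop("not a gatddi checkpoint: ", path)
  methods::new("DDIModel", encoder = x$encoder, mlp = x$mlp,
               config = x$config, version = x$version)
}
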