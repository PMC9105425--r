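test_that("pair features are an ordered concatenation", {
  zx <- rnorm(320); zy <- rnorm(320)
  f <- pairFeatures(zx, zy)
  expect_length(f, 640L)
  expect_equal(f[1:320], zx)
  expect_equal(f[321:640], zy)
  # swapping the inputs exchanges the halves exactly
  fs <- pairFeatures(zy, zx)
  expect_equal(fs, c(f[321:640], f[1:320]))
  expect_equal(pairFeatures(rep(0, 5), rep(0, 5)), rep(0, 10))
  expect_error(pairFeatures(zx, zy[1:10]), "equal length")
})

test_that("classifier forward pass is a softmax-headed ReLU stack", {
  par <- initMlpParams(inputDim = 8, hidden = c(5, 4, 3), seed = 2)
  expect_equal(nrow(par[[1]]$W), 8L)
  # all-zero parameters: softmax over (0, 0) gives probability one half
  zpar <- lapply(par, function(l) list(W = l$W * 0, b = l$b * 0))
  expect_equal(mlpForward(rnorm(8), zpar), 0.5)
  # probabilities always lie in [0, 1]
  set.seed(1)
  X <- matrix(rnorm(50 * 8, sd = 5), 50)
  p <- mlpForward(X, par)
  expect_true(all(p >= 0 & p <= 1))
  # random small net against a hand-rolled dense forward pass
  x <- rnorm(8)
  a <- x
  for (i in 1:3) a <- pmax(as.numeric(a %*% par[[i]]$W) + par[[i]]$b, 0)
  o <- as.numeric(a %*% par[[4]]$W) + par[[4]]$b
  expect_equal(mlpForward(x, par), exp(o[2]) / sum(exp(o)))
  expect_error(mlpForward(rnorm(5), par), "input layer")
})

test_that("binary cross-entropy matches hand-computed values", {
  expect_equal(bceLoss(rep(0.5, 10), rep(c(0, 1), 5)), log(2))
  expect_lt(bceLoss(c(0, 1, 1, 0), c(0, 1, 1, 0)), 1e-5)
  expect_equal(bceLoss(c(0.9, 0.2), c(1, 0)),
               mean(c(-log(0.9), -log(0.8))))
  expect_gte(bceLoss(runif(5), rbinom(5, 1, 0.5)), 0)
})

test_that("gradients of loss through classifier and encoder match finite differences", {
  cfg <- encoderConfig(numLayers = 2, heads = 2, headDim = 3, seed = 42)
  graphs <- list(a = buildGraph("a", "OC(=O)C"), b = buildGraph("b", "CCN"))
  gds <- lapply(graphs, gatddi:::.graphMats)
  enc <- initEncoderParams(cfg, 78)
  mlp <- initMlpParams(inputDim = 24, hidden = c(5, 4, 3), seed = 7)
  pairs <- data.frame(drug_x = c("a", "b"), drug_y = c("b", "a"),
                      label = c(1, 0), stringsAsFactors = FALSE)
  zLen <- 12L
  lossAt <- function(enc, mlp) {
    Z <- lapply(gds, function(gd) gatddi:::.encodeForward(gd, enc, cfg)$z)
    X <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
      c(Z[[pairs$drug_x[i]]], Z[[pairs$drug_y[i]]])))
    fw <- gatddi:::.mlpForwardBatch(X, mlp)
    bceLoss(fw$probs, pairs$label)
  }
  fws <- lapply(gds, gatddi:::.encodeForward, params = enc, config = cfg,
                keepCache = TRUE)
  X <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    c(fws[[pairs$drug_x[i]]]$z, fws[[pairs$drug_y[i]]]$z)))
  fwm <- gatddi:::.mlpForwardBatch(X, mlp)
  bw <- gatddi:::.mlpBackwardBatch(fwm, mlp, pairs$label)
  gz <- list(a = numeric(zLen), b = numeric(zLen))
  for (i in seq_len(nrow(pairs))) {
    gz[[pairs$drug_x[i]]] <- gz[[pairs$drug_x[i]]] + bw$dX[i, 1:zLen]
    gz[[pairs$drug_y[i]]] <- gz[[pairs$drug_y[i]]] + bw$dX[i, zLen + 1:zLen]
  }
  encG <- NULL
  for (id in names(gds)) {
    g <- gatddi:::.encodeBackward(gds[[id]], fws[[id]], enc, cfg,
                                  matrix(gz[[id]], 2, 6, byrow = TRUE))
    encG <- if (is.null(encG)) g else gatddi:::.treeAdd(encG, g)
  }
  eps <- 1e-6
  relErr <- function(num, ana) abs(num - ana) / max(1e-7, abs(num) + abs(ana))
  set.seed(5)
  for (k in 1:2) for (l in 1:2) for (nm in c("W", "a1", "a2")) {
    x <- enc$layers[[k]]$heads[[l]][[nm]]
    for (t in 1:3) {
      i <- sample(length(x), 1)
      ep <- enc; ep$layers[[k]]$heads[[l]][[nm]][i] <- x[i] + eps
      em <- enc; em$layers[[k]]$heads[[l]][[nm]][i] <- x[i] - eps
      num <- (lossAt(ep, mlp) - lossAt(em, mlp)) / (2 * eps)
      expect_lt(relErr(num, encG$layers[[k]]$heads[[l]][[nm]][i]), 1e-4)
    }
  }
  for (k in 1:2) {
    x <- enc$layers[[k]]$score$theta
    i <- sample(length(x), 1)
    ep <- enc; ep$layers[[k]]$score$theta[i] <- x[i] + eps
    em <- enc; em$layers[[k]]$score$theta[i] <- x[i] - eps
    num <- (lossAt(ep, mlp) - lossAt(em, mlp)) / (2 * eps)
    expect_lt(relErr(num, encG$layers[[k]]$score$theta[i]), 1e-4)
  }
  for (li in 1:4) for (nm in c("W", "b")) {
    x <- mlp[[li]][[nm]]
    i <- sample(length(x), 1)
    mp <- mlp; mp[[li]][[nm]][i] <- x[i] + eps
    mm <- mlp; mm[[li]][[nm]][i] <- x[i] - eps
    num <- (lossAt(enc, mp) - lossAt(enc, mm)) / (2 * eps)
    expect_lt(relErr(num, bw$grads[[li]][[nm]][i]), 1e-4)
  }
})

test_that("pair prediction is symmetric and deterministic", {
  fix <- tinyPairFixture()
  graphs <- buildGraphs(fix$drugs)
  m <- trainModel(graphs, fix$pairs, valPairs = NULL,
                  encConfig = encoderConfig(numLayers = 2, headDim = 4, seed = 3),
                  fitConfig = trainConfig(epochs = 2, batchSize = 8, seed = 3))
  p1 <- predictPair(graphs$acid1, graphs$amine1, m)
  p2 <- predictPair(graphs$amine1, graphs$acid1, m)
  expect_identical(p1, p2)
  expect_gte(p1, 0); expect_lte(p1, 1)
  # self pair: both orientations coincide, mean equals either
  pf <- predictPair(graphs$acid1, graphs$acid1, m, symmetrize = FALSE)
  ps <- predictPair(graphs$acid1, graphs$acid1, m, symmetrize = TRUE)
  expect_equal(pf, ps)
  # deterministic under a fixed checkpoint
  expect_identical(p1, predictPair(graphs$acid1, graphs$amine1, m))
})

test_that("training reduces the loss on a small separable set", {
  fix <- tinyPairFixture()
  graphs <- buildGraphs(fix$drugs)
  m <- trainModel(graphs, fix$pairs, valPairs = fix$pairs,
                  encConfig = encoderConfig(numLayers = 2, headDim = 8, seed = 1),
                  fitConfig = trainConfig(epochs = 12, batchSize = 16, seed = 1))
  h <- m@config$history
  expect_lt(mean(tail(h$train_loss, 3)), mean(head(h$train_loss, 3)))
  expect_lt(min(h$val_loss), log(2))   # better than chance
})

test_that("checkpoints round-trip through save and load", {
  fix <- tinyPairFixture()
  graphs <- buildGraphs(fix$drugs)
  m <- trainModel(graphs, fix$pairs,
                  encConfig = encoderConfig(numLayers = 1, headDim = 4, seed = 8),
                  fitConfig = trainConfig(epochs = 1, batchSize = 16, seed = 8))
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(m, f)
  m2 <- loadCheckpoint(f)
  expect_identical(m2@encoder, m@encoder)
  expect_identical(m2@mlp, m@mlp)
  expect_identical(predictPair(graphs$acid1, graphs$amine2, m2),
                   predictPair(graphs$acid1, graphs$amine2, m))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(foo = 1), bad)
  expect_error(loadCheckpoint(bad), "checkpoint")
})
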