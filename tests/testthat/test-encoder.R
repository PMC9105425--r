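test_that("attention logits follow the concatenated-projection form", {
  set.seed(3)
  W <- matrix(rnorm(12), 4, 3)
  hi <- rnorm(4); hj <- rnorm(4)
  # zero attention vector annihilates the logit
  expect_equal(attentionLogit(hi, hj, W, rep(0, 6)), 0)
  # antisymmetric halves cancel when both atoms share features
  a1 <- rnorm(3)
  expect_equal(attentionLogit(hi, hi, W, c(a1, -a1)), 0)
  # random instance against a direct dense computation
  a <- rnorm(6)
  u <- function(h) as.numeric(t(W) %*% h)
  z <- sum(a * c(u(hi), u(hj)))
  expect_equal(attentionLogit(hi, hj, W, a, slope = 0.2),
               if (z > 0) z else 0.2 * z)
  expect_error(attentionLogit(hi[1:2], hj, W, a), "dimension")
})

test_that("attention coefficients are a proper softmax", {
  expect_equal(attentionCoefficients(5), 1)
  expect_equal(attentionCoefficients(c(2, 2)), c(0.5, 0.5))
  expect_equal(attentionCoefficients(c(0, log(3))), c(0.25, 0.75))
  # extreme logits stay finite (max-subtraction stabilization)
  expect_equal(sum(attentionCoefficients(c(1000, 1001, 999))), 1)
  expect_length(attentionCoefficients(numeric(0)), 0)
})

test_that("layer update handles self terms, isolated atoms and hand cases", {
  cfg <- encoderConfig(numLayers = 1, heads = 1, headDim = 3)
  # isolated atom: only the self term survives
  g1 <- buildGraph("m", "C")
  W <- matrix(rnorm(78 * 3), 78, 3)
  par <- list(heads = list(list(W = W, a1 = rnorm(3), a2 = rnorm(3))))
  H <- atomFeatures(g1)
  expect_equal(as.numeric(layerForward(H, g1, par, cfg)),
               pmax(as.numeric(t(W) %*% H[1, ]), 0))
  # two bonded atoms with equal features and zero attention: ReLU(2 Wh)
  g2 <- buildGraph("e", "CC")
  H2 <- atomFeatures(g2)
  par2 <- list(heads = list(list(W = W, a1 = rep(0, 3), a2 = rep(0, 3))))
  out <- layerForward(H2, g2, par2, cfg)
  expect_equal(out[1, ], pmax(2 * as.numeric(t(W) %*% H2[1, ]), 0))
})

test_that("layer update and pooled readout match naive dense oracles", {
  cfg <- encoderConfig(numLayers = 1, heads = 2, headDim = 5, seed = 11)
  small <- fixtureGraphs()[c("methane", "ethane", "benzene", "acetic",
                             "pyrrole", "phenol")]
  for (g in small) {
    expect_lte(numAtoms(g), 8L)
    par <- initEncoderParams(cfg, inputDim = 78L)$layers[[1]]
    H <- atomFeatures(g)
    expect_equal(layerForward(H, g, par, cfg),
                 naiveLayerForward(H, g, par, slope = cfg$leakyReluSlope),
                 tolerance = 1e-5)
    Hout <- layerForward(H, g, par, cfg)
    ro <- sagReadout(Hout, g, par$score)
    nro <- naiveReadout(Hout, g, par$score)
    expect_equal(ro$pooled, nro$pooled, tolerance = 1e-5)
    expect_equal(ro$weights, nro$weights, tolerance = 1e-5)
  }
})

test_that("readout weights are a distribution and trivial cases pool exactly", {
  # single atom: weight 1, pooled vector is the atom's features
  g <- buildGraph("m", "C")
  H <- atomFeatures(g)
  ro <- sagReadout(H, g, list(theta = rnorm(78), b = 0.3))
  expect_equal(ro$weights, 1)
  expect_equal(ro$pooled, as.numeric(H[1, ]))
  # symmetric two-atom molecule: equal weights
  g2 <- buildGraph("e", "CC")
  ro2 <- sagReadout(atomFeatures(g2), g2, list(theta = rnorm(78), b = 0))
  expect_equal(ro2$weights, c(0.5, 0.5))
})

test_that("drug encoding has the documented shape chain and retains weights", {
  cfg <- encoderConfig(seed = 5)
  par <- initEncoderParams(cfg)
  g <- buildGraph("phenol", "c1ccccc1O")
  emb <- encodeDrug(g, par, cfg)
  expect_equal(dim(layerVectors(emb)), c(5L, 64L))
  expect_length(embeddingVector(emb), 320L)
  expect_equal(unname(rowSums(atomWeights(emb))), rep(1, 5), tolerance = 1e-12)
  expect_equal(embeddingVector(emb)[1:64], layerVectors(emb)[1, ])
  # K = 1: the embedding is exactly the single pooled vector
  cfg1 <- encoderConfig(numLayers = 1, seed = 5)
  emb1 <- encodeDrug(g, initEncoderParams(cfg1), cfg1)
  expect_equal(embeddingVector(emb1), layerVectors(emb1)[1, ])
})

test_that("attention rows sum to one over neighborhoods at every layer", {
  cfg <- encoderConfig(seed = 2)
  par <- initEncoderParams(cfg)
  for (g in fixtureGraphs()) {
    gd <- gatddi:::.graphMats(g)
    fw <- gatddi:::.encodeForward(gd, par, cfg, keepCache = TRUE)
    for (k in seq_len(cfg$numLayers)) {
      for (hc in fw$cache[[k]]$heads) {
        rs <- rowSums(hc$A)
        hasNb <- rowSums(gd$mask) > 0
        expect_equal(unname(rs[hasNb]), rep(1, sum(hasNb)), tolerance = 1e-12)
        expect_equal(unname(rs[!hasNb]), rep(0, sum(!hasNb)))
        expect_true(all(hc$A >= 0))
      }
    }
  }
})

test_that("drug encoding is invariant to atom relabeling", {
  cfg <- encoderConfig(seed = 9)
  par <- initEncoderParams(cfg)
  g <- buildGraph("asp", "CC(=O)Oc1ccccc1C(=O)O")
  emb <- encodeDrug(g, par, cfg)
  set.seed(42)
  for (rep in 1:3) {
    perm <- sample(numAtoms(g))          # new position of each old atom
    inv <- order(perm)
    e <- graphEdges(g)
    gp <- methods::new("MolecularGraph", drugId = "asp-perm",
                       smiles = g@smiles,
                       atomFeatures = atomFeatures(g)[inv, , drop = FALSE],
                       edges = matrix(c(perm[e[, 1] + 1L] - 1L,
                                        perm[e[, 2] + 1L] - 1L), ncol = 2),
                       elements = atomElements(g)[inv])
    embp <- encodeDrug(gp, par, cfg)
    expect_equal(embeddingVector(embp), embeddingVector(emb),
                 tolerance = 1e-10)
    expect_equal(atomWeights(embp)[, perm], atomWeights(emb),
                 tolerance = 1e-10)
  }
})
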