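# A small synthetic dataset used throughout the protocol tests.
protoData <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gs <- generatorSpec(nDrugs = 24L, seed = 77L)
      lib <- makeDrugLibrary(gs)
      cache <<- makeDdiDataset(lib, gs)$dataset
    }
    cache
  }
})

test_that("edge partition is a disjoint 75/5/20 cover of the positives", {
  ds <- protoData()
  n <- nrow(positivePairs(ds))
  sp <- splitSpec("edge_partition", seed = 4)
  s <- edgePartitionSplit(ds, sp)
  expect_equal(nrow(s$test), round(0.20 * n))
  expect_equal(nrow(s$val), round(0.05 * n))
  expect_equal(nrow(s$train) + nrow(s$val) + nrow(s$test), n)
  keys <- c(gatddi:::.pairKey(s$train$drug_a, s$train$drug_b),
            gatddi:::.pairKey(s$val$drug_a, s$val$drug_b),
            gatddi:::.pairKey(s$test$drug_a, s$test$drug_b))
  expect_equal(sort(keys),
               sort(gatddi:::.pairKey(positivePairs(ds)$drug_a,
                                      positivePairs(ds)$drug_b)))
  # same seed reproduces the split exactly; different seed differs
  s2 <- edgePartitionSplit(ds, sp)
  expect_identical(s, s2)
  s3 <- edgePartitionSplit(ds, splitSpec("edge_partition", seed = 5))
  expect_false(identical(s$test, s3$test))
})

test_that("a 100-edge toy set splits 75/5/20", {
  drugs <- data.frame(drug_id = sprintf("t%02d", 1:30),
                      smiles = rep("CC", 30), stringsAsFactors = FALSE)
  cmb <- t(combn(drugs$drug_id, 2))[1:100, ]
  ds <- ddiDataset(drugs, data.frame(drug_a = cmb[, 1], drug_b = cmb[, 2],
                                     stringsAsFactors = FALSE))
  s <- edgePartitionSplit(ds, splitSpec("edge_partition", seed = 1))
  expect_equal(c(nrow(s$train), nrow(s$val), nrow(s$test)), c(75L, 5L, 20L))
  tiny <- ddiDataset(drugs, data.frame(drug_a = cmb[1:4, 1],
                                       drug_b = cmb[1:4, 2]))
  expect_error(edgePartitionSplit(tiny, splitSpec("edge_partition")),
               "at least 5")
})

test_that("drug partition holds out new drugs and discards new-new pairs", {
  ds <- protoData()
  sp <- splitSpec("drug_partition", seed = 11)
  s <- drugPartitionSplit(ds, sp)
  nd <- nrow(drugTable(ds))
  expect_equal(length(s$testDrugs), round(0.2 * nd))
  expect_equal(length(s$trainDrugs) + length(s$testDrugs), nd)
  # leakage guard: no held-out drug in any training or validation pair
  expect_false(any(c(s$train$drug_a, s$train$drug_b,
                     s$val$drug_a, s$val$drug_b) %in% s$testDrugs))
  # every test pair joins one training and one held-out drug
  expect_true(all(xor(s$test$drug_a %in% s$testDrugs,
                      s$test$drug_b %in% s$testDrugs)))
  # discarded pairs are exactly those between two held-out drugs
  nHeld <- sum(positivePairs(ds)$drug_a %in% s$testDrugs &
                 positivePairs(ds)$drug_b %in% s$testDrugs)
  expect_equal(nrow(s$train) + nrow(s$val) + nrow(s$test) + nHeld,
               nrow(positivePairs(ds)))
})

test_that("negative sampling is disjoint from positives, seeded, per-split eligible", {
  ds <- protoData()
  posKeys <- gatddi:::.pairKey(positivePairs(ds)$drug_a,
                               positivePairs(ds)$drug_b)
  for (strat in c("edge_partition", "drug_partition")) {
    s <- splitDataset(ds, splitSpec(strat, seed = 3))
    lab <- sampleNegatives(ds, s, ratio = 1, seed = 9)
    for (part in names(lab)) {
      neg <- lab[[part]][lab[[part]]$label == 0, ]
      pos <- lab[[part]][lab[[part]]$label == 1, ]
      expect_equal(nrow(neg), nrow(pos))   # balanced 1:1
      expect_false(any(gatddi:::.pairKey(neg$drug_x, neg$drug_y) %in% posKeys))
      expect_false(any(neg$drug_x == neg$drug_y))
    }
    # disjoint across splits
    allNeg <- do.call(rbind, lapply(lab, function(d) d[d$label == 0, ]))
    expect_false(anyDuplicated(gatddi:::.pairKey(allNeg$drug_x,
                                                 allNeg$drug_y)) > 0)
    # determinism
    lab2 <- sampleNegatives(ds, s, ratio = 1, seed = 9)
    expect_identical(lab, lab2)
    if (strat == "drug_partition") {
      trainNeg <- lab$train[lab$train$label == 0, ]
      expect_true(all(c(trainNeg$drug_x, trainNeg$drug_y) %in% s$trainDrugs))
      testNeg <- lab$test[lab$test$label == 0, ]
      expect_true(all(xor(testNeg$drug_x %in% s$testDrugs,
                          testNeg$drug_y %in% s$testDrugs)))
    }
  }
  # impossible request errors out
  s <- splitDataset(ds, splitSpec("edge_partition", seed = 3))
  expect_error(sampleNegatives(ds, s, ratio = 1e6, seed = 1), "negatives")
})

test_that("confusion-count metrics reproduce their defining formulas", {
  # TP=8, FN=2, FP=2, TN=8 by construction at threshold 0.5
  labels <- c(rep(1, 10), rep(0, 10))
  probs <- c(rep(0.9, 8), rep(0.1, 2), rep(0.8, 2), rep(0.2, 8))
  m <- computeMetrics(labels, probs)
  expect_equal(m$TP, 8L); expect_equal(m$FN, 2L)
  expect_equal(m$FP, 2L); expect_equal(m$TN, 8L)
  expect_equal(m$ACC, 0.8)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$F1, 0.8)
  # F1 is the harmonic mean of precision and recall
  expect_equal(m$F1, 2 * m$precision * m$recall / (m$precision + m$recall))
  expect_error(computeMetrics(rep(1, 5), runif(5)), "negative")
  expect_error(computeMetrics(rep(0, 5), runif(5)), "positive")
})

test_that("perfectly separated scores give AUC and AUPR of 1", {
  labels <- rep(c(1, 0), each = 20)
  probs <- c(runif(20, 0.6, 1), runif(20, 0, 0.4))
  m <- computeMetrics(labels, probs)
  expect_equal(m$AUC, 1)
  expect_equal(m$AUPR, 1)
})

test_that("rank-based AUC equals the pairwise concordance oracle, with ties", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 50
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) %in% c(0, n)) labels[1:2] <- c(0, 1)
    # coarse grid forces ties between and within classes
    probs <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    m <- computeMetrics(labels, probs)
    expect_equal(m$AUC, naiveAUC(labels, probs))
  }
})

test_that("AUPR matches a direct step-integration on a worked example", {
  labels <- c(1, 0, 1, 0)
  probs <- c(0.9, 0.8, 0.7, 0.1)
  # descending: (1), (0), (1), (0) -> steps at recall 1/2 (prec 1) and 1 (prec 2/3)
  m <- computeMetrics(labels, probs)
  expect_equal(m$AUPR, 0.5 * 1 + 0.5 * (2 / 3))
})

test_that("split properties hold across many seeds", {
  ds <- protoData()
  n <- nrow(positivePairs(ds))
  allKeys <- sort(gatddi:::.pairKey(positivePairs(ds)$drug_a,
                                    positivePairs(ds)$drug_b))
  for (seed in 1:200) {
    s <- edgePartitionSplit(ds, splitSpec("edge_partition", seed = seed))
    keys <- c(gatddi:::.pairKey(s$train$drug_a, s$train$drug_b),
              gatddi:::.pairKey(s$val$drug_a, s$val$drug_b),
              gatddi:::.pairKey(s$test$drug_a, s$test$drug_b))
    expect_length(keys, n)
    expect_identical(sort(keys), allKeys)
    d <- drugPartitionSplit(ds, splitSpec("drug_partition", seed = seed))
    expect_false(any(c(d$train$drug_a, d$train$drug_b) %in% d$testDrugs))
  }
})

test_that("the experiment runner is deterministic and averages repeats", {
  fix <- tinyPairFixture()
  drugs <- fix$drugs
  gs <- generatorSpec(nDrugs = 20L, seed = 13L)
  lib <- makeDrugLibrary(gs)
  ds <- makeDdiDataset(lib, gs)$dataset
  graphs <- buildGraphs(drugTable(ds))
  enc <- encoderConfig(numLayers = 2, headDim = 4, seed = 1)
  fit <- trainConfig(epochs = 2, batchSize = 64, seed = 1)
  r1 <- runExperiment(ds, splitSpec("edge_partition", seed = 2), enc, fit,
                      repeats = 1L, graphs = graphs)
  expect_equal(unname(r1$mean["AUC"]), r1$perRepeat[[1]]$AUC)
  expect_true(all(is.na(r1$sd)))
  r2 <- runExperiment(ds, splitSpec("edge_partition", seed = 2), enc, fit,
                      repeats = 1L, graphs = graphs)
  expect_identical(r1$mean, r2$mean)
  expect_identical(r1$perRepeat, r2$perRepeat)
  r3 <- runExperiment(ds, splitSpec("edge_partition", seed = 2), enc, fit,
                      repeats = 2L, graphs = graphs)
  expect_equal(unname(r3$mean["AUC"]),
               mean(c(r3$perRepeat[[1]]$AUC, r3$perRepeat[[2]]$AUC)))
  expect_false(identical(r3$perRepeat[[1]]$AUC, r3$perRepeat[[2]]$AUC))
})

test_that("manifests, metrics JSON and predictions round-trip to disk", {
  ds <- protoData()
  s <- edgePartitionSplit(ds, splitSpec("edge_partition", seed = 6))
  lab <- sampleNegatives(ds, s, ratio = 1, seed = 6)
  f <- tempfile(fileext = ".tsv")
  writeSplitManifest(lab, f)
  back <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_setequal(unique(back$split), c("train", "val", "test"))
  expect_equal(nrow(back), sum(vapply(lab, nrow, integer(1))))

  res <- list(perRepeat = list(list(AUC = 0.9, ACC = 0.8)),
              mean = c(AUC = 0.9, ACC = 0.8), sd = c(AUC = NA, ACC = NA))
  fj <- tempfile(fileext = ".json")
  writeMetricsJson(res, fj)
  j <- jsonlite::fromJSON(fj)
  expect_equal(j$AUC$mean, 0.9)
  expect_equal(j$AUC$per_repeat, 0.9)

  fp <- tempfile(fileext = ".tsv")
  writePredictions(lab$test, runif(nrow(lab$test)), fp)
  pred <- read.table(fp, header = TRUE, sep = "\t")
  expect_equal(names(pred), c("drug_x", "drug_y", "probability"))
})
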