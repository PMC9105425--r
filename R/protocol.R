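# Dataset assembly, the two cross-validation strategies (warm-start edge
# partition and cold-start drug partition), negative sampling, the metric
# suite, and the repeated-experiment runner.

#' Construct a DDIDataset
#'
#' @param drugs data.frame with columns `drug_id`, `smiles`.
#' @param positives data.frame with columns `drug_a`, `drug_b` listing the
#'   known interacting pairs (unordered, each once, no self pairs).
#' @return a [DDIDataset-class] object.
#' @export
ddiDataset <- function(drugs, positives) {
  drugs <- as.data.frame(drugs, stringsAsFactors = FALSE)
  positives <- as.data.frame(positives, stringsAsFactors = FALSE)
  methods::new("DDIDataset", drugs = drugs, positives = positives)
}

#' Read a positive-interaction edge list from TSV/CSV
#'
#' Expects header columns `drug_a` and `drug_b`; `#` comment lines ignored.
#'
#' @param path file path.
#' @return data.frame with columns `drug_a`, `drug_b` (and `label` if present).
#' @export
readEdgeList <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  if (!all(c("drug_a", "drug_b") %in% names(df)))
    stop("edge list must have header columns 'drug_a' and 'drug_b'")
  df
}

#' Cross-validation split specification
#'
#' Under `edge_partition` (warm start) the positive edges are split
#' train/validation/test at the given fractions (default 75/5/20: 80%
#' training edges of which a 5%-of-total slice is held out for validation,
#' 20% test). Under `drug_partition` (cold start) the drugs are split
#' (1 - testFrac)/testFrac; training pairs have both endpoints among
#' training drugs, test pairs exactly one endpoint among the held-out drugs
#' (pairs between two held-out drugs are discarded), and the validation set
#' is carved from the training pairs at `valFrac`.
#'
#' @param strategy `"edge_partition"` or `"drug_partition"`.
#' @param trainFrac,valFrac,testFrac split fractions, summing to 1.
#' @param seed integer seed.
#' @param repeatIndex repetition counter mixed into the seed.
#' @return list of validated settings.
#' @export
splitSpec <- function(strategy = c("edge_partition", "drug_partition"),
                      trainFrac = 0.75, valFrac = 0.05, testFrac = 0.20,
                      seed = 1L, repeatIndex = 1L) {
  strategy <- match.arg(strategy)
  if (abs(trainFrac + valFrac + testFrac - 1) > 1e-9)
    stop("split fractions must sum to 1")
  list(strategy = strategy, trainFrac = trainFrac, valFrac = valFrac,
       testFrac = testFrac, seed = as.integer(seed),
       repeatIndex = as.integer(repeatIndex))
}

#' Partition the positive edges (warm-start split)
#'
#' Shuffles the positive pairs by the spec's seed and assigns
#' `testFrac` to test, `valFrac` to validation and the rest to training —
#' a disjoint cover of the positives.
#'
#' @param dataset a [DDIDataset-class].
#' @param spec list from [splitSpec()] with strategy `edge_partition`.
#' @return list with data.frames `train`, `val`, `test` (columns `drug_a`,
#'   `drug_b`), the `strategy`, and the drug id universe `allDrugs`.
#' @export
edgePartitionSplit <- function(dataset, spec) {
  stopifnot(spec$strategy == "edge_partition")
  pos <- positivePairs(dataset)
  n <- nrow(pos)
  if (n < 5L) stop("need at least 5 positive edges to split")
  ord <- withr::with_seed(.childSeed(spec$seed, spec$repeatIndex),
                          sample.int(n))
  nTest <- round(spec$testFrac * n)
  nVal <- round(spec$valFrac * n)
  if (nTest < 1L || nVal < 1L || n - nTest - nVal < 1L)
    stop("too few positive edges for the requested fractions")
  test <- pos[ord[seq_len(nTest)], , drop = FALSE]
  val <- pos[ord[nTest + seq_len(nVal)], , drop = FALSE]
  train <- pos[ord[(nTest + nVal + 1L):n], , drop = FALSE]
  rownames(train) <- rownames(val) <- rownames(test) <- NULL
  list(strategy = "edge_partition", train = train, val = val, test = test,
       allDrugs = drugTable(dataset)$drug_id)
}

#' Partition the drugs (cold-start split)
#'
#' Shuffles the drugs by the spec's seed and holds out `testFrac` of them as
#' new drugs. Training pairs are the positives with both endpoints among the
#' training drugs; test pairs those with exactly one held-out endpoint;
#' positives between two held-out drugs are discarded. Validation is carved
#' from the training pairs at `valFrac`.
#'
#' @param dataset a [DDIDataset-class].
#' @param spec list from [splitSpec()] with strategy `drug_partition`.
#' @return list with `train`, `val`, `test` pair data.frames plus the
#'   `trainDrugs` / `testDrugs` id vectors.
#' @export
drugPartitionSplit <- function(dataset, spec) {
  stopifnot(spec$strategy == "drug_partition")
  ids <- drugTable(dataset)$drug_id
  nd <- length(ids)
  seed <- .childSeed(spec$seed, spec$repeatIndex)
  ord <- withr::with_seed(seed, sample.int(nd))
  nTestDrugs <- max(1L, round(spec$testFrac * nd))
  testDrugs <- ids[ord[seq_len(nTestDrugs)]]
  trainDrugs <- setdiff(ids, testDrugs)
  pos <- positivePairs(dataset)
  aTest <- pos$drug_a %in% testDrugs
  bTest <- pos$drug_b %in% testDrugs
  test <- pos[xor(aTest, bTest), , drop = FALSE]
  trainAll <- pos[!aTest & !bTest, , drop = FALSE]
  if (nrow(test) == 0L)
    stop("drug partition produced no test pairs; try a different seed")
  if (nrow(trainAll) < 2L)
    stop("drug partition produced too few training pairs; try a different seed")
  nVal <- min(nrow(trainAll) - 1L, max(1L, round(spec$valFrac * nrow(trainAll))))
  vord <- withr::with_seed(.childSeed(seed, 1L), sample.int(nrow(trainAll)))
  val <- trainAll[vord[seq_len(nVal)], , drop = FALSE]
  train <- trainAll[vord[(nVal + 1L):nrow(trainAll)], , drop = FALSE]
  rownames(train) <- rownames(val) <- rownames(test) <- NULL
  list(strategy = "drug_partition", train = train, val = val, test = test,
       trainDrugs = trainDrugs, testDrugs = testDrugs,
       allDrugs = ids)
}

#' Apply the split strategy named in the spec.
#' @export
#' @rdname edgePartitionSplit
splitDataset <- function(dataset, spec) {
  switch(spec$strategy,
         edge_partition = edgePartitionSplit(dataset, spec),
         drug_partition = drugPartitionSplit(dataset, spec))
}

#' Sample negative (non-interacting) pairs for each split
#'
#' Negatives are drawn uniformly without replacement from the unlabeled
#' pairs (never colliding with any positive, no self pairs) and are disjoint
#' across splits. Under the drug partition, train/validation negatives are
#' sampled among training drugs and test negatives between training and
#' held-out drugs, mirroring the eligibility of the positives.
#'
#' @param dataset a [DDIDataset-class].
#' @param split list from [edgePartitionSplit()] / [drugPartitionSplit()].
#' @param ratio negatives per positive (default 1, balanced).
#' @param seed integer seed.
#' @return list with labeled data.frames `train`, `val`, `test` (columns
#'   `drug_x`, `drug_y`, `label`).
#' @export
sampleNegatives <- function(dataset, split, ratio = 1, seed = 1L) {
  stopifnot(ratio > 0)
  posKeys <- .pairKey(positivePairs(dataset)$drug_a,
                      positivePairs(dataset)$drug_b)
  allPairsAmong <- function(a, b = NULL) {
    if (is.null(b)) {
      if (length(a) < 2L) return(data.frame(drug_x = character(0),
                                            drug_y = character(0)))
      m <- utils::combn(a, 2L)
      df <- data.frame(drug_x = m[1L, ], drug_y = m[2L, ],
                       stringsAsFactors = FALSE)
    } else {
      df <- expand.grid(drug_x = a, drug_y = b, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    }
    df[!(.pairKey(df$drug_x, df$drug_y) %in% posKeys), , drop = FALSE]
  }
  need <- vapply(split[c("train", "val", "test")],
                 function(df) as.integer(round(ratio * nrow(df))), integer(1))
  if (split$strategy == "edge_partition") {
    pool <- allPairsAmong(split$allDrugs)
    if (sum(need) > nrow(pool))
      stop("requested more negatives than available unlabeled pairs")
    ord <- withr::with_seed(.childSeed(seed, 97L), sample.int(nrow(pool)))
    takes <- split(ord[seq_len(sum(need))],
                   rep(c("train", "val", "test"), need))
    negs <- lapply(c(train = "train", val = "val", test = "test"),
                   function(s) pool[takes[[s]], , drop = FALSE])
  } else {
    trainPool <- allPairsAmong(split$trainDrugs)
    testPool <- allPairsAmong(split$trainDrugs, split$testDrugs)
    if (need[["train"]] + need[["val"]] > nrow(trainPool))
      stop("requested more train/val negatives than available unlabeled pairs")
    if (need[["test"]] > nrow(testPool))
      stop("requested more test negatives than available unlabeled pairs")
    ord <- withr::with_seed(.childSeed(seed, 97L), sample.int(nrow(trainPool)))
    negs <- list(
      train = trainPool[ord[seq_len(need[["train"]])], , drop = FALSE],
      val = trainPool[ord[need[["train"]] + seq_len(need[["val"]])], ,
                      drop = FALSE],
      test = testPool[withr::with_seed(.childSeed(seed, 98L),
                                       sample.int(nrow(testPool),
                                                  need[["test"]])), ,
                      drop = FALSE])
  }
  out <- lapply(c(train = "train", val = "val", test = "test"), function(s) {
    pos <- split[[s]]
    df <- rbind(
      data.frame(drug_x = pos$drug_a, drug_y = pos$drug_b, label = 1,
                 stringsAsFactors = FALSE),
      data.frame(drug_x = negs[[s]]$drug_x, drug_y = negs[[s]]$drug_y,
                 label = 0, stringsAsFactors = FALSE))
    rownames(df) <- NULL
    df
  })
  out
}

#' Classification metrics for DDI prediction
#'
#' Confusion counts at the threshold, accuracy, precision, recall and F1
#' from those counts, AUC as the tie-averaged rank statistic (probability
#' that a positive outranks a negative) and AUPR by step integration of the
#' precision-recall curve.
#'
#' @param labels numeric vector of 0/1 labels (both classes required).
#' @param probabilities predicted probabilities.
#' @param threshold decision threshold for the confusion counts (default 0.5).
#' @return list with `ACC`, `precision`, `recall`, `F1`, `AUC`, `AUPR`,
#'   `TP`, `FP`, `TN`, `FN` and `threshold`.
#' @export
computeMetrics <- function(labels, probabilities, threshold = 0.5) {
  if (length(labels) != length(probabilities))
    stop("labels and probabilities must have equal length")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L) stop("no positive labels in input")
  if (n0 == 0L) stop("no negative labels in input")
  pred <- as.integer(probabilities >= threshold)
  TP <- sum(pred == 1 & labels == 1)
  FP <- sum(pred == 1 & labels == 0)
  TN <- sum(pred == 0 & labels == 0)
  FN <- sum(pred == 0 & labels == 1)
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  recall <- TP / (TP + FN)
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  # AUC: tie-averaged rank statistic
  r <- rank(probabilities)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # AUPR: step integration over distinct score thresholds, descending
  ord <- order(probabilities, decreasing = TRUE)
  lab <- labels[ord]
  prob <- probabilities[ord]
  keep <- c(prob[-length(prob)] != prob[-1L], TRUE)  # last index of each tie group
  cumTP <- cumsum(lab == 1)[keep]
  cumN <- seq_along(lab)[keep]
  prec <- cumTP / cumN
  rec <- cumTP / n1
  aupr <- sum(diff(c(0, rec)) * prec)
  list(ACC = (TP + TN) / (TP + FP + TN + FN), precision = precision,
       recall = recall, F1 = f1, AUC = auc, AUPR = aupr,
       TP = TP, FP = FP, TN = TN, FN = FN, threshold = threshold)
}

#' Run the full train/evaluate protocol, optionally repeated
#'
#' For each repeat: split the positives by the spec's strategy, sample
#' negatives, train the model on the training pairs (selecting the
#' checkpoint by validation loss) and evaluate on the test pairs. All
#' randomness derives from `(spec$seed, repeat index)`. With several repeats
#' the per-metric mean and standard deviation are reported.
#'
#' @param dataset a [DDIDataset-class].
#' @param spec list from [splitSpec()].
#' @param encConfig list from [encoderConfig()].
#' @param fitConfig list from [trainConfig()].
#' @param repeats number of repetitions (fresh split, negatives and
#'   initialization each time).
#' @param negativeRatio negatives per positive.
#' @param graphs optional pre-built named list of [MolecularGraph-class]
#'   objects (built from the dataset if omitted).
#' @param keepModels retain the trained model of each repeat in the result.
#' @return list with `perRepeat` (metric lists), `mean`, `sd`, and
#'   optionally `models` and `splits`.
#' @export
runExperiment <- function(dataset, spec, encConfig = encoderConfig(),
                          fitConfig = trainConfig(), repeats = 1L,
                          negativeRatio = 1, graphs = NULL,
                          keepModels = FALSE) {
  if (is.null(graphs)) graphs <- buildGraphs(drugTable(dataset))
  perRepeat <- vector("list", repeats)
  models <- if (keepModels) vector("list", repeats) else NULL
  splits <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    rspec <- spec
    rspec$repeatIndex <- spec$repeatIndex + r - 1L
    split <- splitDataset(dataset, rspec)
    labeled <- sampleNegatives(dataset, split, ratio = negativeRatio,
                               seed = .childSeed(rspec$seed, rspec$repeatIndex))
    fc <- fitConfig
    fc$seed <- as.integer(.childSeed(fitConfig$seed, rspec$repeatIndex) %%
                            .Machine$integer.max)
    model <- trainModel(graphs, labeled$train, labeled$val,
                        encConfig = encConfig, fitConfig = fc)
    probs <- predictPairs(model, graphs, labeled$test)
    perRepeat[[r]] <- computeMetrics(labeled$test$label, probs)
    splits[[r]] <- labeled
    if (keepModels) models[[r]] <- model
  }
  metricNames <- c("ACC", "precision", "recall", "F1", "AUC", "AUPR")
  vals <- sapply(metricNames, function(m)
    vapply(perRepeat, `[[`, numeric(1), m))
  vals <- matrix(vals, nrow = repeats,
                 dimnames = list(NULL, metricNames))
  res <- list(perRepeat = perRepeat,
              mean = colMeans(vals),
              sd = apply(vals, 2L, stats::sd),
              splits = splits)
  if (keepModels) res$models <- models
  res
}

#' Write a split manifest as TSV (`drug_a`, `drug_b`, `label`, `split`)
#'
#' @param labeled list from [sampleNegatives()].
#' @param path output file path.
#' @export
writeSplitManifest <- function(labeled, path) {
  df <- do.call(rbind, lapply(names(labeled), function(s)
    data.frame(drug_a = labeled[[s]]$drug_x, drug_b = labeled[[s]]$drug_y,
               label = labeled[[s]]$label, split = s,
               stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an experiment's metrics as JSON `{metric: {mean, sd, per_repeat[]}}`
#'
#' @param result list from [runExperiment()].
#' @param path output file path.
#' @export
writeMetricsJson <- function(result, path) {
  metricNames <- names(result$mean)
  out <- lapply(metricNames, function(m)
    list(mean = unname(result$mean[[m]]), sd = unname(result$sd[[m]]),
         per_repeat = vapply(result$perRepeat, `[[`, numeric(1), m)))
  names(out) <- metricNames
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write predictions as TSV (`drug_x`, `drug_y`, `probability`)
#'
#' @param pairs data.frame with `drug_x`, `drug_y`.
#' @param probabilities numeric vector, one per row of `pairs`.
#' @param path output file path.
#' @export
writePredictions <- function(pairs, probabilities, path) {
  utils::write.table(
    data.frame(drug_x = pairs$drug_x, drug_y = pairs$drug_y,
               probability = probabilities, stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
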