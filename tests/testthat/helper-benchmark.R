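# Trained quick-profile benchmark runs, computed once and shared by the
# learning-performance and attribution tests. Three seeds per partition
# strategy at the quick-profile training settings (50 epochs, batch 128,
# Adam 1e-3, balanced negatives).

quickBenchmarkRuns <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    bench <- benchmarkSuite("quick", seed = 1)
    graphs <- buildGraphs(drugTable(bench$dataset))
    runs <- list()
    for (strategy in c("edge_partition", "drug_partition")) {
      for (seed in 1:3) {
        split <- splitDataset(bench$dataset, splitSpec(strategy, seed = seed))
        labeled <- sampleNegatives(bench$dataset, split, ratio = 1,
                                   seed = seed)
        model <- trainModel(graphs, labeled$train, labeled$val,
                            encConfig = encoderConfig(seed = seed),
                            fitConfig = trainConfig(epochs = 50L,
                                                    batchSize = 128L,
                                                    seed = seed))
        probs <- predictPairs(model, graphs, labeled$test)
        runs[[paste(strategy, seed, sep = "_")]] <-
          list(strategy = strategy, seed = seed, model = model,
               labeled = labeled,
               metrics = computeMetrics(labeled$test$label, probs))
      }
    }
    cache <<- list(bench = bench, graphs = graphs, runs = runs)
    cache
  }
})

# Rule-positive subset of the positive test pairs of one run.
rulePositiveTestPairs <- function(bench, labeled) {
  pt <- bench$pairTruth
  key <- paste(pt$drug_a, pt$drug_b)
  pos <- labeled$test[labeled$test$label == 1, , drop = FALSE]
  k1 <- paste(pos$drug_x, pos$drug_y)
  k2 <- paste(pos$drug_y, pos$drug_x)
  idx <- match(ifelse(k1 %in% key, k1, k2), key)
  pos[pt$rule_label[idx] == 1, , drop = FALSE]
}
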