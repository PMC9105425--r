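# gatddi — graph-attention prediction of drug-drug interactions

`gatddi` predicts drug-drug interactions (DDIs) directly from chemical
structure, for method developers and computational chemists who need a
structure-only DDI screen that also works for *new* drugs — drugs with no
recorded interaction to learn from — and that can say *which substructures*
drove a prediction.

## The model

Each drug's SMILES string becomes a molecular graph (heavy atoms as nodes,
bonds as edges, hydrogens implicit) whose atoms carry 78-dimensional
feature vectors (element, degree, valence, charge, radicals,
hybridization, hydrogen count, aromaticity). A five-layer, two-head
graph-attention encoder updates atom $i$ at each layer as

$$h_i' = \mathrm{ReLU}\Big(\sum_{j \in N_i} \alpha_{ij} W h_j + W h_i\Big),
\qquad
\alpha_{ij} = \mathrm{softmax}_{j \in N_i}\,
\mathrm{LeakyReLU}\big(a^\top [W h_i \| W h_j]\big),$$

and after every layer a self-attention pooling readout
$H_G^{(k)} = \sum_i \gamma_i h_i^{(k)}$ (with learned atom weights
$\gamma$, softmax-normalized) produces one graph vector per layer. The
five $k$-hop vectors are concatenated into the drug embedding
$Z = H_G^{(1)} \| \cdots \| H_G^{(5)}$ (320-dim), pairs are represented as
$[Z_x, Z_y]$ (640-dim), and a five-layer MLP (640→128→64→32→2, softmax
head) yields the interaction probability, trained with binary
cross-entropy and Adam. For an explanation, the layer pair $(s, t)$
maximizing $\langle H_{G_x}^{(s)}, H_{G_y}^{(t)}\rangle$ selects the
receptive-field scale of each drug, and the corresponding $\gamma$ weights
map the prediction back onto atoms.

Two evaluation protocols are built in: **edge partition** (warm start —
held-out interactions among known drugs, 75/5/20) and **drug partition**
(cold start — 20% of drugs held out entirely; test pairs join a known and
a new drug), both with seeded uniform negative sampling and an
ACC/precision/recall/F1/AUC/AUPR metric suite. A seeded synthetic
generator builds desk-scale drug libraries from scaffolds and functional
groups with rule-based labels (nitrate × sulfonamide, carboxyl × amine),
so the whole pipeline runs and is tested without external data. See the
methods vignette (`vignettes/gatddi-methods.Rmd`) for design details.

## Worked example

```r
library(gatddi)

# synthetic library: 40 drugs, rule-labeled pairs, 5% label noise
gs  <- generatorSpec(nDrugs = 40, seed = 7)
lib <- makeDrugLibrary(gs)
ds  <- makeDdiDataset(lib, gs)$dataset
ds
#> DDIDataset: 40 drugs, 257 positive interactions

graphs <- buildGraphs(drugTable(ds))
graphs[["d001"]]
#> MolecularGraph 'd001': 7 atoms, 7 bonds
#>   SMILES: c1ccncc1(N)

# warm-start protocol: split positives 75/5/20, add 1:1 negatives, train
split   <- edgePartitionSplit(ds, splitSpec("edge_partition", seed = 7))
labeled <- sampleNegatives(ds, split, ratio = 1, seed = 7)
model   <- trainModel(graphs, labeled$train, labeled$val,
                      encConfig = encoderConfig(seed = 7),
                      fitConfig = trainConfig(epochs = 25, batchSize = 128,
                                              seed = 7))

probs <- predictPairs(model, graphs, labeled$test)
m <- computeMetrics(labeled$test$label, probs)
sprintf("AUC %.3f  AUPR %.3f  ACC %.3f  F1 %.3f", m$AUC, m$AUPR, m$ACC, m$F1)
#> "AUC 0.870  AUPR 0.859  ACC 0.794  F1 0.792"
```

The AUC/AUPR say how well held-out interactions are ranked above sampled
non-interactions; ACC and F1 are taken at threshold 0.5. Explaining one
predicted pair (d001 carries an amine, d002 a carboxyl — a rule-matching
combination):

```r
res <- explainPair(model, graphs[["d001"]], graphs[["d002"]])
res
#> AttributionResult d001 ~ d002
#>   best layer pair: (5, 5), score 161.8710
head(res@atomsX[order(-res@atomsX$weight), ], 3)
#>   atom_index element      weight
#> 7          6       N 0.947388478
#> 5          4       C 0.030908231
#> 6          5       C 0.011089814
```

The pooling weights concentrate (95%) on the amine nitrogen — the planted
cause of this interaction. `writeAttribution()` exports the table and the
full 5×5 layer-score matrix.

A command-line front end covering
`simulate | split | train | evaluate | predict | explain` is installed at
`inst/scripts/gatddi`.

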