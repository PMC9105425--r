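# Shared fixtures and independent brute-force oracles used across tests.
# The oracles deliberately re-derive every quantity with plain loops so they
# share no code with the package implementation.

FIXTURE_SMILES <- c(
  methane = "C",
  ethane = "CC",
  benzene = "c1ccccc1",
  phenol = "c1ccccc1O",
  acetic = "OC(=O)C",
  pyrrole = "c1cc[nH]c1",
  nitroglycerin = "C(C(CO[N+](=O)[O-])O[N+](=O)[O-])O[N+](=O)[O-]",
  sulfonamide = "CS(=O)(=O)Nc1ccccc1"
)

fixtureGraphs <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- lapply(names(FIXTURE_SMILES), function(n)
        buildGraph(n, FIXTURE_SMILES[[n]]))
    names(cache) <- names(FIXTURE_SMILES)
    cache
  }
})

# adjacency list (1-based) from a MolecularGraph
neighborList <- function(graph) {
  p <- numAtoms(graph)
  e <- graphEdges(graph) + 1L
  nb <- vector("list", p)
  for (i in seq_len(nrow(e))) {
    nb[[e[i, 1L]]] <- c(nb[[e[i, 1L]]], e[i, 2L])
    nb[[e[i, 2L]]] <- c(nb[[e[i, 2L]]], e[i, 1L])
  }
  nb
}

# Naive dense re-implementation of one attention layer: explicit loops over
# atoms and neighbors, plain softmax, self term added outside the sum.
naiveLayerForward <- function(H, graph, layerParams, slope = 0.2) {
  nb <- neighborList(graph)
  p <- nrow(H)
  heads <- list()
  for (head in layerParams$heads) {
    W <- head$W
    a <- c(head$a1, head$a2)
    out <- matrix(0, p, ncol(W))
    for (i in seq_len(p)) {
      ui <- as.numeric(t(W) %*% H[i, ])
      agg <- numeric(ncol(W))
      if (length(nb[[i]])) {
        e <- numeric(length(nb[[i]]))
        for (jx in seq_along(nb[[i]])) {
          uj <- as.numeric(t(W) %*% H[nb[[i]][jx], ])
          z <- sum(a * c(ui, uj))
          e[jx] <- if (z > 0) z else slope * z
        }
        alpha <- exp(e - max(e)) / sum(exp(e - max(e)))
        for (jx in seq_along(nb[[i]])) {
          uj <- as.numeric(t(W) %*% H[nb[[i]][jx], ])
          agg <- agg + alpha[jx] * uj
        }
      }
      s <- agg + ui
      out[i, ] <- pmax(s, 0)
    }
    heads[[length(heads) + 1L]] <- out
  }
  do.call(cbind, heads)
}

# Naive readout: explicit normalized-adjacency scoring and weighted sum.
naiveReadout <- function(H, graph, scoreParams) {
  p <- nrow(H)
  nb <- neighborList(graph)
  deg <- vapply(nb, length, integer(1))
  q <- numeric(p)
  for (i in seq_len(p)) {
    si <- H[i, ] %*% scoreParams$theta / (deg[i] + 1)
    for (j in nb[[i]])
      si <- si + H[j, ] %*% scoreParams$theta /
        (sqrt(deg[i] + 1) * sqrt(deg[j] + 1))
    q[i] <- si + scoreParams$b
  }
  gamma <- exp(q - max(q)) / sum(exp(q - max(q)))
  pooled <- numeric(ncol(H))
  for (i in seq_len(p)) pooled <- pooled + gamma[i] * H[i, ]
  list(pooled = pooled, weights = gamma)
}

# O(n^2) concordant-pair AUC with half credit for ties.
naiveAUC <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Tiny two-drug pair table used by optimization tests.
tinyPairFixture <- function() {
  drugs <- data.frame(
    drug_id = c("acid1", "acid2", "amine1", "amine2", "plain1", "plain2"),
    smiles = c("CC(=O)O", "CCC(=O)O", "CCN", "CCCN", "CCC", "CCCC"),
    stringsAsFactors = FALSE
  )
  combos <- t(combn(drugs$drug_id, 2))
  hasAcid <- function(id) startsWith(id, "acid")
  hasAmine <- function(id) startsWith(id, "amine")
  label <- as.integer(
    (vapply(combos[, 1], hasAcid, logical(1)) &
       vapply(combos[, 2], hasAmine, logical(1))) |
    (vapply(combos[, 1], hasAmine, logical(1)) &
       vapply(combos[, 2], hasAcid, logical(1))))
  list(drugs = drugs,
       pairs = data.frame(drug_x = combos[, 1], drug_y = combos[, 2],
                          label = label, stringsAsFactors = FALSE))
}

# Python/RDKit per-atom oracle; returns NULL when python or rdkit is absent.
rdkitAtomOracle <- function(smiles) {
  script <- sprintf('
import json, sys
try:
    from rdkit import Chem
except Exception:
    print("null"); sys.exit(0)
out = []
for smi in %s:
    m = Chem.MolFromSmiles(smi)
    out.append({
        "smiles": smi,
        "bonds": m.GetNumBonds(),
        "atoms": [dict(element=a.GetSymbol(), degree=a.GetDegree(),
                       hTotal=a.GetTotalNumHs(), charge=a.GetFormalCharge(),
                       radicals=a.GetNumRadicalElectrons(),
                       aromatic=bool(a.GetIsAromatic()),
                       hyb=str(a.GetHybridization()))
                  for a in m.GetAtoms()]})
print(json.dumps(out))
', jsonlite::toJSON(smiles))
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  res <- tryCatch(system2("python", f, stdout = TRUE, stderr = FALSE),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(res) || !length(res)) return(NULL)
  parsed <- tryCatch(jsonlite::fromJSON(paste(res, collapse = ""),
                                        simplifyDataFrame = FALSE),
                     error = function(e) NULL)
  parsed
}
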