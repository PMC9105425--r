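# Seeded generator of desk-scale drug libraries with planted functional
# groups, and rule-based interaction labels driven by group co-occurrence.
# This emulates the structural premise of substructure-driven DDIs (e.g. a
# nitrate ester interacting with a sulfonamide-bearing partner) so the whole
# pipeline is testable without external data.

# Scaffold templates: '{A}' and '{B}' mark substitution slots directly after
# an atom; slots are filled with '(<group>)' or removed. Scaffolds use ring
# digit 1, fragments digit 2, so assembled strings never collide.
.SCAFFOLDS <- c(
  benzene      = "c1cc{B}ccc1{A}",
  pyridine     = "c1cc{B}ncc1{A}",
  cyclohexane  = "C1CC{B}CCC1{A}",
  oxane        = "C1CC{B}OCC1{A}",
  thiophene    = "c1c{B}csc1{A}",
  pentane      = "CC{B}CCC{A}"
)

# Functional-group fragments; each attaches through its first atom.
.GROUPS <- c(
  nitrate     = "O[N+](=O)[O-]",
  carboxyl    = "C(=O)O",
  phenol      = "c2ccc(O)cc2",
  amine       = "N",
  sulfonamide = "S(=O)(=O)N"
)

# Interaction rules: a pair interacts when one drug carries the first group
# and the other the second (nitrate ester x sulfonamide echoes the classic
# nitrate / PDE5-inhibitor interaction; carboxylic acid x amine is a simple
# acid-base pairing).
.RULES <- list(c("nitrate", "sulfonamide"), c("carboxyl", "amine"))

#' Count heavy atoms in a SMILES fragment, returning their element symbols
#' in order of appearance. Handles two-letter organic-subset symbols,
#' bracket atoms and aromatic lowercase symbols.
#' @keywords internal
.scanHeavyAtoms <- function(s) {
  out <- character(0)
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      inner <- substr(s, i + 1L, i + j - 2L)
      sym <- regmatches(inner, regexpr("^[0-9]*([A-Za-z][a-z]?)", inner))
      sym <- sub("^[0-9]*", "", sym)
      # strip chirality/hydrogen suffixes captured by the two-letter match
      if (!sym %in% c(names(.DEFAULT_VALENCE), "Se", "As", "Si"))
        sym <- substr(sym, 1L, 1L)
      if (toupper(sym) != "H")
        out <- c(out, paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, 10)))
      i <- i + j
    } else if (substr(s, i, i + 1L) %in% c("Cl", "Br")) {
      out <- c(out, substr(s, i, i + 1L))
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "S", "P", "F", "I")) {
      out <- c(out, ch)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "s", "p")) {
      out <- c(out, toupper(ch))
      i <- i + 1L
    } else {
      i <- i + 1L   # digits, bonds, branches, ring closures, '%', '.'
    }
  }
  out
}

#' Synthetic-library generator specification
#'
#' @param nDrugs number of drugs to generate (>= 2).
#' @param scaffolds named character vector of scaffold templates with `{A}`
#'   and `{B}` substitution slots.
#' @param groups named character vector of functional-group SMILES fragments.
#' @param rules list of length-2 character vectors naming interacting group
#'   pairs.
#' @param noiseRate probability of flipping each pair label (label noise).
#' @param seed integer seed.
#' @return list of validated settings.
#' @export
generatorSpec <- function(nDrugs = 60L, scaffolds = .SCAFFOLDS,
                          groups = .GROUPS, rules = .RULES,
                          noiseRate = 0.05, seed = 1L) {
  stopifnot(nDrugs >= 2L, noiseRate >= 0, noiseRate <= 1)
  for (r in rules)
    if (!all(r %in% names(groups)))
      stop("rule references an undeclared group: ", paste(r, collapse = ", "))
  list(nDrugs = as.integer(nDrugs), scaffolds = scaffolds, groups = groups,
       rules = rules, noiseRate = noiseRate, seed = as.integer(seed))
}

#' Generate a synthetic drug library with planted functional groups
#'
#' Each drug is one scaffold carrying one or two distinct functional groups
#' attached at the template's slots. The returned ground truth records, per
#' drug, the planted groups and the 0-based atom indices of each group's
#' atoms under the emitted SMILES' atom order (the order [parseSmiles()]
#' uses). Every emitted SMILES is checked to re-parse, and the recorded
#' indices are checked against the parsed element symbols; a fragment that
#' fails either check raises an error naming it.
#'
#' @param spec list from [generatorSpec()].
#' @return list with `drugs` (data.frame `drug_id`, `smiles`) and `truth`
#'   (per-drug list with `scaffold`, `groups`, and `groupAtoms`: named list
#'   of 0-based atom index vectors).
#' @export
makeDrugLibrary <- function(spec) {
  withr::with_seed(spec$seed, {
    n <- spec$nDrugs
    ids <- sprintf("d%03d", seq_len(n))
    rows <- vector("list", n)
    truth <- vector("list", n)
    names(truth) <- ids
    for (i in seq_len(n)) {
      scafIdx <- sample(length(spec$scaffolds), 1L)
      nGroups <- 1L + stats::rbinom(1L, 1L, 0.5)
      grpIdx <- sample(length(spec$groups), nGroups)
      smiles <- spec$scaffolds[[scafIdx]]
      fill <- c(`{A}` = NA_integer_, `{B}` = NA_integer_)
      fill["{A}"] <- grpIdx[1L]
      if (nGroups > 1L) fill["{B}"] <- grpIdx[2L]
      groupAtoms <- list()
      repeat {
        mpos <- regexpr("\\{[AB]\\}", smiles)
        if (mpos < 0L) break
        marker <- substr(smiles, mpos, mpos + 2L)
        gi <- fill[[marker]]
        prefix <- substr(smiles, 1L, mpos - 1L)
        suffix <- substr(smiles, mpos + 3L, nchar(smiles))
        if (is.na(gi)) {
          smiles <- paste0(prefix, suffix)
        } else {
          frag <- spec$groups[[gi]]
          off <- length(.scanHeavyAtoms(prefix))
          groupAtoms[[names(spec$groups)[gi]]] <-
            off + seq_along(.scanHeavyAtoms(frag)) - 1L
          smiles <- paste0(prefix, "(", frag, ")", suffix)
        }
      }
      # validity contract: emitted SMILES must re-parse and recorded indices
      # must land on the fragment's own atoms
      sk <- tryCatch(parseSmiles(smiles, drugId = ids[i]), error = function(e)
        stop(sprintf("generated SMILES for %s (scaffold '%s') failed to parse: %s",
                     ids[i], names(spec$scaffolds)[scafIdx],
                     conditionMessage(e)), call. = FALSE))
      for (g in names(groupAtoms)) {
        want <- .scanHeavyAtoms(spec$groups[[g]])
        got <- sk$atoms$element[groupAtoms[[g]] + 1L]
        if (!identical(got, want))
          stop(sprintf("atom bookkeeping failed for fragment '%s' in %s", g,
                       ids[i]))
      }
      rows[[i]] <- data.frame(drug_id = ids[i], smiles = smiles,
                              stringsAsFactors = FALSE)
      truth[[i]] <- list(scaffold = names(spec$scaffolds)[scafIdx],
                         groups = names(spec$groups)[grpIdx],
                         groupAtoms = groupAtoms)
    }
    list(drugs = do.call(rbind, rows), truth = truth)
  })
}

#' Rule-implied interaction label for one pair, given per-drug group sets.
#' @keywords internal
.ruleLabel <- function(groupsA, groupsB, rules) {
  for (r in rules) {
    if ((r[1L] %in% groupsA && r[2L] %in% groupsB) ||
        (r[2L] %in% groupsA && r[1L] %in% groupsB))
      return(1L)
  }
  0L
}

#' Label all drug pairs by the interaction rules and apply label noise
#'
#' A pair is rule-positive when one drug carries the first group of some
#' rule and the other drug its second group. Each label is then flipped
#' independently with probability `noiseRate`. The positive pairs after
#' noise become the dataset's interaction edge list.
#'
#' @param library list from [makeDrugLibrary()].
#' @param spec list from [generatorSpec()].
#' @return list with `dataset` (a [DDIDataset-class]) and `pairTruth`
#'   (data.frame `drug_a`, `drug_b`, `rule_label` (pre-noise), `label`).
#' @export
makeDdiDataset <- function(library, spec) {
  ids <- library$drugs$drug_id
  cmb <- utils::combn(ids, 2L)
  pairs <- data.frame(drug_a = cmb[1L, ], drug_b = cmb[2L, ],
                      stringsAsFactors = FALSE)
  grps <- lapply(library$truth, `[[`, "groups")
  ruleLab <- vapply(seq_len(nrow(pairs)), function(i)
    .ruleLabel(grps[[pairs$drug_a[i]]], grps[[pairs$drug_b[i]]], spec$rules),
    integer(1))
  flips <- withr::with_seed(.childSeed(spec$seed, 2L),
                            stats::rbinom(nrow(pairs), 1L, spec$noiseRate))
  label <- as.integer(xor(ruleLab == 1L, flips == 1L))
  pairTruth <- cbind(pairs, rule_label = ruleLab, label = label)
  dataset <- ddiDataset(library$drugs,
                        pairs[label == 1L, , drop = FALSE])
  list(dataset = dataset, pairTruth = pairTruth)
}

#' Causal (rule-matching) atom indices for both drugs of a rule-positive pair
#'
#' For every rule the pair satisfies, collects the atoms of the matching
#' planted group on each side; used to evaluate whether attribution weights
#' concentrate on the substructures that caused the label.
#'
#' @param library list from [makeDrugLibrary()].
#' @param rules list of rules (as in [generatorSpec()]).
#' @param drugA,drugB drug identifiers.
#' @return list with 0-based index vectors `atomsA`, `atomsB` (empty when
#'   the pair satisfies no rule).
#' @export
causalAtoms <- function(library, rules, drugA, drugB) {
  ta <- library$truth[[drugA]]
  tb <- library$truth[[drugB]]
  atomsA <- integer(0)
  atomsB <- integer(0)
  for (r in rules) {
    if (r[1L] %in% ta$groups && r[2L] %in% tb$groups) {
      atomsA <- union(atomsA, ta$groupAtoms[[r[1L]]])
      atomsB <- union(atomsB, tb$groupAtoms[[r[2L]]])
    }
    if (r[2L] %in% ta$groups && r[1L] %in% tb$groups) {
      atomsA <- union(atomsA, ta$groupAtoms[[r[2L]]])
      atomsB <- union(atomsB, tb$groupAtoms[[r[1L]]])
    }
  }
  list(atomsA = sort(atomsA), atomsB = sort(atomsB))
}

#' Canned benchmark bundles
#'
#' `quick` generates 60 drugs (a few hundred positive pairs, 1 repeat);
#' `full` 150 drugs (a few thousand positives, 5 repeats). Both are fully
#' seeded and regenerate bit-identically.
#'
#' @param profile `"quick"` or `"full"`.
#' @param seed integer seed.
#' @param strategy split strategy for the bundled [splitSpec()].
#' @return list with `library`, `dataset`, `pairTruth`, `generator` (the
#'   [generatorSpec()] used), `split` (a [splitSpec()]) and `repeats`.
#' @export
benchmarkSuite <- function(profile = c("quick", "full"), seed = 1L,
                           strategy = "edge_partition") {
  profile <- match.arg(profile)
  nDrugs <- switch(profile, quick = 60L, full = 150L)
  repeats <- switch(profile, quick = 1L, full = 5L)
  gspec <- generatorSpec(nDrugs = nDrugs, noiseRate = 0.05,
                         seed = as.integer(.childSeed(seed, 11L) %% 2147483647))
  library <- makeDrugLibrary(gspec)
  labeled <- makeDdiDataset(library, gspec)
  list(profile = profile, library = library, dataset = labeled$dataset,
       pairTruth = labeled$pairTruth, generator = gspec,
       split = splitSpec(strategy, seed = seed), repeats = repeats)
}

#' Write the ground truth of a synthetic library as JSON
#'
#' @param library list from [makeDrugLibrary()].
#' @param pairTruth data.frame from [makeDdiDataset()].
#' @param path output file path.
#' @export
writeTruthJson <- function(library, pairTruth, path) {
  jsonlite::write_json(
    list(drugs = library$truth, pairs = pairTruth),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
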