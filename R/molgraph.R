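# SMILES -> molecular graph -> 78-dim atom features.
#
# Chemistry perception (SMILES parsing, aromaticity, Sybyl atom typing,
# implicit-hydrogen completion, formal charges) is delegated to OpenBabel via
# ChemmineOB; this file only assembles the graph and the feature blocks.

# 43 named element symbols; anything else falls into the 44th catch-all slot.
.ATOM_SYMBOLS <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg",
  "Na", "Ca", "Fe", "As", "Al", "I", "B", "V", "K", "Tl",
  "Yb", "Sb", "Sn", "Ag", "Pd", "Co", "Se", "Ti", "Zn", "H",
  "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn", "Zr", "Cr",
  "Pt", "Hg", "Pb"
)

.HYBRIDIZATIONS <- c("SP", "SP2", "SP3", "SP3D", "SP3D2")

.ATOM_FEATURE_DIM <- 78L

#' @keywords internal
.obConvert <- function(smiles, to, addH = FALSE) {
  out <- tryCatch(
    if (addH) {
      ChemmineOB::convertFormat("SMI", to, source = smiles,
                                options = data.frame(names = "h", args = ""))
    } else {
      ChemmineOB::convertFormat("SMI", to, source = smiles)
    },
    error = function(e) ""
  )
  if (!nzchar(trimws(out))) return(NULL)
  out
}

#' Parse a TRIPOS MOL2 block into atom and bond tables.
#' @keywords internal
.parseMol2 <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  secs <- grep("^@<TRIPOS>", lines)
  section <- function(name) {
    i <- match(paste0("@<TRIPOS>", name), lines)
    if (is.na(i)) return(character(0))
    end <- secs[secs > i]
    end <- if (length(end)) min(end) - 1L else length(lines)
    if (end < i + 1L) return(character(0))
    out <- lines[seq(i + 1L, end)]
    out[nzchar(trimws(out))]
  }
  atomLines <- section("ATOM")
  atoms <- do.call(rbind, lapply(atomLines, function(l) {
    f <- strsplit(trimws(l), "[[:space:]]+")[[1L]]
    data.frame(type = f[6L], stringsAsFactors = FALSE)
  }))
  atoms$element <- vapply(strsplit(atoms$type, ".", fixed = TRUE), `[[`, "", 1L)
  bondLines <- section("BOND")
  bonds <- if (length(bondLines)) {
    do.call(rbind, lapply(bondLines, function(l) {
      f <- strsplit(trimws(l), "[[:space:]]+")[[1L]]
      data.frame(a = as.integer(f[2L]), b = as.integer(f[3L]),
                 type = f[4L], stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(a = integer(0), b = integer(0), type = character(0))
  }
  list(atoms = atoms, bonds = bonds)
}

#' Extract per-atom formal charges from an SDF block (M CHG lines).
#' @keywords internal
.sdfCharges <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  counts <- strsplit(trimws(lines[4L]), "[[:space:]]+")[[1L]]
  nAtoms <- as.integer(counts[1L])
  elements <- vapply(lines[4L + seq_len(nAtoms)], function(l) {
    strsplit(trimws(l), "[[:space:]]+")[[1L]][4L]
  }, "", USE.NAMES = FALSE)
  charges <- integer(nAtoms)
  for (l in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", l)),
                             "[[:space:]]+")[[1L]])
    n <- f[1L]
    for (i in seq_len(n)) {
      charges[f[2L * i]] <- f[2L * i + 1L]
    }
  }
  list(elements = elements, charges = charges)
}

#' Atoms that sit on a cycle of the heavy-atom graph (iterative leaf pruning).
#' @keywords internal
.ringAtoms <- function(p, edges) {
  deg <- tabulate(c(edges[, 1L], edges[, 2L]) + 1L, nbins = p)
  alive <- rep(TRUE, p)
  repeat {
    leaves <- which(alive & deg <= 1L)
    if (!length(leaves)) break
    alive[leaves] <- FALSE
    for (v in leaves) {
      nb <- c(edges[edges[, 1L] + 1L == v, 2L], edges[edges[, 2L] + 1L == v, 1L]) + 1L
      deg[nb] <- deg[nb] - 1L
    }
    deg[leaves] <- 0L
  }
  alive
}

# Sybyl-type suffix -> hybridization state. Atoms typed without a suffix
# (halogens, alkali/alkaline-earth and transition metals) default to SP3
# silently: hybridization is not meaningful there and an all-zero block is
# not allowed.
.SYBYL_HYB <- c(
  "1" = "SP", "2" = "SP2", "ar" = "SP2", "am" = "SP2", "pl3" = "SP2",
  "co2" = "SP2", "cat" = "SP2", "3" = "SP3", "4" = "SP3", "o" = "SP3",
  "o2" = "SP3", "th" = "SP3", "spc" = "SP3", "t3p" = "SP3"
)

# Default valences used only to estimate unpaired (radical) electrons.
.DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, B = 3, Si = 4,
                      F = 1, Cl = 1, Br = 1, I = 1, H = 1)

.BOND_ORDER <- c("1" = 1, "2" = 2, "3" = 3, "am" = 1, "ar" = 1.5,
                 "du" = 1, "un" = 1)

#' Parse a SMILES string into a molecular-graph skeleton
#'
#' Converts the SMILES through OpenBabel and returns the heavy-atom graph
#' (hydrogens are implicit, never nodes) together with the per-atom
#' descriptors that [featurizeAtom()] encodes: element, heavy-atom degree,
#' total and implicit hydrogen counts, formal charge, radical electrons,
#' hybridization and aromaticity.
#'
#' @param smiles character(1), a valid SMILES string.
#' @param drugId character(1), used to contextualize parse errors.
#' @return a list with components `atoms` (data.frame of descriptors, one row
#'   per heavy atom, in SMILES order), `edges` (integer matrix of 0-based
#'   unordered heavy-atom bond pairs) and `smiles`.
#' @examples
#' sk <- parseSmiles("c1ccccc1O", "phenol")
#' nrow(sk$atoms)  # 7 heavy atoms
#' @export
parseSmiles <- function(smiles, drugId = "<unnamed>") {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(trimws(smiles)))
    stop(sprintf("drug '%s': empty or non-character SMILES", drugId))
  mol2 <- .obConvert(smiles, "MOL2", addH = TRUE)
  sdf <- .obConvert(smiles, "SDF", addH = FALSE)
  if (is.null(mol2) || is.null(sdf))
    stop(sprintf("drug '%s': SMILES '%s' could not be parsed", drugId, smiles))
  m <- .parseMol2(mol2)
  heavy <- which(m$atoms$element != "H")
  p <- length(heavy)
  if (p < 1L)
    stop(sprintf("drug '%s': SMILES '%s' has no heavy atoms", drugId, smiles))
  idxMap <- integer(nrow(m$atoms))        # full index -> 0-based heavy index
  idxMap[heavy] <- seq_len(p) - 1L

  chg <- .sdfCharges(sdf)
  heavySdf <- which(chg$elements != "H")
  if (!identical(chg$elements[heavySdf], m$atoms$element[heavy]))
    stop(sprintf("drug '%s': inconsistent atom ordering between conversions",
                 drugId))
  charges <- chg$charges[heavySdf]

  isH <- m$atoms$element == "H"
  aHeavy <- !isH[m$bonds$a]; bHeavy <- !isH[m$bonds$b]
  heavyBonds <- m$bonds[aHeavy & bHeavy, , drop = FALSE]
  edges <- cbind(idxMap[heavyBonds$a], idxMap[heavyBonds$b])
  storage.mode(edges) <- "integer"

  degree <- tabulate(c(edges[, 1L], edges[, 2L]) + 1L, nbins = p)
  hTotal <- integer(p)
  bondOrderSum <- numeric(p)
  arBonds <- integer(p)
  for (i in seq_len(nrow(m$bonds))) {
    a <- m$bonds$a[i]; b <- m$bonds$b[i]; ty <- m$bonds$type[i]
    ord <- unname(.BOND_ORDER[ty])
    if (is.na(ord)) ord <- 1
    if (!isH[a]) {
      k <- idxMap[a] + 1L
      bondOrderSum[k] <- bondOrderSum[k] + ord
      if (isH[b]) hTotal[k] <- hTotal[k] + 1L
      if (ty == "ar") arBonds[k] <- arBonds[k] + 1L
    }
    if (!isH[b]) {
      k <- idxMap[b] + 1L
      bondOrderSum[k] <- bondOrderSum[k] + ord
      if (isH[a]) hTotal[k] <- hTotal[k] + 1L
      if (ty == "ar") arBonds[k] <- arBonds[k] + 1L
    }
  }

  types <- m$atoms$type[heavy]
  suffix <- ifelse(grepl(".", types, fixed = TRUE),
                   tolower(sub("^[^.]*\\.", "", types)), NA_character_)
  hyb <- character(p)
  for (i in seq_len(p)) {
    if (is.na(suffix[i])) {
      hyb[i] <- "SP3"
    } else if (suffix[i] %in% names(.SYBYL_HYB)) {
      hyb[i] <- .SYBYL_HYB[[suffix[i]]]
    } else {
      warning(sprintf(
        "drug '%s': atom %d has unrecognized hybridization type '%s'; using SP3",
        drugId, i - 1L, types[i]), call. = FALSE)
      hyb[i] <- "SP3"
    }
  }

  inRing <- .ringAtoms(p, edges)
  aromatic <- inRing & (suffix %in% "ar" | arBonds >= 2L)

  # conjugated oxygen (phenol, ester, enol ether) is trigonal-planar: promote
  # O typed tetrahedral to SP2 when it borders an aromatic atom or a carbon
  # carrying a double bond
  hasDouble <- logical(p)
  dbl <- heavyBonds[heavyBonds$type == "2", , drop = FALSE]
  if (nrow(dbl)) hasDouble[c(idxMap[dbl$a], idxMap[dbl$b]) + 1L] <- TRUE
  elements <- m$atoms$element[heavy]
  for (i in which(elements == "O" & hyb == "SP3")) {
    nb <- c(edges[edges[, 1L] + 1L == i, 2L], edges[edges[, 2L] + 1L == i, 1L]) + 1L
    if (any(aromatic[nb] | (elements[nb] == "C" & hasDouble[nb])))
      hyb[i] <- "SP2"
  }

  defVal <- unname(.DEFAULT_VALENCE[elements])
  defVal[is.na(defVal)] <- 0
  # charge-adjusted default valence; carbon loses a bond either way
  adj <- ifelse(elements == "C", defVal - abs(charges), defVal + charges)
  radicals <- pmax(0, round(adj - bondOrderSum))  # bond orders include X-H bonds
  radicals[is.na(radicals)] <- 0

  atoms <- data.frame(
    element = elements,
    degree = as.integer(degree),
    hTotal = hTotal,
    implicitValence = hTotal,   # hydrogens are implicit in the graph
    charge = as.integer(charges),
    radicals = as.integer(radicals),
    hybridization = hyb,
    aromatic = as.logical(aromatic),
    stringsAsFactors = FALSE
  )
  list(atoms = atoms, edges = edges, smiles = smiles)
}

#' Encode one atom's descriptors as the 78-dimensional feature vector
#'
#' Block layout (width 78): element symbol one-hot over 43 named symbols plus
#' a catch-all (44); heavy-atom degree one-hot over 0-10 (11); implicit
#' valence one-hot over 0-6 (7); formal charge as a signed scalar (1);
#' radical electron count as a scalar (1); hybridization one-hot over SP,
#' SP2, SP3, SP3D, SP3D2 (5); total hydrogen count one-hot over 0-7 (8);
#' aromaticity flag (1). Out-of-range degree/valence/hydrogen counts clamp to
#' the top bin with a warning.
#'
#' @param atom a single-row data.frame (or list) with fields `element`,
#'   `degree`, `implicitValence`, `charge`, `radicals`, `hybridization`,
#'   `hTotal` and `aromatic`, as produced by [parseSmiles()].
#' @return numeric vector of length 78.
#' @examples
#' sk <- parseSmiles("C", "methane")
#' length(featurizeAtom(sk$atoms[1, ]))  # 78
#' @export
featurizeAtom <- function(atom) {
  sym <- numeric(44L)
  i <- match(atom$element, .ATOM_SYMBOLS)
  sym[if (is.na(i)) 44L else i] <- 1
  hybBlock <- numeric(5L)
  j <- match(atom$hybridization, .HYBRIDIZATIONS)
  if (is.na(j)) {
    warning(sprintf("hybridization '%s' not in listed states; using SP3",
                    atom$hybridization), call. = FALSE)
    j <- 3L
  }
  hybBlock[j] <- 1
  c(
    sym,
    .oneHotClamped(atom$degree, 0L, 10L, "degree"),
    .oneHotClamped(atom$implicitValence, 0L, 6L, "implicit valence"),
    atom$charge,
    atom$radicals,
    hybBlock,
    .oneHotClamped(atom$hTotal, 0L, 7L, "hydrogen count"),
    as.numeric(atom$aromatic)
  )
}

#' Build a fully featurized MolecularGraph from a SMILES string
#'
#' Composes [parseSmiles()] and [featurizeAtom()] and wraps the result in a
#' validity-checked [MolecularGraph-class] object.
#'
#' @param drugId character(1) drug identifier.
#' @param smiles character(1) SMILES string.
#' @return a [MolecularGraph-class] object.
#' @examples
#' g <- buildGraph("benzene", "c1ccccc1")
#' numAtoms(g)
#' @export
buildGraph <- function(drugId, smiles) {
  sk <- parseSmiles(smiles, drugId = drugId)
  feats <- t(vapply(seq_len(nrow(sk$atoms)),
                    function(i) featurizeAtom(sk$atoms[i, ]),
                    numeric(.ATOM_FEATURE_DIM)))
  methods::new("MolecularGraph",
    drugId = as.character(drugId),
    smiles = smiles,
    atomFeatures = feats,
    edges = sk$edges,
    elements = sk$atoms$element
  )
}

#' Build graphs for a whole drug table
#'
#' @param drugs data.frame with columns `drug_id` and `smiles`.
#' @return named list of [MolecularGraph-class] objects.
#' @export
buildGraphs <- function(drugs) {
  out <- lapply(seq_len(nrow(drugs)),
                function(i) buildGraph(drugs$drug_id[i], drugs$smiles[i]))
  names(out) <- drugs$drug_id
  out
}

#' Read a drug table from TSV/CSV
#'
#' Expects header columns `drug_id` and `smiles`; lines starting with `#`
#' are ignored. Files ending in `.csv` are comma-separated, anything else is
#' tab-separated.
#'
#' @param path file path.
#' @return data.frame with columns `drug_id` and `smiles`.
#' @export
readDrugTable <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  if (!all(c("drug_id", "smiles") %in% names(df)))
    stop("drug table must have header columns 'drug_id' and 'smiles'")
  df[, c("drug_id", "smiles")]
}

#' Read a raw SMILES file (one SMILES per line) with auto-generated ids
#'
#' @param path file path.
#' @return data.frame with columns `drug_id` (`drug_0001`, ...) and `smiles`.
#' @export
readSmilesFile <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  data.frame(
    drug_id = sprintf("drug_%04d", seq_along(lines)),
    smiles = lines,
    stringsAsFactors = FALSE
  )
}
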