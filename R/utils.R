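# Internal numerical helpers shared across the encoder, predictor and protocol code.

#' Numerically stable softmax
#'
#' Subtracts the maximum before exponentiating so that large logits do not
#' overflow. Returns a vector of non-negative weights summing to 1.
#'
#' @param x numeric vector of logits.
#' @return numeric vector, same length as `x`.
#' @keywords internal
.softmax <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  z <- exp(x - max(x))
  z / sum(z)
}

#' @keywords internal
.relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' @keywords internal
.leakyRelu <- function(x, slope = 0.2) {
  pos <- x > 0
  x * (pos + slope * !pos)
}

#' @keywords internal
.leakyReluGrad <- function(x, slope = 0.2) {
  pos <- x > 0
  pos + slope * !pos
}

#' One-hot encode an integer into bins `lo:hi`, clamping out-of-range values
#' to the nearest bin with a warning.
#' @keywords internal
.oneHotClamped <- function(value, lo, hi, what = "value") {
  if (value < lo || value > hi) {
    warning(sprintf("%s %s outside [%d, %d]; clamped to nearest bin",
                    what, format(value), lo, hi), call. = FALSE)
    value <- min(max(value, lo), hi)
  }
  v <- numeric(hi - lo + 1L)
  v[value - lo + 1L] <- 1
  v
}

# ---- parameter-tree utilities ------------------------------------------------
# Model parameters live in nested lists whose leaves are numeric vectors or
# matrices. These helpers walk two (or more) trees of identical shape in
# lockstep, which is all Adam and the gradient accumulator need.

#' Apply a function over the leaves of parameter trees of identical shape.
#' @keywords internal
.treeMap <- function(f, ...) {
  trees <- list(...)
  first <- trees[[1L]]
  if (is.list(first)) {
    out <- vector("list", length(first))
    names(out) <- names(first)
    for (i in seq_along(first)) {
      out[[i]] <- do.call(.treeMap, c(list(f), lapply(trees, `[[`, i)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

#' Zero-filled copy of a parameter tree.
#' @keywords internal
.treeZero <- function(tree) .treeMap(function(x) x * 0, tree)

#' Elementwise sum of two parameter trees.
#' @keywords internal
.treeAdd <- function(a, b) .treeMap(`+`, a, b)

#' Glorot (fan-based) uniform initialization for a weight matrix.
#' @keywords internal
.glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

#' Derive a reproducible child seed from a base seed and stream index,
#' staying inside the 32-bit integer range.
#' @keywords internal
.childSeed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647
}

#' Canonical key for an unordered drug pair.
#' @keywords internal
.pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
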