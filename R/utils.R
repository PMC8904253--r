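# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' clobber the global random stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a master seed; keeps values
# within 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1103 * k) %% 2147483647)
}

#' Row-wise softmax
#' @param x numeric matrix of scores (rows = cases)
#' @return matrix of the same shape with rows summing to 1
#' @keywords internal
softmax_rows <- function(x) {
  x <- as.matrix(x)
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Pearson correlation of matching columns of two matrices (vectorized).
col_cor <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  n <- nrow(a)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  num <- colSums(ac * bc)
  den <- sqrt(colSums(ac^2) * colSums(bc^2))
  r <- num / den
  r[den == 0] <- NA_real_
  r
}

#' Benjamini-Hochberg adjusted q-values
#' @param p vector of p-values
#' @return vector of q-values
#' @export
bh_fdr <- function(p) stats::p.adjust(p, method = "BH")

# Permutation / bootstrap p-value with the (k+1)/(n+1) convention: never 0.
perm_pval <- function(null, observed, two_sided = FALSE) {
  if (two_sided) {
    (1 + sum(abs(null) >= abs(observed))) / (length(null) + 1)
  } else {
    (1 + sum(null >= observed)) / (length(null) + 1)
  }
}

#' Partial correlation of x and y controlling for z
#'
#' Uses the closed form on pairwise Pearson correlations:
#' (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)).
#' @param x,y,z numeric vectors of equal length
#' @return partial correlation in \[-1, 1\]
#' @export
partial_cor <- function(x, y, z) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance variable")
  if (stats::sd(z) == 0) stop("zero-variance control variable")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Per-row z-scoring; zero-variance rows map to 0.
zscore_rows <- function(x) {
  mu <- rowMeans(x)
  sdev <- apply(x, 1, stats::sd)
  sdev[sdev == 0] <- Inf
  (x - mu) / sdev
}

# Normalize a guessed/actual token for comparison: case-fold, strip
# punctuation and surrounding whitespace.
normalize_token <- function(x) {
  x <- tolower(trimws(x))
  gsub("[^a-z0-9']", "", x)
}

# Mean over index windows of the rows of `signal` (electrodes x samples),
# returned as events x electrodes. `from`/`to` are inclusive sample indices.
window_means <- function(signal, from, to) {
  cs <- cbind(0, t(apply(signal, 1, cumsum)))  # electrodes x (samples+1)
  len <- to - from + 1
  out <- (t(cs[, to + 1, drop = FALSE]) - t(cs[, from, drop = FALSE])) / len
  # out is events x electrodes when from/to are vectors over events
  out
}
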