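# Embedding-matrix manipulations used by the control analyses: arbitrary
# assignment, per-type averaging, occurrence scrambling, non-match
# assignment, and context concatenation (with PCA reduction).

#' Assign arbitrary (random per-type) embeddings
#'
#' One uniform\[-1,1\] vector per unique word type, broadcast to all of its
#' occurrences: word identity is preserved, semantic structure is not.
#'
#' @param events an `nlx_events` table
#' @param dim embedding dimension (default 50)
#' @param seed integer seed
#' @return an `nlx_embedding` of kind `"arbitrary"`
#' @export
assign_arbitrary <- function(events, dim = 50, seed = 1) {
  stopifnot(inherits(events, "nlx_events"))
  n_types <- max(events$type_id)
  with_seed(seed, {
    base <- matrix(stats::runif(n_types * dim, -1, 1), n_types, dim)
    new_embedding(base[events$type_id, , drop = FALSE], "arbitrary")
  })
}

#' Average contextual embeddings within word type
#'
#' Replaces each retained event's row by the mean over all occurrences of its
#' type, collapsing the contextual embedding into a per-type ("static-like")
#' vector. Events of types with fewer than `min_repetitions` occurrences are
#' dropped; the returned `index_map` gives the retained event indices.
#'
#' @param emb contextual `nlx_embedding`
#' @param events matching `nlx_events`
#' @param min_repetitions minimum occurrences per retained type (default 5)
#' @return list with `embedding` (kind `"derived"`, one row per retained
#'   event) and `index_map` (integer indices into the original events)
#' @export
average_by_type <- function(emb, events, min_repetitions = 5) {
  stopifnot(inherits(emb, "nlx_embedding"), inherits(events, "nlx_events"))
  if (embedding_kind(emb) != "contextual") {
    stop("average_by_type expects a contextual embedding")
  }
  counts <- table(events$type_id)
  ok_types <- as.integer(names(counts)[counts >= min_repetitions])
  if (length(ok_types) == 0) stop("no word type meets the repetition threshold")
  keep <- which(events$type_id %in% ok_types)
  means <- rowsum(unclass(emb)[keep, , drop = FALSE], events$type_id[keep])
  means <- means / as.vector(table(events$type_id[keep]))
  rows <- means[match(events$type_id[keep], as.integer(rownames(means))), ,
                drop = FALSE]
  list(embedding = new_embedding(rows, "derived", "type-averaged contextual"),
       index_map = keep)
}

# Permutation of 1..n with no fixed point (rejection-sampled); for n <= 3 a
# plain random permutation is used (a derangement can be degenerate or
# nonexistent for repeated vectors).
sample_derangement <- function(n) {
  if (n <= 3) return(sample.int(n))
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Scramble contextual embeddings across occurrences of the same word
#'
#' Within each word type, the rows are permuted across that type's
#' occurrences (fixed-point-free when possible), so each occurrence receives
#' the contextual embedding of the same word from a different context. The
#' multiset of rows per type is unchanged.
#'
#' @param emb contextual `nlx_embedding`
#' @param events matching `nlx_events`
#' @param seed integer seed
#' @return scrambled `nlx_embedding` (kind `"contextual"`)
#' @export
scramble_occurrences <- function(emb, events, seed = 1) {
  stopifnot(inherits(emb, "nlx_embedding"), inherits(events, "nlx_events"))
  if (embedding_kind(emb) != "contextual") {
    stop("scramble_occurrences expects a contextual embedding")
  }
  out <- unclass(emb)
  with_seed(seed, {
    for (t_id in unique(events$type_id)) {
      occ <- which(events$type_id == t_id)
      if (length(occ) < 2) next
      out[occ, ] <- out[occ[sample_derangement(length(occ))], , drop = FALSE]
    }
  })
  new_embedding(out, "contextual", "occurrence-scrambled")
}

#' Assign non-matching static embeddings
#'
#' A fixed-point-free permutation over unique word types maps each type to a
#' different type's static vector; all occurrences of a type still share one
#' (wrong) vector, so word identity is preserved while the semantic match is
#' destroyed.
#'
#' @param emb static `nlx_embedding`
#' @param events matching `nlx_events`
#' @param seed integer seed
#' @return an `nlx_embedding` of kind `"derived"`
#' @export
nonmatch_same_word <- function(emb, events, seed = 1) {
  stopifnot(inherits(emb, "nlx_embedding"), inherits(events, "nlx_events"))
  if (embedding_kind(emb) != "static") {
    stop("nonmatch_same_word expects a static embedding")
  }
  types <- sort(unique(events$type_id))
  if (length(types) < 2) stop("need >= 2 word types for a non-match assignment")
  type_rows <- unclass(emb)[match(types, events$type_id), , drop = FALSE]
  with_seed(seed, {
    perm <- if (length(types) == 2) c(2L, 1L) else {
      repeat {
        p <- sample.int(length(types))
        if (!any(p == seq_along(types))) break
      }
      p
    }
    rows <- type_rows[perm[match(events$type_id, types)], , drop = FALSE]
    new_embedding(rows, "derived", "non-match same-word static")
  })
}

#' Concatenate preceding-context embeddings and reduce by PCA
#'
#' Per event, the static vectors of the `k` preceding events are concatenated
#' (zero-padded at the start of the sequence) into a long context vector,
#' which is then reduced to `out_dim` dimensions with PCA. The principal
#' components are fit on `fit_idx` only (default: all rows) and applied
#' everywhere, so callers can restrict the fit to training folds.
#'
#' @param static_emb static (or arbitrary) `nlx_embedding`
#' @param events matching `nlx_events`
#' @param k number of preceding words (default 10); `k = 1` is the
#'   previous-word control
#' @param out_dim output dimension (default 50)
#' @param fit_idx rows used to fit the PCA (default all)
#' @return an `nlx_embedding` of kind `"derived"`, with attribute
#'   `explained_variance` (fraction captured by the retained components)
#' @export
concat_context_pca <- function(static_emb, events, k = 10, out_dim = 50,
                               fit_idx = NULL) {
  stopifnot(inherits(static_emb, "nlx_embedding"), inherits(events, "nlx_events"))
  d <- ncol(static_emb)
  n <- nrow(events)
  if (out_dim > k * d) stop("out_dim exceeds concatenated dimension")
  x <- unclass(static_emb)
  cc <- matrix(0, n, k * d)
  for (j in seq_len(k)) {
    rows <- seq_len(n) - j
    ok <- rows >= 1
    cc[ok, ((j - 1) * d + 1):(j * d)] <- x[rows[ok], , drop = FALSE]
  }
  fit_idx <- fit_idx %||% seq_len(n)
  pc <- stats::prcomp(cc[fit_idx, , drop = FALSE], center = TRUE, scale. = FALSE)
  ncomp <- min(out_dim, ncol(pc$rotation))
  red <- sweep(cc, 2, pc$center) %*% pc$rotation[, seq_len(ncomp), drop = FALSE]
  if (ncomp < out_dim) red <- cbind(red, matrix(0, n, out_dim - ncomp))
  ev <- sum(pc$sdev[seq_len(ncomp)]^2) / sum(pc$sdev^2)
  out <- new_embedding(red, "derived", sprintf("concat-%d-context + PCA-%d", k, out_dim))
  attr(out, "explained_variance") <- ev
  out
}

#' Concatenate previous and current word embeddings
#'
#' Per event, the previous event's row (zeros for the first event) is
#' concatenated with the current row; the dimension doubles.
#'
#' @param emb an `nlx_embedding`
#' @param events matching `nlx_events`
#' @return an `nlx_embedding` of kind `"derived"`
#' @export
concat_prev_current <- function(emb, events) {
  stopifnot(inherits(emb, "nlx_embedding"), inherits(events, "nlx_events"))
  x <- unclass(emb)
  n <- nrow(events)
  prev <- rbind(rep(0, ncol(x)), x[-n, , drop = FALSE])
  new_embedding(cbind(prev, x), "derived", "previous + current concatenation")
}
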