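# Lagged linear encoding: per-electrode, per-lag OLS maps from word
# embeddings to word-aligned neural responses, scored by the Pearson
# correlation of concatenated held-out predictions (tenfold CV).

#' Default lag grid
#'
#' 161 lags from -2000 to 2000 ms in 25-ms increments relative to word onset.
#' @return numeric vector of lags (ms)
#' @export
default_lags <- function() seq(-2000, 2000, by = 25)

# Sample windows for a lag: inclusive index range per event.
lag_window_idx <- function(events, fs, lag_ms, window_ms) {
  center <- round((events$onset_s + lag_ms / 1000) * fs) + 1
  half <- window_ms / 1000 * fs / 2
  from <- center - floor(half)
  to <- center + ceiling(half) - 1
  list(from = from, to = to)
}

#' Extract word-aligned lagged responses
#'
#' Per event and electrode, the mean of the samples in the 200-ms (default)
#' window centered on `onset + lag`. Events whose window falls outside the
#' recording are dropped with a warning; the retained indices are returned in
#' attribute `keep`.
#'
#' @param rec a preprocessed `nlx_recording`
#' @param events an `nlx_events` table
#' @param lag_ms signed lag in ms (negative = pre-onset)
#' @param window_ms averaging window (default 200)
#' @return events x electrodes matrix with attributes `lag_ms` and `keep`
#' @export
extract_lagged_responses <- function(rec, events, lag_ms, window_ms = 200) {
  stopifnot(inherits(rec, "nlx_recording"), inherits(events, "nlx_events"))
  idx <- lag_window_idx(events, rec$fs, lag_ms, window_ms)
  keep <- which(idx$from >= 1 & idx$to <= ncol(rec$signal))
  if (length(keep) < nrow(events)) {
    warning(sprintf("%d event(s) with windows outside the recording dropped",
                    nrow(events) - length(keep)))
  }
  out <- window_means(rec$signal, idx$from[keep], idx$to[keep])
  structure(out, lag_ms = lag_ms, window_ms = window_ms, keep = keep)
}

# Events valid at every lag of a grid (keeps row alignment across lags).
events_valid_at_lags <- function(rec, events, lags_ms, window_ms = 200) {
  lo <- lag_window_idx(events, rec$fs, min(lags_ms), window_ms)
  hi <- lag_window_idx(events, rec$fs, max(lags_ms), window_ms)
  which(lo$from >= 1 & hi$to <= ncol(rec$signal))
}

#' Random cross-validation fold assignment
#' @param n number of events
#' @param n_folds number of folds (default 10)
#' @param seed integer seed
#' @param contiguous use contiguous blocks instead of random assignment
#' @return integer vector of fold ids in 1..n_folds
#' @export
cv_folds <- function(n, n_folds = 10, seed = 1, contiguous = FALSE) {
  if (contiguous) {
    return(as.integer(cut(seq_len(n), breaks = n_folds, labels = FALSE)))
  }
  with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
}

# Per-fold held-out prediction operators for a shared design matrix.
# Returns, for each fold, the rows `test` and the matrix P such that
# held-out predictions = P %*% Y[train, ]. Uses QR; falls back to the
# minimum-norm (pseudoinverse) solution on rank deficiency, with a warning.
fold_predictors <- function(X, folds) {
  Xi <- cbind(1, unclass(X))
  lapply(sort(unique(folds)), function(f) {
    tr <- which(folds != f); te <- which(folds == f)
    A <- Xi[tr, , drop = FALSE]
    qr_a <- qr(A)
    if (qr_a$rank < ncol(A)) {
      warning("rank-deficient training design; using minimum-norm solution")
      sv <- svd(A)
      pos <- sv$d > max(sv$d) * 1e-10
      Ainv <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    } else {
      # (A'A)^-1 A' via QR
      Ainv <- qr.coef(qr_a, diag(nrow(A)))
    }
    list(test = te, train = tr, P = Xi[te, , drop = FALSE] %*% Ainv)
  })
}

# Concatenated held-out predictions for response matrix Y (events x m).
cv_predict <- function(fp, Y) {
  Y <- as.matrix(Y)
  pred <- matrix(NA_real_, nrow(Y), ncol(Y))
  for (f in fp) pred[f$test, ] <- f$P %*% Y[f$train, , drop = FALSE]
  pred
}

#' Cross-validated OLS encoding fit
#'
#' Ordinary least-squares regression (with intercept) from embeddings to each
#' electrode's lagged response, under `n_folds`-fold cross-validation with a
#' random (seeded) fold assignment. The held-out predictions of all folds are
#' concatenated and a single Pearson correlation per electrode is computed
#' over all events.
#'
#' @param X embedding matrix (events x dims)
#' @param y response matrix (events x electrodes) or vector
#' @param n_folds number of folds (default 10)
#' @param seed integer seed for the fold assignment
#' @param folds optional explicit fold assignment (overrides `seed`)
#' @return list with `r` (per-electrode correlation), `predicted` (events x
#'   electrodes held-out predictions), `folds`, and `weights` (per-fold
#'   coefficient matrices, intercept first)
#' @export
fit_encoding_cv <- function(X, y, n_folds = 10, seed = 1, folds = NULL) {
  X <- as.matrix(unclass(X)); Y <- as.matrix(y)
  if (nrow(X) != nrow(Y)) stop("X rows must align with y rows")
  if (nrow(X) < ncol(X) + n_folds) {
    stop("too few events for the requested dimensionality and fold count")
  }
  folds <- folds %||% cv_folds(nrow(X), n_folds, seed)
  fp <- fold_predictors(X, folds)
  pred <- cv_predict(fp, Y)
  Xi <- cbind(1, X)
  weights <- lapply(fp, function(f) {
    qr.coef(qr(Xi[f$train, , drop = FALSE]), Y[f$train, , drop = FALSE])
  })
  list(r = as.vector(col_cor(pred, Y)), predicted = pred, folds = folds,
       weights = weights)
}

#' Encoding across a lag grid
#'
#' Runs the cross-validated encoding fit at every lag of the grid; the fold
#' assignment is shared across lags and electrodes. Events whose window falls
#' outside the recording at any lag of the grid are dropped throughout, so
#' rows stay aligned.
#'
#' @param rec preprocessed `nlx_recording`
#' @param events `nlx_events`
#' @param emb `nlx_embedding` (one row per event)
#' @param lags_ms lag grid in ms (default [default_lags()])
#' @param n_folds folds (default 10)
#' @param seed integer seed
#' @param window_ms averaging window (default 200)
#' @param folds optional explicit fold assignment over the *retained* events
#' @return object of class `nlx_encoding_map`: list with `r` (electrodes x
#'   lags), `lags_ms`, `folds`, `keep` (retained event indices)
#' @export
encode_all_lags <- function(rec, events, emb, lags_ms = default_lags(),
                            n_folds = 10, seed = 1, window_ms = 200,
                            folds = NULL) {
  keep <- events_valid_at_lags(rec, events, lags_ms, window_ms)
  if (length(keep) < nrow(events)) {
    warning(sprintf("%d event(s) outside the recording at extreme lags dropped",
                    nrow(events) - length(keep)))
  }
  X <- unclass(emb)[keep, , drop = FALSE]
  folds <- folds %||% cv_folds(length(keep), n_folds, seed)
  fp <- fold_predictors(X, folds)
  ne <- nrow(rec$signal)
  r <- matrix(NA_real_, ne, length(lags_ms),
              dimnames = list(rec$electrode_ids, lags_ms))
  ev_keep <- events[keep, , drop = FALSE]
  class(ev_keep) <- c("nlx_events", "data.frame")
  for (li in seq_along(lags_ms)) {
    Y <- extract_lagged_responses(rec, ev_keep, lags_ms[li], window_ms)
    pred <- cv_predict(fp, Y)
    r[, li] <- col_cor(pred, Y)
  }
  structure(list(r = r, lags_ms = lags_ms, folds = folds, keep = keep,
                 window_ms = window_ms),
            class = "nlx_encoding_map")
}

#' @export
print.nlx_encoding_map <- function(x, ...) {
  cat(sprintf("<nlx_encoding_map> %d electrodes x %d lags (%g..%g ms); peak mean r = %.3f at %g ms\n",
              nrow(x$r), length(x$lags_ms), min(x$lags_ms), max(x$lags_ms),
              max(colMeans(x$r)), x$lags_ms[which.max(colMeans(x$r))]))
  invisible(x)
}

#' Encoding maps for the correct/incorrect prediction split
#'
#' Three encoding maps mirroring the predicted-versus-perceived analysis:
#' (1) correctly predicted words modeled with the perceived-word embedding;
#' (2) incorrectly predicted words modeled with the *predicted*-word
#' embedding; (3) incorrectly predicted words modeled with the perceived-word
#' embedding.
#'
#' @param rec preprocessed `nlx_recording`
#' @param events `nlx_events`
#' @param emb_predicted embedding rows for each event's predicted word
#' @param emb_perceived embedding rows for each event's actual word
#' @param correct logical per event: was the prediction correct?
#' @param lags_ms,n_folds,seed,window_ms as in [encode_all_lags()]
#' @return named list of three `nlx_encoding_map`s: `correct_perceived`,
#'   `incorrect_predicted`, `incorrect_perceived`
#' @export
encode_by_prediction_split <- function(rec, events, emb_predicted,
                                       emb_perceived, correct,
                                       lags_ms = default_lags(), n_folds = 10,
                                       seed = 1, window_ms = 200) {
  stopifnot(length(correct) == nrow(events))
  d <- ncol(emb_perceived)
  subset_events <- function(idx) {
    if (length(idx) == 0) stop("empty prediction-split class")
    if (length(idx) < d + n_folds) {
      stop("prediction-split class has too few events for folds and dims")
    }
    ev <- events[idx, , drop = FALSE]
    class(ev) <- c("nlx_events", "data.frame")
    ev
  }
  run <- function(idx, emb) {
    encode_all_lags(rec, subset_events(idx), new_embedding(
      unclass(emb)[idx, , drop = FALSE], "derived"),
      lags_ms, n_folds, seed, window_ms)
  }
  ic <- which(!correct)
  list(
    correct_perceived = run(which(correct), emb_perceived),
    incorrect_predicted = run(ic, emb_predicted),
    incorrect_perceived = run(ic, emb_perceived)
  )
}
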