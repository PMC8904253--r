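# Behavioral predictability scoring, model confidence/surprise measures,
# accuracy splits, calibration, agreement, context-window sweeps, and
# n-gram baselines.

#' Per-event behavioral predictability score
#'
#' For each event, the fraction of raters whose normalized guess (case-folded,
#' punctuation-stripped) equals the actual token. 1 means every rater guessed
#' the upcoming word; 0 means none did.
#'
#' @param behavior an `nlx_behavior` matrix (raters x events) or character
#'   matrix of guesses
#' @param events matching `nlx_events`
#' @return numeric vector of per-event scores in \[0,1\]
#' @export
predictability_score <- function(behavior, events) {
  guesses <- as.matrix(behavior)
  if (nrow(guesses) == 0) stop("no raters")
  if (ncol(guesses) != nrow(events)) stop("guesses not aligned to events")
  actual <- normalize_token(events$token)
  norm <- matrix(normalize_token(guesses), nrow(guesses), ncol(guesses))
  colMeans(norm == matrix(actual, nrow(guesses), ncol(guesses), byrow = TRUE))
}

dist_probs <- function(dists) {
  if (inherits(dists, "nlx_dists")) return(dists$probs)
  if (is.null(dim(dists))) rbind(as.numeric(dists)) else as.matrix(dists)
}

#' Prediction entropy (confidence), in nats
#'
#' `-sum_i p_i log p_i` with `0 log 0 := 0`. Low entropy means a confident
#' (peaked) next-word distribution; the maximum, `log n`, is attained by the
#' uniform distribution.
#'
#' @param dists an `nlx_dists`, or a probability matrix (events x vocabulary),
#'   or a single probability vector
#' @param base logarithm base (default `exp(1)`, i.e. nats)
#' @return numeric vector of per-event entropies
#' @export
entropy <- function(dists, base = exp(1)) {
  p <- dist_probs(dists)
  if (is.vector(p)) p <- matrix(p, nrow = 1)
  if (any(p < 0)) stop("negative probabilities")
  lp <- ifelse(p > 0, log(p), 0)
  as.vector(-rowSums(p * lp)) / log(base)
}

#' Cross-entropy surprise of the actual word, in nats
#'
#' `-log P(x_actual)`: the lower the probability assigned to the word that
#' actually occurs, the larger the surprise when it is perceived.
#'
#' @param dists an `nlx_dists` (provides both probabilities and actual-word
#'   indices), or a probability matrix with `actual` supplied
#' @param actual integer vector of actual-word indices (if `dists` is a matrix)
#' @param clamp if TRUE, zero probabilities are clamped to 1e-10 with a
#'   warning instead of raising an error
#' @param base logarithm base (default nats)
#' @return numeric vector of per-event surprises (>= 0)
#' @export
cross_entropy <- function(dists, actual = NULL, clamp = FALSE, base = exp(1)) {
  p <- dist_probs(dists)
  actual <- actual %||% dists$actual
  pa <- p[cbind(seq_len(nrow(p)), actual)]
  if (any(pa <= 0)) {
    if (!clamp) stop("zero probability assigned to an actual word")
    warning("zero probabilities clamped to 1e-10")
    pa <- pmax(pa, 1e-10)
  }
  -log(pa) / log(base)
}

#' Top-k accuracy split
#'
#' Labels each event correct if the actual word is among the k most probable
#' words of its prediction distribution (ties broken deterministically by
#' vocabulary index).
#'
#' @param dists an `nlx_dists`
#' @param k top-k cutoff (1 or 5 in the analyses; any k <= vocabulary size)
#' @return logical vector per event (TRUE = correctly predicted)
#' @export
accuracy_split <- function(dists, k = 5) {
  p <- dist_probs(dists)
  if (k > ncol(p)) stop("k exceeds vocabulary size")
  vapply(seq_len(nrow(p)), function(i) {
    topk <- order(-p[i, ], seq_len(ncol(p)))[seq_len(k)]
    dists$actual[i] %in% topk
  }, logical(1))
}

#' Calibration curve of assigned probability versus realized accuracy
#'
#' Bins the assigned probabilities and reports the empirical accuracy per
#' bin. Empty bins are reported as `NA`, not zero.
#'
#' @param prob assigned probabilities in \[0,1\]
#' @param correct logical correctness per event
#' @param breaks bin edges (default 10 equal bins over \[0,1\])
#' @return data.frame with `bin_low`, `bin_high`, `bin_mid`, `accuracy`, `n`
#' @export
calibration_curve <- function(prob, correct, breaks = seq(0, 1, by = 0.1)) {
  if (any(prob < 0 | prob > 1)) stop("probabilities must lie in [0,1]")
  bin <- cut(prob, breaks, include.lowest = TRUE, labels = FALSE)
  nb <- length(breaks) - 1
  acc <- rep(NA_real_, nb); n <- integer(nb); mp <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    sel <- which(bin == b)
    n[b] <- length(sel)
    if (n[b] > 0) {
      acc[b] <- mean(correct[sel])
      mp[b] <- mean(prob[sel])
    }
  }
  data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
             bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
             mean_prob = mp, accuracy = acc, n = n)
}

#' Agreement between two top-1 predictors
#'
#' Fraction of events where the two predictors' most probable words match
#' (irrespective of accuracy), plus the 2x2 quadrant fractions of joint
#' correctness (summing to 1).
#'
#' @param topA,topB per-event top-1 predicted tokens
#' @param correctA,correctB per-event logical correctness of each predictor
#' @return list with `agreement` and `quadrants` (named fractions:
#'   `both_correct`, `both_incorrect`, `only_A`, `only_B`)
#' @export
agreement_rate <- function(topA, topB, correctA, correctB) {
  if (length(topA) != length(topB)) stop("predictor outputs differ in length")
  list(
    agreement = mean(normalize_token(topA) == normalize_token(topB)),
    quadrants = c(
      both_correct = mean(correctA & correctB),
      both_incorrect = mean(!correctA & !correctB),
      only_A = mean(correctA & !correctB),
      only_B = mean(!correctA & correctB)
    )
  )
}

#' Context-window sweep
#'
#' For each context-window size, queries `predictor(context_tokens, actual)`
#' for every event (the context is the up-to-`w` preceding tokens; shorter
#' histories are passed whole) and correlates the returned probabilities with
#' the behavioral predictability scores.
#'
#' @param predictor function(context_tokens, actual_token) -> probability
#' @param events `nlx_events`
#' @param window_sizes integer vector of context sizes
#' @param scores per-event behavioral predictability scores
#' @return data.frame with `window`, `r` (Pearson correlation), `n_used`
#' @export
context_window_sweep <- function(predictor, events, window_sizes, scores) {
  tokens <- events$token
  n <- length(tokens)
  out <- lapply(window_sizes, function(w) {
    p <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      ctx <- tokens[seq_len(max(0, i - 1))]
      if (length(ctx) > w) ctx <- ctx[(length(ctx) - w + 1):length(ctx)]
      p[i] <- tryCatch(predictor(ctx, tokens[i]), error = function(e) NA_real_)
    }
    ok <- is.finite(p) & is.finite(scores)
    r <- if (stats::sd(p[ok]) == 0) 0 else stats::cor(p[ok], scores[ok])
    data.frame(window = w, r = r, n_used = sum(ok))
  })
  do.call(rbind, out)
}

#' Fit an n-gram language model
#'
#' Counts n-grams over a lowercased, punctuation-stripped token stream.
#' Conditional probabilities are maximum-likelihood (`"mle"`: unseen history
#' gives probability 0) or add-k smoothed (`"add_k"`:
#' `(c(h,w) + k) / (c(h) + k V)`).
#'
#' @param tokens character vector of corpus tokens
#' @param n n-gram order (2..5 typical)
#' @param smoothing "mle" or "add_k"
#' @param k add-k constant (default 1, i.e. Laplace)
#' @return object of class `nlx_ngram`
#' @export
ngram_fit <- function(tokens, n = 2, smoothing = c("mle", "add_k"), k = 1) {
  smoothing <- match.arg(smoothing)
  if (length(tokens) < n) stop("corpus shorter than n-gram order")
  tokens <- normalize_token(tokens)
  tokens <- tokens[nzchar(tokens)]
  vocab <- sort(unique(tokens))
  m <- length(tokens)
  hist_str <- vapply(seq_len(m - n + 1), function(i) {
    paste(tokens[i:(i + n - 2)], collapse = " ")
  }, character(1))
  word <- tokens[seq(n, m)]
  gram_tab <- table(paste(hist_str, word, sep = "\t"))
  hist_tab <- table(hist_str)
  structure(list(n = n, smoothing = smoothing, k = k, vocab = vocab,
                 gram = gram_tab, hist = hist_tab),
            class = "nlx_ngram")
}

#' Conditional n-gram probability
#'
#' @param model an `nlx_ngram`
#' @param context character vector of preceding tokens (at least n-1; only
#'   the last n-1 are used)
#' @param word the word whose probability is requested
#' @return probability; under MLE an unseen history yields 0 with attribute
#'   `unseen_history = TRUE`
#' @export
ngram_prob <- function(model, context, word) {
  n <- model$n
  context <- normalize_token(context)
  word <- normalize_token(word)
  if (length(context) < n - 1) return(structure(NA_real_, short_history = TRUE))
  h <- paste(utils::tail(context, n - 1), collapse = " ")
  ch <- if (h %in% names(model$hist)) as.numeric(model$hist[[h]]) else 0
  key <- paste(h, word, sep = "\t")
  chw <- if (key %in% names(model$gram)) as.numeric(model$gram[[key]]) else 0
  v <- length(model$vocab)
  if (model$smoothing == "add_k") {
    (chw + model$k) / (ch + model$k * v)
  } else {
    if (ch == 0) structure(0, unseen_history = TRUE) else chw / ch
  }
}

#' Per-event n-gram probabilities over an event sequence
#'
#' @param model an `nlx_ngram`
#' @param tokens token sequence (e.g. `events$token`)
#' @return numeric vector: probability of each token given its n-1 preceding
#'   tokens (`NA` where the history is shorter than n-1)
#' @export
ngram_prob_events <- function(model, tokens) {
  vapply(seq_along(tokens), function(i) {
    ctx <- tokens[seq_len(i - 1)]
    as.numeric(ngram_prob(model, ctx, tokens[i]))
  }, numeric(1))
}
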