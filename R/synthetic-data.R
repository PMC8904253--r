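# Synthetic-data generators with known ground truth.
#
# Every downstream stage (preprocessing, encoding, significance testing,
# confidence/surprise coupling, decoding) is exercised on data from these
# generators, whose planted structure is recorded in a ground-truth ledger.

#' Generate a Zipfian vocabulary
#'
#' Word-type relative frequencies are proportional to `rank^(-zipf_exponent)`,
#' emulating the heavy-tailed frequency profile of natural speech (which is
#' what guarantees that a subset of word types recurs often enough, e.g. five
#' or more times, to support per-type analyses).
#'
#' @param n_types number of word types (>= 2)
#' @param zipf_exponent nonnegative Zipf exponent; 0 gives a uniform vocabulary
#' @param seed integer seed
#' @return object of class `nlx_vocabulary`: list with `types` (character)
#'   and `frequencies` (positive, summing to 1)
#' @export
gen_vocabulary <- function(n_types, zipf_exponent = 1, seed = 1) {
  if (!is.numeric(n_types) || n_types < 2) stop("n_types must be >= 2")
  if (zipf_exponent < 0) stop("zipf_exponent must be nonnegative")
  n_types <- as.integer(n_types)
  w <- seq_len(n_types)^(-zipf_exponent)
  vocab <- list(
    types = sprintf("w%04d", seq_len(n_types)),
    frequencies = w / sum(w)
  )
  class(vocab) <- "nlx_vocabulary"
  vocab
}

#' Generate a word-event table
#'
#' Tokens are sampled i.i.d. from the vocabulary frequencies; inter-onset gaps
#' are exponential with a 50-ms floor (natural-speech-like, keeps successive
#' events separable), with the stated mean.
#'
#' @param vocab an `nlx_vocabulary`
#' @param n_words number of word events (>= 1)
#' @param mean_gap_s mean inter-onset gap in seconds (> 0.05)
#' @param seed integer seed
#' @param start_s leading silence before the first onset (default 3 s), so
#'   pre-onset analysis windows exist even for the first words
#' @return data.frame of class `nlx_events` with columns `token`, `onset_s`,
#'   `offset_s`, `type_id`, `repetition_count`
#' @export
gen_word_events <- function(vocab, n_words, mean_gap_s = 0.3, seed = 1,
                            start_s = 3) {
  stopifnot(inherits(vocab, "nlx_vocabulary"))
  if (!is.numeric(n_words) || n_words < 1) stop("n_words must be >= 1")
  if (mean_gap_s <= 0.05) stop("mean_gap_s must exceed the 50-ms gap floor")
  n_words <- as.integer(n_words)
  with_seed(seed, {
    type_id <- sample.int(length(vocab$types), n_words, replace = TRUE,
                          prob = vocab$frequencies)
    gaps <- 0.05 + stats::rexp(n_words, rate = 1 / (mean_gap_s - 0.05))
    onset <- start_s + cumsum(gaps)
    # word duration: most of the gap to the next onset, capped at 400 ms
    next_gap <- c(gaps[-1], mean_gap_s)
    offset <- onset + pmin(0.8 * next_gap, 0.4)
    ev <- data.frame(
      token = vocab$types[type_id],
      onset_s = onset,
      offset_s = offset,
      type_id = type_id,
      stringsAsFactors = FALSE
    )
    counts <- table(factor(type_id, levels = seq_along(vocab$types)))
    ev$repetition_count <- as.integer(counts[type_id])
    class(ev) <- c("nlx_events", "data.frame")
    ev
  })
}

#' Construct an embedding matrix
#'
#' @param vectors numeric matrix, one row per word event
#' @param kind one of "arbitrary", "static", "contextual", "derived"
#' @param note free-text provenance note
#' @return an `nlx_embedding`
#' @export
new_embedding <- function(vectors, kind, note = "") {
  vectors <- as.matrix(vectors)
  structure(vectors, kind = kind, note = note,
            class = c("nlx_embedding", class(vectors)))
}

#' Embedding kind tag
#' @param emb an `nlx_embedding`
#' @return one of "arbitrary", "static", "contextual", "derived"
#' @export
embedding_kind <- function(emb) attr(emb, "kind")

#' Generate word embeddings for a sequence of events
#'
#' Three kinds are supported, mirroring the embedding families compared in
#' the analyses:
#' \itemize{
#'   \item `arbitrary`: one uniform\[-1,1\] vector per word type, identical
#'     across occurrences -- carries word identity but no semantic structure.
#'   \item `static`: one Gaussian vector per type with a planted low-rank
#'     similarity structure (types share a 5-dimensional latent factor),
#'     standardized to unit per-coordinate variance.
#'   \item `contextual`: `sqrt(1 - s^2) * static_base(type) + s * c_i`, where
#'     `s = context_strength` and `c_i` is an occurrence-specific unit-variance
#'     component correlated with the static embeddings of the preceding
#'     `context_k` events (geometric weights), so all occurrences of a type
#'     share a vector iff `s = 0`.
#' }
#'
#' @param events an `nlx_events` table
#' @param dim embedding dimension (>= 1)
#' @param kind "arbitrary", "static" or "contextual"
#' @param context_strength scalar in \[0,1\]; share of occurrence-specific
#'   (contextual) standard deviation for `kind = "contextual"`
#' @param context_k number of preceding events feeding the contextual component
#' @param seed integer seed
#' @return an `nlx_embedding` matrix (events x dim) with attributes `kind`,
#'   `dim`; for contextual embeddings also `static_base` (the per-event static
#'   rows) and `context_strength`
#' @export
gen_embeddings <- function(events, dim = 50,
                           kind = c("static", "arbitrary", "contextual"),
                           context_strength = 0.8, context_k = 10, seed = 1) {
  stopifnot(inherits(events, "nlx_events"))
  kind <- match.arg(kind)
  if (dim < 1) stop("dim must be >= 1")
  if (context_strength < 0 || context_strength > 1) {
    stop("context_strength must lie in [0, 1]")
  }
  n <- nrow(events)
  n_types <- max(events$type_id)
  with_seed(seed, {
    if (kind == "arbitrary") {
      base <- matrix(stats::runif(n_types * dim, -1, 1), n_types, dim)
      return(new_embedding(base[events$type_id, , drop = FALSE], "arbitrary"))
    }
    # static base with planted low-rank similarity among types
    r <- min(5L, dim)
    f_load <- matrix(stats::rnorm(n_types * r), n_types, r)
    g <- matrix(stats::rnorm(r * dim), r, dim) / sqrt(r)
    base <- sqrt(0.5) * (f_load %*% g) + sqrt(0.5) * matrix(stats::rnorm(n_types * dim), n_types, dim)
    static_rows <- base[events$type_id, , drop = FALSE]
    if (kind == "static") return(new_embedding(static_rows, "static"))
    s <- context_strength
    # occurrence-specific component: geometric mixture of the preceding
    # context_k events' static vectors plus fresh noise, unit variance
    wts <- 0.7^(0:(context_k - 1))
    mix_w <- 0.5  # share of context-history sd inside the component
    ctx <- matrix(0, n, dim)
    for (i in seq_len(n)) {
      j <- seq(i - 1, by = -1, length.out = min(context_k, i - 1))
      hist_part <-
        if (length(j) == 0) stats::rnorm(dim) else {
          w <- wts[seq_along(j)]
          h <- colSums(base[events$type_id[j], , drop = FALSE] * w) / sqrt(sum(w^2))
          h
        }
      ctx[i, ] <- mix_w * hist_part + sqrt(1 - mix_w^2) * stats::rnorm(dim)
    }
    vec <- sqrt(1 - s^2) * static_rows + s * ctx
    emb <- new_embedding(vec, "contextual")
    attr(emb, "static_base") <- static_rows
    attr(emb, "context_strength") <- s
    emb
  })
}

#' Generate next-word prediction distributions
#'
#' Each event gets a temperature-controlled softmax over the vocabulary
#' (temperature = 1/confidence) on i.i.d. Gaussian logits. For a Bernoulli
#' subset of events the actual word's logit is boosted just above a uniformly
#' drawn rank within the top `accuracy_k`, so boosted events are predicted
#' correctly at k = `accuracy_k` while their top-1 confidence stays graded
#' (mirroring predictors whose top-5 hit rate well exceeds their top-1 hit
#' rate). Because an unboosted event still lands in a random top-k set with
#' probability k/n, the boost probability is inverse-corrected,
#' `a' = (accuracy - k/n) / (1 - k/n)`, so the realized top-`accuracy_k`
#' accuracy matches `accuracy` in expectation.
#'
#' @param events an `nlx_events` table
#' @param vocab the matching `nlx_vocabulary`
#' @param confidence positive scalar; inverse softmax temperature. Small
#'   values approach the uniform distribution.
#' @param accuracy target top-`accuracy_k` accuracy in \[0,1\]
#' @param accuracy_k the k at which `accuracy` is targeted (default 5)
#' @param seed integer seed
#' @return object of class `nlx_dists`: list with `probs` (events x n matrix,
#'   rows sum to 1), `actual` (index of the actually occurring word) and
#'   `vocab`
#' @export
gen_prediction_distributions <- function(events, vocab, confidence = 2,
                                         accuracy = 0.62, accuracy_k = 5,
                                         seed = 1) {
  stopifnot(inherits(events, "nlx_events"), inherits(vocab, "nlx_vocabulary"))
  if (confidence <= 0) stop("confidence must be positive")
  if (accuracy < 0 || accuracy > 1) stop("accuracy must lie in [0, 1]")
  n_types <- length(vocab$types)
  if (max(events$type_id) > n_types) stop("vocabulary does not match events")
  n <- nrow(events)
  chance <- accuracy_k / n_types
  boost_p <- max(0, min(1, (accuracy - chance) / (1 - chance)))
  with_seed(seed, {
    logits <- matrix(stats::rnorm(n * n_types), n, n_types)
    boosted <- stats::runif(n) < boost_p
    ranks <- sample.int(accuracy_k, n, replace = TRUE)
    for (i in which(boosted)) {
      others <- sort(logits[i, -events$type_id[i]], decreasing = TRUE)
      logits[i, events$type_id[i]] <- others[ranks[i]] + 0.25
    }
    probs <- softmax_rows(logits * confidence)
    out <- list(probs = probs, actual = events$type_id, vocab = vocab,
                boosted = boosted)
    class(out) <- "nlx_dists"
    out
  })
}

#' Gaussian lag kernel
#'
#' Convenience constructor for the evoked-response kernel used by
#' [gen_neural_recording()]: a Gaussian bump of unit peak gain centered at
#' `center_ms` after word onset.
#'
#' @param center_ms kernel peak relative to onset (ms); positive = post-onset
#' @param width_ms Gaussian s.d. (ms)
#' @param support_ms half-support; the kernel is zero outside
#'   `center_ms +/- support_ms`
#' @return list with `lag_s` and `gain`, sampled on a 1-ms grid
#' @export
lag_kernel_gaussian <- function(center_ms = 150, width_ms = 60,
                                support_ms = 3 * width_ms) {
  t_ms <- seq(center_ms - support_ms, center_ms + support_ms, by = 1)
  list(lag_s = t_ms / 1000, gain = exp(-0.5 * ((t_ms - center_ms) / width_ms)^2))
}

# Sample a kernel onto the recording's sample grid.
kernel_taps <- function(kernel, fs) {
  lag_smp <- round(range(kernel$lag_s) * fs)
  taps_at <- seq(lag_smp[1], lag_smp[2])
  gain <- stats::approx(kernel$lag_s * fs, kernel$gain, xout = taps_at,
                        yleft = 0, yright = 0)$y
  list(offsets = taps_at, gain = gain)
}

# Spectrally shaped 1/f^alpha Gaussian noise, unit variance per electrode.
pink_noise <- function(n_electrodes, n_samples, exponent) {
  white <- matrix(stats::rnorm(n_electrodes * n_samples), n_samples, n_electrodes)
  if (exponent == 0) return(t(white))
  f <- c(0, seq_len(n_samples - 1))
  f <- pmin(f, n_samples - f)  # two-sided frequency index
  shape <- c(1, (f[-1])^(-exponent / 2))
  sh <- Re(stats::mvfft(stats::mvfft(white) * shape, inverse = TRUE)) / n_samples
  sh <- sweep(sh, 2, apply(sh, 2, stats::sd), "/")
  t(sh)
}

#' Generate a word-evoked multi-electrode recording
#'
#' Each electrode's evoked signal is the lag-kernel-convolved projection of
#' the per-event embeddings onto a random electrode tuning vector:
#' `signal_e(t) = sum_w kernel(t - onset_w) * <u_e, emb_w>`, rescaled so that
#' the realized evoked/noise variance ratio equals `snr`, plus unit-variance
#' `1/f^noise_exponent` Gaussian noise. Additional evoked components (e.g.
#' prediction-locked pre-onset activity, or per-event scalar modulation such
#' as entropy) can be planted via `extra_components`.
#'
#' @param events an `nlx_events` table
#' @param embeddings an `nlx_embedding` with one row per event
#' @param kernel lag kernel as returned by [lag_kernel_gaussian()]
#' @param n_electrodes electrode count
#' @param fs sampling rate (Hz)
#' @param snr requested evoked/noise variance ratio (0 = pure noise)
#' @param noise_exponent spectral exponent alpha of the 1/f^alpha noise
#' @param seed integer seed
#' @param extra_components optional list of extra evoked components, each a
#'   list with `features` (events x p matrix), `kernel`, `weight`
#'   (gain relative to the main component) and optionally `tuning`
#'   (p x n_electrodes matrix; default random Gaussian)
#' @param pad_s silent padding before the first and after the last event (s)
#' @return list with `recording` (an `nlx_recording`) and `ledger`
#'   (ground truth: tuning vectors, kernel, snr, seed, ...)
#' @export
gen_neural_recording <- function(events, embeddings, kernel = lag_kernel_gaussian(),
                                 n_electrodes = 20, fs = 512, snr = 1,
                                 noise_exponent = 1, seed = 1,
                                 extra_components = NULL, pad_s = 3) {
  stopifnot(inherits(events, "nlx_events"))
  if (nrow(embeddings) < nrow(events)) stop("embedding rows fewer than events")
  if (fs <= 0) stop("fs must be positive")
  if (snr < 0) stop("snr must be nonnegative")
  n <- nrow(events)
  dur <- max(events$offset_s) + pad_s
  # round up to a 5-smooth length: keeps every FFT-based stage fast
  n_samples <- stats::nextn(ceiling(dur * fs), c(2, 3, 5))
  onset_smp <- round(events$onset_s * fs) + 1
  with_seed(seed, {
    comps <- c(
      list(list(features = unclass(embeddings), kernel = kernel, weight = 1)),
      extra_components %||% list()
    )
    evoked <- matrix(0, n_electrodes, n_samples)
    tuning <- vector("list", length(comps))
    for (ci in seq_along(comps)) {
      feat <- as.matrix(comps[[ci]]$features)
      u <- comps[[ci]]$tuning %||%
        (matrix(stats::rnorm(ncol(feat) * n_electrodes), ncol(feat),
                n_electrodes) / sqrt(ncol(feat)))
      proj <- feat[seq_len(n), , drop = FALSE] %*% u        # events x electrodes
      taps <- kernel_taps(comps[[ci]]$kernel %||% kernel, fs)
      # impulse train at word onsets, convolved with the kernel by FFT
      # (circular; the silent padding at both ends makes wraparound inert)
      agg <- rowsum(proj, group = onset_smp)
      imp <- matrix(0, n_samples, n_electrodes)
      imp[as.integer(rownames(agg)), ] <- agg
      kvec <- numeric(n_samples)
      kvec[(taps$offsets %% n_samples) + 1] <- taps$gain
      part <- Re(stats::mvfft(stats::mvfft(imp) * as.vector(stats::fft(kvec)),
                              inverse = TRUE)) / n_samples
      evoked <- evoked + (comps[[ci]]$weight %||% 1) * t(part)
      tuning[[ci]] <- u
    }
    noise <- pink_noise(n_electrodes, n_samples, noise_exponent)
    ev_sd <- stats::sd(as.vector(evoked))
    scale <- if (ev_sd == 0 || snr == 0) 0 else sqrt(snr) / ev_sd *
      stats::sd(as.vector(noise))
    signal <- scale * evoked + noise
    rec <- new_recording(signal, fs, stage = "smoothed")
    ledger <- list(
      tuning = tuning[[1]], extra_tuning = tuning[-1],
      kernel = kernel, snr = snr, noise_exponent = noise_exponent,
      scale = scale, seed = seed,
      context_strength = attr(embeddings, "context_strength")
    )
    list(recording = rec, ledger = ledger)
  })
}

#' Generate behavioral next-word guesses
#'
#' Each of `n_raters` simulated raters guesses each event's upcoming word by
#' sampling from that event's prediction distribution.
#'
#' @param events an `nlx_events` table
#' @param dists an `nlx_dists` object aligned to `events`
#' @param n_raters number of raters (>= 1)
#' @param seed integer seed
#' @return character matrix (raters x events) of guessed tokens, class
#'   `nlx_behavior`
#' @export
gen_behavioral_responses <- function(events, dists, n_raters = 50, seed = 1) {
  stopifnot(inherits(events, "nlx_events"), inherits(dists, "nlx_dists"))
  if (n_raters < 1) stop("n_raters must be >= 1")
  n <- nrow(events)
  types <- dists$vocab$types
  with_seed(seed, {
    guesses <- matrix("", n_raters, n)
    for (w in seq_len(n)) {
      guesses[, w] <- types[sample.int(length(types), n_raters, replace = TRUE,
                                       prob = dists$probs[w, ])]
    }
    structure(guesses, class = c("nlx_behavior", "matrix", "array"))
  })
}
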