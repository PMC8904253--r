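# Shared small fixtures, built in code.

# Hand-built event table with explicit onsets (seconds).
make_events <- function(tokens, onsets, gap = 0.25) {
  type_id <- as.integer(factor(tokens, levels = unique(tokens)))
  ev <- data.frame(token = tokens, onset_s = onsets,
                   offset_s = onsets + gap * 0.8, type_id = type_id,
                   stringsAsFactors = FALSE)
  counts <- table(type_id)
  ev$repetition_count <- as.integer(counts[as.character(type_id)])
  class(ev) <- c("nlx_events", "data.frame")
  ev
}

# Small standard synthetic scene used by several encoding/stats tests.
small_scene <- function(n_words = 200, n_types = 30, dim = 8, snr = 2,
                        fs = 64, seed = 42, kind = "static", strength = 0.8,
                        n_electrodes = 10, center_ms = 150) {
  vocab <- gen_vocabulary(n_types, 1.1, seed)
  ev <- gen_word_events(vocab, n_words, 0.3, seed + 1)
  emb <- gen_embeddings(ev, dim, kind, context_strength = strength,
                        seed = seed + 2)
  kern <- lag_kernel_gaussian(center_ms, 50)
  gen <- gen_neural_recording(ev, emb, kern, n_electrodes = n_electrodes,
                              fs = fs, snr = snr, seed = seed + 3)
  list(vocab = vocab, events = ev, emb = emb, rec = gen$recording,
       ledger = gen$ledger)
}

# Brute-force step-up BH oracle (independent of stats::p.adjust).
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# Brute-force pairwise AUC oracle.
auc_brute <- function(scores, positive) {
  pos <- which(positive); neg <- which(!positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}
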