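#!/usr/bin/env Rscript
# Embedding-space decoding on a strongly coupled synthetic scene: map
# spatiotemporal windows (ten 62.5-ms bins) to the embedding space with an
# ensemble of feed-forward nets and classify word identity by cosine
# distance, scoring frequency-weighted one-vs-rest ROC-AUC per lag, for
# contextual, static and arbitrary target spaces.

suppressPackageStartupMessages(library(neurolex))
dir.create("results", showWarnings = FALSE)

seed <- 101
vocab <- gen_vocabulary(25, 1.1, seed)
ev <- gen_word_events(vocab, 450, 0.35, seed + 1)
ctx <- gen_embeddings(ev, 12, "contextual", 0.8, seed = seed + 2)
static <- new_embedding(attr(ctx, "static_base"), "static")
arb <- assign_arbitrary(ev, 12, seed + 3)
gen <- gen_neural_recording(ev, ctx, lag_kernel_gaussian(150, 80),
                            n_electrodes = 15, fs = 128, snr = 8,
                            seed = seed + 4)

lags <- c(-2000, -500, -150, 0, 150, 500, 2000)
suite <- run_decoding_suite(
  gen$recording, ev,
  list(contextual = ctx, static = static, arbitrary = arb),
  lags_ms = lags, seed = seed + 5,
  n_folds = 5, ensemble = 3, lr = 5e-3, batch_size = 64,
  max_epochs = 120, patience = 8)

curves <- data.frame(lag_ms = lags,
                     sapply(suite, function(d) d$mean_auc),
                     se = sapply(suite, function(d) d$se_auc))
utils::write.csv(curves, "results/decoding_auc.csv", row.names = FALSE)
for (nm in names(suite)) {
  pk <- which.max(suite[[nm]]$mean_auc)
  cat(sprintf("%-10s: peak AUC %.3f at %+d ms\n", nm,
              suite[[nm]]$mean_auc[pk], lags[pk]))
}
cat("(chance = 0.5; the planted response peaks +150 ms after onset)\n")
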