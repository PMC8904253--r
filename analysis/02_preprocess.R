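#!/usr/bin/env Rscript
# Demonstrate the high-gamma preprocessing chain on a raw-like signal and
# audit how much "future" leaks backward through the acausal stages.
#
# The audit drives the chain with a unit impulse and measures the earliest
# pre-impulse sample exceeding 1e-3 of the output peak. The two analytic
# bounds: half the six-cycle window at the 70-Hz band edge (43 ms) for the
# wavelet stage, plus the 50-ms zero-phase Hamming kernel, 93 ms in total.

suppressPackageStartupMessages(library(neurolex))
dir.create("results", showWarnings = FALSE)

set.seed(7)
fs <- 512
raw <- matrix(stats::rnorm(8 * fs * 30), 8)       # 8 electrodes, 30 s
raw[3, 5000] <- 60                                # an artifact spike
rec <- new_recording(raw, fs, stage = "raw")

pp <- preprocess_highgamma(rec)
cat(sprintf("preprocessed: %d x %d, per-electrode mean %.1e, sd %.3f\n",
            nrow(pp$signal), ncol(pp$signal),
            max(abs(rowMeans(pp$signal))), mean(apply(pp$signal, 1, sd))))

stages <- list(full_chain = c("power", "smooth"),
               wavelet_only = "power",
               smoothing_only = "smooth")
audit <- do.call(rbind, lapply(names(stages), function(nm) {
  a <- impulse_leak_audit(fs, stages[[nm]])
  data.frame(stage = nm, backward_ms = a$backward_extent_ms,
             forward_ms = a$forward_extent_ms)
}))
print(audit, row.names = FALSE)
utils::write.csv(audit, "results/leak_audit.csv", row.names = FALSE)
cat("the full chain leaks", round(audit$backward_ms[1], 1),
    "ms from the future (bound: 93 ms)\n")
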