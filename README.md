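# neurolex

Analysis machinery for linking word embeddings to word-aligned intracranial
neural activity during natural speech comprehension.

During listening, the high-gamma (70–200 Hz) power envelope of
electrocorticography (ECoG) recordings carries word-locked information —
about the upcoming word *before* its onset (prediction) and about the
perceived word and its surprise *after* onset. `neurolex` provides, as
tested R functions plus a numbered analysis workflow, everything needed to
quantify that coupling:

- **Preprocessing**: despike → common-average reference → six-cycle Morlet
  wavelet broadband power (70–200 Hz, line-noise frequencies excluded) →
  log → z-score → zero-phase 50-ms Hamming smoothing, with an impulse audit
  of the chain's acausal ("leak from the future") extent.
- **Lagged encoding models**: per electrode and lag, ordinary least squares
  from embedding space to the 200-ms-averaged response, 10-fold
  cross-validated, scored as the Pearson correlation r of concatenated
  held-out predictions over the lag grid −2000…+2000 ms (25-ms steps).
- **Significance procedures**: phase-randomization permutation testing with
  the max-over-lags, max-over-electrodes statistic; paired sign-flip
  comparison of two encoding maps; bootstrap-shift thresholds for mean
  curves; Benjamini–Hochberg FDR (q < 0.01) throughout.
- **Confidence and surprise**: prediction entropy H(X) = −Σ pᵢ log pᵢ and
  cross-entropy −log P(x_actual), their partial correlations with neural
  power per lag, and trigger averages for correctly versus incorrectly
  predicted words.
- **Embedding manipulations**: per-type averaging, occurrence scrambling,
  non-match assignment, and context concatenation with PCA — the control
  analyses that dissect contextual from static word information.
- **Decoding**: an ensemble of feed-forward nets mapping ten 62.5-ms bins
  of multi-electrode activity into embedding space, evaluated as word
  classification by cosine distance with frequency-weighted one-vs-rest
  ROC-AUC under contiguous temporal folds and nested electrode selection.
- **Behavioral measures**: per-word predictability scores from rater
  guesses, top-k accuracy splits, calibration curves, agreement rates,
  context-window sweeps, and n-gram baselines.

Real ECoG/behavioral data of this kind are not distributable, so the
package ships a **synthetic-data generator** (`gen_*` functions) that plants
known structure — Zipfian vocabularies, static/contextual/arbitrary
embeddings with controllable context strength, lag-kernel-convolved evoked
responses in 1/f noise at exact SNR, prediction distributions with
controllable entropy and top-k accuracy, simulated raters — and the entire
pipeline is validated by recovering what was planted.

## Worked example

```r
library(neurolex)

vocab  <- gen_vocabulary(n_types = 60, zipf_exponent = 1.1, seed = 1)
events <- gen_word_events(vocab, n_words = 800, mean_gap_s = 0.3, seed = 2)
emb    <- gen_embeddings(events, dim = 16, kind = "static", seed = 3)
gen    <- gen_neural_recording(events, emb, lag_kernel_gaussian(center_ms = 150),
                               n_electrodes = 20, fs = 128, snr = 1, seed = 4)

map <- encode_all_lags(gen$recording, events, emb,
                       lags_ms = seq(-600, 600, by = 25), seed = 5)
print(map)
#> <nlx_encoding_map> 20 electrodes x 49 lags (-600..600 ms); peak mean r = 0.723 at 150 ms

sig <- electrode_significance(gen$recording, events, emb,
                              lags_ms = seq(-300, 300, by = 100),
                              n_perm = 500, seed = 6)
#> 20 of 20 electrodes significant (q < 0.01)

audit <- impulse_leak_audit(fs = 512, stages = c("power", "smooth"))
#> backward leak of the full chain: 52.7 ms
```

The encoding map recovers the planted response kernel: the electrode-mean
held-out correlation peaks at +150 ms — exactly where the generator placed
the evoked response — at r ≈ 0.72 for SNR 1. The permutation test (maximum
encoding value over lags per electrode, maximum over electrodes per
permutation) flags all 20 truly tuned electrodes at q < 0.01. The impulse
audit certifies that the preprocessing chain leaks at most ~53 ms of future
signal backward (six-cycle wavelet support plus the zero-phase smoothing
kernel), safely below the 93-ms analytic bound — so encoding found at lags
≤ −100 ms genuinely reflects pre-onset activity.

## Analysis workflow

The `analysis/` scripts run the full study pipeline on the synthetic
benchmark and write tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | generate the benchmark dataset (2,500 events, 150 types, contextual strength 0.8, 40 electrodes, SNR 1) |
| `02_preprocess.R` | preprocessing demo + leak-audit table |
| `03_behavior.R` | predictability scores, top-5/top-1 splits, calibration, agreement, n-gram baseline, context sweep |
| `04_encoding.R` | encoding maps for all embedding variants, electrode significance, paired comparisons |
| `05_coupling.R` | trigger averages and entropy/surprise partial correlations |
| `06_decoding.R` | ROC-AUC decoding curves for contextual/static/arbitrary targets |

Each is a thin driver over the package functions, e.g.
`Rscript analysis/04_encoding.R` prints the recovered peak lag (+150 ms)
and the variant ordering at the peak (contextual 0.75 > averaged 0.41 ≈
static 0.40 > arbitrary 0.34 > scrambled 0.26).

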