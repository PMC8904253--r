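---
title: "Methods: lagged encoding and decoding of word-aligned neural activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lagged encoding and decoding of word-aligned neural activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neurolex)
```

## The problem

During natural listening, intracranial (ECoG) recordings contain word-locked
structure: the high-gamma (70–200 Hz) power envelope around each spoken
word's onset carries information about that word's identity — before onset
(prediction) as well as after it (perception and surprise). `neurolex`
implements the full analysis machinery for studying this coupling between
word embeddings and word-aligned neural activity:

1. **Preprocessing** raw multi-electrode signals into smoothed, z-scored
   high-gamma power, with an explicit audit of how much *future* signal
   leaks backward through the acausal stages.
2. **Lagged encoding**: per-electrode, per-lag cross-validated linear maps
   from embedding space to the neural response, scored by held-out
   correlation.
3. **Significance procedures**: phase-randomization max-statistic
   permutation tests for electrode selection, paired sign-flip comparisons
   between models, bootstrap-shift thresholds for mean curves, all with
   Benjamini–Hochberg FDR control.
4. **Confidence/surprise coupling**: trigger averages for correct versus
   incorrect predictions, and partial correlations of power with prediction
   entropy and cross-entropy.
5. **Embedding manipulations**: the control analyses that dissect what part
   of a contextual embedding drives encoding (type averaging, occurrence
   scrambling, non-match assignment, context concatenation with PCA).
6. **Decoding**: a feed-forward regressor from binned spatiotemporal windows
   into embedding space, evaluated as word classification by cosine
   distance with frequency-weighted one-vs-rest ROC-AUC.

Because suitable ECoG data cannot be bundled, the package is organized
around a **synthetic-data generator** with a known ground truth, and every
claim the test suite makes is a claim about recovering that planted
structure.

## The encoding model

For an embedding matrix $X$ (events × $d$) and the neural response $y_e(\ell)$
of electrode $e$ at lag $\ell$ — the mean z-scored power in a 200-ms window
centered on `onset + lag` — the encoding model is ordinary least squares with
intercept, fit under 10-fold cross-validation with a random, seeded fold
assignment shared across electrodes and lags. The held-out predictions of
all folds are concatenated and a single Pearson correlation per electrode
and lag is reported. The canonical lag grid is 161 lags from −2000 ms to
+2000 ms in 25-ms steps (`default_lags()`).

Numerical choices:

* the 200-ms window is *centered* on `onset + lag` (a centered window keeps
  the lag axis symmetric around the true response latency; a causal variant
  would shift apparent latencies by half a window);
* OLS is solved by QR; on rank deficiency the minimum-norm (pseudoinverse)
  solution is used with a warning;
* events whose window leaves the recording at any lag of the grid are
  dropped from *all* lags, so rows stay aligned;
* held-out correlation is invariant to any invertible affine recoding of
  the embedding coordinates (tested to 1e-8), which is why PCA rotations of
  concatenated context vectors are legitimate inputs.

## Significance procedures

**Electrode selection.** Each permutation phase-randomizes every
electrode's signal independently — preserving the Fourier amplitude
spectrum exactly, hence the autocorrelation, while destroying any relation
to the word onsets — and re-runs the entire lagged encoding. The maximum
correlation over lags is retained per electrode, then the maximum over
electrodes, giving one null value per permutation. Each electrode's
observed max-over-lags value is ranked in this pooled null; p-values use the
$(k+1)/(n+1)$ convention (never exactly zero), and electrodes with BH-adjusted
$q < 0.01$ are significant. Phases are drawn i.i.d. uniform per electrode
(per-electrode randomization breaks cross-electrode correlation; this
matches the stated procedure and makes the null slightly conservative for
spatially correlated noise).

**Paired model comparison.** The per-lag difference of two encoding maps is
tested with a sign-flip null: each electrode's pair of values is randomly
swapped, flips drawn per electrode and shared across lags (preserving each
electrode's lag profile), two-sided by default, BH across lags. With $E$
electrodes the smallest attainable two-sided p-value is about $2^{1-E}$, so
panels of fewer than ~12 electrodes cannot clear $q<0.01$ regardless of
effect size.

**Bootstrap-shift threshold.** Electrodes are resampled with replacement;
the bootstrap distribution of the mean is shifted by the observed mean to
form a null, giving a per-lag threshold (its $1-q$ quantile) and p-values, BH
across lags.

**Coupling.** Partial correlations use the closed form on pairwise Pearson
correlations, $r_{xy\cdot z}=(r_{xy}-r_{xz}r_{yz})/\sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}$;
per-lag significance is a one-sample t-test of Fisher-z transformed partial
correlations across electrodes, BH across lags.

## Preprocessing and the leak audit

The chain is despike → common-average re-reference → Morlet wavelet power →
natural log → per-electrode z-score → zero-phase Hamming smoothing.

* **Despike**: samples beyond median ± 4·IQR (alternative rule: mean ±
  3·IQR) are removed and re-imputed by cubic spline interpolation.
* **Wavelets**: six-cycle complex Morlets, $\sigma_t = n_{cyc}/(2\pi f)$,
  truncated at $\pm n_{cyc}/(2f)$ so the temporal support is exactly six
  periods (the envelope at the truncation point is $e^{-\pi^2/2}\approx0.007$).
  Center frequencies: 70–200 Hz in 10-Hz steps, dropping centers within
  ±5 Hz of 60/120/180 Hz. A linear grid is used because its points coincide
  with the line frequencies, making the exclusion meaningful; a log-spaced
  option exists. Note that six-cycle wavelets have wide passbands
  ($\sigma_f = f/6$), so excluding a center *attenuates* line-frequency
  content rather than nulling it. Power is aggregated as the mean of
  per-frequency log power (configurable to log-of-mean).
* **Smoothing**: a unit-sum 50-ms Hamming window applied forward and then
  backward (zero phase), with reflection padding.
* **Leak audit**: `impulse_leak_audit()` drives the power and/or smoothing
  stages with a unit impulse and reports the earliest pre-impulse time at
  which the output exceeds 1e-3 of its peak. The threshold 1e-3 is a
  package choice (the analytic support bounds hold at any threshold). The
  wavelet stage alone is bounded by half the six-cycle window at the 70-Hz
  band edge (3/70 s ≈ 43 ms); the smoothing contributes up to 50 ms (the
  kernel is traversed once per direction); the full chain is bounded by
  93 ms. Measured at 512 Hz the package reports ≈ 53 ms for the full chain
  and ≈ 25 ms for the wavelet stage — comfortably inside both bounds.

## The synthetic-data generator

The generator emulates the statistical structure of the study setting, not
its physiology:

* **Vocabulary and events**: Zipfian type frequencies
  (`rank^-1.1` by default over 150 types — heavy-tailed enough that a
  sizable subset of types recurs ≥ 5 times, which the per-type analyses
  need), i.i.d. token sampling, exponential inter-onset gaps with a 50-ms
  floor and 300-ms mean, and 3 s of leading silence so pre-onset windows
  exist for the first words.
* **Embeddings**: `static` types get Gaussian vectors sharing a rank-5
  latent factor (a planted similarity structure); `arbitrary` types get
  uniform[−1,1] vectors (identity without structure); `contextual` rows are
  $\sqrt{1-s^2}\,B_{type} + s\,c_i$ with $s$ the context strength and $c_i$ a
  unit-variance occurrence-specific component correlated with the static
  vectors of the 10 preceding events (geometric weights) plus fresh noise.
  Two occurrences of a type then have expected cosine similarity $1-s^2$,
  and the within-type component variance scales as $s^2$ (both tested).
  The benchmark uses $s = 0.8$: strongly context-dependent coding, the
  regime in which occurrence scrambling visibly collapses performance.
* **Recording**: electrode $e$'s evoked signal is
  $\sum_w k(t-\mathrm{onset}_w)\,\langle u_e, x_w\rangle$ for a Gaussian lag
  kernel $k$ peaking +150 ms after onset (width 60 ms) and random tuning
  vectors $u_e$, rescaled so the realized evoked/noise variance ratio equals
  the requested SNR exactly, plus unit-variance $1/f$ Gaussian noise
  (spectral shaping; exponent 1, typical of field-potential spectra).
  Additional components (prediction-locked pre-onset activity, scalar
  entropy/surprise modulations with fixed-sign tuning) can be planted for
  the coupling analyses. Recordings are padded to 5-smooth lengths so the
  FFT-heavy permutation machinery stays fast.
* **Predictions**: per-event softmax distributions over the vocabulary with
  temperature 1/confidence on i.i.d. Gaussian logits. A Bernoulli subset of
  events is "predictable": the actual word's logit is raised just above a
  uniformly drawn rank within the top 5, so top-5 accuracy hits the target
  (62% by default) while top-1 confidence stays graded. The boost
  probability is inverse-corrected for the $k/n$ chance rate so the
  realized top-k accuracy matches the request in expectation.
* **Raters**: each simulated rater guesses each upcoming word by sampling
  from that event's prediction distribution.

What the generator does *not* emulate: acoustic/phonetic structure,
syntax-dependent latencies, electrode geometry and spatial correlation,
non-stationarity across the session, and rater idiosyncrasies. Passing
tests therefore certify the *machinery* (calibration, recovery, ordering,
leak bounds) on data satisfying the model's assumptions — not that real
cortex satisfies them.

## Embedding manipulations

* `average_by_type()` replaces each occurrence by its type mean (types with
  < 5 repetitions dropped, with an index map) — removing occurrence-specific
  context while keeping a corpus-specific static vector.
* `scramble_occurrences()` permutes rows within type (fixed-point-free
  permutations where possible; plain permutations for ≤ 3 occurrences,
  where derangements can be degenerate).
* `nonmatch_same_word()` deranges the type→vector assignment: identity
  without the semantic match.
* `concat_context_pca()` concatenates the k = 10 preceding static vectors
  (zeros at the sequence start) and reduces to 50 dimensions by PCA. The
  PCA can be fit on caller-supplied training rows only; by default it is
  fit on all rows, which is harmless for *encoding* because held-out
  correlation is invariant to affine recodings fit without the response.
  `k = 1` reproduces the previous-word control.
* `concat_prev_current()` doubles the dimension with the previous event's
  row (zeros for the first event).

On the benchmark (contextual-coded brain, $s=0.8$, SNR 1, 40 electrodes,
2,500 events), the electrode-mean held-out correlations at the planted lag
order exactly as the control logic predicts: contextual ≈ 0.75 >
averaged ≈ static ≈ 0.40 > scrambled ≈ arbitrary ≈ 0.26–0.34. Averaging
lands at the static level because it strips precisely the occurrence
component; scrambling falls to the identity floor because the mismatched
context component acts as regressor noise with variance $s^2$.

## Decoding

Inputs are ten 62.5-ms bins spanning 625 ms around `onset + lag`
(32 samples per bin at 512 Hz), flattened over a per-fold electrode subset.
Folds are five contiguous temporal blocks; each rotation uses one block for
testing, the next for early stopping, the rest for training. Electrode
selection, when enabled, runs the permutation encoding test on train+dev
events only. The regressor is a multilayer perceptron (ReLU hidden layers,
default 64/32, dropout 0.2, linear output) trained with Adam to minimize the
MSE of predicted embeddings, stopping when the dev MSE has not improved for
10 epochs and restoring the best-dev weights; training is bit-deterministic
given its seed. An ensemble (default 10; reduced profiles for desk-scale
runs) retrains with different initializations and batch orders.

Scoring: for each test event, the cosine distance from the predicted
embedding to every training instance of each eligible label (≥ 5 training
repetitions) is averaged per label, negated, averaged across the ensemble,
then softmaxed over labels — averaging precedes the softmax, so the ensemble
operates on commensurable distance scales. Per-label one-vs-rest ROC-AUC is
computed by the rank (Mann–Whitney) statistic and summarized as the mean
weighted by test-set label frequencies. A zero-norm predicted embedding
receives the maximal distance (2) with a warning.

## Measures and baselines

Entropy is $-\sum_i p_i \log p_i$ (natural log throughout, configurable to
other bases; the sign convention keeps entropy nonnegative) and
cross-entropy is $-\log P(x_{actual})$, with an optional 1e-10 clamp for
zero probabilities. Top-k splits break ties by vocabulary index for
determinism. Behavioral guesses are compared after case-folding and
punctuation stripping (no spell correction; a hook exists at the
normalization step). N-gram baselines are maximum likelihood (unseen
histories flagged, probability 0) or add-k smoothed,
$(c(h,w)+k)/(c(h)+kV)$; Kneser–Ney is out of scope.

## Problem sizes used by the test suite

The acceptance-style tests run at sizes chosen for a single CPU: the null
calibration uses 20 electrodes, 1,000 permutations and 100 Monte-Carlo runs
(events 100, three lags, 40-Hz power signals); signal recovery uses 50
electrodes × 3,000 events at SNR 1 over ten seeds; the manipulation
ordering uses the default benchmark (above); decoding runs a 3-net ensemble
at 128 Hz with 450 events. The `analysis/` scripts use the same seeds and
conditions and write their tables under `results/`.

## Known limitations

* The permutation electrode test is fastest on 5-smooth signal lengths
  (mixed-radix FFT); other lengths work but slower.
* The paired sign-flip test has a granularity floor of about $2^{1-E}$.
* Per-electrode phase randomization ignores cross-electrode noise
  correlation; the family-wise calibration tested here is for spatially
  independent noise.
* The MLP decoder is plain R matrix code: appropriate for hundreds of
  events and tens of electrodes, not for GPU-scale sweeps over dense lag
  grids.
* `average_by_type()` requires a contextual input and at least one type
  meeting the repetition threshold; `nonmatch_same_word()` requires at
  least two types.
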