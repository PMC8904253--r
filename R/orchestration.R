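# Reproducible end-to-end runs over the synthetic benchmark: configuration,
# the encoding suite over embedding variants, the decoding suite, and a
# ground-truth comparison report.

#' Default benchmark configuration
#'
#' The benchmark conditions: 150 word types (Zipf 1.1), 50-dimensional
#' embeddings, contextual strength 0.8, a Gaussian evoked kernel peaking
#' 150 ms after word onset, 1/f noise, SNR 1, and reduced lag/permutation
#' grids sized for a single-CPU run.
#'
#' @param seed master seed; all stage seeds derive from it
#' @return named list of configuration values
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    n_types = 150, zipf_exponent = 1.1,
    n_words = 2500, mean_gap_s = 0.3,
    dim = 50, context_strength = 0.8,
    n_electrodes = 40, fs = 128, snr = 1, noise_exponent = 1,
    kernel_center_ms = 150, kernel_width_ms = 60,
    lags_ms = seq(-600, 600, by = 25),
    n_folds = 10, n_perm = 500, q = 0.01,
    decode_lags_ms = c(150), decode_ensemble = 3, decode_folds = 5
  )
}

#' Generate the full synthetic dataset for a configuration
#'
#' @param config a configuration list, see [default_config()]
#' @return list with `vocab`, `events`, embeddings (`contextual`, `static`,
#'   `arbitrary`), `dists`, `recording`, `ledger`
#' @export
simulate_dataset <- function(config = default_config()) {
  cfg <- config
  vocab <- gen_vocabulary(cfg$n_types, cfg$zipf_exponent, child_seed(cfg$seed, 1))
  events <- gen_word_events(vocab, cfg$n_words, cfg$mean_gap_s,
                            child_seed(cfg$seed, 2))
  ctx <- gen_embeddings(events, cfg$dim, "contextual",
                        context_strength = cfg$context_strength,
                        seed = child_seed(cfg$seed, 3))
  static <- new_embedding(attr(ctx, "static_base"), "static")
  arb <- assign_arbitrary(events, cfg$dim, child_seed(cfg$seed, 4))
  dists <- gen_prediction_distributions(events, vocab,
                                        seed = child_seed(cfg$seed, 5))
  kern <- lag_kernel_gaussian(cfg$kernel_center_ms, cfg$kernel_width_ms)
  gen <- gen_neural_recording(events, ctx, kern, cfg$n_electrodes, cfg$fs,
                              cfg$snr, cfg$noise_exponent,
                              seed = child_seed(cfg$seed, 6))
  list(vocab = vocab, events = events, contextual = ctx, static = static,
       arbitrary = arb, dists = dists, recording = gen$recording,
       ledger = gen$ledger, config = cfg)
}

#' Encoding suite over embedding variants
#'
#' Fits one lagged encoding map per embedding variant with a shared fold
#' assignment, plus paired per-lag comparisons between requested variant
#' pairs.
#'
#' @param rec preprocessed `nlx_recording`
#' @param events `nlx_events`
#' @param variants named list of `nlx_embedding`s (row-aligned with events)
#' @param lags_ms lag grid
#' @param n_folds,seed,window_ms as in [encode_all_lags()]
#' @param comparisons list of 2-element character vectors naming variant
#'   pairs to compare (default: every variant against the first)
#' @param n_perm permutations for the paired comparisons
#' @return list with `maps` (named `nlx_encoding_map`s), `comparisons`,
#'   `folds`
#' @export
run_encoding_suite <- function(rec, events, variants,
                               lags_ms = default_lags(), n_folds = 10,
                               seed = 1, window_ms = 200, comparisons = NULL,
                               n_perm = 1000) {
  stopifnot(length(names(variants)) == length(variants))
  keep <- events_valid_at_lags(rec, events, lags_ms, window_ms)
  folds <- cv_folds(length(keep), n_folds, child_seed(seed, 1))
  maps <- lapply(variants, function(v) {
    encode_all_lags(rec, events, v, lags_ms, n_folds, seed,
                    window_ms, folds = folds)
  })
  if (is.null(comparisons) && length(variants) > 1) {
    comparisons <- lapply(names(variants)[-1],
                          function(nm) c(names(variants)[1], nm))
  }
  comp <- lapply(comparisons, function(pr) {
    paired_model_comparison(maps[[pr[1]]], maps[[pr[2]]], n_perm = n_perm,
                            seed = child_seed(seed, 2))
  })
  names(comp) <- vapply(comparisons, paste, character(1), collapse = "_vs_")
  list(maps = maps, comparisons = comp, folds = folds)
}

#' Decoding suite over embedding variants
#'
#' One decoding run (AUC curve over lags) per embedding target space, on a
#' shared lag grid and shared fold structure.
#'
#' @param rec preprocessed `nlx_recording`
#' @param events `nlx_events`
#' @param variants named list of `nlx_embedding`s
#' @param lags_ms decoding lag grid
#' @param seed integer seed
#' @param ... passed to [run_decoding()]
#' @return named list of `nlx_decoding` results
#' @export
run_decoding_suite <- function(rec, events, variants,
                               lags_ms = c(-150, 0, 150), seed = 1, ...) {
  stopifnot(length(names(variants)) == length(variants))
  lapply(variants, function(v) {
    run_decoding(rec, events, v, lags_ms = lags_ms, seed = seed, ...)
  })
}

#' End-to-end synthetic benchmark
#'
#' Generates a dataset from the configuration, runs the encoding suite over
#' the contextual/static/arbitrary variants, locates the recovered peak lag,
#' and (optionally) runs electrode significance and a small decoding run;
#' reports recovered quantities next to the planted ground truth.
#'
#' @param config configuration list, see [default_config()]
#' @param run_significance run the permutation electrode test (slower)
#' @param run_decode run the decoding stage (slower)
#' @return report list with `planted`, `recovered`, and the stage outputs
#' @export
run_synthetic_benchmark <- function(config = default_config(),
                                    run_significance = FALSE,
                                    run_decode = FALSE) {
  t0 <- Sys.time()
  ds <- simulate_dataset(config)
  cfg <- ds$config
  suite <- run_encoding_suite(
    ds$recording, ds$events,
    list(contextual = ds$contextual, static = ds$static, arbitrary = ds$arbitrary),
    lags_ms = cfg$lags_ms, n_folds = cfg$n_folds, seed = child_seed(cfg$seed, 7),
    n_perm = cfg$n_perm)
  curve <- colMeans(suite$maps$contextual$r)
  recovered_peak <- cfg$lags_ms[which.max(curve)]
  report <- list(
    planted = list(peak_lag_ms = cfg$kernel_center_ms, snr = cfg$snr,
                   context_strength = cfg$context_strength),
    recovered = list(peak_lag_ms = recovered_peak,
                     peak_mean_r = max(curve),
                     mean_r_by_variant = vapply(
                       suite$maps, function(m) max(colMeans(m$r)), numeric(1))),
    encoding = suite,
    config = cfg
  )
  if (run_significance) {
    report$significance <- electrode_significance(
      ds$recording, ds$events, ds$contextual, lags_ms = cfg$lags_ms,
      n_perm = cfg$n_perm, q = cfg$q, seed = child_seed(cfg$seed, 8))
    report$recovered$n_significant <- length(report$significance$significant)
  }
  if (run_decode) {
    report$decoding <- run_decoding(
      ds$recording, ds$events, ds$contextual, lags_ms = cfg$decode_lags_ms,
      n_folds = cfg$decode_folds, ensemble = cfg$decode_ensemble,
      seed = child_seed(cfg$seed, 9))
    report$recovered$decode_auc <- report$decoding$mean_auc
  }
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report
}
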