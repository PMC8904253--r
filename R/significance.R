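# Significance procedures: phase-randomization max-statistic permutation
# test for electrode selection, paired sign-flip comparison of two encoding
# maps, bootstrap-shift test for mean encoding curves, trigger averaging,
# and entropy/cross-entropy (confidence/surprise) partial correlations.

# Phase-randomize the columns of a samples x series matrix using the current
# RNG state. Fourier amplitudes are preserved exactly; free-bin phases are
# i.i.d. uniform with conjugate symmetry; DC (and Nyquist) bins untouched.
phase_randomize_cols <- function(m) {
  n <- nrow(m)
  fx <- stats::mvfft(m)
  h <- (n - 1) %/% 2            # number of free bins
  if (h > 0) {
    free <- 2:(h + 1)
    phi <- matrix(stats::runif(h * ncol(m), 0, 2 * pi), h, ncol(m))
    rot <- exp(1i * phi)
    fx[free, ] <- Mod(fx[free, , drop = FALSE]) * rot
    fx[n + 2 - free, ] <- Conj(fx[free, , drop = FALSE])
  }
  Re(stats::mvfft(fx, inverse = TRUE)) / n
}

#' Phase-randomized surrogate signal
#'
#' Returns a surrogate with exactly the same Fourier amplitude spectrum (and
#' hence autocorrelation) as the input, but i.i.d. uniform phases: the
#' relationship between the signal and any event structure is destroyed while
#' the signal's temporal statistics are preserved.
#'
#' @param x numeric vector
#' @param seed integer seed
#' @return surrogate numeric vector of the same length
#' @export
phase_randomize <- function(x, seed = 1) {
  with_seed(seed, as.vector(phase_randomize_cols(matrix(x, ncol = 1))))
}

#' Electrode significance by phase-randomization max-statistic permutation
#'
#' For each permutation, every electrode's signal is phase-randomized
#' independently and the entire lagged encoding procedure is re-run; the
#' maximum encoding correlation across all lags is retained per electrode,
#' and the maximum of those across electrodes gives one null value per
#' permutation. Each electrode's observed max-over-lags correlation is
#' compared against this pooled null (p-values use the (k+1)/(n+1)
#' convention), and electrodes with Benjamini-Hochberg q below `q` are
#' declared significant.
#'
#' @param rec preprocessed `nlx_recording`
#' @param events `nlx_events`
#' @param emb `nlx_embedding`
#' @param lags_ms lag grid (ms)
#' @param n_perm number of permutations (default 5000)
#' @param q FDR level (default 0.01)
#' @param seed integer seed
#' @param n_folds CV folds (default 10)
#' @param window_ms averaging window (default 200)
#' @param chunk permutations processed per vectorized block
#' @return object of class `nlx_significance`: list with `p`, `q_values`,
#'   `significant`, `null_max` (length `n_perm`), `observed_max`, and the
#'   observed encoding `map`
#' @export
electrode_significance <- function(rec, events, emb, lags_ms = default_lags(),
                                   n_perm = 5000, q = 0.01, seed = 1,
                                   n_folds = 10, window_ms = 200, chunk = 50) {
  if (n_perm < 100) warning("fewer than 100 permutations: p-value resolution is coarse")
  keep <- events_valid_at_lags(rec, events, lags_ms, window_ms)
  # the vectorized null needs one sample of headroom before each window
  keep <- keep[lag_window_idx(events[keep, , drop = FALSE], rec$fs,
                              min(lags_ms), window_ms)$from >= 2]
  ev <- events[keep, , drop = FALSE]
  class(ev) <- c("nlx_events", "data.frame")
  X <- unclass(emb)[keep, , drop = FALSE]
  folds <- cv_folds(length(keep), n_folds, child_seed(seed, 1))
  fp <- fold_predictors(X, folds)
  map <- encode_all_lags(rec, ev, new_embedding(X, "derived"), lags_ms,
                         n_folds, seed, window_ms, folds = folds)
  obs_max <- apply(map$r, 1, max)
  ne <- nrow(rec$signal)
  S <- ncol(rec$signal)
  idx <- lapply(lags_ms, function(l) lag_window_idx(ev, rec$fs, l, window_ms))
  base <- t(rec$signal)  # samples x electrodes
  # spectral amplitudes computed once; each permutation only needs fresh
  # phases and one inverse FFT
  fx <- stats::mvfft(base)
  h <- (S - 1) %/% 2
  free <- if (h > 0) 2:(h + 1) else integer(0)
  amp_free <- Mod(fx[free, , drop = FALSE])
  fixed_rows <- setdiff(seq_len(S), c(free, S + 2 - free))
  null_max <- numeric(n_perm)
  with_seed(child_seed(seed, 2), {
    done <- 0
    while (done < n_perm) {
      nb <- min(chunk, n_perm - done)
      rep_idx <- rep(seq_len(ne), nb)
      G <- matrix(0i, S, ne * nb)
      G[fixed_rows, ] <- fx[fixed_rows, rep_idx, drop = FALSE]
      rot <- exp(1i * matrix(stats::runif(h * ne * nb, 0, 2 * pi), h, ne * nb))
      gf <- amp_free[, rep_idx, drop = FALSE] * rot
      G[free, ] <- gf
      G[S + 2 - free, ] <- Conj(gf)
      surro <- Re(stats::mvfft(G, inverse = TRUE)) / S
      # flattened cumulative sum; per-column offsets cancel in differences
      # (window starts are > 1 because events sit inside the padding)
      cm <- matrix(cumsum(as.vector(surro)), S, ne * nb)
      max_r <- matrix(-Inf, ne, nb)
      for (li in seq_along(idx)) {
        from <- idx[[li]]$from; to <- idx[[li]]$to
        Y <- (cm[to, , drop = FALSE] - cm[from - 1, , drop = FALSE]) /
          (to - from + 1)
        pred <- cv_predict(fp, Y)
        r <- matrix(col_cor(pred, Y), ne, nb)
        max_r <- pmax(max_r, r)
      }
      null_max[(done + 1):(done + nb)] <- apply(max_r, 2, max)
      done <- done + nb
    }
  })
  p <- vapply(obs_max, function(o) perm_pval(null_max, o), numeric(1))
  qv <- bh_fdr(p)
  structure(list(p = p, q_values = qv, significant = which(qv < q),
                 null_max = null_max, observed_max = obs_max, map = map,
                 q_level = q),
            class = "nlx_significance")
}

#' Paired comparison of two encoding maps
#'
#' Tests, per lag, whether the electrode-mean difference between two encoding
#' maps differs from zero, by randomly swapping the assignment of the two
#' models' encoding values within each electrode (a sign-flip null on the
#' paired differences). P-values are BH-adjusted across lags.
#'
#' @param mapA,mapB `nlx_encoding_map`s on identical electrodes and lag grids
#' @param n_perm permutations (default 5000)
#' @param q FDR level (default 0.01)
#' @param seed integer seed
#' @param alternative "two.sided" (default) or "greater" (A > B)
#' @return list with `diff` (per-lag mean difference), `p`, `q_values`,
#'   `significant` (lag indices), `lags_ms`
#' @export
paired_model_comparison <- function(mapA, mapB, n_perm = 5000, q = 0.01,
                                    seed = 1,
                                    alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (!identical(dim(mapA$r), dim(mapB$r)) ||
      !identical(mapA$lags_ms, mapB$lags_ms)) {
    stop("encoding maps must share electrodes and lag grid")
  }
  d <- mapA$r - mapB$r
  ne <- nrow(d)
  obs <- colMeans(d)
  with_seed(seed, {
    flips <- matrix(sample(c(-1, 1), ne * n_perm, replace = TRUE), ne, n_perm)
    null <- crossprod(d, flips) / ne   # lags x n_perm
  })
  p <- vapply(seq_along(obs), function(l) {
    perm_pval(null[l, ], obs[l], two_sided = alternative == "two.sided")
  }, numeric(1))
  qv <- bh_fdr(p)
  list(diff = obs, p = p, q_values = qv, significant = which(qv < q),
       lags_ms = mapA$lags_ms)
}

#' Bootstrap-shift test for the electrode-mean encoding curve
#'
#' Per lag, electrodes are resampled with replacement `n_boot` times; the
#' bootstrap distribution of the mean is shifted by the observed mean to form
#' the null, and the observed mean is tested against it (one-sided). P-values
#' are BH-adjusted across lags. The per-lag `threshold` is the 1-q quantile
#' of the shifted null.
#'
#' @param map an `nlx_encoding_map` with >= 2 electrodes
#' @param n_boot bootstrap samples (default 5000)
#' @param q FDR level (default 0.01)
#' @param seed integer seed
#' @return list with `mean` (per-lag observed mean), `threshold`, `p`,
#'   `q_values`, `significant`, `lags_ms`
#' @export
bootstrap_mean_threshold <- function(map, n_boot = 5000, q = 0.01, seed = 1) {
  r <- map$r
  ne <- nrow(r)
  if (ne < 2) stop("bootstrap needs >= 2 electrodes")
  obs <- colMeans(r)
  with_seed(seed, {
    counts <- matrix(0L, ne, n_boot)
    draws <- matrix(sample.int(ne, ne * n_boot, replace = TRUE), ne, n_boot)
    for (b in seq_len(n_boot)) counts[, b] <- tabulate(draws[, b], nbins = ne)
    boot_means <- crossprod(r, counts) / ne       # lags x n_boot
  })
  null <- boot_means - obs                        # shifted: centered at 0
  p <- vapply(seq_along(obs), function(l) perm_pval(null[l, ], obs[l]),
              numeric(1))
  thr <- apply(null, 1, stats::quantile, probs = 1 - q)
  qv <- bh_fdr(p)
  list(mean = obs, threshold = as.vector(thr), p = p, q_values = qv,
       significant = which(qv < q), lags_ms = map$lags_ms)
}

#' Trigger-averaged activity by event class
#'
#' Per lag and event class, the event-mean response of every electrode is
#' computed and summarized by its mean and standard error across electrodes.
#'
#' @param rec preprocessed `nlx_recording`
#' @param events `nlx_events`
#' @param labels factor-like per-event class labels (e.g. correct/incorrect)
#' @param lags_ms lag grid (ms)
#' @param window_ms averaging window (default 200)
#' @return list with `lags_ms` and, per class, `mean` and `se` vectors
#' @export
trigger_average <- function(rec, events, labels, lags_ms = default_lags(),
                            window_ms = 200) {
  labels <- as.factor(labels)
  if (any(table(labels) == 0)) stop("empty event class")
  keep <- events_valid_at_lags(rec, events, lags_ms, window_ms)
  ev <- events[keep, , drop = FALSE]
  class(ev) <- c("nlx_events", "data.frame")
  labels <- labels[keep]
  ne <- nrow(rec$signal)
  out <- lapply(levels(labels), function(cl) {
    list(mean = numeric(length(lags_ms)), se = numeric(length(lags_ms)))
  })
  names(out) <- levels(labels)
  for (li in seq_along(lags_ms)) {
    Y <- extract_lagged_responses(rec, ev, lags_ms[li], window_ms)
    for (cl in levels(labels)) {
      m_e <- colMeans(Y[labels == cl, , drop = FALSE])  # per electrode
      out[[cl]]$mean[li] <- mean(m_e)
      out[[cl]]$se[li] <- stats::sd(m_e) / sqrt(ne)
    }
  }
  c(list(lags_ms = lags_ms, n_electrodes = ne), out)
}

#' Entropy/cross-entropy coupling with neural activity
#'
#' Per lag, computes for every electrode the partial correlation of the
#' word-aligned response with prediction entropy (confidence) controlling for
#' cross-entropy (surprise), and vice versa; reports the electrode-mean
#' series with standard errors and per-lag FDR significance flags (one-sample
#' t-test on Fisher-z transformed partial correlations across electrodes,
#' BH-adjusted across lags).
#'
#' @param rec preprocessed `nlx_recording`
#' @param events `nlx_events`
#' @param dists an `nlx_dists` aligned to `events`
#' @param lags_ms lag grid (ms)
#' @param window_ms averaging window (default 200)
#' @param q FDR level for the per-lag flags (default 0.01)
#' @return list with `lags_ms` and two components `entropy` and
#'   `cross_entropy`, each with `mean`, `se`, `p`, `q_values`, `significant`
#' @export
entropy_surprise_coupling <- function(rec, events, dists,
                                      lags_ms = default_lags(),
                                      window_ms = 200, q = 0.01) {
  H <- entropy(dists)
  CE <- cross_entropy(dists)
  keep <- events_valid_at_lags(rec, events, lags_ms, window_ms)
  ev <- events[keep, , drop = FALSE]
  class(ev) <- c("nlx_events", "data.frame")
  H <- H[keep]; CE <- CE[keep]
  if (stats::sd(H) == 0 || stats::sd(CE) == 0) stop("zero-variance regressor")
  r_hc <- stats::cor(H, CE)
  ne <- nrow(rec$signal)
  nl <- length(lags_ms)
  res <- list(entropy = list(mean = numeric(nl), se = numeric(nl), p = numeric(nl)),
              cross_entropy = list(mean = numeric(nl), se = numeric(nl), p = numeric(nl)))
  for (li in seq_len(nl)) {
    Y <- extract_lagged_responses(rec, ev, lags_ms[li], window_ms)
    r_yh <- as.vector(stats::cor(Y, H))
    r_yc <- as.vector(stats::cor(Y, CE))
    pr_h <- (r_yh - r_yc * r_hc) / sqrt((1 - r_yc^2) * (1 - r_hc^2))
    pr_c <- (r_yc - r_yh * r_hc) / sqrt((1 - r_yh^2) * (1 - r_hc^2))
    for (nm in c("entropy", "cross_entropy")) {
      pr <- if (nm == "entropy") pr_h else pr_c
      res[[nm]]$mean[li] <- mean(pr)
      res[[nm]]$se[li] <- stats::sd(pr) / sqrt(ne)
      res[[nm]]$p[li] <- if (ne > 2) stats::t.test(atanh(pmin(pmax(pr, -1 + 1e-12),
                                                              1 - 1e-12)))$p.value else NA_real_
    }
  }
  for (nm in c("entropy", "cross_entropy")) {
    res[[nm]]$q_values <- bh_fdr(res[[nm]]$p)
    res[[nm]]$significant <- which(res[[nm]]$q_values < q)
  }
  c(list(lags_ms = lags_ms), res)
}
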