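# Significance machinery: phase randomization, max-statistic electrode test,
# paired comparison, bootstrap-shift test, trigger averaging, partial
# correlations.

test_that("phase randomization preserves amplitudes, power, autocorrelation", {
  set.seed(1)
  x <- as.vector(arima.sim(list(ar = 0.9), 512))
  s <- phase_randomize(x, seed = 2)
  expect_equal(length(s), length(x))
  # amplitude spectrum identical (construction)
  expect_lt(max(Mod(Mod(fft(s)) - Mod(fft(x)))) / max(Mod(fft(x))), 1e-10)
  # Parseval: total power preserved
  expect_lt(abs(sum(s^2) - sum(x^2)) / sum(x^2), 1e-10)
  # Wiener-Khinchin oracle: autocorrelations agree within 5/sqrt(N)
  acf_x <- stats::acf(x, lag.max = 20, plot = FALSE, demean = FALSE)$acf
  acf_s <- stats::acf(s, lag.max = 20, plot = FALSE, demean = FALSE)$acf
  expect_lt(max(abs(acf_x - acf_s)), 5 / sqrt(512))
  # constant signal: all power in DC, surrogate constant
  expect_equal(phase_randomize(rep(2, 64), 3), rep(2, 64), tolerance = 1e-12)
  # surrogate actually differs from the input
  expect_gt(max(abs(s - x)), 0.1)
})

test_that("BH-FDR agrees with a brute-force step-up oracle", {
  # exhaustive over a p-grid for short vectors, plus random vectors
  grid <- c(0.001, 0.01, 0.04, 0.2, 0.8)
  for (n in 2:4) {
    combos <- as.matrix(expand.grid(rep(list(grid), n)))
    for (i in seq_len(nrow(combos))) {
      p <- as.numeric(combos[i, ])
      expect_equal(bh_fdr(p), bh_brute(p), tolerance = 1e-12)
    }
  }
  set.seed(2)
  for (i in 1:25) {
    p <- runif(sample(5:20, 1))
    expect_equal(bh_fdr(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("permutation p-values use the (k+1)/(n+1) convention", {
  null <- 1:99 / 100
  expect_equal(neurolex:::perm_pval(null, 2), 1 / 100)
  expect_equal(neurolex:::perm_pval(null, -1), 1)
  expect_gt(neurolex:::perm_pval(null, 2), 0)
})

test_that("electrode significance flags planted coupling and not null data", {
  # planted strong coupling: tuned electrodes found significant
  sc <- small_scene(n_words = 250, dim = 6, snr = 2, seed = 51,
                    n_electrodes = 8, fs = 64)
  sig <- electrode_significance(sc$rec, sc$events, sc$emb,
                                lags_ms = c(0, 150, 300), n_perm = 300,
                                seed = 5, chunk = 100)
  expect_gte(length(sig$significant), 7)
  # null: no coupling
  sc0 <- small_scene(n_words = 250, dim = 6, snr = 0, seed = 52,
                     n_electrodes = 8, fs = 64)
  sig0 <- electrode_significance(sc0$rec, sc0$events, sc0$emb,
                                 lags_ms = c(0, 150, 300), n_perm = 300,
                                 seed = 5, chunk = 100)
  expect_lte(length(sig0$significant), 1)
  expect_true(all(sig0$p > 0 & sig0$p <= 1))
  expect_equal(length(sig$null_max), 300)
  # observed below every null max: boundary p = 1 handled
  expect_equal(neurolex:::perm_pval(sig$null_max, -10), 1)
  expect_warning(
    electrode_significance(sc0$rec, sc0$events, sc0$emb, lags_ms = c(0),
                           n_perm = 50, seed = 6, chunk = 50),
    "resolution")
})

test_that("paired comparison is exact on forced cases and calibrated on null", {
  lags <- seq(0, 900, 100)
  fake_map <- function(r) structure(list(r = r, lags_ms = lags),
                                    class = "nlx_encoding_map")
  set.seed(3)
  A <- fake_map(matrix(rnorm(160 * 10, 0.2, 0.05), 160, 10))
  # identical maps: nothing significant
  cmp_same <- paired_model_comparison(A, A, n_perm = 500, seed = 1)
  expect_equal(length(cmp_same$significant), 0)
  # constant positive difference on all electrodes: everything significant
  B <- fake_map(A$r - 0.05)
  cmp <- paired_model_comparison(A, B, n_perm = 2000, seed = 2)
  expect_equal(cmp$significant, seq_along(lags))
  expect_true(all(cmp$p <= 1 / 1000))
  # null calibration: i.i.d. maps flag at most ~q of lags
  n_flagged <- 0; n_lags_tot <- 0
  for (i in 1:20) {
    set.seed(100 + i)
    A0 <- fake_map(matrix(rnorm(40 * 10), 40, 10))
    B0 <- fake_map(matrix(rnorm(40 * 10), 40, 10))
    cmp0 <- paired_model_comparison(A0, B0, n_perm = 400, seed = i)
    n_flagged <- n_flagged + length(cmp0$significant)
    n_lags_tot <- n_lags_tot + length(lags)
  }
  expect_lte(n_flagged / n_lags_tot, 0.01 + 3 * sqrt(0.01 * 0.99 / n_lags_tot))
  # mismatched grids error
  C <- structure(list(r = A$r[, 1:5], lags_ms = lags[1:5]),
                 class = "nlx_encoding_map")
  expect_error(paired_model_comparison(A, C), "share")
})

test_that("bootstrap-shift test behaves on degenerate, null and growing panels", {
  lags <- seq(0, 400, 100)
  fake_map <- function(r) structure(list(r = r, lags_ms = lags),
                                    class = "nlx_encoding_map")
  # all electrodes at r = 0.3: degenerate bootstrap, observed significant
  const <- fake_map(matrix(0.3, 50, 5))
  bt <- bootstrap_mean_threshold(const, n_boot = 500, seed = 1)
  expect_equal(bt$significant, 1:5)
  # null: significant-lag rate <= q (over repeated draws)
  flagged <- 0; tot <- 0
  for (i in 1:20) {
    set.seed(i)
    m0 <- fake_map(matrix(rnorm(40 * 5, 0, 0.1), 40, 5))
    b0 <- bootstrap_mean_threshold(m0, n_boot = 400, seed = i)
    flagged <- flagged + length(b0$significant); tot <- tot + 5
  }
  expect_lte(flagged / tot, 0.01 + 3 * sqrt(0.01 * 0.99 / tot))
  # threshold shrinks as the electrode panel grows
  thr <- vapply(c(10, 40, 160), function(ne) {
    set.seed(7)
    m <- fake_map(matrix(rnorm(ne * 5, 0.1, 0.1), ne, 5))
    mean(bootstrap_mean_threshold(m, n_boot = 800, seed = 8)$threshold)
  }, numeric(1))
  expect_true(all(diff(thr) < 0))
  expect_error(bootstrap_mean_threshold(fake_map(matrix(0.1, 1, 5))),
               "2 electrodes")
})

test_that("trigger averaging separates classes with planted post-onset bumps", {
  v <- gen_vocabulary(20, 1, 1)
  ev <- gen_word_events(v, 400, 0.4, 2)
  with_seed(3, incorrect <- stats::runif(400) < 0.4)
  emb <- gen_embeddings(ev, 4, "static", seed = 4)
  bump_kern <- lag_kernel_gaussian(400, 80)
  gen <- gen_neural_recording(
    ev, emb, lag_kernel_gaussian(150, 50), n_electrodes = 10, fs = 64,
    snr = 0.5, seed = 5,
    extra_components = list(list(features = matrix(as.numeric(incorrect)),
                                 kernel = bump_kern, weight = 8)))
  lags <- seq(-200, 800, 100)
  ta <- trigger_average(gen$recording, ev, ifelse(incorrect, "inc", "cor"), lags)
  diffc <- abs(ta$inc$mean - ta$cor$mean)
  # curves diverge post-onset, peaking near the planted 400 ms
  expect_gt(max(diffc[lags >= 200]), 3 * max(diffc[lags <= 0]))
  expect_lte(abs(lags[which.max(diffc)] - 400), 100)
  # identical responses for both classes -> identical curves
  ta_same <- trigger_average(gen$recording, ev, rep(c("a", "b"), 200), c(0))
  expect_lt(abs(ta_same$a$mean - ta_same$b$mean), 0.15)
  expect_error(trigger_average(gen$recording, ev, factor(rep("a", 400),
                                                         levels = c("a", "b")),
                               c(0)), "empty")
  # s.e. scales as 1/sqrt(electrode count): rebuild with more electrodes
  gen2 <- gen_neural_recording(ev, emb, lag_kernel_gaussian(150, 50),
                               n_electrodes = 40, fs = 64, snr = 0.5, seed = 5)
  ta2 <- trigger_average(gen2$recording, ev, ifelse(incorrect, "inc", "cor"),
                         c(200))
  expect_lt(ta2$inc$se, ta$inc$se[which(lags == 200)] * 1.2)
})

test_that("partial correlation matches the closed form and degenerates correctly", {
  set.seed(9)
  # known 3-variable Gaussian: closed form against direct computation
  n <- 2000
  z <- rnorm(n)
  x <- 0.6 * z + rnorm(n)
  y <- -0.4 * z + 0.3 * x + rnorm(n)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(partial_cor(x, y, z), closed, tolerance = 1e-10)
  # residual-based oracle
  rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
  expect_equal(partial_cor(x, y, z), cor(rx, ry), tolerance = 1e-10)
  # control independent of both: partial equals simple correlation
  w <- rnorm(n)
  expect_equal(partial_cor(x, y, w), cor(x, y), tolerance = 0.1)
  expect_error(partial_cor(x, y, rep(1, n)), "zero-variance")
})

test_that("entropy coupling recovers a planted negative pre-onset correlation", {
  v <- gen_vocabulary(30, 1, 1)
  ev <- gen_word_events(v, 500, 0.4, 2)
  d <- gen_prediction_distributions(ev, v, confidence = 1.5, accuracy = 0.6,
                                    seed = 3)
  H <- entropy(d)
  emb <- gen_embeddings(ev, 4, "static", seed = 4)
  # pre-onset power proportional to -entropy; post-onset to +cross-entropy
  CE <- cross_entropy(d)
  gen <- gen_neural_recording(
    ev, emb, lag_kernel_gaussian(150, 50), n_electrodes = 12, fs = 64,
    snr = 0.3, seed = 5,
    extra_components = list(
      list(features = matrix(-scale(H)[, 1]),
           kernel = lag_kernel_gaussian(-300, 80), weight = 6,
           tuning = matrix(1, 1, 12)),
      list(features = matrix(scale(CE)[, 1]),
           kernel = lag_kernel_gaussian(400, 80), weight = 6,
           tuning = matrix(1, 1, 12))))
  lags <- seq(-500, 600, 100)
  cp <- entropy_surprise_coupling(gen$recording, ev, d, lags)
  pre <- which(lags == -300); post <- which(lags == 400)
  # negative pre-onset entropy coupling and positive post-onset surprise
  # coupling are recovered where they were planted
  expect_lt(cp$entropy$mean[pre], -0.05)
  expect_gt(cp$cross_entropy$mean[post], 0.05)
  expect_true(pre %in% cp$entropy$significant)
  expect_true(post %in% cp$cross_entropy$significant)
  expect_true(all(abs(cp$entropy$mean) <= 1, na.rm = TRUE))
  expect_error(entropy_surprise_coupling(gen$recording, ev,
                                         structure(list(probs = matrix(1 / 30, 500, 30),
                                                        actual = ev$type_id,
                                                        vocab = v),
                                                   class = "nlx_dists"),
                                         c(0)),
               "zero-variance")
})
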