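# High-gamma broadband power preprocessing:
# despike -> common-average re-reference -> Morlet wavelet power (70-200 Hz,
# line-noise frequencies excluded) -> natural log -> z-score -> zero-phase
# Hamming smoothing; plus an impulse audit of the chain's acausal leak.

#' Construct a multi-electrode recording
#'
#' @param signal numeric matrix, electrodes x samples
#' @param fs sampling rate (Hz)
#' @param electrode_ids optional electrode labels
#' @param stage processing stage tag
#' @return object of class `nlx_recording`
#' @export
new_recording <- function(signal, fs, electrode_ids = NULL,
                          stage = c("raw", "despiked", "rereferenced",
                                    "power", "smoothed")) {
  signal <- as.matrix(signal)
  stage <- match.arg(stage)
  if (fs <= 0) stop("fs must be positive")
  structure(
    list(signal = signal, fs = fs,
         electrode_ids = electrode_ids %||% sprintf("e%03d", seq_len(nrow(signal))),
         stage = stage),
    class = "nlx_recording")
}

#' @export
print.nlx_recording <- function(x, ...) {
  cat(sprintf("<nlx_recording> %d electrodes x %d samples @ %g Hz [%s]\n",
              nrow(x$signal), ncol(x$signal), x$fs, x$stage))
  invisible(x)
}

#' Remove large-amplitude spikes by robust thresholding and cubic interpolation
#'
#' Samples deviating beyond a robust per-electrode threshold are removed and
#' re-imputed by cubic spline interpolation over the retained samples. Two
#' threshold rules are available: `"iqr4median"` (default), median +/-
#' `iqr_multiplier` * IQR, and `"iqr3mean"`, mean +/- `iqr_multiplier` * IQR
#' (with default multiplier 3).
#'
#' @param rec a raw `nlx_recording`
#' @param iqr_multiplier positive multiplier of the IQR
#' @param rule threshold rule, see above
#' @return despiked `nlx_recording`
#' @export
despike <- function(rec, iqr_multiplier = NULL,
                    rule = c("iqr4median", "iqr3mean")) {
  stopifnot(inherits(rec, "nlx_recording"))
  rule <- match.arg(rule)
  mult <- iqr_multiplier %||% if (rule == "iqr4median") 4 else 3
  if (mult <= 0) stop("iqr_multiplier must be positive")
  sig <- rec$signal
  for (e in seq_len(nrow(sig))) {
    x <- sig[e, ]
    iqr <- stats::IQR(x)
    center <- if (rule == "iqr4median") stats::median(x) else mean(x)
    bad <- abs(x - center) > mult * iqr
    if (!any(bad)) next
    if (all(bad)) stop("entire electrode beyond despike threshold")
    keep <- which(!bad)
    sig[e, bad] <- stats::spline(keep, x[keep], xout = which(bad),
                                 method = "fmm")$y
  }
  out <- rec
  out$signal <- sig
  out$stage <- "despiked"
  out
}

#' Common-average re-referencing
#'
#' Subtracts the per-sample mean across electrodes from every electrode,
#' removing signals shared by all channels.
#'
#' @param rec an `nlx_recording` with >= 2 electrodes
#' @return re-referenced `nlx_recording`
#' @export
rereference_car <- function(rec) {
  stopifnot(inherits(rec, "nlx_recording"))
  if (nrow(rec$signal) < 2) stop("common-average reference needs >= 2 electrodes")
  out <- rec
  out$signal <- sweep(rec$signal, 2, colMeans(rec$signal))
  out$stage <- "rereferenced"
  out
}

# Complex Morlet kernel at center frequency f: Gaussian envelope with
# sigma_t = n_cycles / (2 pi f), truncated at +/- n_cycles / (2 f) so the
# temporal support is exactly n_cycles periods (envelope at the edge is
# exp(-pi^2/2) ~ 0.007). Normalized to unit l2 norm.
morlet_kernel <- function(f, fs, n_cycles = 6) {
  half_s <- n_cycles / (2 * f)
  t <- seq(-half_s, half_s, by = 1 / fs)
  sigma_t <- n_cycles / (2 * pi * f)
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

# Frequency grid: centers in [band] (linear spacing by default, log-spaced
# optionally), dropping centers within +/- exclude_halfwidth_hz of each
# excluded line frequency.
wavelet_freq_grid <- function(band = c(70, 200), n_freqs = 14,
                              exclude_hz = c(60, 120, 180),
                              exclude_halfwidth_hz = 5, spacing = "linear") {
  f <- if (spacing == "linear") {
    seq(band[1], band[2], length.out = n_freqs)
  } else {
    exp(seq(log(band[1]), log(band[2]), length.out = n_freqs))
  }
  keep <- vapply(f, function(fc) all(abs(fc - exclude_hz) > exclude_halfwidth_hz),
                 logical(1))
  f[keep]
}

# Convolve each electrode with a complex kernel, same-size output, using
# reflection padding at the edges.
conv_same <- function(signal, kern) {
  L <- length(kern)
  half <- (L - 1) %/% 2
  n <- ncol(signal)
  pad <- min(half, n - 1)
  idx_pre <- seq(pad + 1, 2, length.out = pad)
  idx_post <- seq(n - 1, n - pad, length.out = pad)
  x <- cbind(signal[, idx_pre, drop = FALSE], signal,
             signal[, idx_post, drop = FALSE])
  m <- ncol(x)
  nf <- stats::nextn(m + L - 1)
  kf <- stats::fft(c(kern, rep(0, nf - L)))
  xf <- stats::mvfft(t(cbind(x, matrix(0, nrow(x), nf - m))))
  y <- stats::mvfft(xf * kf, inverse = TRUE) / nf
  # alignment: kernel center half+1; valid same-size region starts there
  t(y)[, (pad + half + 1):(pad + half + n), drop = FALSE]
}

#' Broadband power via complex Morlet wavelets
#'
#' Per electrode, power is computed with six-cycle complex Morlet wavelets at
#' center frequencies spanning `band` (linearly spaced by 10 Hz under the
#' defaults), excluding frequencies within 5 Hz of the line-noise harmonics,
#' aggregated across frequencies, then natural-log transformed and z-scored
#' per electrode. Note the six-cycle wavelets have wide spectral passbands
#' (sigma_f = f / n_cycles), so excluding a center frequency attenuates, but
#' does not null, content at that frequency.
#'
#' @param rec an `nlx_recording`; `fs` must exceed twice the band's upper edge
#' @param band frequency band in Hz (default 70-200)
#' @param n_cycles wavelet cycles (default 6)
#' @param exclude_hz line-noise frequencies to exclude (+/- 5 Hz)
#' @param n_freqs number of candidate center frequencies
#' @param aggregate `"mean_log"` (mean of per-frequency log power, default) or
#'   `"log_mean"` (log of mean power)
#' @param log_z apply natural log + per-electrode z-score (default TRUE;
#'   disabled inside the impulse audit, which needs the raw power envelope)
#' @return `nlx_recording` at stage `"power"`
#' @export
broadband_power <- function(rec, band = c(70, 200), n_cycles = 6,
                            exclude_hz = c(60, 120, 180), n_freqs = 14,
                            aggregate = c("mean_log", "log_mean"),
                            log_z = TRUE) {
  stopifnot(inherits(rec, "nlx_recording"))
  aggregate <- match.arg(aggregate)
  if (rec$fs <= 2 * band[2]) stop("sampling rate too low for requested band")
  freqs <- wavelet_freq_grid(band, n_freqs, exclude_hz)
  pow_acc <- NULL
  eps <- 1e-300
  for (f in freqs) {
    kern <- morlet_kernel(f, rec$fs, n_cycles)
    p <- Mod(conv_same(rec$signal, kern))^2
    term <- if (aggregate == "mean_log" && log_z) log(p + eps) else p
    pow_acc <- if (is.null(pow_acc)) term else pow_acc + term
  }
  pw <- pow_acc / length(freqs)
  if (log_z) {
    if (aggregate == "log_mean") pw <- log(pw + eps)
    pw <- zscore_rows(pw)
  }
  out <- rec
  out$signal <- pw
  out$stage <- "power"
  out
}

#' Zero-phase Hamming smoothing
#'
#' Convolves each electrode with a unit-sum Hamming window of `kernel_ms`
#' length, applied in the forward and then the reverse direction (zero-phase,
#' so isolated peaks keep their location).
#'
#' @param rec an `nlx_recording` (typically at stage `"power"`)
#' @param kernel_ms kernel length in ms (default 50)
#' @return smoothed `nlx_recording`
#' @export
smooth_zero_phase <- function(rec, kernel_ms = 50) {
  stopifnot(inherits(rec, "nlx_recording"))
  L <- max(3L, round(kernel_ms / 1000 * rec$fs))
  if (L > ncol(rec$signal)) stop("smoothing kernel longer than signal")
  k <- seq_len(L) - 1
  h <- 0.54 - 0.46 * cos(2 * pi * k / (L - 1))
  h <- h / sum(h)
  sig <- rec$signal
  pad <- L - 1
  smooth_dir <- function(x) {
    # reflection padding, causal FIR, then crop the filter delay
    xp <- cbind(x[, pmin(pad + 1, ncol(x)):2, drop = FALSE], x,
                x[, (ncol(x) - 1):max(1, ncol(x) - pad), drop = FALSE])
    y <- t(apply(xp, 1, function(v) stats::filter(v, h, sides = 1)))
    y[, (pad + pad + 1):(pad + pad + ncol(x)), drop = FALSE]
  }
  fwd <- smooth_dir(sig)
  bwd <- smooth_dir(fwd[, ncol(fwd):1, drop = FALSE])
  out <- rec
  out$signal <- bwd[, ncol(bwd):1, drop = FALSE]
  out$stage <- "smoothed"
  out
}

#' Impulse audit of acausal leakage in the power/smoothing chain
#'
#' Runs the requested stages on a unit impulse in silence and measures how far
#' before (and after) the impulse the output exceeds `threshold` times its
#' peak. The backward extent quantifies how much "future" signal leaks into
#' each preprocessed sample.
#'
#' @param fs sampling rate (Hz)
#' @param stages character vector drawn from `c("power", "smooth")`
#' @param threshold fraction of the peak output defining the extent
#' @param kernel_ms smoothing kernel length (ms)
#' @param band,n_cycles,exclude_hz,n_freqs passed to [broadband_power()]
#' @param duration_s length of the test signal
#' @return list with `backward_extent_ms`, `forward_extent_ms`, `threshold`
#' @export
impulse_leak_audit <- function(fs = 512, stages = c("power", "smooth"),
                               threshold = 1e-3, kernel_ms = 50,
                               band = c(70, 200), n_cycles = 6,
                               exclude_hz = c(60, 120, 180), n_freqs = 14,
                               duration_s = 4) {
  stages <- match.arg(stages, c("power", "smooth"), several.ok = TRUE)
  n <- round(duration_s * fs)
  mid <- n %/% 2
  sig <- matrix(0, 1, n)
  sig[1, mid] <- 1
  rec <- new_recording(sig, fs, stage = "raw")
  out <- rec
  if ("power" %in% stages) {
    out <- broadband_power(out, band = band, n_cycles = n_cycles,
                           exclude_hz = exclude_hz, n_freqs = n_freqs,
                           log_z = FALSE)
  }
  if ("smooth" %in% stages) out <- smooth_zero_phase(out, kernel_ms = kernel_ms)
  y <- abs(out$signal[1, ])
  hot <- which(y >= threshold * max(y))
  list(
    backward_extent_ms = max(0, (mid - min(hot)) / fs * 1000),
    forward_extent_ms = max(0, (max(hot) - mid) / fs * 1000),
    threshold = threshold
  )
}

#' Full preprocessing chain
#'
#' despike -> common-average re-reference -> wavelet broadband power (log,
#' z-score) -> zero-phase Hamming smoothing.
#'
#' @param rec a raw `nlx_recording`
#' @param despike_rule threshold rule for [despike()]
#' @param kernel_ms smoothing kernel (ms)
#' @param ... passed to [broadband_power()]
#' @return preprocessed `nlx_recording` (z-units high-gamma power)
#' @export
preprocess_highgamma <- function(rec, despike_rule = "iqr4median",
                                 kernel_ms = 50, ...) {
  rec <- despike(rec, rule = despike_rule)
  rec <- rereference_car(rec)
  rec <- broadband_power(rec, ...)
  smooth_zero_phase(rec, kernel_ms = kernel_ms)
}
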