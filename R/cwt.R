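#' Morlet wavelet conventions
#'
#' The mother wavelet is the L1-normalised complex Morlet with bandwidth
#' parameter `fb` and centre frequency `fc` (both default 1, balancing
#' temporal and spectral resolution at low frequencies):
#' `psi(t) = (pi*fb)^(-1/2) exp(2i*pi*fc*t) exp(-t^2/fb)`.
#' Its temporal Heisenberg half-width at analysis frequency `f` is
#' `sigma_t = sqrt(fb/2) / f` (the standard deviation of the scaled Gaussian
#' envelope), giving a full box width of `2*sigma_t` -- about 354 ms at 4 Hz,
#' which is why the delta band cannot fit a 300 ms response window.
#'
#' @param freq_hz Analysis frequency (scale centre frequency) in Hz.
#' @param fb Bandwidth parameter of the Morlet envelope.
#' @return `morlet_sigma_t()`: the temporal half-width in seconds.
#' @export
morlet_sigma_t <- function(freq_hz, fb = 1) sqrt(fb / 2) / freq_hz

#' Logarithmic scale grid of analysis frequencies
#'
#' Centre frequencies log-spaced between `low_hz` and `high_hz` (both
#' included). The default density of 6 voices per octave samples the
#' spectrum at roughly two scales per Morlet bandwidth (`sigma_f` is about
#' 22% of `f` at `fb = 1`), so no band is skipped while adjacent scales stay
#' only moderately correlated.
#'
#' @param low_hz,high_hz Frequency range in Hz.
#' @param voices Scales per octave.
#' @return Increasing numeric vector of frequencies in Hz.
#' @export
morlet_freqs <- function(low_hz = 4, high_hz = 70, voices = 6) {
  if (low_hz <= 0 || high_hz <= low_hz)
    plv_stop("Need 0 < low_hz < high_hz.")
  n <- ceiling(voices * log2(high_hz / low_hz)) + 1
  f <- low_hz * (high_hz / low_hz)^seq(0, 1, length.out = n)
  f[1] <- low_hz; f[n] <- high_hz
  f
}

#' Cone-of-influence validity mask
#'
#' A wavelet coefficient at time `t` (relative to the window start) and
#' frequency `f` is valid iff its temporal Heisenberg box
#' `[t - sigma_t(f), t + sigma_t(f)]` lies entirely inside the window. Rows
#' are scales (in the order of `freqs_hz`), columns the window's sample grid.
#' For each scale the valid entries form a contiguous central run, empty when
#' the box cannot fit (e.g. 4 Hz in a 300 ms window).
#'
#' @param window_len_s Window length in seconds (span between first and last
#'   sample).
#' @param fs_hz Sampling rate in Hz.
#' @param freqs_hz Analysis frequencies.
#' @param fb Morlet bandwidth parameter.
#' @return Logical matrix `length(freqs_hz) x n_samples`.
#' @export
coi_mask <- function(window_len_s, fs_hz, freqs_hz, fb = 1) {
  if (window_len_s <= 0) plv_stop("`window_len_s` must be positive.")
  tt <- seq(0, window_len_s, by = 1 / fs_hz)
  sig <- morlet_sigma_t(freqs_hz, fb)
  out <- outer(sig, tt, function(s, t)
    t - s >= -1e-12 & t + s <= window_len_s + 1e-12)
  dimnames(out) <- NULL
  out
}

# choose the FFT length for a window of n samples: power of two with a
# 5-sigma guard band for the widest wavelet, so circular wrap-around of the
# Gaussian tails is below ~4e-6 relative amplitude (and farther below at
# any COI-valid cell)
cwt_nfft <- function(n, fs, fmin, fb = 1) {
  pad <- ceiling(5 * morlet_sigma_t(fmin, fb) * fs)
  2^ceiling(log2(n + pad))
}

# per-scale decimation plan: power-of-two stride of one-to-two temporal
# half-widths sigma_t (coefficients closer than sigma_t are strongly
# correlated, so denser sampling adds little information), capped so that a
# nonempty COI-valid run always receives at least one cell; returns the
# COI-valid decimated cell indices (0-based, for the kernel)
cwt_cells <- function(n, fs, freqs, fb = 1, stride = "auto") {
  len <- (n - 1) / fs
  lapply(freqs, function(f) {
    sig <- morlet_sigma_t(f, fb)
    if (identical(stride, "auto")) {
      k_auto <- max(0, ceiling(log2(sig * fs)))
      run <- (len - 2 * sig) * fs          # valid run width in samples
      k_cap <- if (run >= 1) floor(log2(run)) else 0
      d <- 2^max(0, min(k_auto, k_cap))
    } else d <- as.integer(stride)
    m <- seq(0, floor((n - 1) / d))        # decimated grid
    t <- m * d / fs
    list(stride = as.integer(d),
         cells = as.integer(m[t - sig >= -1e-12 & t + sig <= len + 1e-12]))
  })
}

#' Continuous wavelet transform of an analysis window
#'
#' Complex Morlet coefficients of every channel and trial over the window's
#' segment, at the requested analysis frequencies. The transform is linear in
#' the input; a unit-amplitude cosine at a scale's centre frequency yields
#' coefficients of modulus 1/2 (the analytic half). Computed by
#' frequency-domain filtering with zero padding, so edge effects are confined
#' to the region excluded by [coi_mask()].
#'
#' @param rec An [epoched_recording()].
#' @param window An [analysis_window()] or window label.
#' @param freqs_hz Analysis frequencies in Hz, all below Nyquist.
#' @param fb,fc Morlet parameters.
#' @return An object of class `wavelet_spectrum`: complex `coeffs` array
#'   `channels x trials x scales x time`, `freqs_hz`, `time_s` (epoch time of
#'   each window sample), `window_label`, and the `coi` mask.
#' @export
cwt <- function(rec, window = "poststimulus", freqs_hz = morlet_freqs(),
                fb = 1, fc = 1) {
  window <- as_analysis_window(window)
  if (any(freqs_hz >= rec$fs_hz / 2))
    plv_stop("All analysis frequencies must be below Nyquist.")
  idx <- samples_in_span(rec, window$span_ms)
  if (length(idx) < 2)
    plv_stop("Analysis window lies outside the epoch.")
  x <- window_signal_matrix(rec, idx)
  nfft <- cwt_nfft(length(idx), rec$fs_hz, min(freqs_hz), fb)
  co <- cpp_cwt_morlet(x, rec$fs_hz, freqs_hz, fb, fc, nfft)
  nch <- n_channels(rec); ntr <- n_trials(rec)
  # kernel layout: (time, signal, scale) with signal channel-fastest
  co <- array(co, dim = c(length(idx), nch, ntr, length(freqs_hz)))
  co <- aperm(co, c(2, 3, 4, 1))
  structure(list(coeffs = co, freqs_hz = freqs_hz,
                 time_s = rec$time_s[idx], window_label = window$label,
                 fb = fb, fc = fc,
                 coi = coi_mask((length(idx) - 1) / rec$fs_hz, rec$fs_hz,
                                freqs_hz, fb)),
            class = "wavelet_spectrum")
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  d <- dim(x$coeffs)
  cat(sprintf(
    "<wavelet_spectrum> %s window: %d ch x %d trials x %d scales x %d samples\n",
    x$window_label, d[1], d[2], d[3], d[4]))
  cat(sprintf("  %g .. %g Hz, %d scales; %.0f%% of cells COI-valid\n",
              min(x$freqs_hz), max(x$freqs_hz), d[3], 100 * mean(x$coi)))
  invisible(x)
}
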