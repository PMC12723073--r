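#' Preprocessing configuration
#'
#' Defaults reproduce the standard single-pulse TMS-EEG conditioning chain:
#' excision of the unrecoverable -1..10 ms pulse segment with cubic
#' interpolation, common-average re-referencing, robust bad-channel
#' interpolation and bad-trial rejection, baseline correction over the
#' 800 ms before the pulse, optional resampling, and a zero-phase 0.5-70 Hz
#' band-pass.
#'
#' @param excise_ms Closed interval (ms) to cut and interpolate.
#' @param baseline_ms Baseline window (ms), inside the prestimulus period.
#' @param resample_hz Target rate; `NULL` keeps the input rate. (The
#'   acquisition-scale value would be 5000.)
#' @param bandpass_hz Band-pass edges (Hz), `0 < low < high < Nyquist`.
#' @param bad_channel_z,bad_trial_z Robust z-score thresholds on
#'   peak-to-peak amplitude; `Inf` disables.
#' @param filter_order Butterworth order (applied forward-backward).
#' @param flank_ms Flank length fitted on each side of the excision window.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(excise_ms = c(-1, 10),
                              baseline_ms = c(-800, 0),
                              resample_hz = NULL,
                              bandpass_hz = c(0.5, 70),
                              bad_channel_z = 5, bad_trial_z = 5,
                              filter_order = 4, flank_ms = 20) {
  if (bandpass_hz[1] <= 0 || bandpass_hz[1] >= bandpass_hz[2])
    plv_stop("Need 0 < bandpass low < high.",
             class = "plvnet_config_error")
  structure(list(excise_ms = excise_ms, baseline_ms = baseline_ms,
                 resample_hz = resample_hz, bandpass_hz = bandpass_hz,
                 bad_channel_z = bad_channel_z, bad_trial_z = bad_trial_z,
                 filter_order = filter_order, flank_ms = flank_ms),
            class = "preprocess_config")
}

#' Excise a window and bridge it with a cubic interpolant
#'
#' Replaces the samples whose time lies in the closed interval `excise_ms`
#' with a natural cubic spline fitted to `flank_ms` of data on each side of
#' the window; every other sample is untouched. Used to remove the
#' unrecoverable pulse transient.
#'
#' @param rec An [epoched_recording()].
#' @param excise_ms Closed interval in ms, strictly inside the epoch with at
#'   least 4 flank samples on each side.
#' @param flank_ms Flank length in ms.
#' @return The repaired recording.
#' @export
excise_interpolate <- function(rec, excise_ms = c(-1, 10), flank_ms = 20) {
  idx <- samples_in_span(rec, excise_ms)
  if (length(idx) == 0) return(rec)
  lo <- min(idx); hi <- max(idx)
  nfl <- max(4L, round(flank_ms / 1000 * rec$fs_hz))
  if (lo - nfl < 1 || hi + nfl > n_samples(rec))
    plv_stop("Excision window touches the epoch edge: no flank to fit.")
  fl <- c(seq(lo - nfl, lo - 1), seq(hi + 1, hi + nfl))
  tx <- rec$time_s[fl]
  tout <- rec$time_s[idx]
  d <- dim(rec$data)
  flat <- matrix(rec$data, nrow = d[1] * d[2])   # (ch*tr) x samples
  for (r in seq_len(nrow(flat)))
    flat[r, idx] <- spline(tx, flat[r, fl], xout = tout,
                           method = "natural")$y
  rec$data <- array(flat, dim = d)
  rec
}

#' Common-average re-referencing
#'
#' Subtracts the instantaneous mean across channels at every (trial,
#' sample), so the channel mean is 0 everywhere afterwards. Idempotent.
#'
#' @param rec An [epoched_recording()] with at least 2 channels.
#' @return The re-referenced recording.
#' @export
rereference_common_average <- function(rec) {
  if (n_channels(rec) < 2)
    plv_stop("Common-average reference needs at least 2 channels.")
  mu <- colMeans(rec$data)                        # trials x samples
  rec$data <- rec$data - rep(mu, each = n_channels(rec))
  rec
}

#' Baseline correction
#'
#' Removes, per channel and trial, the mean over the baseline window, so
#' baseline-window means are 0 afterwards. Idempotent.
#'
#' @param rec An [epoched_recording()].
#' @param baseline_ms Closed window in ms, inside the epoch and nonempty.
#' @return The corrected recording.
#' @export
baseline_correct <- function(rec, baseline_ms = c(-800, 0)) {
  idx <- samples_in_span(rec, baseline_ms)
  if (length(idx) == 0)
    plv_stop("Baseline window contains no samples.")
  mu <- apply(rec$data[, , idx, drop = FALSE], c(1, 2), mean)
  rec$data <- rec$data - as.vector(mu)            # recycles over samples
  rec
}

#' Resample and band-pass filter
#'
#' Optional polyphase resampling to `resample_hz` followed by a zero-phase
#' (forward-backward) Butterworth band-pass. The filter is applied per
#' channel and trial; zero-phase filtering preserves the instantaneous
#' phase structure that the PLV estimators depend on. Time 0 must still map
#' to a sample after resampling.
#'
#' @param rec An [epoched_recording()].
#' @param resample_hz Target rate (`NULL` or equal to the input rate: no
#'   resampling). Must be at least twice the band-pass high edge.
#' @param bandpass_hz Band edges in Hz.
#' @param filter_order Butterworth order (the effective order doubles
#'   through the forward-backward pass).
#' @return The filtered recording.
#' @export
resample_and_filter <- function(rec, resample_hz = NULL,
                                bandpass_hz = c(0.5, 70),
                                filter_order = 4) {
  target <- if (is.null(resample_hz)) rec$fs_hz else resample_hz
  if (target < 2 * bandpass_hz[2])
    plv_stop("Nyquist violation: resample rate must exceed twice the band-pass high edge.")
  if (target != rec$fs_hz) {
    frac <- ratio_integers(target, rec$fs_hz)
    d <- dim(rec$data)
    flat <- matrix(rec$data, nrow = d[1] * d[2])
    new_n <- ceiling(d[3] * frac[1] / frac[2])
    out <- matrix(0, nrow(flat), new_n)
    for (r in seq_len(nrow(flat)))
      out[r, ] <- signal::resample(flat[r, ], frac[1], frac[2])
    t0 <- rec$time_s[1]
    time_s <- t0 + (seq_len(new_n) - 1) / target
    onset <- which.min(abs(time_s))
    if (abs(time_s[onset]) > 1e-9)
      plv_stop("Resampling grid no longer contains the pulse sample.")
    rec <- epoched_recording(array(out, dim = c(d[1], d[2], new_n)),
                             fs_hz = target, time_s = time_s,
                             channel_labels = rec$channel_labels,
                             onset_index = onset)
  }
  bf <- signal::butter(filter_order, bandpass_hz / (rec$fs_hz / 2),
                       type = "pass")
  d <- dim(rec$data)
  flat <- matrix(rec$data, nrow = d[1] * d[2])
  for (r in seq_len(nrow(flat)))
    flat[r, ] <- signal::filtfilt(bf, flat[r, ])
  rec$data <- array(flat, dim = d)
  rec
}

ratio_integers <- function(p, q) {
  # reduce p/q assuming both are rational with modest denominators
  k <- 1
  while (k < 1000 &&
         (abs(p * k - round(p * k)) > 1e-9 ||
          abs(q * k - round(q * k)) > 1e-9)) k <- k + 1
  a <- round(p * k); b <- round(q * k)
  g <- gcd_int(a, b)
  c(a / g, b / g)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Bad-channel interpolation and bad-trial rejection
#'
#' Channel amplitude is the median across trials of the peak-to-peak range;
#' trial amplitude the maximum across channels. Robust z-scores
#' (median/MAD) above the thresholds flag channels -- replaced by the mean
#' of the remaining channels -- and trials, which are dropped. Homogeneous
#' data reject nothing, and infinite thresholds are the identity.
#'
#' @param rec An [epoched_recording()] with >= 3 channels and >= 3 trials.
#' @param bad_channel_z,bad_trial_z Robust z thresholds.
#' @return The cleaned recording, with attribute `rejection` listing
#'   `bad_channels` (interpolated) and `bad_trials` (dropped).
#' @export
reject_bad <- function(rec, bad_channel_z = 5, bad_trial_z = 5) {
  if (n_channels(rec) < 3 || n_trials(rec) < 3)
    plv_stop("Need at least 3 channels and 3 trials.")
  p2p <- apply(rec$data, c(1, 2), function(v) diff(range(v)))
  ch_amp <- apply(p2p, 1, median)
  bad_ch <- which(robust_z(ch_amp) > bad_channel_z)
  if (length(bad_ch) >= n_channels(rec) - 1)
    plv_stop("Almost all channels flagged bad; check the data.")
  if (length(bad_ch)) {
    good <- setdiff(seq_len(n_channels(rec)), bad_ch)
    repl <- colMeans(rec$data[good, , , drop = FALSE])  # trials x samples
    for (b in bad_ch) rec$data[b, , ] <- repl
    p2p <- apply(rec$data, c(1, 2), function(v) diff(range(v)))
  }
  tr_amp <- apply(p2p, 2, max)
  bad_tr <- which(robust_z(tr_amp) > bad_trial_z)
  if (length(bad_tr) == n_trials(rec))
    plv_stop("All trials rejected.")
  if (length(bad_tr))
    rec$data <- rec$data[, -bad_tr, , drop = FALSE]
  attr(rec, "rejection") <- list(bad_channels = as.integer(bad_ch),
                                 bad_trials = as.integer(bad_tr))
  rec
}

robust_z <- function(x) {
  m <- median(x); s <- mad(x)
  if (s == 0) return(ifelse(x == m, 0, Inf))
  (x - m) / s
}

#' Full preprocessing chain
#'
#' Applies, in order: pulse-window excision and cubic interpolation,
#' common-average re-referencing, bad-channel/bad-trial handling (with the
#' reference re-applied if any channel was interpolated), baseline
#' correction, resampling, zero-phase band-pass filtering, and a final
#' re-referencing + baseline re-centering pass so that the delivered epochs
#' are exactly reference-zero and baseline-zero (the near-unit-circle poles
#' of the 0.5 Hz high-pass leave small channel-dependent rounding residue,
#' and filtering perturbs baseline means; both closing steps are
#' idempotent). The applied order is recorded in the `preprocessing`
#' attribute together with the rejection report.
#'
#' @param rec An [epoched_recording()].
#' @param config A [preprocess_config()].
#' @return The preprocessed recording.
#' @export
preprocess <- function(rec, config = preprocess_config()) {
  steps <- character()
  rec <- excise_interpolate(rec, config$excise_ms, config$flank_ms)
  steps <- c(steps, "excise_interpolate")
  rec <- rereference_common_average(rec)
  steps <- c(steps, "rereference_common_average")
  rec <- reject_bad(rec, config$bad_channel_z, config$bad_trial_z)
  rej <- attr(rec, "rejection")
  steps <- c(steps, "reject_bad")
  if (length(rej$bad_channels)) {
    rec <- rereference_common_average(rec)
    steps <- c(steps, "rereference_common_average")
  }
  rec <- baseline_correct(rec, config$baseline_ms)
  steps <- c(steps, "baseline_correct")
  rec <- resample_and_filter(rec, config$resample_hz, config$bandpass_hz,
                             config$filter_order)
  steps <- c(steps, "resample_and_filter")
  rec <- rereference_common_average(rec)
  rec <- baseline_correct(rec, config$baseline_ms)
  steps <- c(steps, "rereference_common_average", "baseline_correct")
  assert_no_nan(rec, "preprocessed recording")
  attr(rec, "preprocessing") <- list(steps = steps, config = config,
                                     rejection = rej)
  rec
}
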