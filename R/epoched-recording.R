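#' Epoched multi-trial EEG recording
#'
#' The common currency of the pipeline: a `channels x trials x samples` array
#' of epoched EEG (in microvolts) together with its time axis relative to the
#' stimulus pulse, sampling rate, channel labels, and the sample index of
#' time zero (pulse onset).
#'
#' @param data Numeric array `channels x trials x samples` (microvolts).
#' @param fs_hz Sampling rate in Hz.
#' @param time_s Numeric vector of per-sample epoch times in seconds relative
#'   to the pulse; must be strictly increasing with uniform step `1/fs_hz`.
#'   Defaults to a grid ending at `onset_index` = time 0.
#' @param channel_labels Character vector of channel names.
#' @param onset_index Sample index (1-based) of time 0. Derived from `time_s`
#'   when omitted.
#'
#' @return An object of class `epoched_recording`.
#' @export
epoched_recording <- function(data, fs_hz, time_s = NULL,
                              channel_labels = NULL, onset_index = NULL) {
  if (length(dim(data)) != 3L)
    plv_stop("`data` must be a channels x trials x samples array.")
  n <- dim(data)[3]
  if (is.null(time_s)) {
    if (is.null(onset_index))
      plv_stop("Provide `time_s` or `onset_index` to anchor the pulse.")
    time_s <- (seq_len(n) - onset_index) / fs_hz
  }
  if (length(time_s) != n)
    plv_stop("`time_s` length must equal the number of samples.")
  step <- diff(time_s)
  if (any(step <= 0) || max(abs(step - 1 / fs_hz)) > 1e-9 / fs_hz)
    plv_stop("`time_s` must be strictly increasing with uniform step 1/fs_hz.")
  if (is.null(onset_index)) {
    onset_index <- which.min(abs(time_s))
    if (abs(time_s[onset_index]) > 1e-9)
      plv_stop("`time_s` must contain time 0 (the pulse onset sample).")
  }
  if (abs(time_s[onset_index]) > 1e-9)
    plv_stop("`onset_index` is inconsistent with `time_s`.")
  if (is.null(channel_labels))
    channel_labels <- sprintf("Ch%02d", seq_len(dim(data)[1]))
  if (length(channel_labels) != dim(data)[1])
    plv_stop("`channel_labels` length must equal the number of channels.")
  structure(
    list(data = data, time_s = as.numeric(time_s), fs_hz = fs_hz,
         channel_labels = as.character(channel_labels),
         onset_index = as.integer(onset_index)),
    class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoched_recording> %d channels x %d trials x %d samples @ %g Hz\n",
    d[1], d[2], d[3], x$fs_hz))
  cat(sprintf("  epoch %.3f .. %.3f s around pulse (onset sample %d)\n",
              x$time_s[1], x$time_s[length(x$time_s)], x$onset_index))
  invisible(x)
}

#' @export
dim.epoched_recording <- function(x) dim(x$data)

n_channels <- function(rec) dim(rec$data)[1]
n_trials   <- function(rec) dim(rec$data)[2]
n_samples  <- function(rec) dim(rec$data)[3]

# samples whose time (ms) lies in the closed interval span_ms
samples_in_span <- function(rec, span_ms) {
  t_ms <- rec$time_s * 1000
  which(t_ms >= span_ms[1] - 1e-9 & t_ms <= span_ms[2] + 1e-9)
}

assert_no_nan <- function(rec, where = "recording") {
  if (anyNA(rec$data) || any(!is.finite(rec$data)))
    plv_stop(sprintf("Non-finite values in %s.", where))
  invisible(rec)
}

# signals matrix for a window: samples x (channels*trials), channel-fastest
window_signal_matrix <- function(rec, idx) {
  seg <- rec$data[, , idx, drop = FALSE]          # ch x tr x n
  n <- length(idx)
  m <- matrix(aperm(seg, c(3, 1, 2)), nrow = n)   # col = (tr-1)*nch + ch
  m
}
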