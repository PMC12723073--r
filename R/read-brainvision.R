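#' Read a BrainVision recording
#'
#' Minimal reader for the BrainVision triplet: the INI-style `.vhdr` header
#' (channel count, labels, resolutions, sampling interval, binary format),
#' the `.vmrk` marker file, and the multiplexed binary `.eeg` payload
#' (IEEE_FLOAT_32 or INT_16, little-endian). Returns the continuous data in
#' microvolts plus the markers, ready for [epoch_continuous()].
#'
#' @param vhdr_path Path to the `.vhdr` header file.
#' @return A list: `data` (`channels x samples`, uV), `fs_hz`,
#'   `channel_labels`, `markers` (data.frame with `type`, `description`,
#'   `position` in samples).
#' @export
read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, warn = FALSE)
  get_val <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(hit)) plv_stop(sprintf("Header lacks '%s'.", key))
    sub(paste0("^", key, "="), "", hit[1])
  }
  n_ch <- as.integer(get_val("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get_val("SamplingInterval"))   # interval in us
  fmt <- get_val("BinaryFormat")
  orient <- get_val("DataOrientation")
  if (toupper(orient) != "MULTIPLEXED")
    plv_stop("Only MULTIPLEXED orientation is supported.")
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  if (length(ch_lines) < n_ch) plv_stop("Channel info lines missing.")
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines[seq_len(n_ch)]), ",")
  labels <- vapply(parts, `[`, "", 1)
  resol <- vapply(parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, 0)

  dir <- dirname(vhdr_path)
  eeg_path <- file.path(dir, get_val("DataFile"))
  size <- file.info(eeg_path)$size
  if (toupper(fmt) == "IEEE_FLOAT_32") {
    raw <- readBin(eeg_path, "numeric", n = size / 4, size = 4,
                   endian = "little")
  } else if (toupper(fmt) == "INT_16") {
    raw <- readBin(eeg_path, "integer", n = size / 2, size = 2,
                   signed = TRUE, endian = "little")
  } else plv_stop(sprintf("Unsupported BinaryFormat '%s'.", fmt))
  n_samp <- length(raw) %/% n_ch
  dat <- matrix(raw[seq_len(n_samp * n_ch)], nrow = n_ch)  # multiplexed
  dat <- dat * resol

  markers <- data.frame(type = character(), description = character(),
                        position = integer())
  vmrk <- tryCatch(file.path(dir, get_val("MarkerFile")), error = function(e) NULL)
  if (!is.null(vmrk) && file.exists(vmrk)) {
    ml <- grep("^Mk[0-9]+=", readLines(vmrk, warn = FALSE), value = TRUE)
    mp <- strsplit(sub("^Mk[0-9]+=", "", ml), ",")
    markers <- data.frame(
      type = vapply(mp, `[`, "", 1),
      description = vapply(mp, `[`, "", 2),
      position = as.integer(vapply(mp, `[`, "", 3)))
  }
  list(data = dat, fs_hz = fs, channel_labels = labels, markers = markers)
}

#' Epoch continuous data around event onsets
#'
#' Cuts fixed-length epochs around marker positions, dropping events whose
#' epoch would leave the recording.
#'
#' @param data `channels x samples` matrix (uV).
#' @param fs_hz Sampling rate.
#' @param onsets Event positions in samples (1-based).
#' @param span_s `(pre, post)` epoch limits in seconds around each event.
#' @param channel_labels Optional channel names.
#' @return An [epoched_recording()] with one trial per retained event.
#' @export
epoch_continuous <- function(data, fs_hz, onsets, span_s = c(-1, 1),
                             channel_labels = NULL) {
  pre <- round(span_s[1] * fs_hz)
  post <- round(span_s[2] * fs_hz) - 1
  keep <- onsets + pre >= 1 & onsets + post <= ncol(data)
  onsets <- onsets[keep]
  if (!length(onsets)) plv_stop("No event fits inside the recording.")
  rel <- pre:post
  arr <- array(0, dim = c(nrow(data), length(onsets), length(rel)))
  for (k in seq_along(onsets))
    arr[, k, ] <- data[, onsets[k] + rel, drop = FALSE]
  epoched_recording(arr, fs_hz = fs_hz, time_s = rel / fs_hz,
                    channel_labels = channel_labels,
                    onset_index = which(rel == 0))
}
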