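#' Cross-trial phase-coupling specification for a channel pair
#'
#' Describes one coupled channel pair in the synthetic cohort: a shared
#' band-limited oscillator whose per-trial initial phase is uniform, received
#' by both channels, with the second channel phase-jittered so that the
#' cross-trial phase difference of the pair is von Mises distributed with
#' concentration `kappa_pre` before the pulse and `kappa_post` after it, and
#' centred on `lag_rad`.
#'
#' @param pair Integer vector of length 2: the coupled channel indices.
#' @param band_hz Numeric `(low, high)` in Hz, within `[0.5, 70]`; the
#'   oscillator sits at the band midpoint.
#' @param kappa_pre,kappa_post Von Mises concentrations (>= 0) of the
#'   cross-trial phase difference in the pre/post-stimulus halves. 0 means
#'   uniform (no locking); values above `1e5` are treated as perfect locking.
#' @param lag_rad Phase offset of the second channel relative to the first,
#'   in radians. 0 emulates a zero-lag (volume-conduction-like) interaction.
#' @param amplitude Oscillator amplitude in microvolts.
#'
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(pair, band_hz, kappa_pre = 0, kappa_post = 5,
                          lag_rad = 0, amplitude = 2) {
  pair <- as.integer(pair)
  if (length(pair) != 2L || pair[1] == pair[2] || any(pair < 1L))
    plv_stop("`pair` must be two distinct positive channel indices.",
             class = "plvnet_config_error")
  if (length(band_hz) != 2L || band_hz[1] >= band_hz[2] ||
      band_hz[1] < 0.5 || band_hz[2] > 70)
    plv_stop("`band_hz` must be an increasing pair within [0.5, 70] Hz.",
             class = "plvnet_config_error")
  if (kappa_pre < 0 || kappa_post < 0)
    plv_stop("Concentrations `kappa_pre`/`kappa_post` must be >= 0.",
             class = "plvnet_config_error")
  structure(list(pair = pair, band_hz = as.numeric(band_hz),
                 kappa_pre = kappa_pre, kappa_post = kappa_post,
                 lag_rad = lag_rad, amplitude = amplitude),
            class = "coupling_spec")
}

#' Synthetic cohort configuration
#'
#' Desk-scale defaults emulate the study conditions after pulse-artifact
#' cleaning: 20 subjects, 16 channels, 60 retained trials (75 delivered
#' pulses minus rejections), 2 s epochs (-1 to +1 s around the pulse) at
#' 1000 Hz, pink (1/f) background noise band-limited to 1-100 Hz, and
#' optional instantaneous (zero-lag) channel mixing emulating volume
#' conduction, plus an optional simulated pulse artifact.
#'
#' @param n_subjects,n_channels,n_trials Cohort dimensions. `n_trials >= 2`.
#' @param fs_hz Sampling rate, >= 200 Hz so 70 Hz content is representable.
#' @param epoch_span_s Epoch limits in seconds around the pulse.
#' @param couplings List of [coupling_spec()] objects.
#' @param noise_sd Standard deviation of the pink background noise (uV).
#' @param mixing Optional square `channels x channels` mixing matrix with
#'   positive diagonal, applied instantaneously after source summation.
#' @param artifact_uV Pulse-artifact amplitude passed to
#'   [inject_pulse_artifact()]; 0 disables it.
#' @param seed RNG seed; generation is bit-reproducible given the config.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 20, n_channels = 16, n_trials = 60,
                             fs_hz = 1000, epoch_span_s = c(-1, 1),
                             couplings = list(), noise_sd = 1,
                             mixing = NULL, artifact_uV = 0, seed = 1) {
  if (n_trials < 2) plv_stop("`n_trials` must be >= 2.",
                             class = "plvnet_config_error")
  if (fs_hz < 200) plv_stop("`fs_hz` must be >= 200 Hz.",
                            class = "plvnet_config_error")
  if (epoch_span_s[1] >= 0 || epoch_span_s[2] <= 0)
    plv_stop("`epoch_span_s` must straddle the pulse at time 0.",
             class = "plvnet_config_error")
  for (cs in couplings) {
    if (!inherits(cs, "coupling_spec"))
      plv_stop("`couplings` must be a list of coupling_spec objects.",
               class = "plvnet_config_error")
    if (any(cs$pair > n_channels))
      plv_stop("Coupling channel index exceeds `n_channels`.",
               class = "plvnet_config_error")
  }
  if (!is.null(mixing)) {
    if (!is.matrix(mixing) || nrow(mixing) != n_channels ||
        ncol(mixing) != n_channels || any(diag(mixing) <= 0))
      plv_stop("`mixing` must be channels x channels with positive diagonal.",
               class = "plvnet_config_error")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_channels = as.integer(n_channels),
                 n_trials = as.integer(n_trials), fs_hz = fs_hz,
                 epoch_span_s = as.numeric(epoch_span_s),
                 couplings = couplings, noise_sd = noise_sd,
                 mixing = mixing, artifact_uV = artifact_uV,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Study-condition cohort configurations
#'
#' `effect_cohort_config()` is the default effect-bearing cohort: three
#' coupled pairs (theta, alpha, beta-2) that are phase-incoherent before the
#' pulse (`kappa_pre = 0`) and strongly locked after it (`kappa_post = 5`),
#' emulating a stimulus-evoked increase in cross-trial phase coupling.
#' `null_cohort_config()` is the sham-like null: identical layout with no
#' coupling change (`kappa_post = 0`).
#'
#' @param seed RNG seed.
#' @param n_subjects Number of subjects.
#' @return A [synthetic_config()].
#' @export
effect_cohort_config <- function(seed = 1, n_subjects = 20) {
  synthetic_config(
    n_subjects = n_subjects, seed = seed,
    couplings = list(
      coupling_spec(c(1, 2), c(4, 8),  kappa_pre = 0, kappa_post = 5,
                    lag_rad = pi / 3),
      coupling_spec(c(3, 4), c(8, 13), kappa_pre = 0, kappa_post = 5,
                    lag_rad = pi / 4),
      coupling_spec(c(5, 6), c(19, 30), kappa_pre = 0, kappa_post = 5,
                    lag_rad = pi / 2)))
}

#' @rdname effect_cohort_config
#' @export
null_cohort_config <- function(seed = 1, n_subjects = 20) {
  cfg <- effect_cohort_config(seed = seed, n_subjects = n_subjects)
  cfg$couplings <- lapply(cfg$couplings, function(cs) {
    cs$kappa_post <- 0
    cs
  })
  cfg
}

#' Volume-conduction demonstration scenario
#'
#' A 5-channel, single-subject configuration used to separate genuine lagged
#' coupling from zero-lag leakage: channels 1-2 share an alpha oscillator at
#' lag pi/2 (a genuinely lagged interaction that both PLV and ciPLV should
#' see), while channel 4 receives an instantaneous 0.9-weighted copy of
#' channel 3, whose alpha oscillator it therefore shares at exactly zero lag
#' (the volume-conduction confound that ciPLV is built to discount). Channel
#' 5 is an inert sink: it receives an independent, uniformly jittered copy of
#' the second oscillator so that channel 3 can carry an oscillator without
#' coupling to any measured channel. Locking is held at the perfect-coupling
#' cap in both halves so either analysis window can be used.
#'
#' @param seed RNG seed.
#' @return A [synthetic_config()].
#' @export
scenario_volume_conduction <- function(seed = 1) {
  mixing <- diag(5)
  mixing[4, 3] <- 0.9
  synthetic_config(
    n_subjects = 1, n_channels = 5, seed = seed, mixing = mixing,
    couplings = list(
      coupling_spec(c(1, 2), c(8, 13), kappa_pre = 1e6, kappa_post = 1e6,
                    lag_rad = pi / 2, amplitude = 3),
      coupling_spec(c(3, 5), c(8, 13), kappa_pre = 0, kappa_post = 0,
                    lag_rad = 0, amplitude = 3)))
}

# Best-Fisher (1979) von Mises sampler via R's RNG; kappa 0 -> uniform,
# kappa > 1e5 -> degenerate at 0.
rvonmises <- function(n, kappa) {
  if (kappa == 0) return(runif(n, -pi, pi))
  if (kappa > 1e5) return(rep(0, n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

# pink (1/f power) band-limited noise, samples x nsig, unit SD
pink_noise_matrix <- function(nsamp, nsig, fs, band = c(1, 100)) {
  nfft <- 2^ceiling(log2(nsamp))
  band[2] <- min(band[2], fs / 2 * 0.98)
  bins <- seq(max(1, ceiling(band[1] * nfft / fs)),
              floor(band[2] * nfft / fs))
  amps <- (bins * fs / nfft)^(-0.5)
  ncx <- ceiling(nsig / 2)   # Re/Im of each complex column are independent
  nb <- length(bins)
  z <- array(rnorm(4 * nb * ncx), dim = c(nb, ncx, 4))
  zm <- function(k) matrix(z[, , k], nb, ncx)
  x <- cpp_spectral_synth(nfft, nsamp, bins[1], amps,
                          zm(1), zm(2), zm(3), zm(4))
  x[, seq_len(nsig), drop = FALSE] * (nfft / sqrt(2 * sum(amps^2)))
}

generate_recording <- function(config) {
  nch <- config$n_channels; ntr <- config$n_trials
  fs <- config$fs_hz
  time_s <- seq(config$epoch_span_s[1], config$epoch_span_s[2] - 1 / fs,
                by = 1 / fs)
  nsamp <- length(time_s)
  onset <- which.min(abs(time_s))

  noise <- pink_noise_matrix(nsamp, nch * ntr, fs) * config$noise_sd
  dat <- aperm(array(noise, dim = c(nsamp, nch, ntr)), c(2, 3, 1))

  post <- time_s >= 0
  for (cs in config$couplings) {
    f0 <- mean(cs$band_hz)
    theta <- runif(ntr, -pi, pi)               # shared per-trial phase
    eps_pre <- rvonmises(ntr, cs$kappa_pre)    # second-channel jitter
    eps_post <- rvonmises(ntr, cs$kappa_post)
    base <- outer(2 * pi * f0 * time_s, theta, "+")    # nsamp x ntr
    dat[cs$pair[1], , ] <- dat[cs$pair[1], , ] + cs$amplitude * t(cos(base))
    jit <- matrix(eps_pre, nsamp, ntr, byrow = TRUE)
    jit[post, ] <- matrix(eps_post, sum(post), ntr, byrow = TRUE)
    dat[cs$pair[2], , ] <- dat[cs$pair[2], , ] +
      cs$amplitude * t(cos(base + cs$lag_rad + jit))
  }
  if (!is.null(config$mixing)) {
    flat <- matrix(dat, nrow = nch)
    dat <- array(config$mixing %*% flat, dim = dim(dat))
  }
  rec <- epoched_recording(dat, fs_hz = fs, time_s = time_s,
                           onset_index = onset)
  if (config$artifact_uV > 0)
    rec <- inject_pulse_artifact(rec, config$artifact_uV)
  rec
}

#' Generate a synthetic cohort of epoched recordings
#'
#' One [epoched_recording()] per subject, with the cross-trial phase
#' structure requested in the configuration's couplings. Deterministic given
#' the configuration seed (R's RNG state is restored on exit).
#'
#' @param config A [synthetic_config()].
#' @return A list of `epoched_recording` objects with the config attached as
#'   attribute `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config"))
    plv_stop("`config` must be a synthetic_config.",
             class = "plvnet_config_error")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)
  cohort <- lapply(seq_len(config$n_subjects),
                   function(k) generate_recording(config))
  attr(cohort, "config") <- config
  cohort
}

#' Add a simulated TMS pulse artifact
#'
#' Adds a large decaying-exponential transient (time constant 3 ms) to every
#' channel and trial inside `span_ms`; samples outside the span are
#' untouched. This is the artifact that the excision/interpolation step of
#' preprocessing exists to remove.
#'
#' @param rec An [epoched_recording()].
#' @param amplitude_uV Peak amplitude in microvolts; 0 returns the input
#'   unchanged.
#' @param span_ms Closed interval in ms around the pulse; must lie inside
#'   the epoch.
#' @return The recording with the transient added.
#' @export
inject_pulse_artifact <- function(rec, amplitude_uV, span_ms = c(-1, 10)) {
  t_ms <- rec$time_s * 1000
  if (span_ms[1] < t_ms[1] || span_ms[2] > t_ms[length(t_ms)])
    plv_stop("`span_ms` must lie inside the epoch.")
  if (amplitude_uV == 0) return(rec)
  idx <- samples_in_span(rec, span_ms)
  tau_ms <- 3
  shape <- amplitude_uV * exp(-(t_ms[idx] - span_ms[1]) / tau_ms)
  rec$data[, , idx] <- rec$data[, , idx] +
    rep(shape, each = prod(dim(rec$data)[1:2]))
  rec
}
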