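# Independent oracles and fixture builders shared across the suite.

# recording with explicit per-trial signals: x is samples x trials (one
# channel) or a list of such matrices (one per channel)
rec_from_signals <- function(x, fs = 1000, onset = NULL) {
  if (!is.list(x)) x <- list(x)
  n <- nrow(x[[1]]); ntr <- ncol(x[[1]])
  arr <- array(0, c(length(x), ntr, n))
  for (ch in seq_along(x)) arr[ch, , ] <- t(x[[ch]])
  if (is.null(onset)) onset <- floor(n / 2)
  epoched_recording(arr, fs_hz = fs, onset_index = onset)
}

# direct time-domain Morlet correlation (L1-normalised analytic wavelet);
# quadratic cost, small inputs only
cwt_direct <- function(x, fs, f0, fb = 1, fc = 1) {
  n <- length(x); tt <- (seq_len(n) - 1) / fs; a <- fc / f0
  vapply(seq_len(n), function(k) {
    dt <- tt[k] - tt
    h <- (1 / (a * sqrt(pi * fb))) * exp(2i * pi * fc * dt / a) *
      exp(-dt^2 / (a^2 * fb))
    sum(x * h) / fs
  }, complex(1))
}

# brute-force masked band mean (loop form)
band_mean_loop <- function(values, freqs, low, high, coi, closed_top) {
  acc <- 0; cnt <- 0
  for (s in seq_len(nrow(values))) {
    inband <- freqs[s] >= low &&
      (freqs[s] < high || (closed_top && freqs[s] <= high))
    if (!inband) next
    for (k in seq_len(ncol(values))) {
      if (coi[s, k]) { acc <- acc + values[s, k]; cnt <- cnt + 1 }
    }
  }
  if (cnt == 0) return(NA_real_)
  acc / cnt
}

# random symmetric weight matrix with zero diagonal, weights in (lo, hi)
random_weights <- function(n, lo = 0.15, hi = 0.95) {
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- runif(n * (n - 1) / 2, lo, hi)
  W + t(W)
}

# triple-loop clustering coefficient, strength-denominator formula
clc_loop_strength <- function(W) {
  n <- nrow(W)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    t_i <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && h != j)
        t_i <- t_i + (W[i, j] * W[i, h] * W[j, h])^(1 / 3)
    }
    t_i <- t_i / 2
    s_i <- sum(W[i, ])
    vals[i] <- 2 * t_i / (s_i * (s_i - 1))
  }
  mean(vals)
}

clc_loop_degree <- function(W) {
  n <- nrow(W)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    t_i <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && h != j)
        t_i <- t_i + (W[i, j] * W[i, h] * W[j, h])^(1 / 3)
    }
    vals[i] <- t_i / ((n - 1) * (n - 2))
  }
  mean(vals)
}

# all-pairs shortest paths by Floyd-Warshall dynamic programming
pl_floyd <- function(W) {
  n <- nrow(W)
  D <- 1 / W; diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  sum(D[upper.tri(D)]) * 2 / (n * (n - 1))
}

# stats-level null metrics table: no true pre/post difference
null_metrics_table <- function(n_subjects = 20,
                               bands = c("theta", "alpha", "beta1",
                                         "beta2", "gamma", "global")) {
  rows <- expand.grid(subject = seq_len(n_subjects),
                      window = c("prestimulus", "poststimulus"),
                      band = bands,
                      parameter = c("cs", "clc", "pl"),
                      stringsAsFactors = FALSE)
  rows$estimator <- "plv"
  rows$value <- rnorm(nrow(rows))
  tibble::as_tibble(rows)
}
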