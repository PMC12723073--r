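make_noise_rec <- function(seed = 1, nch = 4, ntr = 6, n = 2000,
                           fs = 1000) {
  set.seed(seed)
  arr <- array(rnorm(nch * ntr * n), c(nch, ntr, n))
  epoched_recording(arr, fs_hz = fs, onset_index = n / 2 + 1)
}

test_that("excision replaces the window with a cubic bridge", {
  # constant signal: interpolant of a constant is the constant
  rec <- make_noise_rec()
  rec$data[] <- 3.0
  out <- excise_interpolate(rec, c(-1, 10))
  expect_equal(max(abs(out$data - 3.0)), 0, tolerance = 1e-12)

  # cubic polynomial: the spline bridge reproduces t^3 on the gap
  rec2 <- make_noise_rec(nch = 1, ntr = 1)
  rec2$data[1, 1, ] <- rec2$time_s^3
  out2 <- excise_interpolate(rec2, c(-1, 10))
  idx <- which(rec2$time_s >= -0.001 - 1e-12 & rec2$time_s <= 0.010 + 1e-12)
  relerr <- max(abs(out2$data[1, 1, idx] - rec2$time_s[idx]^3)) /
    max(abs(rec2$time_s^3))
  expect_lt(relerr, 1e-6)
  # samples outside the window are untouched
  expect_identical(out2$data[1, 1, -idx], rec2$data[1, 1, -idx])

  # a confined 5000 uV spike on EEG-like (band-limited) background is
  # brought back to flank level
  cfg <- synthetic_config(n_subjects = 1, n_channels = 4, n_trials = 6,
                          seed = 3)
  rec3 <- generate_cohort(cfg)[[1]]
  idx3 <- which(rec3$time_s >= -0.001 - 1e-12 & rec3$time_s <= 0.010 + 1e-12)
  rec3$data[, , idx3] <- rec3$data[, , idx3] + 5000
  out3 <- excise_interpolate(rec3, c(-1, 10))
  flank <- setdiff(which(abs(rec3$time_s * 1000 - 5) <= 55), idx3)
  expect_lte(max(abs(out3$data[, , idx3])),
             max(abs(out3$data[, , flank])))

  # window touching the epoch edge has no flank to fit
  expect_error(excise_interpolate(rec, c(-1000, -980)))
})

test_that("common-average re-referencing zeroes the channel mean", {
  rec <- make_noise_rec()
  out <- rereference_common_average(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  # already balanced data are unchanged
  rec2 <- make_noise_rec(nch = 2)
  rec2$data[2, , ] <- -rec2$data[1, , ]
  expect_equal(rereference_common_average(rec2)$data, rec2$data,
               tolerance = 1e-12)
  # {2, 4} -> {-1, +1}
  rec3 <- make_noise_rec(nch = 2, ntr = 1, n = 10)
  rec3$data[1, , ] <- 2; rec3$data[2, , ] <- 4
  out3 <- rereference_common_average(rec3)
  expect_equal(unique(as.vector(out3$data[1, , ])), -1)
  expect_equal(unique(as.vector(out3$data[2, , ])), 1)
  # idempotent
  expect_equal(rereference_common_average(out)$data, out$data,
               tolerance = 1e-12)
  rec1 <- make_noise_rec(nch = 1)
  expect_error(rereference_common_average(rec1))
})

test_that("baseline correction zeroes the baseline-window mean", {
  rec <- make_noise_rec()
  out <- baseline_correct(rec, c(-800, 0))
  idx <- which(rec$time_s >= -0.8 - 1e-12 & rec$time_s <= 1e-12)
  mus <- apply(out$data[, , idx], c(1, 2), mean)
  expect_lt(max(abs(mus)), 1e-10)
  # constant offset is removed everywhere
  rec2 <- make_noise_rec()
  out2a <- baseline_correct(rec2, c(-800, 0))
  rec2$data <- rec2$data + 7
  out2b <- baseline_correct(rec2, c(-800, 0))
  expect_equal(out2a$data, out2b$data, tolerance = 1e-10)
  # idempotent
  expect_equal(baseline_correct(out, c(-800, 0))$data, out$data,
               tolerance = 1e-10)
  expect_error(baseline_correct(rec, c(500, 400)))
})

test_that("band-pass keeps the passband and rejects stopband and DC", {
  fs <- 1000
  tt <- seq(-1, 0.999, by = 1 / fs)
  mk <- function(x) {
    arr <- array(0, c(1, 1, length(tt))); arr[1, 1, ] <- x
    epoched_recording(arr, fs_hz = fs, onset_index = 1001)
  }
  mid <- 500:1500   # avoid filter edge transients
  p10 <- resample_and_filter(mk(sin(2 * pi * 10 * tt)))
  expect_lt(abs(max(p10$data[1, 1, mid]) - 1), 0.05)

  p100 <- resample_and_filter(mk(sin(2 * pi * 100 * tt)))
  expect_lt(max(abs(p100$data[1, 1, mid])), 10^(-20 / 20))

  pdc <- resample_and_filter(mk(rep(5, length(tt))))
  expect_lt(max(abs(pdc$data[1, 1, mid])), 5 * 10^(-20 / 20))

  expect_error(resample_and_filter(mk(tt), resample_hz = 120),
               regexp = "Nyquist")
})

test_that("resampling keeps the pulse on a sample and changes the rate", {
  rec <- make_noise_rec(nch = 2, ntr = 2)
  out <- resample_and_filter(rec, resample_hz = 500)
  expect_equal(out$fs_hz, 500)
  expect_lt(abs(out$time_s[out$onset_index]), 1e-9)
  expect_equal(dim(out$data)[3], 1000)
})

test_that("bad channel and trial handling is robust and conservative", {
  rec <- make_noise_rec(seed = 8, nch = 6, ntr = 10)
  out <- reject_bad(rec, 5, 5)
  expect_length(attr(out, "rejection")$bad_channels, 0)
  expect_length(attr(out, "rejection")$bad_trials, 0)

  # one trial at 100x amplitude: exactly that trial in the report
  rec2 <- make_noise_rec(seed = 9, nch = 6, ntr = 10)
  rec2$data[, 4, ] <- rec2$data[, 4, ] * 100
  out2 <- reject_bad(rec2, 5, 5)
  expect_identical(attr(out2, "rejection")$bad_trials, 4L)
  expect_equal(dim(out2$data)[2], 9)

  # one wild channel: interpolated, not dropped
  rec3 <- make_noise_rec(seed = 10, nch = 6, ntr = 10)
  rec3$data[2, , ] <- rec3$data[2, , ] * 50
  out3 <- reject_bad(rec3, 5, 5)
  expect_identical(attr(out3, "rejection")$bad_channels, 2L)
  good_mean <- colMeans(rec3$data[-2, , , drop = FALSE])
  expect_equal(out3$data[2, , ], good_mean, tolerance = 1e-12)

  # infinite thresholds are the identity
  out4 <- reject_bad(rec2, Inf, Inf)
  expect_identical(out4$data, rec2$data)
})

test_that("the full chain meets its contracts and records its order", {
  cfg <- synthetic_config(n_subjects = 1, n_channels = 6, n_trials = 8,
                          seed = 31, artifact_uV = 5000)
  rec <- generate_cohort(cfg)[[1]]
  out <- preprocess(rec)

  expect_lt(max(abs(colMeans(out$data))), 1e-10)          # CAR zero
  idx <- which(out$time_s >= -0.8 - 1e-12 & out$time_s <= 1e-12)
  expect_lt(max(abs(apply(out$data[, , idx], c(1, 2), mean))), 1e-10)
  expect_false(anyNA(out$data))
  expect_true(all(is.finite(out$data)))

  meta <- attr(out, "preprocessing")
  expect_equal(meta$steps[1:2],
               c("excise_interpolate", "rereference_common_average"))
  expect_true("resample_and_filter" %in% meta$steps)

  # artifact gone: excision window no larger than its flanks
  exc <- which(out$time_s >= -0.001 - 1e-12 & out$time_s <= 0.010 + 1e-12)
  flank <- setdiff(which(abs(out$time_s) <= 0.08), exc)
  expect_lte(max(abs(out$data[, , exc])), max(abs(out$data[, , flank])))
})
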