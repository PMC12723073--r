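test_that("PLV obeys its closed-form cases and chance level", {
  # identical phases in every trial: unit resultant
  ph <- matrix(exp(1i * runif(8)), nrow = 4, ncol = 2, byrow = TRUE)
  expect_equal(as.vector(plv(ph, ph * exp(1i * 0.3))), c(1, 1),
               tolerance = 1e-12)

  # two trials at opposite phase: perfect cancellation
  x <- matrix(exp(1i * c(0, 0)), 2, 1)
  y <- matrix(exp(1i * c(0, pi)), 2, 1)
  expect_equal(as.vector(plv(x, y)), 0, tolerance = 1e-12)

  # 60 uniform phase differences: Monte-Carlo mean near sqrt(pi/240)
  set.seed(7)
  u <- matrix(exp(1i * runif(60 * 2000, 0, 2 * pi)), 60, 2000)
  ones <- matrix(1 + 0i, 60, 2000)
  expect_lt(abs(mean(plv(u, ones)) - sqrt(pi / 240)), 0.01)

  expect_error(plv(u[1, , drop = FALSE], ones[1, , drop = FALSE]),
               regexp = "2 trials")
  expect_error(plv(u, ones[, 1:10]), regexp = "grid")
})

test_that("ciPLV isolates lagged coupling and kills zero-lag locking", {
  # constant zero phase difference: exactly 0
  z <- matrix(exp(1i * 0.7) + 0i, 10, 3)
  expect_equal(max(abs(ciplv(z, z))), 0)

  # constant pi/2 difference: exactly 1
  x <- matrix(exp(1i * (pi / 2)) + 0i, 10, 3)
  o <- matrix(1 + 0i, 10, 3)
  expect_equal(as.vector(ciplv(x, o)), rep(1, 3), tolerance = 1e-12)

  # degenerate denominator |Re| = 1 is defined as 0
  expect_equal(max(abs(ciplv(o, o))), 0)

  # time-average mode returns one signed value per trial x scale
  # (phase difference is phi_x - phi_y, so a +pi/2 shift of y gives -1)
  arr <- array(exp(1i * runif(2 * 3 * 50)), c(2, 3, 50))
  out <- ciplv(arr, arr * exp(1i * pi / 2), over = "time")
  expect_equal(dim(out), c(2, 3))
  expect_equal(as.vector(out), rep(-1, 6), tolerance = 1e-12)

  # cell-wise ciPLV can never exceed cell-wise PLV
  set.seed(8)
  a <- matrix(exp(1i * runif(40 * 500, 0, 2 * pi)), 40, 500)
  b <- matrix(exp(1i * runif(40 * 500, 0, 2 * pi)), 40, 500)
  expect_true(all(abs(ciplv(a, b)) <= plv(a, b) + 1e-12))
})

test_that("band/window averaging honours the mask and matches a loop", {
  f <- morlet_freqs(4, 70)
  coi <- coi_mask(1, 1000, f)[, seq(1, 1001, by = 50)]
  vals <- matrix(0.5, length(f), ncol(coi))
  expect_equal(band_window_average(vals, f, "alpha", coi), 0.5)

  vals2 <- ifelse(coi, 0.2, 0.9)
  expect_equal(band_window_average(vals2, f, "alpha", coi), 0.2)

  set.seed(9)
  vals3 <- matrix(runif(length(f) * ncol(coi)), length(f))
  for (bname in c("theta", "alpha", "gamma", "global")) {
    b <- band_spec(bname)
    expect_equal(
      band_window_average(vals3, f, b, coi),
      band_mean_loop(vals3, f, b$low_hz, b$high_hz, coi, b$closed_top),
      tolerance = 1e-12)
  }

  expect_error(band_window_average(vals3, f, "alpha", coi & FALSE),
               class = "plvnet_band_invalid")
})

test_that("band edges are half-open with a closed 70 Hz ceiling", {
  f <- c(4, 7.99, 8, 12.99, 13, 30, 69.9, 70)
  expect_equal(plvnet:::band_members(f, band_spec("theta")),
               c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(plvnet:::band_members(f, band_spec("gamma")),
               c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_true(all(plvnet:::band_members(f, band_spec("global"))))
})

test_that("connectivity matrices are symmetric, bounded and consistent", {
  cfg <- synthetic_config(
    n_subjects = 1, n_channels = 5, n_trials = 30, seed = 17,
    couplings = list(coupling_spec(c(2, 4), c(8, 13), kappa_pre = 0,
                                   kappa_post = 50, amplitude = 3)))
  rec <- generate_cohort(cfg)[[1]]
  mats <- connectivity_matrices(rec, estimators = c("plv", "ciplv"))
  for (m in mats) {
    expect_identical(m$weights, t(m$weights))
    expect_true(all(diag(m$weights) == 0))
    off <- m$weights[upper.tri(m$weights)]
    expect_true(all(off >= 0 & off <= 1))
  }
  # the coupled pair dominates its own band post-stimulus
  alpha <- mats[["poststimulus.alpha.plv"]]$weights
  expect_equal(which.max(alpha[upper.tri(alpha)]),
               which(upper.tri(alpha), arr.ind = TRUE) |>
                 (\(ix) which(ix[, 1] == 2 & ix[, 2] == 4))())
})

test_that("duplicated channels give unit PLV", {
  set.seed(18)
  x <- matrix(rnorm(400 * 10), 400, 10)
  rec <- rec_from_signals(list(x, x), onset = 200)
  m <- build_connectivity(rec, analysis_window("seg", span_ms = c(-100, 100)),
                          "global", "plv")
  expect_equal(m$weights[1, 2], 1, tolerance = 1e-9)
})

test_that("the compiled path equals the reference path exactly", {
  cfg <- synthetic_config(
    n_subjects = 1, n_channels = 4, n_trials = 12, seed = 19,
    couplings = list(coupling_spec(c(1, 3), c(13, 19), kappa_post = 8)))
  rec <- generate_cohort(cfg)[[1]]
  f <- morlet_freqs(4, 70)
  for (w in c("prestimulus", "poststimulus")) {
    for (est in c("plv", "ciplv")) {
      fast <- build_connectivity(rec, w, "global", est, engine = "fast",
                                 freqs_hz = f)
      ref <- build_connectivity(rec, w, "global", est, engine = "reference",
                                freqs_hz = f)
      expect_lt(max(abs(fast$weights - ref$weights)), 1e-10)
    }
  }
  # stride = 1 reproduces the full-COI-grid band average
  s1 <- build_connectivity(rec, "poststimulus", "alpha", "plv",
                           freqs_hz = f, stride = 1)
  sp <- cwt(rec, "poststimulus", f)
  field <- plv(sp$coeffs[1, , , ], sp$coeffs[2, , , ])
  expect_equal(s1$weights[1, 2],
               band_window_average(field, f, "alpha", sp$coi),
               tolerance = 1e-10)
})

test_that("delta is excluded by the response window but not the baseline", {
  cfg <- synthetic_config(n_subjects = 1, n_channels = 3, n_trials = 8,
                          seed = 23)
  rec <- generate_cohort(cfg)[[1]]
  f <- morlet_freqs(1, 8)
  expect_error(build_connectivity(rec, "poststimulus", "delta", "plv",
                                  freqs_hz = f),
               class = "plvnet_band_invalid")
  m <- build_connectivity(rec, "prestimulus", "delta", "plv", freqs_hz = f)
  expect_true(all(is.finite(m$weights)))
})
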