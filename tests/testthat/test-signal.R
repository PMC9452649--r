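test_that("constant input is removed by the band-pass (DC outside band)", {
  n <- 2000
  tr <- accel_trace(rep(0.7, n), rep(-0.2, n), rep(1, n), 100)
  f <- bandpass_filter(tr)
  expect_lt(max(abs(colMeans(f[, c("ax_g", "ay_g", "az_g")]))), 1e-6)
  expect_lt(max(abs(f$az_g)), 1e-6)
})

test_that("pass-band and stop-band sine amplitudes match the analytic response", {
  fs <- 100; n <- 60 * fs
  t <- (seq_len(n) - 1) / fs
  steady <- function(freq) {
    tr <- accel_trace(sin(2 * pi * freq * t), numeric(n), rep(1, n), fs)
    filt <- bandpass_filter(tr)
    max(abs(filt$ax_g[2000:(n - 2000)]))
  }
  # zero-phase filtering applies the magnitude response twice
  expect_equal(steady(1), 1, tolerance = 0.02)
  expect_lt(steady(40), 0.05)
  expect_lt(steady(40),
            butterworth_bandpass_response(40)^2 * 1.5)
})

test_that("implemented frequency response matches the closed-form Butterworth", {
  bf <- signal::butter(2, c(0.1, 15) / 50, type = "pass")
  f <- c(seq(0.01, 0.095, by = 0.005), seq(0.1, 49, by = 0.05))
  measured <- abs(signal::freqz(bf, 2 * pi * f / 100)$h)
  oracle <- butterworth_bandpass_response(f, 0.1, 15, 4, 100)
  expect_lt(max(abs(measured - oracle) / pmax(oracle, 1e-12)), 0.01)
})

test_that("filter rejects invalid cut-offs and too-short traces", {
  tr <- accel_trace(rnorm(500), rnorm(500), rnorm(500), 100)
  expect_error(bandpass_filter(tr, low = 0), "cut-offs")
  expect_error(bandpass_filter(tr, low = 20, high = 15), "cut-offs")
  expect_error(bandpass_filter(tr, high = 60), "cut-offs")
  short <- accel_trace(rnorm(10), rnorm(10), rnorm(10), 100)
  expect_error(bandpass_filter(short), "too short")
})

test_that("resultant magnitude follows the Euclidean norm", {
  tr <- accel_trace(c(3, 0, 1), c(4, 0, 1), c(0, 0, 1), 100)
  expect_equal(resultant_acceleration(tr), c(5, 0, sqrt(3)))
})

test_that("force conversion applies 9.81 x mass and epoch averaging", {
  mag <- rep(0.5, 300)  # 3 s at 100 Hz
  fs <- compute_force_series(mag, 80, 100, 1)
  expect_length(fs, 3)
  expect_equal(as.numeric(fs), rep(0.5 * 9.81 * 80, 3))  # 392.4 N
  expect_equal(as.numeric(compute_force_series(rep(0, 300), 80, 100)),
               rep(0, 3))
  # linear in mass
  expect_equal(as.numeric(compute_force_series(mag, 160, 100)),
               2 * as.numeric(fs))
  expect_error(compute_force_series(mag, 0, 100), "mass")
  # trailing partial epoch dropped
  expect_length(compute_force_series(rep(0.5, 350), 80, 100), 3)
})

test_that("session intensity and impulse follow the definition", {
  fs <- structure(rep(215, 100), epoch_length = 1,
                  class = "force_series")
  expect_equal(session_intensity(fs), 215)
  expect_equal(session_impulse(fs, duration_s = 5665),
               215 * 5665 / 1000)  # 1217.975 kN·s
  zero <- structure(rep(0, 10), epoch_length = 1,
                    class = "force_series")
  expect_equal(session_impulse(zero), 0)
  expect_error(session_intensity(structure(numeric(0),
                                           class = "force_series")),
               "empty")
})

test_that("impulse is additive over concatenated sessions", {
  set.seed(4)
  a <- structure(runif(60, 100, 300), epoch_length = 1,
                 class = "force_series")
  b <- structure(runif(40, 100, 300), epoch_length = 1,
                 class = "force_series")
  ab <- structure(c(unclass(a), unclass(b)), epoch_length = 1,
                  class = "force_series")
  expect_equal(session_impulse(ab), session_impulse(a) +
                 session_impulse(b))
  # impulse identity: intensity x duration exactly
  expect_identical(session_impulse(a),
                   session_intensity(a) * 60 / 1000)
})

test_that("scaling all axes scales AvF_NET linearly (post-filter)", {
  set.seed(9)
  n <- 6000
  ax <- 0.3 * sin(2 * pi * 2 * (seq_len(n) - 1) / 100) + rnorm(n, 0, 0.02)
  tr1 <- accel_trace(ax, rnorm(n, 0, 0.02), 1 + rnorm(n, 0, 0.02), 100)
  tr3 <- accel_trace(3 * tr1$ax_g, 3 * tr1$ay_g, 3 * tr1$az_g, 100)
  f1 <- trace_to_force(tr1, 80)
  f3 <- trace_to_force(tr3, 80)
  expect_equal(session_intensity(f3), 3 * session_intensity(f1),
               tolerance = 1e-10)
})
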