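test_that("artifact blanking flattens the spike and touches nothing else", {
  p <- fast_params()
  rec <- generate_recording(p, "control", "s", seed = 3)
  out <- remove_stimulus_artifact(rec, c(2, 10))
  t_ms <- (seq_along(rec$samples) - 1L) / rec$fs * 1000 - rec$stim_time_ms

  inside <- t_ms >= -2 & t_ms < 10
  adjacent <- (t_ms >= -12 & t_ms < -2) | (t_ms >= 10 & t_ms < 20)
  expect_lte(max(abs(out$samples[inside])), max(abs(out$samples[adjacent])))
  # locality: outside a one-sample margin of the window, output == input
  outside <- t_ms < -2 - 1000 / rec$fs | t_ms >= 10 + 1000 / rec$fs
  expect_identical(out$samples[outside], rec$samples[outside])
  expect_length(out$samples, length(rec$samples))
})

test_that("artifact blanking refuses windows past the trace end", {
  rec <- recording(sin(1:100), fs = 1000, stim_time_ms = 95,
                   condition = "control", slice_id = "s")
  expect_error(remove_stimulus_artifact(rec, c(2, 10)), "past the trace")
})

test_that("resampling decimates with correct length and passband fidelity", {
  # 50,000 samples at 100 kHz (500 ms) -> 1,000 samples at 2 kHz
  rec <- recording(numeric(50000) + 1e-9, fs = 1e5, stim_time_ms = 10,
                   condition = "control", slice_id = "s")
  out <- resample_signal(rec, 2000)
  expect_length(out$samples, 1000)
  expect_equal(out$fs, 2000)
  expect_equal(out$stim_time_ms, 10)

  # 60 Hz unit sine survives with amplitude within [0.98, 1.02]
  s <- recording(make_sine(60, fs = 1e5, n = 1e5), fs = 1e5, stim_time_ms = 1,
                 condition = "control", slice_id = "s")
  out <- resample_signal(s, 2000)
  mid <- out$samples[500:1500]
  expect_gt(max(mid), 0.98); expect_lt(max(mid), 1.02)

  # 900 Hz (above the 800 Hz anti-alias corner) is crushed below 5 % RMS
  h <- recording(make_sine(900, fs = 1e5, n = 1e5), fs = 1e5, stim_time_ms = 1,
                 condition = "control", slice_id = "s")
  out <- resample_signal(h, 2000)
  expect_lt(sqrt(mean(out$samples^2)) / sqrt(mean(h$samples^2)), 0.05)

  expect_error(resample_signal(s, 1500), "integer multiple")
})

test_that("piecewise detrend zeroes lines and preserves oscillations", {
  fs <- 2000
  tt <- (0:999) / fs * 1000
  mk <- function(x) recording(x, fs, 1, "control", "s")

  # a pure ramp is its own trend -> all-zero residual
  out <- piecewise_detrend(mk(3 + 0.25 * tt), 100)
  expect_lt(max(abs(out$samples)), 1e-9 * max(abs(3 + 0.25 * tt)))
  # constant trace -> zero
  out <- piecewise_detrend(mk(rep(42, 1000)), 100)
  expect_lt(max(abs(out$samples)), 1e-9)

  # every piece has zero mean and zero LS slope
  set.seed(5)
  out <- piecewise_detrend(mk(rnorm(1000)), 100)
  knots <- out$meta$detrend_knots_ms
  starts <- as.integer(round(knots / 1000 * fs)) + 1L
  ends <- c(starts[-1L] - 1L, 1000L)
  for (i in seq_along(starts)) {
    piece <- out$samples[starts[i]:ends[i]]
    tc <- seq_along(piece) - mean(seq_along(piece))
    expect_lt(abs(mean(piece)), 1e-9)
    expect_lt(abs(sum(tc * piece) / sum(tc^2)), 1e-9)
  }

  # ramp + 60 Hz sine: residual recovers the sine (r > 0.99)
  sine <- make_sine(60, fs, 1000)
  out <- piecewise_detrend(mk(5 + 0.1 * tt + sine), 100)
  expect_gt(stats::cor(out$samples, sine), 0.99)

  expect_error(piecewise_detrend(mk(sine), 0.4), "at least 2 samples")
})

test_that("band-pass has unit mid-band gain, kills stopband and DC", {
  fs <- 2000
  mk <- function(x) recording(x, fs, 1, "control", "s")
  s60 <- make_sine(60, fs, 4000)
  out <- bandpass_filter(mk(s60), 30, 300)
  amp <- max(out$samples[1000:3000])
  expect_gt(amp, 0.95); expect_lt(amp, 1.05)

  s5 <- make_sine(5, fs, 4000)
  out <- bandpass_filter(mk(s5), 30, 300)
  expect_lt(sqrt(mean(out$samples^2)) / sqrt(mean(s5^2)), 0.1)

  out <- bandpass_filter(mk(rep(100, 4000)), 30, 300)
  expect_lt(mean(abs(out$samples)), 1)

  # zero phase: band-limited probe peaks at lag 0
  probe <- make_sine(80, fs, 4000) * exp(-((0:3999) - 2000)^2 / (2 * 300^2))
  out <- bandpass_filter(mk(probe), 30, 300)
  cc <- stats::ccf(out$samples, probe, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(bandpass_filter(mk(s60), 30, 1200), "Nyquist")
  expect_error(bandpass_filter(mk(s60), 300, 30), "low < high")
})

test_that("the full chain runs in order and reports provenance", {
  rec <- generate_recording(synth_params(), "control", "s", seed = 2)
  pp <- preprocess(rec, pipeline_config())
  expect_equal(pp$recording$fs, 2000)
  expect_equal(pp$report$decimation_factor, 50L)
  expect_match(pp$report$filter_description, "30")
  expect_match(pp$report$filter_description, "300")
  expect_length(pp$recording$samples, round(duration_ms(rec) / 1000 * 2000))

  # approximate idempotence: a second pass changes RMS by < 2 %
  second <- preprocess(pp$recording, pipeline_config())
  r1 <- sqrt(mean(pp$recording$samples^2))
  r2 <- sqrt(mean(second$recording$samples^2))
  expect_lt(abs(r2 - r1) / r1, 0.02)
})

test_that("detrending does not eat gamma-band energy", {
  cfg <- pipeline_config()
  for (seed in c(4, 9)) {
    rec <- generate_recording(fast_params(), "control", "s", seed = seed)
    r2 <- resample_signal(remove_stimulus_artifact(rec, cfg$artifact_blank_ms),
                          cfg$target_fs)
    band_energy <- function(r) {
      f <- bandpass_filter(r, 30, 300)
      sum(f$samples^2)
    }
    e_before <- band_energy(r2)
    e_after <- band_energy(piecewise_detrend(r2, cfg$detrend_breakpoint_ms))
    expect_lt(abs(e_after - e_before) / e_before, 0.05)
  }
})
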