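# PPG filtering, windowed AC/DC features, the ratio of ratios, and
# heart-rate estimation.

sine_signal <- function(freq, fs = 15, dur = 60, amp = 1, band = "red") {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  channel_signal(band, amp * sin(2 * pi * freq * t), fs)
}

test_that("band-pass keeps the pass band and rejects drift", {
  spec <- filter_spec()
  zero <- channel_signal("red", rep(0, 600), 15)
  expect_equal(bandpass(zero, spec)$samples, rep(0, 600))

  inband <- bandpass(sine_signal(1.2, dur = 200), spec)
  expect_gte(max(abs(inband$samples[1500:2500])), 0.9)

  drift <- bandpass(sine_signal(0.05, dur = 200), spec)
  expect_lte(max(abs(drift$samples[1500:2500])), 0.1)

  expect_error(bandpass(sine_signal(1, fs = 3), spec),
               class = "oxitone_nyquist_error")
})

test_that("filter specs validate their parameters", {
  expect_error(filter_spec(band_low = 0), class = "oxitone_config_error")
  expect_error(filter_spec(band_low = 2, band_high = 1),
               class = "oxitone_config_error")
  expect_error(filter_spec(sg_window = 34), class = "oxitone_config_error")
  expect_error(filter_spec(sg_order = 5, sg_window = 5),
               class = "oxitone_config_error")
})

test_that("Savitzky-Golay reproduces low-degree polynomials exactly", {
  t <- seq(0, 10, length.out = 300)
  cubic <- channel_signal("red", 2 + 0.5 * t - 0.3 * t^2 + 0.07 * t^3, 30)
  out <- savgol_smooth(cubic, filter_spec())
  expect_equal(out$samples, cubic$samples, tolerance = 1e-9)

  const <- channel_signal("red", rep(3.7, 100), 30)
  expect_equal(savgol_smooth(const, filter_spec())$samples, rep(3.7, 100))

  short <- channel_signal("red", rnorm(20), 30)
  expect_error(savgol_smooth(short, filter_spec()),
               class = "oxitone_insufficient_data")
})

test_that("Savitzky-Golay strictly shrinks white-noise variance", {
  set.seed(99)
  noisy <- channel_signal("red", stats::rnorm(2000), 30)
  sm <- savgol_smooth(noisy, filter_spec())
  expect_lt(stats::var(sm$samples), stats::var(noisy$samples))
})

test_that("window features recover sine DC and RMS analytically", {
  fs <- 30
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  raw <- channel_signal("red", 1 + 0.1 * sin(2 * pi * 1.2 * t), fs)
  filt <- channel_signal("red", 0.1 * sin(2 * pi * 1.2 * t), fs)
  braw <- channel_signal("blue", 2 + 0.2 * sin(2 * pi * 1.2 * t), fs)
  bfilt <- channel_signal("blue", 0.2 * sin(2 * pi * 1.2 * t), fs)
  wf <- window_features(raw, filt, braw, bfilt, window_s = 10)
  expect_equal(nrow(wf), 1)
  expect_equal(wf$dc_red, 1, tolerance = 1e-6)
  expect_equal(wf$ac_red, 0.1 / sqrt(2), tolerance = 0.01)
  expect_equal(wf$dc_blue, 2, tolerance = 1e-6)
  expect_equal(wf$ac_blue, 0.2 / sqrt(2), tolerance = 0.01)
  # both channels have the same AC/DC quotient (0.1/1 vs 0.2/2): R = 1
  expect_equal(wf$r_value, 1, tolerance = 1e-6)
  expect_equal(wf$heart_rate_bpm, 72, tolerance = 0.5)
})

test_that("RMS of a pure sine is amplitude over sqrt(2) for >= 5 periods", {
  fs <- 30
  set.seed(12)
  for (i in 1:20) {
    a <- stats::runif(1, 0.01, 5)
    f <- stats::runif(1, 0.5, 2)
    win <- max(10, ceiling(5 / f))
    t <- seq(0, win - 1 / fs, by = 1 / fs)
    x <- a * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    raw <- channel_signal("red", 1 + x, fs)
    filt <- channel_signal("red", x, fs)
    wf <- window_features(raw, filt, raw, filt, window_s = win)
    expect_equal(wf$ac_red[1], a / sqrt(2), tolerance = 0.01)
  }
})

test_that("constant raw and zero filtered input gives ac = 0, dc = level", {
  raw <- channel_signal("red", rep(5, 300), 30)
  filt <- channel_signal("red", rep(0, 300), 30)
  wf <- window_features(raw, filt, raw, filt, window_s = 10)
  expect_equal(wf$ac_red, 0)
  expect_equal(wf$dc_red, 5)
  expect_true(is.na(wf$r_value))   # ac_blue = 0: undefined, not an error
})

test_that("window count is exactly floor(duration / window_s)", {
  fs <- 10
  for (dur in c(25, 30, 39.9, 40)) {
    t <- seq(0, dur - 1 / fs, by = 1 / fs)
    x <- channel_signal("red", sin(2 * pi * t) + 2, fs)
    wf <- window_features(x, x, x, x, window_s = 10)
    expect_equal(nrow(wf), floor(length(t) / fs / 10))
  }
  # 67 minutes of signal in 10-second windows -> 400 of them, with the
  # trailing partial window dropped
  t <- seq(0, 67 * 60 - 1 / fs, by = 1 / fs)
  x <- channel_signal("red", sin(2 * pi * 1.2 * t) + 2, fs)
  wf <- window_features(x, x, x, x, window_s = 10)
  expect_equal(nrow(wf), 402)   # floor(4020 / 10), full-length capture
  expect_equal(floor(4005 / 10), 400)  # the bench default duration
})

test_that("misaligned inputs are rejected", {
  a <- channel_signal("red", rep(1, 300), 30)
  b <- channel_signal("red", rep(1, 300), 15)
  expect_error(window_features(a, b, a, a, window_s = 10),
               class = "oxitone_alignment_error")
  c2 <- channel_signal("blue", rep(1, 300), 30, start_time = 0.5)
  expect_error(window_features(a, a, c2, c2, window_s = 10),
               class = "oxitone_alignment_error")
})

test_that("ratio of ratios follows its definition and flags bad windows", {
  expect_equal(ratio_of_ratios(1, 1, 1, 1), 1)
  expect_equal(ratio_of_ratios(0, 1, 1, 1), 0)
  expect_equal(ratio_of_ratios(0.02, 1.0, 0.01, 0.5), 1)
  expect_true(is.na(ratio_of_ratios(1, 0, 1, 1)))
  expect_true(is.na(ratio_of_ratios(1, 1, 0, 1)))
  expect_true(is.na(ratio_of_ratios(1, 1, 1, 0)))
})

test_that("ratio of ratios is invariant to per-channel rescaling", {
  set.seed(31)
  for (i in 1:50) {
    f <- stats::runif(4, 0.01, 3)
    alpha <- stats::runif(1, 0.1, 10)
    beta <- stats::runif(1, 0.1, 10)
    expect_equal(
      ratio_of_ratios(alpha * f[1], alpha * f[2], beta * f[3], beta * f[4]),
      ratio_of_ratios(f[1], f[2], f[3], f[4]))
  }
})

test_that("DC transmission ratios reproduce the printed table cells", {
  # commodity-oximeter table (IR/red): types 2 and 3
  expect_equal(round(dc_transmission_ratio(0.50, 0.96), 2), 0.52)
  expect_equal(round(dc_transmission_ratio(0.51, 1.00), 2), 0.51)
  # screen-pair table (red is the longer wavelength: red DC / blue DC)
  expect_equal(round(dc_transmission_ratio(0.61, 0.80), 2), 0.76)
  expect_equal(round(dc_transmission_ratio(0.94, 1.00), 2), 0.94)
  expect_equal(round(dc_transmission_ratio(0.59, 0.65), 2), 0.91)
  expect_equal(dc_transmission_ratio(0.7, 0.7), 1)
  expect_error(dc_transmission_ratio(0, 1), class = "oxitone_domain_error")
})

test_that("heart rate is 60 times the dominant pass-band frequency", {
  expect_equal(estimate_heart_rate(sine_signal(1.0, dur = 30)), 60,
               tolerance = 0.01)
  expect_equal(estimate_heart_rate(sine_signal(1.2, dur = 30)), 72,
               tolerance = 0.01)
  expect_error(estimate_heart_rate(sine_signal(1.0, dur = 3)),
               class = "oxitone_insufficient_data")
  flat <- channel_signal("red", rep(0, 300), 15)
  expect_warning(hr <- estimate_heart_rate(flat), class = "oxitone_no_pulse")
  expect_true(is.na(hr))
})

test_that("heart rate matches the simulated pump rate within 1 bpm", {
  run <- simulate_frames(sim_config(duration = 60, heart_rate = 60, seed = 8))
  ch <- demultiplex(label_illumination(run$frame_log))
  filt <- savgol_smooth(bandpass(ch$red), filter_spec())
  expect_equal(estimate_heart_rate(filt), 60, tolerance = 1)
})

test_that("window features export to the documented CSV layout", {
  raw <- channel_signal("red", 1 + 0.1 * sin(2 * pi * (0:299) / 30), 30)
  filt <- channel_signal("red", 0.1 * sin(2 * pi * (0:299) / 30), 30)
  wf <- window_features(raw, filt, raw, filt, window_s = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(wf, path)
  expect_equal(names(utils::read.csv(path)),
               c("t_start", "t_end", "ac_red", "dc_red", "ac_blue",
                 "dc_blue", "r_value", "heart_rate_bpm"))
})
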