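# The Beer-Lambert forward simulator: pulse waveform, transmitted
# intensities, frame simulation, the ex vivo bench run, and the
# reference-strip image fixtures.

test_that("the pulse waveform is normalized, periodic, and band-correct", {
  t <- seq(0, 10, by = 0.001)
  w <- pulse_waveform(t, 72)
  expect_equal(max(w), 1, tolerance = 1e-6)
  expect_equal(min(w), 0)
  expect_equal(pulse_waveform(t, 72), pulse_waveform(t + 60 / 72, 72),
               tolerance = 1e-9)
  # fundamental frequency by FFT oracle: 72 bpm -> 1.2 Hz
  fs <- 100
  tt <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- pulse_waveform(tt, 72)
  x <- x - mean(x)
  spec <- (Mod(stats::fft(x))^2)[seq_len(length(x) / 2)]
  f_peak <- (which.max(spec) - 1) * fs / length(x)
  expect_equal(f_peak, 1.2, tolerance = 0.05)
})

test_that("transmitted intensity follows the modified Beer-Lambert law", {
  const <- optical_constants()
  cfg <- sim_config(tone_class = 1, concentration = 0, duration = 10)
  # no absorber, class-1 tone attenuation is zero -> the source intensity
  expect_equal(transmitted_intensity("red", 0.9, cfg, const, t = 0.3),
               cfg$source_intensity[[1]])

  # doubling concentration * path squares the transmission fraction
  c1 <- sim_config(concentration = 1, duration = 10, tone_class = 1)
  c2 <- sim_config(concentration = 2, duration = 10, tone_class = 1)
  for (band in c("red", "blue", "ir")) {
    t1 <- transmitted_intensity(band, 0.8, c1, const, 0.2) / 200
    t2 <- transmitted_intensity(band, 0.8, c2, const, 0.2) / 200
    expect_equal(t2, t1^2, tolerance = 1e-12)
  }

  # deoxygenation: red transmission falls with s, blue rises
  cfg3 <- sim_config(duration = 10)
  expect_lt(transmitted_intensity("red", 0.75, cfg3, const),
            transmitted_intensity("red", 0.95, cfg3, const))
  expect_gt(transmitted_intensity("blue", 0.75, cfg3, const),
            transmitted_intensity("blue", 0.95, cfg3, const))
})

test_that("optical constants enforce their spectral constraints", {
  expect_error(optical_constants(
    extinction = rbind(red = c(Hb = 0.2, HbO2 = 0.5),
                       blue = c(Hb = 0.3, HbO2 = 0.55),
                       ir = c(Hb = 0.28, HbO2 = 0.33))),
    class = "oxitone_config_error")
  expect_error(optical_constants(
    tone_attenuation = outer(c(0, 2, 1, 3, 4, 5),
                             c(red = 0.07, blue = 0.13, ir = 0.04))),
    class = "oxitone_config_error")
})

test_that("frame simulation is seed-deterministic and duration-exact", {
  cfg <- sim_config(duration = 15, mixed_frame_prob = 0.05, seed = 33)
  a <- simulate_frames(cfg)
  b <- simulate_frames(cfg)
  expect_identical(a$frame_log, b$frame_log)
  expect_identical(a$truth$mixed_indices, b$truth$mixed_indices)
  expect_equal(nrow(a$frame_log), 15 * 30)

  empty <- simulate_frames(sim_config(duration = 0))
  expect_equal(nrow(empty$frame_log), 0)
})

test_that("pipeline DC matches the analytic window average at zero noise", {
  cfg <- sim_config(duration = 65, noise_sd = 0, seed = 2)
  run <- simulate_frames(cfg)
  res <- process_run(run$frame_log, run_config(model = NULL))
  const <- optical_constants()
  for (j in seq_len(nrow(res$windows))) {
    t <- seq(res$windows$t_start[j], res$windows$t_end[j], by = 0.001)
    for (side in c("red", "blue")) {
      shunt <- const$shunt_frac[match(side, c("red", "blue"))] *
        cfg$source_intensity[[match(side, c("red", "blue"))]]
      analytic <- mean(transmitted_intensity(side, cfg$spo2(t), cfg,
                                             const, t)) + shunt
      measured <- res$windows[[paste0("dc_", side)]][j]
      expect_lt(abs(measured - analytic) / analytic, 0.005)
    }
  }
})

test_that("the ex vivo bench run yields 400 monotone-truth windows", {
  run <- simulate_ex_vivo_run(config = sim_config(duration = 4005,
                                                  heart_rate = 60, seed = 3))
  expect_equal(length(run$truth$spo2_percent), 400)
  expect_true(all(diff(run$truth$spo2_percent) <= 0))
  expect_equal(run$truth$spo2_percent[1], 95, tolerance = 0.1)
  expect_equal(run$truth$spo2_percent[400], 75, tolerance = 0.2)
  expect_error(simulate_ex_vivo_run(spo2_start = 75, spo2_end = 95),
               class = "oxitone_config_error")
})

test_that("R is strictly monotone in SpO2 at zero noise", {
  svals <- seq(0.70, 1.00, by = 0.05)
  rvals <- vapply(svals, function(s) {
    run <- simulate_frames(sim_config(spo2 = s, duration = 35,
                                      noise_sd = 0, seed = 1))
    res <- process_run(run$frame_log, run_config(model = NULL))
    mean(res$windows$r_value)
  }, numeric(1))
  expect_true(all(diff(rvals) < 0) || all(diff(rvals) > 0))
})

test_that("skin tone shifts R itself at fixed SpO2, not just amplitude", {
  mean_r <- function(tone) {
    run <- simulate_frames(sim_config(spo2 = 0.9, tone_class = tone,
                                      duration = 65, noise_sd = 0, seed = 4))
    mean(process_run(run$frame_log, run_config(model = NULL))$windows$r_value)
  }
  r2 <- mean_r(2)
  r5 <- mean_r(5)
  gap <- 100 * abs(r5 - r2) / max(r5, r2)
  expect_gt(gap, 1)
  expect_lt(gap, 18)
})

test_that("strip-image fixtures close the classification loop", {
  clean <- make_reference_strip_image(4, noise_sd = 0)
  patch <- mean_rgb(clean$image, clean$regions$skin)
  res <- classify_tone(patch)
  expect_equal(res$fitzpatrick_class, 4)
  expect_equal(res$distances[4], 0)

  for (cls in c(2, 3, 5)) {
    fix <- make_reference_strip_image(cls, noise_sd = 3, seed = 7)
    got <- classify_tone(mean_rgb(fix$image, fix$regions$skin))
    expect_equal(got$fitzpatrick_class, cls)
  }

  a <- make_reference_strip_image(3, noise_sd = 5, seed = 10)
  b <- make_reference_strip_image(3, noise_sd = 5, seed = 10)
  expect_identical(a$image, b$image)
})

test_that("strip images survive a PPM round trip", {
  fix <- make_reference_strip_image(5, noise_sd = 0)
  path <- withr::local_tempfile(fileext = ".ppm")
  write_ppm(fix$image, path)
  back <- read_ppm(path)
  expect_equal(dim(back), dim(fix$image))
  expect_true(max(abs(back - round(fix$image))) < 1e-9)
  expect_equal(classify_tone(mean_rgb(back, fix$regions$skin))$fitzpatrick_class,
               5)
})
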