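test_that("MTI reduces a static scene to numerical zero", {
  cfg <- tiny_config()
  cube <- simulate_if_cube(cfg, slow_time_series(numeric(80), cfg$slow_rate,
                                                 "mm"),
                           statics = list(static_reflector(1.1)),
                           baseline_range = 0.5)
  out <- mti_filter(cube, 20)
  res_var <- max(apply(out$data, c(2, 3), stats::var))
  expect_lt(res_var, 1e-10 * mean(cube$data^2))
})

test_that("MTI matches the brute-force windowed mean-subtract-average oracle", {
  x <- c(1, 1, 5, 1, 1)
  win <- 2
  ## independent loop oracle
  res <- numeric(5); cnt <- integer(5)
  for (w in 1:(5 - win + 1)) {
    idx <- w:(w + win - 1)
    mu <- mean(x[idx])
    for (i in idx) { res[i] <- res[i] + (x[i] - mu); cnt[i] <- cnt[i] + 1 }
  }
  oracle <- res / cnt
  cube <- as_cube(array(x, c(5, 1, 1)), tiny_config())
  expect_equal(as.vector(mti_filter(cube, 2)$data), oracle)

  ## a longer random case against the same oracle
  set.seed(1)
  y <- rnorm(40)
  win <- 7
  res <- numeric(40); cnt <- integer(40)
  for (w in 1:(40 - win + 1)) {
    idx <- w:(w + win - 1)
    mu <- mean(y[idx])
    for (i in idx) { res[i] <- res[i] + (y[i] - mu); cnt[i] <- cnt[i] + 1 }
  }
  cube <- as_cube(array(y, c(40, 1, 1)), tiny_config())
  expect_equal(as.vector(mti_filter(cube, win)$data), res / cnt,
               tolerance = 1e-12)
})

test_that("MTI preserves moving-target energy and is idempotent on statics", {
  cfg <- tiny_config()
  m <- displacement_model(noise_sd = 0)
  d <- make_displacement(m, 20, cfg$slow_rate, seed = 1)
  cube <- simulate_if_cube(cfg, d, baseline_range = 0.5)
  zm <- sweep(cube$data, c(2, 3), apply(cube$data, c(2, 3), mean))
  out <- mti_filter(cube, 100)
  expect_gt(cor(as.vector(out$data), as.vector(zm)), 0.99)

  ## second MTI pass changes a static-only residual negligibly
  st <- simulate_if_cube(cfg, slow_time_series(numeric(60), cfg$slow_rate,
                                               "mm"),
                         statics = list(static_reflector(0.9)),
                         baseline_range = 0.45)
  once <- mti_filter(st, 20)
  twice <- mti_filter(once, 20)
  expect_lt(sum((twice$data - once$data)^2),
            1e-6 * mean(st$data^2) * length(st$data))
  expect_error(mti_filter(st, 100), "window_n")
})

test_that("range FFT puts a target at the closed-form bin", {
  cfg <- tiny_config()
  R <- 0.8
  d <- slow_time_series(numeric(30), cfg$slow_rate, "mm")
  cube <- simulate_if_cube(cfg, d, baseline_range = R)
  stack <- range_fft(cube)
  f_if <- 2 * cfg$freq_slope * R / 299792458
  expected_bin <- round(f_if / cfg$adc_rate * cfg$samples_per_chirp) + 1
  got <- which.max(colMeans(abs(stack$spectra)))
  expect_lte(abs(got - expected_bin), 1)
  expect_equal(stack$bin_scale,
               299792458 * cfg$adc_rate / cfg$samples_per_chirp /
                 (2 * cfg$freq_slope))
  ## zero cube -> zero spectra
  z <- as_cube(array(0, dim(cube$data)), cfg)
  expect_true(all(Mod(range_fft(z)$spectra) == 0))
})

test_that("two separated reflectors yield two distinct range peaks", {
  cfg <- tiny_config()
  cube <- simulate_if_cube(cfg, NULL,
                           statics = list(static_reflector(0.6),
                                          static_reflector(1.6, 0.8)))
  mag <- colMeans(abs(range_fft(cube)$spectra))
  loc <- which(diff(sign(diff(mag))) == -2) + 1
  top2 <- sort(loc[order(mag[loc], decreasing = TRUE)][1:2])
  r_at <- (top2 - 1) * range_fft(cube)$bin_scale
  expect_equal(r_at, c(0.6, 1.6), tolerance = 0.15)
})

test_that("target-bin selection flags low SNR on noise and static-after-MTI cubes", {
  cfg <- tiny_config()
  set.seed(2)
  noise <- as_cube(array(rnorm(60 * 2 * 256), c(60, 2, 256)), cfg)
  expect_warning(select_target_bin(range_fft(noise)), "low SNR")
  st <- simulate_if_cube(cfg, slow_time_series(numeric(60), cfg$slow_rate,
                                               "mm"),
                         statics = list(static_reflector(0.9)),
                         baseline_range = 0.45)
  expect_warning(select_target_bin(range_fft(mti_filter(st, 20))),
                 "low SNR")
  ## clean moving target: bin within 1 of closed form, no warning
  m <- displacement_model(noise_sd = 0)
  d <- make_displacement(m, 10, cfg$slow_rate, seed = 1)
  cube <- simulate_if_cube(cfg, d, baseline_range = 0.5)
  bin <- expect_silent(select_target_bin(range_fft(mti_filter(cube, 20))))
  f_if <- 2 * cfg$freq_slope * 0.5 / 299792458
  expect_lte(abs(bin - (round(f_if / cfg$adc_rate *
                                cfg$samples_per_chirp) + 1)), 1)
})

test_that("extracted phase follows 4*pi*R/lambda", {
  cfg <- tiny_config()
  st <- simulate_if_cube(cfg, slow_time_series(numeric(40), cfg$slow_rate,
                                               "mm"),
                         baseline_range = 0.5, complex_iq = TRUE)
  stack <- range_fft(st)
  bin <- which.max(colMeans(abs(stack$spectra)))
  ph <- extract_phase(stack, bin)
  ## static target: constant phase
  expect_lt(diff(range(ph$values)), 1e-9)
  expect_true(all(ph$values > -pi & ph$values <= pi))
})

test_that("a 0.1 mm step at 77 GHz shifts the IF phase by about 18 degrees", {
  cfg <- radar_profile("analytic")
  ex <- if_sensitivity_experiment(cfg, range0 = 0.5, delta_m = 1e-4)
  th <- if_sensitivity_theory(cfg, 1e-4)
  expect_equal(th$phase_shift_deg, 18.49, tolerance = 0.001)
  expect_equal(ex$phase_shift_deg, th$phase_shift_deg, tolerance = 0.02)
})

test_that("phase unwrapping restores ramps and leaves small steps alone", {
  rate <- 20
  ramp <- seq(0, 40, length.out = 200)
  wrapped <- slow_time_series(atan2(sin(ramp), cos(ramp)), rate, "rad")
  un <- unwrap_phase(wrapped)
  expect_equal(un$values, ramp, tolerance = 1e-9)
  small <- slow_time_series(0.5 * sin(seq(0, 6, length.out = 100)), rate,
                            "rad")
  expect_equal(unwrap_phase(small)$values, small$values)
})

test_that("a 6 mm peak-to-peak motion (beyond lambda/4) unwraps to 4*pi*d/lambda", {
  cfg <- tiny_config()
  m <- displacement_model(resp_amplitude = 3, resp_freq = 0.2,
                          heart_amplitude = 0, noise_sd = 0)
  d <- make_displacement(m, 20, cfg$slow_rate, seed = 1)
  cube <- simulate_if_cube(cfg, d, baseline_range = 0.5, complex_iq = TRUE)
  stack <- range_fft(cube)
  bin <- select_target_bin(range_fft(mti_filter(cube, 50)))
  ph <- unwrap_phase(extract_phase(stack, bin))
  ## the DFT phase at a fixed bin carries, besides 4*pi*R/lambda, the
  ## beat-frequency migration term 2*pi*df*(N-1)/(2*fs) of the range change
  ## (about B/(2*f_c), 2.6% here); the expected slope includes it
  scale <- 4 * pi / cfg$wavelength +
    2 * pi * (2 * cfg$freq_slope / 299792458) *
      (cfg$samples_per_chirp - 1) / (2 * cfg$adc_rate)
  expected <- scale * d$values / 1000
  expect_gt(diff(range(ph$values)), 2 * pi)  # really wrapped more than once
  expect_equal(ph$values - mean(ph$values), expected - mean(expected),
               tolerance = 1e-3)
})

test_that("phase converts to displacement as lambda * phi / (4 pi)", {
  lambda <- 299792458 / 77e9 # metres
  s <- slow_time_series(c(0, pi), 20, "rad")
  d <- phase_to_displacement(s, lambda)
  ## pi rad <-> lambda/4; mean removed so the step is the full information
  expect_equal(diff(d$values), lambda / 4 * 1000, tolerance = 1e-9)
  expect_equal(diff(d$values), 0.9733, tolerance = 1e-3)
  z <- phase_to_displacement(slow_time_series(numeric(10), 20, "rad"),
                             lambda)
  expect_true(all(z$values == 0))
})

test_that("the zero-phase Butterworth has the designed magnitude response", {
  s_dc <- slow_time_series(rep(2.5, 400), 20, "mm")
  expect_equal(lowpass(s_dc)$values, rep(2.5, 400), tolerance = 1e-6)

  ## single-pass -3 dB at the cutoff (filter-design identity), evaluating
  ## H(e^{jw}) = B(e^{-jw}) / A(e^{-jw}) directly
  bf <- signal::butter(4, 3.3 / 10, type = "low")
  w <- pi * 3.3 / 10
  ew <- exp(-1i * w * (seq_along(bf$b) - 1))
  H <- sum(bf$b * ew) / sum(bf$a * exp(-1i * w * (seq_along(bf$a) - 1)))
  expect_equal(20 * log10(Mod(H)), -3.01, tolerance = 0.1)

  ## an 8 Hz tone at 20 Hz sampling is strongly attenuated
  t <- (0:799) / 20
  tone <- slow_time_series(sin(2 * pi * 8 * t), 20, "mm")
  out <- lowpass(tone)
  mid <- 100:700
  atten <- 20 * log10(stats::sd(out$values[mid]) /
                        stats::sd(tone$values[mid]))
  expect_lt(atten, -30)
  expect_error(lowpass(slow_time_series(1:10, 5, "mm"), cutoff = 3.3),
               "Nyquist")
})

test_that("the whole radar chain recovers the chest displacement", {
  cfg <- tiny_config()
  m <- displacement_model(resp_amplitude = 4, resp_freq = 0.3,
                          heart_amplitude = 0.4, heart_freq = 1.3,
                          noise_sd = 0.05)
  d <- make_displacement(m, 30, cfg$slow_rate, seed = 3)
  cube <- simulate_if_cube(cfg, d, baseline_range = 0.5, seed = 4)
  rec <- extract_displacement(cube)
  truth <- lowpass(slow_time_series(d$values - mean(d$values), d$rate,
                                    "mm"))
  expect_gt(cor(rec$values, truth$values), 0.98)
  ## amplitude linearity: doubling displacement doubles the excursion.
  ## Amplitudes stay modest so the per-frame phase step is well below pi
  ## (the regime where Eq.-(7)-style linearity is claimed).
  m2 <- displacement_model(resp_amplitude = 3, resp_freq = 0.3,
                           heart_amplitude = 0.2, heart_freq = 1.3,
                           noise_sd = 0)
  d1 <- make_displacement(displacement_model(resp_amplitude = 1.5,
                                             resp_freq = 0.3,
                                             heart_amplitude = 0.2,
                                             heart_freq = 1.3,
                                             noise_sd = 0),
                          30, cfg$slow_rate, seed = 1)
  d2 <- make_displacement(m2, 30, cfg$slow_rate, seed = 1)
  ## I/Q cubes isolate the mathematical linearity of Eq-style phase
  ## extraction (a real mixer adds image-leakage distortion at large
  ## excursions)
  r1 <- extract_displacement(simulate_if_cube(cfg, d1, baseline_range = 0.5,
                                              complex_iq = TRUE))
  r2 <- extract_displacement(simulate_if_cube(cfg, d2, baseline_range = 0.5,
                                              complex_iq = TRUE))
  truth_ratio <- diff(range(lowpass(d2)$values)) /
    diff(range(lowpass(d1)$values))
  expect_equal(diff(range(r2$values)) / diff(range(r1$values)),
               truth_ratio, tolerance = 0.01)
  expect_gt(truth_ratio, 1.8)
})
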