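test_that("noiseless single-sinusoid displacement follows the closed form", {
  m <- displacement_model(resp_amplitude = 1, resp_freq = 0.25,
                          heart_amplitude = 0, noise_sd = 0)
  d <- make_displacement(m, duration = 4, rate = 100, seed = 1)
  expect_length(d$values, 400)
  t <- time_axis(d)
  expect_equal(d$values, sin(2 * pi * 0.25 * t), tolerance = 1e-12)
  expect_equal(t[which.max(d$values)], 1, tolerance = 0.02)
  expect_equal(max(d$values), 1, tolerance = 1e-3)
})

test_that("two-component displacement has FFT peaks at the model frequencies", {
  m <- displacement_model(resp_amplitude = 4, resp_freq = 0.3,
                          heart_amplitude = 0.3, heart_freq = 1.2,
                          heart_harmonics = list(), noise_sd = 0)
  d <- make_displacement(m, duration = 60, rate = 20, seed = 1)
  peaks <- sort(fft_peak_freqs(d, 2))
  expect_equal(peaks, c(0.3, 1.2), tolerance = 0.02)
})

test_that("displacement generation is seed-deterministic and validates Nyquist", {
  m <- displacement_model(noise_sd = 0.1)
  expect_identical(make_displacement(m, 10, 20, seed = 9)$values,
                   make_displacement(m, 10, 20, seed = 9)$values)
  expect_false(identical(make_displacement(m, 10, 20, seed = 1)$values,
                         make_displacement(m, 10, 20, seed = 2)$values))
  ## heart 1.2 Hz with 2x harmonic -> highest component 2.4 Hz
  expect_error(make_displacement(m, 10, rate = 4, seed = 1), "Nyquist")
})

test_that("displacement model enforces physiological invariants", {
  expect_error(displacement_model(resp_freq = 0.05), "resp_freq")
  expect_error(displacement_model(heart_freq = 4), "heart_freq")
  expect_error(displacement_model(resp_amplitude = 1, heart_amplitude = 2),
               "sub-mm")
})

test_that("a static-only cube is constant across slow time", {
  cfg <- tiny_config()
  st <- simulate_if_cube(cfg, NULL,
                         statics = list(static_reflector(0.8, 0.7)))
  base <- simulate_if_cube(cfg, slow_time_series(numeric(50), cfg$slow_rate,
                                                 "mm"),
                           statics = list(static_reflector(0.8, 0.7)),
                           baseline_range = 0.5)
  v <- apply(base$data, c(2, 3), stats::var)
  expect_lt(max(v), 1e-20)
  expect_equal(dim(st$data), c(1L, cfg$chirps_per_frame,
                               cfg$samples_per_chirp))
})

test_that("the simulator rejects a displacement at the wrong rate", {
  cfg <- tiny_config()
  d <- slow_time_series(numeric(100), 5, "mm")
  expect_error(simulate_if_cube(cfg, d), "frame rate")
})

test_that("cube amplitude scaling is linear and phase extraction invariant to it", {
  cfg <- tiny_config()
  m <- displacement_model(noise_sd = 0)
  d <- make_displacement(m, 10, cfg$slow_rate, seed = 1)
  cube <- simulate_if_cube(cfg, d, baseline_range = 0.5)
  cube2 <- as_cube(cube$data * 7.5, cfg)
  s1 <- range_fft(cube)
  s2 <- range_fft(cube2)
  bin <- select_target_bin(range_fft(mti_filter(cube, 20)))
  expect_equal(extract_phase(s1, bin)$values,
               extract_phase(s2, bin)$values, tolerance = 1e-12)
})

test_that("the four emotion presets are pairwise distinct and physiological", {
  ps <- emotion_presets()
  expect_named(ps, c("relaxed", "happy", "sad", "angry"))
  boxes <- lapply(ps, function(p) c(p$resp_freq, p$heart_freq))
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(isTRUE(all.equal(boxes[[i]], boxes[[j]])))
  for (p in ps) {
    expect_true(p$resp_freq[1] >= 0.1 && p$resp_freq[2] <= 0.6)
    expect_true(p$heart_freq[1] >= 0.8 && p$heart_freq[2] <= 3.3)
    expect_true(p$heart_amp[2] < p$resp_amp[1])
  }
})

test_that("face rendering is deterministic, jitter-free when asked, and preset-signed", {
  happy <- emotion_preset("happy")
  sad <- emotion_preset("sad")
  f1 <- render_face_frames(happy, n_frames = 11, size = 48, jitter = 0,
                           seed = 5)
  f2 <- render_face_frames(happy, n_frames = 11, size = 48, jitter = 0,
                           seed = 5)
  expect_identical(f1$frames, f2$frames)
  for (f in f1$frames[-1]) expect_identical(f, f1$frames[[1]])
  expect_error(render_face_frames(happy, n_frames = 5), "11")
  ## mouth curvature sign differs between happy and sad
  expect_gt(emotion_preset("happy")$face$mouth_curvature[1], 0)
  expect_lt(emotion_preset("sad")$face$mouth_curvature[2], 0)
  ## jittered frames differ
  fj <- render_face_frames(happy, n_frames = 11, size = 48, seed = 5)
  expect_false(identical(fj$frames[[1]], fj$frames[[2]]))
})

test_that("frames rendered at 227 px pass through keyframe resize unchanged", {
  clip <- render_face_frames(emotion_preset("relaxed"), n_frames = 11,
                             size = 227, jitter = 0, seed = 2)
  kf <- select_keyframes(clip, out_size = 227)
  expect_equal(dim(kf$images), c(1, 227, 227, 3))
  expect_equal(kf$images[1, , , ], clip$frames[[kf$source_indices[1]]],
               tolerance = 1e-12)
})

test_that("make_dataset is balanced, reproducible and in-box", {
  ds <- make_dataset(2, duration = 10, image_size = 24, n_keyframes = 2,
                     seed = 3)
  expect_length(ds$samples, 8)
  expect_equal(unname(table(ds$manifest$label)), rep(2L, 4),
               ignore_attr = TRUE)
  ds2 <- make_dataset(2, duration = 10, image_size = 24, n_keyframes = 2,
                      seed = 3)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$samples[[1]]$resp$values, ds2$samples[[1]]$resp$values)
  ds3 <- make_dataset(2, duration = 10, image_size = 24, n_keyframes = 2,
                      seed = 4)
  expect_false(identical(ds$samples[[1]]$resp$values,
                         ds3$samples[[1]]$resp$values))
  ps <- emotion_presets()
  for (i in seq_len(nrow(ds$manifest))) {
    p <- ps[[ds$manifest$label[i]]]
    expect_gte(ds$manifest$resp_freq_true[i], p$resp_freq[1])
    expect_lte(ds$manifest$resp_freq_true[i], p$resp_freq[2])
    expect_gte(ds$manifest$heart_freq_true[i], p$heart_freq[1])
    expect_lte(ds$manifest$heart_freq_true[i], p$heart_freq[2])
  }
})

test_that("cube container and raw int16 import round-trip", {
  cfg <- radar_config(chirps_per_frame = 2, samples_per_chirp = 32)
  m <- displacement_model(noise_sd = 0)
  d <- make_displacement(m, 1, cfg$slow_rate, seed = 1)
  cube <- simulate_if_cube(cfg, d, baseline_range = 0.4)
  path <- tempfile(fileext = ".cube")
  write_radar_cube(cube, path)
  back <- read_radar_cube(path)
  expect_equal(back$data, cube$data, tolerance = 1e-12)
  expect_equal(back$config$carrier_freq, cfg$carrier_freq)

  ## raw int16 stream, fast-time-major
  raw_path <- tempfile(fileext = ".bin")
  q <- round(aperm(cube$data, c(3, 2, 1)) * 2^15 / max(abs(cube$data)) / 2)
  con <- file(raw_path, "wb")
  writeBin(as.integer(q), con, size = 2, endian = "little")
  close(con)
  imp <- read_raw_int16(raw_path, cfg)
  expect_equal(dim(imp$data), dim(cube$data))
  expect_gt(cor(as.vector(imp$data), as.vector(cube$data)), 0.999)
})

test_that("slow-time series CSV round-trips with units and rate", {
  s <- slow_time_series(sin(1:50), 20, "mm")
  p <- tempfile(fileext = ".csv")
  write_series_csv(s, p)
  r <- read_series_csv(p)
  expect_equal(r$values, s$values, tolerance = 1e-6)
  expect_equal(r$rate, 20)
  expect_equal(r$units, "mm")
})
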