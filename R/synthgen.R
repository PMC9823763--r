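#' Generate a chest-displacement waveform
#'
#' Samples the parametric displacement model at the slow-time rate:
#' respiration sinusoid + heartbeat sinusoid (+ harmonics) + Gaussian noise.
#'
#' @param model A [displacement_model()].
#' @param duration Trial length in seconds.
#' @param rate Sampling rate in Hz; must be at least twice the highest
#'   harmonic frequency present in the model (Nyquist).
#' @param seed Integer seed; the series is bit-reproducible per seed.
#' @return A [slow_time_series()] in mm of length `round(duration * rate)`.
#' @export
make_displacement <- function(model, duration = 60, rate = 20, seed = 1) {
  stopifnot(inherits(model, "displacement_model"), duration > 0, rate > 0)
  fmax <- model$resp_freq
  if (model$heart_amplitude > 0) {
    fmax <- max(fmax, model$heart_freq)
    for (h in model$heart_harmonics)
      if (h[2] > 0) fmax <- max(fmax, h[1] * model$heart_freq)
  }
  if (rate < 2 * fmax)
    stop(sprintf("sampling rate %.3g Hz is below Nyquist for the %.3g Hz component",
                 rate, fmax))
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  d <- model$resp_amplitude * sin(2 * pi * model$resp_freq * t + model$resp_phase)
  if (model$heart_amplitude > 0) {
    d <- d + model$heart_amplitude *
      sin(2 * pi * model$heart_freq * t + model$heart_phase)
    for (h in model$heart_harmonics) {
      d <- d + model$heart_amplitude * h[2] *
        sin(2 * pi * h[1] * model$heart_freq * t + h[1] * model$heart_phase)
    }
  }
  if (model$noise_sd > 0) {
    d <- d + with_seed(seed, stats::rnorm(n, sd = model$noise_sd))
  }
  slow_time_series(d, rate, "mm")
}

#' Simulate an FMCW intermediate-frequency data cube
#'
#' Produces the mixer (IF) output for a chest at range
#' `R(t) = baseline + d(t)` plus any static reflectors. Per chirp the moving
#' target contributes a tone at beat frequency `f_IF = 2 * slope * R / c`
#' with phase `phi_IF = 4 pi R / lambda`; a static reflector contributes the
#' same with fixed `R`. Chirps within a frame see the same chest position
#' (the chest moves on the 50 ms frame scale, not the microsecond chirp
#' scale), differing only through per-chirp phase noise if requested.
#'
#' @param config A [radar_config()].
#' @param displacement A [slow_time_series()] in mm sampled at the frame rate
#'   (`1 / config$frame_period`), or `NULL` for a static-only scene.
#' @param statics List of [static_reflector()] objects.
#' @param baseline_range Chest standoff distance `Delta d` in metres (ignored
#'   when `displacement` is `NULL`).
#' @param target_amplitude Relative amplitude of the chest echo.
#' @param phase_noise_sd Gaussian phase-noise SD per chirp (rad); 0 disables.
#' @param complex_iq If `TRUE` store complex I/Q samples (`exp(j ...)`),
#'   otherwise real samples (`cos(...)`, single mixer).
#' @param seed Seed for the phase noise.
#' @return An object of class `radar_cube`: list with `data`
#'   (`[frames x chirps x samples]` array, real or complex) and `config`.
#' @export
simulate_if_cube <- function(config, displacement = NULL,
                             statics = list(),
                             baseline_range = 0.5,
                             target_amplitude = 1,
                             phase_noise_sd = 0,
                             complex_iq = FALSE,
                             seed = 1) {
  stopifnot(inherits(config, "radar_config"))
  if (!is.null(displacement)) {
    stopifnot(inherits(displacement, "slow_time_series"))
    if (abs(displacement$rate - config$slow_rate) / config$slow_rate > 1e-9)
      stop("displacement must be sampled at the frame rate 1/frame_period")
    n_frames <- length(displacement$values)
  } else {
    n_frames <- 1L
  }
  nc <- config$chirps_per_frame
  ns <- config$samples_per_chirp
  t_fast <- (seq_len(ns) - 1) / config$adc_rate
  max_range <- SPEED_OF_LIGHT * config$adc_rate / (4 * config$freq_slope)

  ranges_static <- vapply(statics, function(s) s$range, numeric(1))
  amps_static <- vapply(statics, function(s) s$amplitude, numeric(1))
  for (r in ranges_static)
    if (r >= max_range)
      stop(sprintf("static reflector at %.2f m beyond unambiguous range %.2f m",
                   r, max_range))

  tone <- function(R, amp, extra_phase = 0) {
    f_if <- 2 * config$freq_slope * R / SPEED_OF_LIGHT
    phi <- 4 * pi * R / config$wavelength + extra_phase
    if (complex_iq) amp * exp(1i * (2 * pi * f_if * t_fast + phi))
    else amp * cos(2 * pi * f_if * t_fast + phi)
  }

  static_chirp <- if (length(statics)) {
    Reduce(`+`, Map(tone, ranges_static, amps_static))
  } else {
    if (complex_iq) complex(ns) else numeric(ns)
  }

  pn <- if (phase_noise_sd > 0) {
    with_seed(seed, matrix(stats::rnorm(n_frames * nc, sd = phase_noise_sd),
                           n_frames, nc))
  } else NULL

  mode_empty <- if (complex_iq) complex(1) else numeric(1)
  data <- array(mode_empty, dim = c(n_frames, nc, ns))
  for (f in seq_len(n_frames)) {
    if (!is.null(displacement)) {
      R <- baseline_range + displacement$values[f] / 1000
      if (R >= max_range || R <= 0)
        stop("target range outside the unambiguous interval")
    }
    for (ch in seq_len(nc)) {
      extra <- if (is.null(pn)) 0 else pn[f, ch]
      sig <- static_chirp
      if (!is.null(displacement))
        sig <- sig + tone(R, target_amplitude, extra)
      data[f, ch, ] <- sig
    }
  }
  structure(list(data = data, config = config, complex_iq = complex_iq),
            class = "radar_cube")
}

#' @export
print.radar_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<radar_cube> %d frames x %d chirps x %d samples (%s)\n",
              d[1], d[2], d[3], if (x$complex_iq) "complex I/Q" else "real"))
  invisible(x)
}

#' Run a function with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not perturb the
#' caller's RNG stream.
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Write a radar cube to a single-file binary container
#'
#' Layout: the ASCII magic line `REMOTIONCUBE1`, one line with the byte length
#' of a JSON header (config, dimensions, storage mode), the JSON itself, then
#' little-endian float64 samples in frame-major order (real, or interleaved
#' re/im for I/Q cubes).
#'
#' @param cube A `radar_cube`.
#' @param path Output path.
#' @export
write_radar_cube <- function(cube, path) {
  stopifnot(inherits(cube, "radar_cube"))
  hdr <- jsonlite::toJSON(list(
    dims = dim(cube$data),
    complex_iq = cube$complex_iq,
    config = unclass(cube$config)
  ), auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("REMOTIONCUBE1", as.character(nchar(hdr, type = "bytes"))), con)
  writeChar(as.character(hdr), con, eos = NULL)
  x <- aperm(cube$data, c(3, 2, 1))  # fast time fastest on disk
  if (cube$complex_iq) {
    buf <- numeric(2 * length(x))
    buf[c(TRUE, FALSE)] <- Re(x)
    buf[c(FALSE, TRUE)] <- Im(x)
    writeBin(buf, con, size = 8, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read a radar cube written by [write_radar_cube()]
#' @param path File path.
#' @return A `radar_cube`.
#' @export
read_radar_cube <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "REMOTIONCUBE1")) stop("not a remotion cube file")
  nhdr <- as.integer(readLines(con, n = 1))
  hdr <- jsonlite::fromJSON(readChar(con, nhdr, useBytes = TRUE))
  dims <- as.integer(hdr$dims)
  n <- prod(dims)
  cfg <- do.call(radar_config, hdr$config[c("carrier_freq", "bandwidth",
                                            "chirp_duration", "frame_period",
                                            "chirps_per_frame",
                                            "samples_per_chirp", "adc_rate")])
  if (isTRUE(hdr$complex_iq)) {
    buf <- readBin(con, numeric(), 2 * n, size = 8, endian = "little")
    x <- complex(real = buf[c(TRUE, FALSE)], imaginary = buf[c(FALSE, TRUE)])
  } else {
    x <- readBin(con, numeric(), n, size = 8, endian = "little")
  }
  data <- aperm(array(x, dim = rev(dims)), c(3, 2, 1))
  structure(list(data = data, config = cfg,
                 complex_iq = isTRUE(hdr$complex_iq)),
            class = "radar_cube")
}

#' Import a raw interleaved int16 capture
#'
#' Reads a flat little-endian int16 stream as written by streaming capture
#' boards. Samples are expected fast-time-major: sample index varies fastest,
#' then chirp, then frame; for I/Q captures the I and Q of each sample are
#' adjacent (`I0 Q0 I1 Q1 ...`). Values are scaled by `1 / 2^15` to the
#' nominal full-scale range \[-1, 1).
#'
#' @param path Raw file path.
#' @param config A [radar_config()] giving the cube geometry.
#' @param n_frames Number of frames to read; `NULL` reads all complete frames.
#' @param complex_iq Whether the stream is interleaved I/Q.
#' @return A `radar_cube`.
#' @export
read_raw_int16 <- function(path, config, n_frames = NULL, complex_iq = FALSE) {
  stopifnot(inherits(config, "radar_config"))
  per_frame <- config$chirps_per_frame * config$samples_per_chirp *
    (if (complex_iq) 2L else 1L)
  sz <- file.info(path)$size
  avail <- floor(sz / 2 / per_frame)
  if (is.null(n_frames)) n_frames <- avail
  if (n_frames > avail) stop("file holds fewer frames than requested")
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, integer(), n_frames * per_frame, size = 2,
                 signed = TRUE, endian = "little") / 2^15
  if (complex_iq) {
    x <- complex(real = raw[c(TRUE, FALSE)], imaginary = raw[c(FALSE, TRUE)])
  } else {
    x <- raw
  }
  data <- aperm(array(x, dim = c(config$samples_per_chirp,
                                 config$chirps_per_frame, n_frames)),
                c(3, 2, 1))
  structure(list(data = data, config = config, complex_iq = complex_iq),
            class = "radar_cube")
}
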