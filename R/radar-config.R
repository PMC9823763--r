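#' @keywords internal
"_PACKAGE"

## Speed of light in vacuum (m/s), used throughout the FMCW geometry.
SPEED_OF_LIGHT <- 299792458

#' FMCW radar configuration
#'
#' Bundles the chirp and frame timing of a sawtooth FMCW radar. The frequency
#' slope is derived from bandwidth and chirp duration (`slope = B / T_c`), and
#' the wavelength from the carrier (`lambda = c / f_c`), so the object is
#' always internally consistent.
#'
#' @param carrier_freq Carrier (chirp start) frequency in Hz.
#' @param bandwidth Swept bandwidth of one chirp in Hz.
#' @param chirp_duration Duration of one chirp in seconds.
#' @param frame_period Frame repetition period in seconds; the slow-time
#'   sampling interval of the vital-sign series.
#' @param chirps_per_frame Number of chirps transmitted per frame.
#' @param samples_per_chirp Number of ADC samples per chirp (fast time).
#' @param adc_rate ADC sampling rate in Hz. Defaults to
#'   `samples_per_chirp / chirp_duration` (the ADC spans the whole chirp).
#'
#' @return An object of class `radar_config` with derived fields
#'   `freq_slope` (Hz/s), `wavelength` (m) and `slow_rate` (Hz).
#' @seealso [radar_profile()] for named presets.
#' @export
radar_config <- function(carrier_freq = 77e9,
                         bandwidth = 4e9,
                         chirp_duration = 60e-6,
                         frame_period = 50e-3,
                         chirps_per_frame = 128L,
                         samples_per_chirp = 256L,
                         adc_rate = NULL) {
  stopifnot(carrier_freq > 0, bandwidth > 0, chirp_duration > 0,
            frame_period > 0)
  chirps_per_frame <- as.integer(chirps_per_frame)
  samples_per_chirp <- as.integer(samples_per_chirp)
  if (chirps_per_frame < 1L || samples_per_chirp < 1L)
    stop("chirps_per_frame and samples_per_chirp must be >= 1")
  if (is.null(adc_rate)) adc_rate <- samples_per_chirp / chirp_duration
  cfg <- structure(list(
    carrier_freq = carrier_freq,
    bandwidth = bandwidth,
    chirp_duration = chirp_duration,
    freq_slope = bandwidth / chirp_duration,
    frame_period = frame_period,
    chirps_per_frame = chirps_per_frame,
    samples_per_chirp = samples_per_chirp,
    adc_rate = adc_rate,
    wavelength = SPEED_OF_LIGHT / carrier_freq,
    slow_rate = 1 / frame_period
  ), class = "radar_config")
  validate_radar_config(cfg)
  cfg
}

validate_radar_config <- function(cfg) {
  stopifnot(inherits(cfg, "radar_config"))
  rel <- abs(cfg$freq_slope * cfg$chirp_duration - cfg$bandwidth) /
    cfg$bandwidth
  if (rel > 1e-6)
    stop("inconsistent radar_config: freq_slope * chirp_duration != bandwidth")
  rel_l <- abs(cfg$wavelength * cfg$carrier_freq - SPEED_OF_LIGHT) /
    SPEED_OF_LIGHT
  if (rel_l > 1e-9) stop("inconsistent radar_config: wavelength * carrier_freq != c")
  invisible(cfg)
}

#' Named radar profiles
#'
#' `"iwr1642"` is the default 77 GHz profile (4 GHz bandwidth, 60 us chirps,
#' 50 ms frames, 128 chirps/frame, 256 samples/chirp) mirroring a common
#' single-chip mmWave evaluation setup. `"analytic"` is a 2 GHz / 40 us
#' profile (slope 50 MHz/us) convenient for closed-form sensitivity checks.
#' `"sim-small"` is the iwr1642 timing with 2 chirps per frame, used when
#' simulating many trials: chirps within a frame are redundant for a target
#' that moves only frame-to-frame, so keeping two preserves the chirp axis at
#' a fraction of the memory.
#'
#' @param name One of `"iwr1642"`, `"analytic"`, `"sim-small"`.
#' @param ... Overrides passed on to [radar_config()].
#' @return A `radar_config`.
#' @export
radar_profile <- function(name = c("iwr1642", "analytic", "sim-small"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    "iwr1642" = list(),
    "analytic" = list(bandwidth = 2e9, chirp_duration = 40e-6),
    "sim-small" = list(chirps_per_frame = 2L)
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(radar_config, args)
}

#' @export
print.radar_config <- function(x, ...) {
  cat("<radar_config>\n")
  cat(sprintf("  carrier %.2f GHz, bandwidth %.2f GHz, chirp %.1f us (slope %.2f MHz/us)\n",
              x$carrier_freq / 1e9, x$bandwidth / 1e9, x$chirp_duration * 1e6,
              x$freq_slope / 1e12))
  cat(sprintf("  frame %.1f ms (slow rate %.1f Hz), %d chirps x %d samples, ADC %.2f MHz\n",
              x$frame_period * 1e3, x$slow_rate, x$chirps_per_frame,
              x$samples_per_chirp, x$adc_rate / 1e6))
  invisible(x)
}

#' Parametric chest-displacement model
#'
#' Chest-wall displacement is modelled as the sum of a respiration sinusoid, a
#' heartbeat sinusoid with optional harmonics, and white measurement noise:
#' `d(t) = A_r sin(2 pi f_r t + p_r) + A_h sin(2 pi f_h t + p_h) + harmonics + noise`.
#' Amplitudes are in millimetres; cardiac displacement is physiologically
#' sub-millimetre and must be smaller than the respiratory excursion.
#'
#' @param resp_amplitude Respiration amplitude (mm).
#' @param resp_freq Respiration frequency (Hz), in `[0.1, 0.6]`.
#' @param heart_amplitude Heartbeat amplitude (mm), `< resp_amplitude`.
#' @param heart_freq Heartbeat frequency (Hz), in `[0.8, 3.3]`.
#' @param heart_harmonics List of `c(multiple, relative_amplitude)` pairs added
#'   at `multiple * heart_freq` with amplitude `relative * heart_amplitude`.
#'   Default: one harmonic at 2x with relative amplitude 0.3, so the cardiac
#'   band holds more than a single line.
#' @param noise_sd Gaussian displacement noise standard deviation (mm).
#' @param baseline_range Static chest-to-radar distance `Delta d` (m).
#' @param resp_phase,heart_phase Component phases (rad).
#' @return An object of class `displacement_model`.
#' @export
displacement_model <- function(resp_amplitude = 5,
                               resp_freq = 0.25,
                               heart_amplitude = 0.5,
                               heart_freq = 1.2,
                               heart_harmonics = list(c(2, 0.3)),
                               noise_sd = 0.05,
                               baseline_range = 0.5,
                               resp_phase = 0,
                               heart_phase = 0) {
  if (resp_freq < 0.1 || resp_freq > 0.6)
    stop("resp_freq must lie in [0.1, 0.6] Hz")
  if (heart_freq < 0.8 || heart_freq > 3.3)
    stop("heart_freq must lie in [0.8, 3.3] Hz")
  if (resp_amplitude <= 0 || heart_amplitude < 0)
    stop("amplitudes must be positive")
  if (heart_amplitude >= resp_amplitude && heart_amplitude > 0)
    stop("heart_amplitude must be below resp_amplitude (cardiac motion is sub-mm)")
  structure(list(
    resp_amplitude = resp_amplitude, resp_freq = resp_freq,
    heart_amplitude = heart_amplitude, heart_freq = heart_freq,
    heart_harmonics = heart_harmonics, noise_sd = noise_sd,
    baseline_range = baseline_range,
    resp_phase = resp_phase, heart_phase = heart_phase
  ), class = "displacement_model")
}

#' A static reflector in the scene
#'
#' Desks, laptops and walls return echoes that are constant over slow time;
#' they are what moving-target indication removes.
#'
#' @param range Distance from the radar (m), `> 0`.
#' @param amplitude Relative echo amplitude (a.u.).
#' @return An object of class `static_reflector`.
#' @export
static_reflector <- function(range, amplitude = 1) {
  stopifnot(range > 0)
  structure(list(range = range, amplitude = amplitude),
            class = "static_reflector")
}

#' Uniformly sampled slow-time series
#'
#' The scalar time-series container used across the pipeline, tagged with its
#' sampling rate and units (`"rad"`, `"mm"` or `"a.u."`).
#'
#' @param values Numeric vector of samples.
#' @param rate Sampling rate in Hz.
#' @param units One of `"rad"`, `"mm"`, `"a.u."`.
#' @return An object of class `slow_time_series`.
#' @export
slow_time_series <- function(values, rate, units = c("a.u.", "rad", "mm")) {
  units <- match.arg(units)
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("slow_time_series values must be finite")
  stopifnot(rate > 0)
  structure(list(values = values, rate = rate, units = units),
            class = "slow_time_series")
}

#' @export
print.slow_time_series <- function(x, ...) {
  cat(sprintf("<slow_time_series> %d samples @ %.3g Hz [%s]\n",
              length(x$values), x$rate, x$units))
  invisible(x)
}

#' Time axis of a slow-time series
#' @param x A `slow_time_series`.
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
time_axis <- function(x) {
  stopifnot(inherits(x, "slow_time_series"))
  (seq_along(x$values) - 1) / x$rate
}

#' Write a slow-time series as a two-column CSV
#'
#' Columns `time_s` and `value`; a leading comment line records units and rate.
#'
#' @param x A `slow_time_series`.
#' @param path Output file path.
#' @export
write_series_csv <- function(x, path) {
  stopifnot(inherits(x, "slow_time_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units=%s rate_hz=%.10g", x$units, x$rate), con)
  utils::write.csv(data.frame(time_s = time_axis(x), value = x$values),
                   con, row.names = FALSE)
}

#' Read a slow-time series written by [write_series_csv()]
#' @param path CSV path.
#' @return A `slow_time_series`.
#' @export
read_series_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  units <- sub(".*units=([^ ]+).*", "\\1", hdr)
  rate <- as.numeric(sub(".*rate_hz=([0-9.eE+-]+).*", "\\1", hdr))
  df <- utils::read.csv(path, comment.char = "#")
  slow_time_series(df$value, rate, units)
}
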