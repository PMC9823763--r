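#' Moving-target indication (MTI) clutter removal
#'
#' Suppresses returns that are constant over slow time. For every fast-time
#' position, each sliding window of `window_n` consecutive frames estimates
#' the static component as its mean and yields `sample - window mean` for the
#' samples it covers; a sample's output is the average of those residuals
#' over all windows containing it. Content constant across frames maps to
#' (numerically) zero while frame-to-frame motion passes through.
#'
#' @param cube A `radar_cube`.
#' @param window_n Sliding-window length in frames, `2 <= window_n <= n_frames`.
#'   Default 20 frames (1 s at a 50 ms frame period) — a convention: long
#'   enough that breathing is not averaged out, short enough to track slow
#'   drift.
#' @return A `radar_cube` of the same shape with static clutter removed.
#' @export
mti_filter <- function(cube, window_n = 20) {
  stopifnot(inherits(cube, "radar_cube"))
  n <- dim(cube$data)[1]
  window_n <- as.integer(window_n)
  if (window_n < 2 || window_n > n)
    stop(sprintf("window_n must be in [2, %d]", n))
  d <- dim(cube$data)
  X <- cube$data
  dim(X) <- c(d[1], d[2] * d[3])
  out <- X - mti_static_estimate(X, window_n)
  dim(out) <- d
  structure(list(data = out, config = cube$config,
                 complex_iq = cube$complex_iq),
            class = "radar_cube")
}

## For each row i of X [n x k], the average over windows covering i of the
## window means. Two cumulative sums: one to form window means, one to
## average them over the covering windows.
mti_static_estimate <- function(X, win) {
  n <- nrow(X)
  W <- n - win + 1L                      # number of windows
  zero_row <- X[1, , drop = FALSE] * 0
  CS <- apply_cumsum(rbind(zero_row, X))
  M <- (CS[(win + 1L):(win + W), , drop = FALSE] -
        CS[1:W, , drop = FALSE]) / win   # window means [W x k]
  CM <- apply_cumsum(rbind(zero_row, M))
  lo <- pmax(1L, seq_len(n) - win + 1L)  # first window covering i
  hi <- pmin(seq_len(n), W)              # last window covering i
  (CM[hi + 1L, , drop = FALSE] - CM[lo, , drop = FALSE]) / (hi - lo + 1L)
}

apply_cumsum <- function(X) {
  if (is.complex(X)) {
    matrix(complex(real = apply(Re(X), 2, cumsum),
                   imaginary = apply(Im(X), 2, cumsum)), nrow(X), ncol(X))
  } else {
    apply(X, 2, cumsum)
  }
}

#' Range FFT over fast time
#'
#' Reduces the chirps of each frame (mean by default, to raise SNR), applies
#' a Hann window along fast time and Fourier-transforms, yielding one complex
#' range profile per frame. For real-valued (single-mixer) cubes the
#' one-sided spectrum is kept.
#'
#' @param cube A `radar_cube`.
#' @param chirp_reduction `"mean"` or `"first"`.
#' @return A `range_profiles` object: `spectra` (`[n_frames x n_bins]`
#'   complex), `bin_scale` (m per bin), `bin_freqs` (Hz), `rate` (slow-time
#'   Hz) and `config`.
#' @export
range_fft <- function(cube, chirp_reduction = c("mean", "first")) {
  stopifnot(inherits(cube, "radar_cube"))
  chirp_reduction <- match.arg(chirp_reduction)
  cfg <- cube$config
  d <- dim(cube$data)
  X <- if (chirp_reduction == "first" || d[2] == 1L) {
    array(cube$data[, 1, ], dim = c(d[1], d[3]))
  } else {
    apply(cube$data, c(1, 3), mean)
  }
  ns <- d[3]
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(ns) - 1) / ns))  # periodic Hann
  Xw <- sweep(X, 2, w, `*`)
  sp <- t(stats::mvfft(t(Xw)))
  n_bins <- if (cube$complex_iq) ns else ns %/% 2L
  sp <- sp[, seq_len(n_bins), drop = FALSE]
  df <- cfg$adc_rate / ns
  structure(list(
    spectra = sp,
    bin_scale = SPEED_OF_LIGHT * df / (2 * cfg$freq_slope),
    bin_freqs = (seq_len(n_bins) - 1) * df,
    rate = cfg$slow_rate,
    config = cfg
  ), class = "range_profiles")
}

#' Pick the range bin holding the moving target
#'
#' Chooses the bin with the largest mean magnitude across frames — run it on
#' MTI-filtered profiles so static reflectors cannot win. Ties resolve to the
#' lowest bin. When the winning bin barely exceeds the background (peak
#' below `snr_min` times the median bin magnitude) a low-SNR warning is
#' raised; the bin is still returned.
#'
#' @param stack A `range_profiles` (normally from an MTI-filtered cube).
#' @param exclude_dc Drop bin 1 (zero frequency) from the search.
#' @param snr_min Peak-to-median ratio below which the result is flagged.
#' @return Integer bin index (into `stack$spectra` columns).
#' @export
select_target_bin <- function(stack, exclude_dc = TRUE, snr_min = 3) {
  stopifnot(inherits(stack, "range_profiles"))
  mag <- colMeans(abs(stack$spectra))
  search <- if (exclude_dc && length(mag) > 1) 2:length(mag) else
    seq_along(mag)
  bin <- search[which.max(mag[search])]
  med <- stats::median(mag[search])
  if (!is.finite(med) || med <= 0 || mag[bin] < snr_min * med)
    warning("low SNR: no range bin clearly dominates; target bin is unreliable")
  bin
}

#' Extract the per-frame phase at a range bin
#'
#' The complex argument of the selected bin per frame, wrapped to
#' `(-pi, pi]`. For a target at range `R` this is `4 pi R / lambda` modulo
#' `2 pi`; sub-wavelength chest motion rides on it.
#'
#' @param stack A `range_profiles` built from the *unfiltered* cube (MTI
#'   distorts absolute phase; use it only to choose the bin).
#' @param bin Bin index from [select_target_bin()].
#' @return A [slow_time_series()] in radians.
#' @export
extract_phase <- function(stack, bin) {
  stopifnot(inherits(stack, "range_profiles"),
            bin >= 1, bin <= ncol(stack$spectra))
  slow_time_series(Arg(stack$spectra[, bin]), stack$rate, "rad")
}

#' Unwrap a wrapped phase series
#'
#' `method = "nearest"` removes the `2 pi` jumps of wrapped phase the
#' classical way: successive differences larger than `pi` in magnitude are
#' shifted by the nearest multiple of `2 pi`; the first sample is unchanged.
#' It assumes the true phase never moves more than `pi` per sample.
#'
#' `method = "predictive"` instead picks, for each sample, the `2 pi` branch
#' closest to a linear (constant-velocity) prediction from the two previous
#' unwrapped samples. Chest motion can legitimately step more than `pi` per
#' frame (fast breathing at 77 GHz exceeds the classical limit above
#' ~15 mm/s) while its *acceleration* stays far below the corresponding
#' bound, so the predictive branch choice stays correct where the nearest
#' branch aliases; it is the standard remedy in phase interferometry.
#'
#' @param series A [slow_time_series()] in radians.
#' @param method `"nearest"` (classical) or `"predictive"` (second-order).
#' @return A [slow_time_series()] in radians, unwrapped.
#' @export
unwrap_phase <- function(series, method = c("nearest", "predictive")) {
  stopifnot(inherits(series, "slow_time_series"))
  method <- match.arg(method)
  v <- series$values
  n <- length(v)
  if (n > 1) {
    if (method == "nearest") {
      d <- diff(v)
      d <- d - 2 * pi * round(d / (2 * pi))
      v <- c(v[1], v[1] + cumsum(d))
    } else {
      out <- numeric(n)
      out[1] <- v[1]
      out[2] <- out[1] + (v[2] - out[1]) -
        2 * pi * round((v[2] - out[1]) / (2 * pi))
      for (i in 3:n) {
        pred <- 2 * out[i - 1] - out[i - 2]
        out[i] <- v[i] + 2 * pi * round((pred - v[i]) / (2 * pi))
      }
      ## A wrong branch on the very first step makes the tracker follow a
      ## velocity aliased by a whole 2*pi per sample — self-consistent but
      ## unphysical: the chest has no net drift over the record. Detect and
      ## remove any whole-cycle-per-sample velocity offset.
      drift <- round(mean(diff(out)) / (2 * pi))
      if (drift != 0)
        out <- out - drift * 2 * pi * (seq_len(n) - 1)
      v <- out
    }
  }
  slow_time_series(v, series$rate, "rad")
}

#' Convert unwrapped phase to relative displacement
#'
#' `d = lambda * phi / (4 pi)`, reported in millimetres with the mean removed
#' (the absolute standoff is not recoverable from phase alone).
#'
#' @param series A [slow_time_series()] in radians (unwrapped).
#' @param wavelength Radar wavelength in metres.
#' @return A [slow_time_series()] in mm, zero-mean.
#' @export
phase_to_displacement <- function(series, wavelength) {
  stopifnot(inherits(series, "slow_time_series"), wavelength > 0)
  d <- wavelength * series$values / (4 * pi) * 1000
  slow_time_series(d - mean(d), series$rate, "mm")
}

#' Zero-phase Butterworth low-pass
#'
#' Fourth-order Butterworth applied forward and backward
#' (`signal::filtfilt`), so the pass band is delay-free — recovered waveforms
#' stay aligned with ground truth. The 3.3 Hz default cutoff sits just above
#' the cardiac band.
#'
#' @param series A [slow_time_series()].
#' @param order Filter order (single-pass).
#' @param cutoff Cutoff frequency in Hz, `< rate / 2`.
#' @return A filtered [slow_time_series()] (same units).
#' @export
lowpass <- function(series, order = 4, cutoff = 3.3) {
  stopifnot(inherits(series, "slow_time_series"))
  if (cutoff >= series$rate / 2)
    stop(sprintf("cutoff %.3g Hz must be below the Nyquist rate %.3g Hz",
                 cutoff, series$rate / 2))
  bf <- signal::butter(order, cutoff / (series$rate / 2), type = "low")
  ## odd-reflection padding suppresses the start-up transient of the
  ## forward-backward pass (same idea as MATLAB's filtfilt edge handling)
  v <- series$values
  n <- length(v)
  p <- min(n - 1, 3 * (2 * order + 1))
  pre <- 2 * v[1] - v[(p + 1):2]
  post <- 2 * v[n] - v[(n - 1):(n - p)]
  out <- signal::filtfilt(bf, c(pre, v, post))[p + seq_len(n)]
  slow_time_series(out, series$rate, series$units)
}

#' Full displacement recovery from a radar cube
#'
#' Convenience chain: MTI (for bin selection) -> range FFT -> target bin ->
#' phase at that bin from the raw profiles -> unwrap -> displacement ->
#' zero-phase low-pass.
#'
#' Unwrapping uses the predictive branch rule (see [unwrap_phase()]): at a
#' 20 Hz frame rate fast deep breathing can step the phase by more than `pi`
#' per frame, which the classical rule would alias.
#'
#' @param cube A `radar_cube`.
#' @param mti_window MTI sliding-window length in frames.
#' @param chirp_reduction Passed to [range_fft()].
#' @param cutoff Low-pass cutoff in Hz; `NULL` skips filtering.
#' @param unwrap Phase unwrapping method, see [unwrap_phase()].
#' @return A [slow_time_series()] of chest displacement in mm.
#' @export
extract_displacement <- function(cube, mti_window = 20,
                                 chirp_reduction = "mean", cutoff = 3.3,
                                 unwrap = "predictive") {
  stack_mti <- range_fft(mti_filter(cube, mti_window), chirp_reduction)
  bin <- select_target_bin(stack_mti)
  stack_raw <- range_fft(cube, chirp_reduction)
  ph <- unwrap_phase(extract_phase(stack_raw, bin), method = unwrap)
  d <- phase_to_displacement(ph, cube$config$wavelength)
  if (!is.null(cutoff)) d <- lowpass(d, cutoff = cutoff)
  d
}
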