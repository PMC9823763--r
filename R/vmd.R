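#' Variational mode decomposition (VMD)
#'
#' Decomposes a series into `k` band-limited intrinsic mode functions (IMFs)
#' by the alternating frequency-domain updates of the augmented-Lagrangian
#' VMD problem: each mode is refreshed by a Wiener-filter step
#' `u_k <- (f - sum(u_i, i != k) + lambda/2) / (1 + 2 alpha (w - w_k)^2)`
#' and its centre frequency by the power-weighted spectral centroid of the
#' mode, with optional dual ascent on the Lagrange multiplier. The signal is
#' mirror-extended by half its length on each side before the updates and
#' cropped afterwards to curb edge ringing.
#'
#' @param signal A [slow_time_series()] (length at least `8 * k`).
#' @param k Number of modes.
#' @param alpha Quadratic bandwidth penalty (dimensionless, on normalized
#'   frequency). Default 2000, the customary value for vital-sign work.
#' @param tau Dual-ascent step; 0 (default) drops the exact-reconstruction
#'   constraint, which is the noise-robust choice.
#' @param tol Convergence threshold on the summed relative squared mode
#'   update.
#' @param max_iter Iteration cap; non-convergence is flagged, not an error.
#' @param dc_mode Pin the first mode's centre frequency at 0.
#' @param omega_init Optional numeric vector of initial centre frequencies in
#'   Hz (length `k`); default uniform over `(0, rate/4]`.
#' @return An object of class `imf_set`: `modes` (`[n x k]`, columns in
#'   ascending centre frequency), `center_freqs` (Hz), `n_iterations`,
#'   `final_update_norm`, `converged`, `rate`, `units`.
#' @export
vmd_decompose <- function(signal, k, alpha = 2000, tau = 0, tol = 1e-7,
                          max_iter = 500, dc_mode = FALSE,
                          omega_init = NULL) {
  stopifnot(inherits(signal, "slow_time_series"), k >= 1, alpha > 0, tol > 0)
  x <- signal$values
  n <- length(x)
  if (n < 8 * k) stop("signal too short: need length >= 8 * k")
  rate <- signal$rate

  half <- n %/% 2
  xm <- c(rev(x[1:half]), x, rev(x[(n - half + 1):n]))
  T <- length(xm)
  hT <- T %/% 2
  f_hat <- stats::fft(xm)
  f_plus <- f_hat[1:hT]                  # positive-frequency half
  nu <- (0:(hT - 1)) / T                 # normalized frequency in [0, 0.5)

  omega <- if (is.null(omega_init)) 0.25 * seq_len(k) / k
           else sort(omega_init) / rate
  if (dc_mode) omega[1] <- 0
  u_hat <- matrix(complex(real = 0), k, hT)
  lambda_hat <- complex(hT)

  iter <- 0L
  udiff <- Inf
  while (iter < max_iter && udiff > tol) {
    iter <- iter + 1L
    u_prev <- u_hat
    for (kk in seq_len(k)) {
      sum_others <- if (k > 1) colSums(u_hat[-kk, , drop = FALSE]) else
        complex(hT)
      u_hat[kk, ] <- (f_plus - sum_others + lambda_hat / 2) /
        (1 + 2 * alpha * (nu - omega[kk])^2)
      if (!(dc_mode && kk == 1L)) {
        pw <- Mod(u_hat[kk, ])^2
        tot <- sum(pw)
        if (tot > 0) omega[kk] <- sum(nu * pw) / tot
      }
    }
    if (tau != 0)
      lambda_hat <- lambda_hat + tau * (colSums(u_hat) - f_plus)
    num <- rowSums(Mod(u_hat - u_prev)^2)
    den <- rowSums(Mod(u_prev)^2)
    udiff <- sum(num / (den + .Machine$double.eps))
  }

  ord <- order(omega)
  modes <- matrix(0, n, k)
  for (j in seq_len(k)) {
    uf <- complex(T)
    uf[1:hT] <- u_hat[ord[j], ]
    if (hT > 1) uf[T:(T - hT + 2)] <- Conj(uf[2:hT])
    ut <- Re(stats::fft(uf, inverse = TRUE)) / T
    modes[, j] <- ut[(half + 1):(half + n)]
  }
  structure(list(
    modes = modes,
    center_freqs = omega[ord] * rate,
    n_iterations = iter,
    final_update_norm = udiff,
    converged = udiff <= tol,
    rate = rate,
    units = signal$units
  ), class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d modes x %d samples @ %.3g Hz; centres: %s Hz; %s in %d iter\n",
              ncol(x$modes), nrow(x$modes), x$rate,
              paste(sprintf("%.3f", x$center_freqs), collapse = ", "),
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' Serialize an IMF set to CSV
#'
#' One column per mode; the header comment line carries the centre
#' frequencies and rate.
#' @param imfs An `imf_set`.
#' @param path Output path.
#' @export
write_imf_csv <- function(imfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%.10g center_freqs_hz=%s", imfs$rate,
                     paste(sprintf("%.10g", imfs$center_freqs),
                           collapse = ";")), con)
  df <- as.data.frame(imfs$modes)
  names(df) <- sprintf("imf%d", seq_len(ncol(df)))
  utils::write.csv(df, con, row.names = FALSE)
}

#' Choose the mode count by centre-frequency stability
#'
#' Runs [vmd_decompose()] for increasing `k`. A decomposition is
#' over-decomposed when two adjacent centre frequencies come too close —
#' their ratio `min/max` exceeds `ratio_max` (0.9) — and unstable when a
#' centre found at `k - 1` has no match at `k` within relative tolerance
#' `stability_rtol`. The scan stops at the first over-decomposed or unstable
#' `k` and returns the last acceptable one.
#'
#' A decomposition is also rejected when it contains a *spurious* mode: one
#' whose spectrum is broadband rather than peaked (spectral concentration —
#' the largest power bin over the total mode power — below `conc_min`). Such
#' modes collect the leakage skirt of a finite record instead of a physical
#' oscillation; their centre drifts with `k`, which is how over-decomposition
#' shows itself between the ratio-rule violations. Finally, the centres of
#' the last accepted decomposition must persist (greedy nearest matching
#' within `stability_rtol` relative tolerance) in any larger accepted one.
#'
#' @param signal A [slow_time_series()].
#' @param k_range Increasing integer vector of candidate mode counts.
#' @param ratio_max Adjacent-centre ratio marking over-decomposition.
#' @param stability_rtol Relative tolerance for matching centres between
#'   accepted decompositions.
#' @param conc_min Minimum spectral concentration of a non-spurious mode.
#' @param ... Passed to [vmd_decompose()].
#' @return Selected `k` (integer), with the per-`k` centre frequencies
#'   attached as attribute `"centers"`.
#' @export
select_k <- function(signal, k_range = 2:8, ratio_max = 0.9,
                     stability_rtol = 0.1, conc_min = 0.3, ...) {
  if (length(k_range) < 1) stop("k_range must be non-empty")
  k_range <- sort(unique(as.integer(k_range)))
  centers_log <- list()
  spectral_conc <- function(mode) {
    p <- Mod(stats::fft(mode))^2
    p <- p[seq_len(max(1L, length(p) %/% 2L))]
    max(p) / sum(p)
  }
  selected <- NA_integer_
  last_valid_ctr <- NULL
  for (k in k_range) {
    dec <- vmd_decompose(signal, k, ...)
    ctr <- dec$center_freqs
    centers_log[[as.character(k)]] <- ctr
    if (k > 1) {
      lo <- ctr[-length(ctr)]
      hi <- ctr[-1]
      if (any(pmin(lo, hi) / pmax(lo, hi) > ratio_max, na.rm = TRUE))
        break                               # over-decomposed: stop the scan
    }
    conc <- apply(dec$modes, 2, spectral_conc)
    if (any(conc < conc_min)) next          # spurious broadband mode
    if (!is.null(last_valid_ctr)) {
      persists <- all(vapply(last_valid_ctr, function(w) {
        min(abs(ctr - w)) <= stability_rtol * max(w, 1e-12)
      }, logical(1)))
      if (!persists) next
    }
    selected <- k
    last_valid_ctr <- ctr
  }
  if (is.na(selected)) {
    warning("no candidate k passed the stability rules; returning the smallest")
    selected <- k_range[1]
  }
  structure(as.integer(selected), centers = centers_log)
}

#' Mean instantaneous frequency of a mode
#'
#' Analytic signal by the FFT Hilbert transform, instantaneous frequency as
#' the unwrapped analytic-phase derivative over `2 pi`, averaged over the
#' central 90% of samples (5% trimmed at each edge, where the Hilbert
#' estimate rings).
#'
#' @param mode Numeric vector (one IMF).
#' @param rate Sampling rate in Hz.
#' @return Mean instantaneous frequency in Hz.
#' @export
mean_instantaneous_frequency <- function(mode, rate) {
  n <- length(mode)
  stopifnot(n >= 4, rate > 0)
  if (all(mode == 0)) return(0)
  X <- stats::fft(mode)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  analytic <- stats::fft(X * h, inverse = TRUE) / n
  ph <- Arg(analytic)
  d <- diff(ph)
  d <- d - 2 * pi * round(d / (2 * pi))
  inst <- d * rate / (2 * pi)
  m <- length(inst)
  trim <- floor(0.05 * m)
  keep <- (trim + 1):(m - trim)
  mean(inst[keep])
}

#' Reconstruct a physiological band from an IMF set
#'
#' Sums the modes whose mean instantaneous frequency falls inside the closed
#' band. The respiration band is `[0.1, 0.6]` Hz and the cardiac band
#' `[0.8, 3.3]` Hz; a mode in the gap belongs to neither. An empty selection
#' returns a zero series with a warning.
#'
#' @param imfs An `imf_set`.
#' @param band Numeric `c(f_lo, f_hi)` in Hz.
#' @return A [slow_time_series()] (same units as the decomposed input).
#' @export
reconstruct_band <- function(imfs, band) {
  stopifnot(inherits(imfs, "imf_set"), length(band) == 2, band[1] <= band[2])
  mif <- apply(imfs$modes, 2, mean_instantaneous_frequency, rate = imfs$rate)
  sel <- mif >= band[1] & mif <= band[2]
  if (!any(sel)) {
    warning(sprintf("no IMF has mean instantaneous frequency in [%.3g, %.3g] Hz",
                    band[1], band[2]))
    return(slow_time_series(numeric(nrow(imfs$modes)), imfs$rate, imfs$units))
  }
  slow_time_series(rowSums(imfs$modes[, sel, drop = FALSE]), imfs$rate,
                   imfs$units)
}

#' Estimate a per-minute rate from a waveform
#'
#' Zero-padded magnitude spectrum (Hann window), peak restricted to the
#' search band, refined by quadratic interpolation around the peak bin, and
#' converted to a per-minute rate.
#'
#' @param signal A [slow_time_series()].
#' @param search_band `c(f_lo, f_hi)` in Hz.
#' @param pad_factor Zero-padding factor for the FFT.
#' @return Rate in events per minute. A peak that barely exceeds the in-band
#'   background raises a low-SNR warning.
#' @export
estimate_rate <- function(signal, search_band, pad_factor = 8) {
  stopifnot(inherits(signal, "slow_time_series"), length(search_band) == 2)
  v <- signal$values - mean(signal$values)
  n <- length(v)
  if (all(v == 0)) {
    warning("zero signal: no rate to estimate")
    return(NA_real_)
  }
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
  nfft <- 2^ceiling(log2(n * pad_factor))
  mag <- Mod(stats::fft(c(v * w, numeric(nfft - n))))[1:(nfft %/% 2)]
  freqs <- (seq_len(nfft %/% 2) - 1) * signal$rate / nfft
  inband <- which(freqs >= search_band[1] & freqs <= search_band[2])
  if (!length(inband)) stop("search band holds no FFT bins")
  i0 <- inband[which.max(mag[inband])]
  if (mag[i0] < 3 * stats::median(mag[inband]))
    warning("low SNR: spectral peak barely exceeds the in-band background")
  f <- freqs[i0]
  if (i0 > 1 && i0 < length(mag)) {
    a <- mag[i0 - 1]; b <- mag[i0]; cc <- mag[i0 + 1]
    den <- a - 2 * b + cc
    if (den < 0) {
      delta <- 0.5 * (a - cc) / den
      f <- f + delta * signal$rate / nfft
    }
  }
  60 * f
}

#' Coefficient of determination of estimates against references
#'
#' Ordinary least-squares line of the estimated rates on the reference rates;
#' returns the regression R-squared.
#'
#' @param estimates Numeric vector of estimated rates.
#' @param references Numeric vector of reference rates (same length, not
#'   constant).
#' @return R-squared in \[0, 1\].
#' @export
fit_r2 <- function(estimates, references) {
  stopifnot(length(estimates) == length(references), length(estimates) >= 3)
  if (stats::var(references) == 0)
    stop("references are constant: R-squared is undefined")
  fit <- stats::lm(estimates ~ references)
  1 - sum(stats::residuals(fit)^2) /
    sum((estimates - mean(estimates))^2)
}

#' Respiration and heartbeat from a displacement series
#'
#' VMD decomposition (with [select_k()] unless `k` is given), band
#' reconstruction into the respiration `[0.1, 0.6]` Hz and cardiac
#' `[0.8, 3.3]` Hz bands, and spectral rate estimation for each.
#'
#' @param displacement A [slow_time_series()] in mm.
#' @param k Mode count; `NULL` selects it via [select_k()] over `k_range`.
#' @param k_range Candidate mode counts for selection.
#' @param resp_band,heart_band Band edges in Hz.
#' @param ... Passed to [vmd_decompose()].
#' @return An object of class `vital_signs`: `respiration`, `heartbeat`
#'   (series), `breathing_rate` (breaths/min), `heart_rate` (beats/min),
#'   `imfs`, `k`.
#' @export
extract_vitals <- function(displacement, k = NULL, k_range = 2:6,
                           resp_band = c(0.1, 0.6),
                           heart_band = c(0.8, 3.3), ...) {
  if (is.null(k)) k <- as.integer(select_k(displacement, k_range, ...))
  imfs <- vmd_decompose(displacement, k, ...)
  resp <- reconstruct_band(imfs, resp_band)
  heart <- reconstruct_band(imfs, heart_band)
  br <- if (any(resp$values != 0)) estimate_rate(resp, resp_band) else NA_real_
  hr <- if (any(heart$values != 0)) estimate_rate(heart, heart_band) else
    NA_real_
  if (!is.na(br) && (br < 6 || br > 36))
    warning(sprintf("breathing rate %.1f/min outside the physiological band", br))
  if (!is.na(hr) && (hr < 48 || hr > 198))
    warning(sprintf("heart rate %.1f/min outside the physiological band", hr))
  structure(list(respiration = resp, heartbeat = heart,
                 breathing_rate = br, heart_rate = hr,
                 imfs = imfs, k = k),
            class = "vital_signs")
}

#' @export
print.vital_signs <- function(x, ...) {
  cat(sprintf("<vital_signs> breathing %.1f /min, heart %.1f bpm (k = %d)\n",
              x$breathing_rate, x$heart_rate, x$k))
  invisible(x)
}
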