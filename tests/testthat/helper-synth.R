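## Shared fixtures: small configs and tone builders.

tiny_config <- function(...) radar_profile("sim-small", ...)

tone_series <- function(freqs, amps, duration = 60, rate = 20,
                        phases = rep(0, length(freqs))) {
  t <- (seq_len(round(duration * rate)) - 1) / rate
  v <- numeric(length(t))
  for (i in seq_along(freqs))
    v <- v + amps[i] * sin(2 * pi * freqs[i] * t + phases[i])
  slow_time_series(v, rate, "mm")
}

## Wrap a plain slow-time matrix [frames x chirps x samples] as a cube.
as_cube <- function(data, config, complex_iq = FALSE) {
  structure(list(data = data, config = config, complex_iq = complex_iq),
            class = "radar_cube")
}

## Dominant FFT frequencies of a series (top n peaks by magnitude).
fft_peak_freqs <- function(series, n = 2) {
  v <- series$values - mean(series$values)
  m <- Mod(stats::fft(v))[seq_len(length(v) %/% 2)]
  freqs <- (seq_along(m) - 1) * series$rate / length(v)
  ## local maxima only
  loc <- which(diff(sign(diff(m))) == -2) + 1
  loc[order(m[loc], decreasing = TRUE)][seq_len(n)] |> (\(i) freqs[i])()
}
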