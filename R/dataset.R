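#' Generate a balanced labeled dataset of synthetic emotion trials
#'
#' For each of the four emotion presets, draws `n_per_class` trials: a
#' displacement model sampled from the preset box, respiration and heartbeat
#' slow-time series, a procedural face clip reduced to keyframes, and the
#' ground-truth rates. Samples are assigned round-robin to `n_subjects`
#' synthetic subjects so the split protocols have subject structure to work
#' with.
#'
#' Two signal paths are available. `signals = "truth"` synthesizes the
#' respiration and heartbeat series directly from the drawn displacement
#' model (each component plus its share of the measurement noise) — fast, and
#' exactly the decomposition an ideal radar chain would recover.
#' `signals = "radar"` runs the full chain per trial: IF-cube simulation,
#' clutter removal, range FFT, phase extraction, displacement conversion,
#' low-pass and variational mode decomposition with band reconstruction; it
#' is two orders of magnitude slower and is meant for pipeline validation at
#' small `n_per_class`.
#'
#' @param n_per_class Trials per emotion class.
#' @param config A [radar_config()]; sets the slow-time rate and, for the
#'   `"radar"` path, the cube geometry.
#' @param presets Named list of four [emotion_preset()] objects.
#' @param duration Trial length in seconds.
#' @param image_size Rendered keyframe side length in pixels.
#' @param n_keyframes Keyframes per trial fed to the classifier.
#' @param noise_sd Displacement noise SD (mm).
#' @param n_subjects Number of synthetic subject ids.
#' @param signals `"truth"` or `"radar"` (see above).
#' @param vmd_k Mode count for the `"radar"` path decomposition.
#' @param seed Master seed; everything downstream derives from it.
#' @return An object of class `emotion_dataset`: list with `samples` (each a
#'   list `label`, `subject`, `resp`, `heart`, `keyframes`
#'   (`[F x size x size x 3]` array), `truth`) and `manifest` (data.frame with
#'   `sample_id`, `label`, `subject`, `resp_freq_true`, `heart_freq_true`,
#'   `resp_bpm_true`, `heart_bpm_true`, `seed`).
#' @export
make_dataset <- function(n_per_class,
                         config = radar_profile("sim-small"),
                         presets = emotion_presets(),
                         duration = 60,
                         image_size = 227,
                         n_keyframes = 8,
                         noise_sd = 0.05,
                         n_subjects = 5,
                         signals = c("truth", "radar"),
                         vmd_k = 4,
                         seed = 1) {
  signals <- match.arg(signals)
  stopifnot(length(presets) == 4, n_per_class >= 1)
  rate <- config$slow_rate
  labels <- names(presets)
  n_total <- 4L * n_per_class
  sample_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n_total))
  n_video <- (n_keyframes - 1L) * 8L + 11L

  samples <- vector("list", n_total)
  rows <- vector("list", n_total)
  idx <- 0L
  for (li in seq_along(labels)) {
    for (j in seq_len(n_per_class)) {
      idx <- idx + 1L
      s <- sample_seeds[idx]
      preset <- presets[[li]]
      model <- sample_displacement_model(preset, noise_sd = noise_sd,
                                         seed = s)
      if (signals == "truth") {
        sig <- truth_signals(model, duration, rate, seed = s + 1L)
      } else {
        sig <- radar_signals(model, config, duration, vmd_k, seed = s + 1L)
      }
      clip <- render_face_frames(preset, n_frames = n_video,
                                 size = image_size, seed = s + 2L)
      kf <- select_keyframes(clip, out_size = image_size)
      samples[[idx]] <- list(
        label = preset$label,
        subject = ((idx - 1L) %% n_subjects) + 1L,
        resp = sig$resp, heart = sig$heart,
        keyframes = kf$images,
        truth = list(resp_freq = model$resp_freq,
                     heart_freq = model$heart_freq,
                     resp_bpm = 60 * model$resp_freq,
                     heart_bpm = 60 * model$heart_freq),
        seed = s
      )
      rows[[idx]] <- data.frame(
        sample_id = idx, label = preset$label,
        subject = samples[[idx]]$subject,
        resp_freq_true = model$resp_freq,
        heart_freq_true = model$heart_freq,
        resp_bpm_true = 60 * model$resp_freq,
        heart_bpm_true = 60 * model$heart_freq,
        seed = s
      )
    }
  }
  structure(list(samples = samples, manifest = do.call(rbind, rows)),
            class = "emotion_dataset")
}

#' @export
print.emotion_dataset <- function(x, ...) {
  cat(sprintf("<emotion_dataset> %d samples: %s\n", length(x$samples),
              paste(sprintf("%s=%d", names(table(x$manifest$label)),
                            table(x$manifest$label)), collapse = ", ")))
  invisible(x)
}

## Ideal-decomposition signal path: each physiological component plus noise.
truth_signals <- function(model, duration, rate, seed) {
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  resp <- model$resp_amplitude * sin(2 * pi * model$resp_freq * t +
                                     model$resp_phase)
  heart <- model$heart_amplitude * sin(2 * pi * model$heart_freq * t +
                                       model$heart_phase)
  for (h in model$heart_harmonics)
    heart <- heart + model$heart_amplitude * h[2] *
      sin(2 * pi * h[1] * model$heart_freq * t + h[1] * model$heart_phase)
  if (model$noise_sd > 0) {
    nz <- with_seed(seed, matrix(stats::rnorm(2 * n, sd = model$noise_sd), n))
    resp <- resp + nz[, 1]
    heart <- heart + nz[, 2]
  }
  list(resp = slow_time_series(resp, rate, "mm"),
       heart = slow_time_series(heart, rate, "mm"))
}

## Full radar path: simulate the IF cube and run the extraction chain.
radar_signals <- function(model, config, duration, vmd_k, seed) {
  disp <- make_displacement(model, duration, config$slow_rate, seed = seed)
  cube <- simulate_if_cube(config, disp,
                           baseline_range = model$baseline_range,
                           seed = seed + 1L)
  d <- extract_displacement(cube)
  vit <- extract_vitals(d, k = vmd_k)
  list(resp = vit$respiration, heart = vit$heartbeat)
}

#' Write a dataset's manifest and series to a directory
#'
#' Writes `manifest.csv`, per-sample series CSVs and keyframe PNGs under
#' `dir`. Intended for the command-line pipeline; the in-memory object is the
#' primary interface.
#'
#' @param ds An `emotion_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "emotion_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(ds$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  for (i in seq_along(ds$samples)) {
    s <- ds$samples[[i]]
    base <- file.path(dir, sprintf("sample_%04d", i))
    write_series_csv(s$resp, paste0(base, "_resp.csv"))
    write_series_csv(s$heart, paste0(base, "_heart.csv"))
    for (f in seq_len(dim(s$keyframes)[1])) {
      png::writePNG(s$keyframes[f, , , ],
                    paste0(base, sprintf("_kf_%03d.png", f)))
    }
  }
  invisible(dir)
}
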