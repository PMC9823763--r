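#' Procedurally render a synthetic face-video clip
#'
#' Draws a schematic face (elliptical head, eyes with pupils, eyebrows, a
#' parabolic mouth arc) whose geometry is sampled once per clip from the
#' preset's ranges, then jittered slightly per frame to mimic natural head
#' motion. This is a synthetic stand-in for recorded facial video: it carries
#' the coarse geometry that distinguishes expressions (mouth curvature sign,
#' eyebrow slope, eye openness) and nothing else.
#'
#' @param preset An [emotion_preset()] (its `face` ranges are used).
#' @param n_frames Number of frames, at least 11 (one keyframe window).
#' @param size Frame side length in pixels (square frames).
#' @param jitter Per-frame positional jitter SD in normalized face units;
#'   0 yields pixel-identical frames.
#' @param seed Integer seed.
#' @return A `frame_sequence`: list with `frames` (list of
#'   `[size x size x 3]` arrays in \[0, 1\]), `frame_rate` and `source_id`.
#' @export
render_face_frames <- function(preset, n_frames = 40, size = 227,
                               jitter = 0.004, seed = 1) {
  stopifnot(inherits(preset, "emotion_preset"))
  if (n_frames < 11) stop("n_frames must be >= 11 (one keyframe window)")
  stopifnot(size >= 16)
  geom <- with_seed(seed, {
    g <- list(
      mouth_curv = runif_range(preset$face$mouth_curvature),
      brow_angle = runif_range(preset$face$eyebrow_angle),
      eye_open = runif_range(preset$face$eye_openness)
    )
    g$jit <- if (jitter > 0)
      matrix(stats::rnorm(2 * n_frames, sd = jitter), n_frames, 2)
    else matrix(0, n_frames, 2)
    g
  })
  frames <- lapply(seq_len(n_frames), function(f) {
    draw_face(size, geom$mouth_curv, geom$brow_angle, geom$eye_open,
              dx = geom$jit[f, 1], dy = geom$jit[f, 2])
  })
  structure(list(frames = frames, frame_rate = 15, source_id = preset$label),
            class = "frame_sequence")
}

runif_range <- function(rg) stats::runif(1, rg[1], rg[2])

## One face frame on a [size x size] grid. Coordinates are normalized to
## [0, 1] with y increasing downward; mouth_curv > 0 means a smile.
draw_face <- function(size, mouth_curv, brow_angle, eye_open, dx = 0, dy = 0) {
  xs <- (seq_len(size) - 0.5) / size
  ys <- (seq_len(size) - 0.5) / size
  X <- matrix(xs, size, size, byrow = TRUE)
  Y <- matrix(ys, size, size)
  cx <- 0.5 + dx; cy <- 0.5 + dy

  img <- array(0.15, dim = c(size, size, 3))  # dark background
  paint <- function(mask, col) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- col[ch]
      img[, , ch] <<- plane
    }
  }

  head <- ((X - cx) / 0.34)^2 + ((Y - cy) / 0.44)^2 <= 1
  paint(head, c(0.92, 0.78, 0.62))

  for (s in c(-1, 1)) {
    ex <- cx + s * 0.14; ey <- cy - 0.10
    eye <- ((X - ex) / 0.065)^2 + ((Y - ey) / (0.042 * eye_open))^2 <= 1
    paint(eye, c(0.98, 0.98, 0.98))
    pupil <- ((X - ex) / 0.022)^2 + ((Y - ey) / (0.022 * eye_open))^2 <= 1
    paint(pupil, c(0.10, 0.08, 0.08))
    ## Eyebrow: slanted bar above the eye. brow_angle > 0 raises the outer
    ## end (surprise/happy); < 0 lowers it toward the nose (anger).
    bx <- X - ex; by <- Y - (ey - 0.085)
    slope <- tan(brow_angle) * s
    brow <- abs(by - slope * bx) <= 0.016 & abs(bx) <= 0.085
    paint(brow, c(0.25, 0.15, 0.10))
  }

  ## Mouth: parabolic arc; on a screen y-axis a smile bends downward in the
  ## middle, i.e. corners sit above the centre.
  mx <- X - cx; my <- Y - (cy + 0.24)
  arc <- my - (-mouth_curv) * ((mx / 0.16)^2 - 0.5)
  mouth <- abs(arc) <= 0.018 & abs(mx) <= 0.16
  paint(mouth, c(0.55, 0.15, 0.15))

  img
}

#' Per-emotion synthetic presets
#'
#' A preset couples a box of physiological parameters (respiration and
#' heartbeat frequency/amplitude ranges the displacement model is drawn from)
#' with facial-geometry ranges for the procedural renderer. The four presets
#' are synthetic conventions chosen to be separable yet overlapping enough
#' that no single modality suffices: happy and sad share most of their
#' heart-rate range and are told apart chiefly by mouth curvature, while
#' relaxed and angry separate on breathing depth and rate.
#'
#' * relaxed: slow deep breathing (~0.15-0.25 Hz, 5-7 mm), HR ~60-70 bpm,
#'   neutral face.
#' * happy: moderate breathing, HR ~72-78 bpm, strongly positive mouth
#'   curvature, raised brows.
#' * sad: shallow breathing (2-3.5 mm), HR ~66-74 bpm, negative curvature,
#'   drooping brows and eyes.
#' * angry: fast breathing (0.40-0.55 Hz), HR ~90-100 bpm, flat-to-negative
#'   mouth, sharply lowered brows, narrowed eyes.
#'
#' @param label One of `"relaxed"`, `"happy"`, `"sad"`, `"angry"`.
#' @return An `emotion_preset` (or, from [emotion_presets()], a named list of
#'   all four).
#' @export
emotion_preset <- function(label = c("relaxed", "happy", "sad", "angry")) {
  label <- match.arg(label)
  p <- switch(label,
    relaxed = list(
      resp_freq = c(0.15, 0.25), resp_amp = c(5.0, 7.0),
      heart_freq = c(1.00, 1.17), heart_amp = c(0.4, 0.6),
      face = list(mouth_curvature = c(0.00, 0.04),
                  eyebrow_angle = c(-0.05, 0.05),
                  eye_openness = c(0.9, 1.1))),
    happy = list(
      resp_freq = c(0.25, 0.35), resp_amp = c(4.0, 6.0),
      heart_freq = c(1.20, 1.30), heart_amp = c(0.4, 0.6),
      face = list(mouth_curvature = c(0.10, 0.16),
                  eyebrow_angle = c(0.15, 0.30),
                  eye_openness = c(1.0, 1.2))),
    sad = list(
      resp_freq = c(0.20, 0.30), resp_amp = c(2.0, 3.5),
      heart_freq = c(1.10, 1.23), heart_amp = c(0.3, 0.5),
      face = list(mouth_curvature = c(-0.16, -0.10),
                  eyebrow_angle = c(-0.30, -0.15),
                  eye_openness = c(0.6, 0.8))),
    angry = list(
      resp_freq = c(0.40, 0.55), resp_amp = c(4.0, 6.0),
      heart_freq = c(1.50, 1.67), heart_amp = c(0.5, 0.7),
      face = list(mouth_curvature = c(-0.06, 0.00),
                  eyebrow_angle = c(-0.50, -0.35),
                  eye_openness = c(0.5, 0.7)))
  )
  structure(c(list(label = label), p), class = "emotion_preset")
}

#' @rdname emotion_preset
#' @export
emotion_presets <- function() {
  labs <- c("relaxed", "happy", "sad", "angry")
  stats::setNames(lapply(labs, emotion_preset), labs)
}

#' Draw a displacement model from a preset's parameter box
#'
#' Uniform draw of respiration/heartbeat frequency and amplitude from the
#' preset ranges, with random component phases so trials differ by more than
#' noise realizations.
#'
#' @param preset An [emotion_preset()].
#' @param noise_sd Displacement noise SD in mm.
#' @param baseline_range Chest standoff in metres.
#' @param seed Integer seed.
#' @return A [displacement_model()].
#' @export
sample_displacement_model <- function(preset, noise_sd = 0.05,
                                      baseline_range = 0.5, seed = 1) {
  stopifnot(inherits(preset, "emotion_preset"))
  with_seed(seed, {
    displacement_model(
      resp_amplitude = runif_range(preset$resp_amp),
      resp_freq = runif_range(preset$resp_freq),
      heart_amplitude = runif_range(preset$heart_amp),
      heart_freq = runif_range(preset$heart_freq),
      noise_sd = noise_sd,
      baseline_range = baseline_range,
      resp_phase = stats::runif(1, 0, 2 * pi),
      heart_phase = stats::runif(1, 0, 2 * pi)
    )
  })
}
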