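#' Detect and crop the largest face in a frame
#'
#' The detector is a pluggable contract: any function taking a frame array
#' and returning a data.frame of candidate boxes with columns `x`, `y`
#' (1-based top-left, column/row), `w`, `h`, `confidence`. The crop keeps the
#' largest-area box. A frame with no detection is not an error — `NULL` is
#' returned and the frame is excluded downstream. A cascade classifier (e.g.
#' LBP-AdaBoost) slots in as a production detector; the package ships a
#' brightness-based detector suited to its synthetic faces and a fixed-box
#' oracle for tests.
#'
#' @param frame `[H x W x 3]` array in \[0, 1\].
#' @param detector Detector function (see above).
#' @return The cropped array, or `NULL` when no face is found.
#' @seealso [detector_brightness()], [detector_oracle()]
#' @export
detect_and_crop_face <- function(frame, detector = detector_brightness()) {
  boxes <- detector(frame)
  if (is.null(boxes) || nrow(boxes) == 0) return(NULL)
  best <- boxes[which.max(boxes$w * boxes$h), ]
  rows <- best$y:(best$y + best$h - 1)
  cols <- best$x:(best$x + best$w - 1)
  rows <- rows[rows >= 1 & rows <= dim(frame)[1]]
  cols <- cols[cols >= 1 & cols <= dim(frame)[2]]
  if (!length(rows) || !length(cols)) return(NULL)
  frame[rows, cols, , drop = FALSE]
}

#' Brightness-threshold face detector for synthetic frames
#'
#' Returns the bounding box of pixels whose channel mean exceeds `thresh` —
#' the rendered head is bright on a dark background. Yields zero boxes on
#' blank frames.
#'
#' @param thresh Luminance threshold in \[0, 1\].
#' @return A detector function for [detect_and_crop_face()].
#' @export
detector_brightness <- function(thresh = 0.4) {
  function(frame) {
    lum <- (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3
    hit <- which(lum > thresh, arr.ind = TRUE)
    if (nrow(hit) == 0)
      return(data.frame(x = integer(), y = integer(), w = integer(),
                        h = integer(), confidence = numeric()))
    data.frame(x = min(hit[, 2]), y = min(hit[, 1]),
               w = diff(range(hit[, 2])) + 1L,
               h = diff(range(hit[, 1])) + 1L, confidence = 1)
  }
}

#' Fixed-box oracle detector
#'
#' @param boxes data.frame of boxes (`x`, `y`, `w`, `h`, `confidence`)
#'   returned for every frame.
#' @return A detector function.
#' @export
detector_oracle <- function(boxes) {
  force(boxes)
  function(frame) boxes
}

#' Concatenated per-channel histogram of a frame
#'
#' Equal-width bins on \[0, 1\] per channel, concatenated and normalized so
#' the whole vector sums to 1.
#'
#' @param image `[H x W x C]` array in \[0, 1\].
#' @param bins_per_channel Bins per channel (default 32).
#' @return Numeric vector of length `C * bins_per_channel`.
#' @export
frame_histogram <- function(image, bins_per_channel = 32) {
  stopifnot(length(dim(image)) == 3, bins_per_channel >= 1)
  nch <- dim(image)[3]
  edges <- seq(0, 1, length.out = bins_per_channel + 1)
  h <- unlist(lapply(seq_len(nch), function(ch) {
    v <- image[, , ch]
    tabulate(findInterval(v, edges, all.inside = TRUE), bins_per_channel)
  }))
  h / sum(h)
}

#' Chi-square distance between two histograms
#'
#' `sum((h1 - h2)^2 / (h1 + h2))` over bins with a nonzero denominator.
#' Symmetric and zero iff the histograms are identical.
#'
#' @param h1,h2 Histogram vectors of equal length.
#' @return Non-negative scalar.
#' @export
chi_square_distance <- function(h1, h2) {
  stopifnot(length(h1) == length(h2))
  num <- (h1 - h2)^2
  den <- h1 + h2
  keep <- den > 0
  sum(num[keep] / den[keep])
}

#' Select stable keyframes from a frame sequence
#'
#' Slides a window of `2i + 1` frames (11 for the default `i = 5`) in steps
#' of `stride` (8) while a full window fits. Within a window each frame is
#' scored by the summed chi-square distance between its histogram and those
#' of its in-window temporal neighbours (previous and next frame; edge
#' frames have one neighbour); the lowest-scoring — most stable — frame is
#' the window's keyframe, ties resolving to the earliest. Keyframes are
#' resized to `out_size x out_size x 3`.
#'
#' @param seq A `frame_sequence` (see [render_face_frames()]) or plain list
#'   of `[H x W x 3]` arrays.
#' @param i Window half-width; the window holds `2i + 1` frames.
#' @param stride Window step in frames.
#' @param bins_per_channel Histogram resolution.
#' @param out_size Output side length in pixels (227 matches the classifier
#'   input).
#' @return A `keyframe_set`: `images` (`[K x out_size x out_size x 3]`),
#'   `source_indices` (strictly increasing frame indices).
#' @export
select_keyframes <- function(seq, i = 5, stride = 8, bins_per_channel = 32,
                             out_size = 227) {
  frames <- if (inherits(seq, "frame_sequence")) seq$frames else seq
  frames <- frames[!vapply(frames, is.null, logical(1))]
  n <- length(frames)
  win <- 2L * i + 1L
  if (n < win)
    stop(sprintf("need at least %d usable frames, got %d", win, n))
  hists <- lapply(frames, frame_histogram, bins_per_channel = bins_per_channel)

  starts <- seq(1L, n - win + 1L, by = stride)
  picks <- integer(length(starts))
  last <- 0L
  for (wi in seq_along(starts)) {
    s <- starts[wi]
    idx <- s:(s + win - 1L)
    score <- vapply(seq_along(idx), function(j) {
      sc <- 0
      if (j > 1) sc <- sc + chi_square_distance(hists[[idx[j]]],
                                                hists[[idx[j - 1]]])
      if (j < win) sc <- sc + chi_square_distance(hists[[idx[j]]],
                                                  hists[[idx[j + 1]]])
      sc
    }, numeric(1))
    ## overlapping windows may not re-pick at or before the previous
    ## keyframe: indices stay strictly increasing
    ok <- idx > last
    picks[wi] <- idx[ok][which.min(score[ok])]
    last <- picks[wi]
  }
  images <- array(0, dim = c(length(picks), out_size, out_size, 3))
  for (p in seq_along(picks))
    images[p, , , ] <- resize_frame(frames[[picks[p]]], out_size, out_size)
  structure(list(images = images, source_indices = picks),
            class = "keyframe_set")
}

#' Bilinear frame resize
#'
#' @param image `[H x W x C]` array.
#' @param height,width Target size in pixels.
#' @return `[height x width x C]` array, values clamped to \[0, 1\].
#' @export
resize_frame <- function(image, height = 227, width = 227) {
  d <- dim(image)
  if (d[1] == height && d[2] == width) return(image)
  out <- EBImage::resize(image, w = height, h = width, filter = "bilinear")
  out <- pmin(pmax(out, 0), 1)
  array(out, dim = c(height, width, d[3]))
}
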