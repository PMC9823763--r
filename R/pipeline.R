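## Command-style pipeline entry points. Each function is a thin, file-based
## wrapper over the package API so the whole chain can be driven from a
## shell (see inst/cli/remotion.R) or scripted; every command writes its
## effective configuration to the output directory for reproducibility.

log_config <- function(out_dir, cmd, cfg) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(c(list(command = cmd), cfg),
                       file.path(out_dir, paste0(cmd, "_config.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
}

#' Pipeline command: generate a synthetic dataset on disk
#'
#' @param out_dir Output directory.
#' @param n_per_class Trials per emotion.
#' @param duration Trial seconds.
#' @param image_size,n_keyframes Keyframe geometry.
#' @param signals `"truth"` or `"radar"` (see [make_dataset()]).
#' @param seed Master seed.
#' @return The manifest data.frame, invisibly.
#' @export
run_simulate <- function(out_dir, n_per_class = 5, duration = 60,
                         image_size = 64, n_keyframes = 4,
                         signals = "truth", seed = 1) {
  cfg <- list(n_per_class = n_per_class, duration = duration,
              image_size = image_size, n_keyframes = n_keyframes,
              signals = signals, seed = seed)
  log_config(out_dir, "simulate", cfg)
  ds <- make_dataset(n_per_class, duration = duration,
                     image_size = image_size, n_keyframes = n_keyframes,
                     signals = signals, seed = seed)
  write_dataset(ds, out_dir)
  invisible(ds$manifest)
}

#' Pipeline command: vitals from a radar cube file
#'
#' MTI -> range FFT -> target bin -> phase -> displacement -> low-pass ->
#' VMD band reconstruction -> rates. Writes `displacement.csv`,
#' `respiration.csv`, `heartbeat.csv`, `imfs.csv` and `vitals.csv` into
#' `out_dir`.
#'
#' @param cube_path A cube container ([write_radar_cube()]) or raw int16
#'   capture (with `raw_config` given).
#' @param out_dir Output directory.
#' @param raw_config `radar_config` for raw captures; `NULL` for containers.
#' @param mti_window,cutoff,k Processing knobs (see [extract_displacement()]
#'   and [extract_vitals()]).
#' @return The `vital_signs` object, invisibly.
#' @export
run_extract <- function(cube_path, out_dir, raw_config = NULL,
                        mti_window = 20, cutoff = 3.3, k = NULL) {
  cfg <- list(cube_path = cube_path, mti_window = mti_window,
              cutoff = cutoff, k = k)
  log_config(out_dir, "extract", cfg)
  cube <- if (is.null(raw_config)) read_radar_cube(cube_path)
          else read_raw_int16(cube_path, raw_config)
  disp <- extract_displacement(cube, mti_window = mti_window,
                               cutoff = cutoff)
  write_series_csv(disp, file.path(out_dir, "displacement.csv"))
  vit <- extract_vitals(disp, k = k)
  write_series_csv(vit$respiration, file.path(out_dir, "respiration.csv"))
  write_series_csv(vit$heartbeat, file.path(out_dir, "heartbeat.csv"))
  write_imf_csv(vit$imfs, file.path(out_dir, "imfs.csv"))
  utils::write.csv(data.frame(breathing_rate = vit$breathing_rate,
                              heart_rate = vit$heart_rate, k = vit$k),
                   file.path(out_dir, "vitals.csv"), row.names = FALSE)
  invisible(vit)
}

#' Pipeline command: keyframes from a directory of frames
#'
#' Reads PNG frames in lexical order, optionally detects and crops the
#' face, selects keyframes and writes them as PNGs plus an index CSV.
#'
#' @param frames_dir Directory of PNG frames.
#' @param out_dir Output directory.
#' @param i,stride,out_size Keyframe parameters (see [select_keyframes()]).
#' @param detect Apply [detect_and_crop_face()] with the brightness
#'   detector before selection.
#' @return The `keyframe_set`, invisibly.
#' @export
run_keyframes <- function(frames_dir, out_dir, i = 5, stride = 8,
                          out_size = 227, detect = FALSE) {
  cfg <- list(frames_dir = frames_dir, i = i, stride = stride,
              out_size = out_size, detect = detect)
  log_config(out_dir, "keyframes", cfg)
  paths <- sort(list.files(frames_dir, pattern = "\\.png$",
                           full.names = TRUE))
  if (!length(paths)) stop("no PNG frames in ", frames_dir)
  frames <- lapply(paths, function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  })
  if (detect)
    frames <- lapply(frames, detect_and_crop_face)
  kf <- select_keyframes(frames, i = i, stride = stride,
                         out_size = out_size)
  for (j in seq_len(dim(kf$images)[1]))
    png::writePNG(kf$images[j, , , ],
                  file.path(out_dir, sprintf("keyframe_%03d.png", j)))
  utils::write.csv(data.frame(keyframe = seq_along(kf$source_indices),
                              source_frame = kf$source_indices),
                   file.path(out_dir, "keyframes.csv"), row.names = FALSE)
  invisible(kf)
}

#' Pipeline command: train and evaluate the classifier on a dataset
#'
#' Splits by the chosen protocol, trains the network, writes the training
#' history, test confusion matrix and metric report to `out_dir`, and saves
#' the checkpoint.
#'
#' @param ds An `emotion_dataset` (from [make_dataset()]).
#' @param out_dir Output directory.
#' @param mode Split protocol (see [split_protocols()]).
#' @param epochs,batch_size,lr Training settings.
#' @param seed Seed (weights, shuffling, split).
#' @return List with `model`, `report`, `cm`, `split`, invisibly.
#' @export
run_train <- function(ds, out_dir, mode = "person_dependent", epochs = 30,
                      batch_size = 16, lr = 1e-3, seed = 1) {
  cfg <- list(mode = mode, epochs = epochs, batch_size = batch_size,
              lr = lr, seed = seed)
  log_config(out_dir, "train", cfg)
  split <- split_protocols(ds$manifest, mode, seed = seed)
  s1 <- ds$samples[[1]]
  model <- emotion_net(input_length = length(s1$resp$values),
                       image_size = dim(s1$keyframes)[2],
                       n_keyframes = dim(s1$keyframes)[1], seed = seed)
  model <- train_emotion_net(model, ds$samples[split$train],
                             ds$samples[split$val], epochs = epochs,
                             batch_size = batch_size, lr = lr, seed = seed)
  utils::write.csv(model$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  pred <- predict_emotion(model, ds$samples[split$test])
  truth <- vapply(ds$samples[split$test], `[[`, character(1), "label")
  cm <- confusion(truth, pred$labels, labels = model$spec$labels)
  rep <- metrics(cm)
  utils::write.csv(as.data.frame(unclass(cm)),
                   file.path(out_dir, "confusion.csv"))
  jsonlite::write_json(unclass(rep), file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  save_emotion_net(model, file.path(out_dir, "checkpoint"))
  invisible(list(model = model, report = rep, cm = cm, split = split))
}

#' Pipeline command: full synthetic end-to-end run
#'
#' Dataset generation, training under the requested protocol and test
#' evaluation, all from one seed.
#'
#' @param out_dir Output directory.
#' @param n_per_class Trials per emotion.
#' @param mode Split protocol.
#' @param image_size,n_keyframes,epochs See the respective commands.
#' @param seed Master seed.
#' @return The [run_train()] result, invisibly.
#' @export
run_e2e <- function(out_dir, n_per_class = 25, mode = "person_dependent",
                    image_size = 32, n_keyframes = 4, epochs = 25,
                    seed = 1) {
  cfg <- list(n_per_class = n_per_class, mode = mode,
              image_size = image_size, n_keyframes = n_keyframes,
              epochs = epochs, seed = seed)
  log_config(out_dir, "e2e", cfg)
  ds <- make_dataset(n_per_class, image_size = image_size,
                     n_keyframes = n_keyframes, seed = seed)
  run_train(ds, out_dir, mode = mode, epochs = epochs, seed = seed)
}
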