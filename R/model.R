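#' Branch specifications of the emotion network
#'
#' The two physiological branches are four-block 1-D CNNs and the facial
#' branch a four-block 2-D CNN; each block is convolution -> max pooling ->
#' batch normalization -> ELU. Kernel/filter/stride settings per block:
#'
#' 1-D: conv(5, 16, s1) + pool(4); conv(5, 32, s1) + pool(2);
#' conv(5, 32, s2) + pool(2); conv(5, 64, s2) + pool(2).
#'
#' 2-D: conv(3x3, 32, s1) + pool(2x2); conv(3x3, 64, s1) + pool(2x2);
#' conv(3x3, 96, s1) + pool(4x4); conv(3x3, 96, s1) + pool(4x4).
#'
#' Convolutions use 'same' padding (strides alone downsample); pooling is
#' floor-mode with stride equal to the window.
#'
#' @return A list of per-block settings (`kernel`, `filters`, `conv_stride`,
#'   `pool`).
#' @export
branch_spec_1d <- function() list(
  list(kernel = 5L, filters = 16L, conv_stride = 1L, pool = 4L),
  list(kernel = 5L, filters = 32L, conv_stride = 1L, pool = 2L),
  list(kernel = 5L, filters = 32L, conv_stride = 2L, pool = 2L),
  list(kernel = 5L, filters = 64L, conv_stride = 2L, pool = 2L)
)

#' @rdname branch_spec_1d
#' @export
branch_spec_2d <- function() list(
  list(kernel = 3L, filters = 32L, conv_stride = 1L, pool = 2L),
  list(kernel = 3L, filters = 64L, conv_stride = 1L, pool = 2L),
  list(kernel = 3L, filters = 96L, conv_stride = 1L, pool = 4L),
  list(kernel = 3L, filters = 96L, conv_stride = 1L, pool = 4L)
)

#' Build the three-branch CNN + GRU emotion classifier
#'
#' Two 1-D CNN branches digest the respiration and heartbeat series (keeping
#' a reduced temporal axis), a 2-D CNN digests each keyframe to a
#' 96-dimensional vector (global average over space). Per time step of the
#' 1-D branches the three feature vectors are concatenated (respiration,
#' heartbeat, face — the face sequence is nearest-index resampled to the
#' 1-D temporal length), and the fused sequence drives a 64-unit GRU whose
#' final state feeds a softmax dense layer over the four emotions.
#'
#' @param input_length Length of the physiological series (default 1200 =
#'   60 s at 20 Hz).
#' @param image_size Keyframe side length in pixels.
#' @param n_keyframes Keyframes per sample.
#' @param n_classes Number of emotion classes.
#' @param gru_units GRU hidden width.
#' @param seed Seed for weight initialization.
#' @return An object of class `emotion_net`.
#' @export
emotion_net <- function(input_length = 1200, image_size = 227,
                        n_keyframes = 8, n_classes = 4, gru_units = 64,
                        seed = 1) {
  spec1 <- branch_spec_1d()
  spec2 <- branch_spec_2d()
  shapes1 <- branch_shapes(input_length, spec1)
  shapes2 <- branch_shapes(image_size, spec2)
  T_out <- shapes1$len[length(shapes1$len)]
  c1 <- spec1[[length(spec1)]]$filters
  c2 <- spec2[[length(spec2)]]$filters
  fused_dim <- 2L * c1 + c2

  params <- list()
  bn_stats <- list()
  init <- function(dims, fan_in) {
    array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
  }
  add_branch <- function(prefix, spec, cin0, two_d) {
    cin <- cin0
    for (b in seq_along(spec)) {
      s <- spec[[b]]
      key <- sprintf("%s.c%d", prefix, b)
      if (two_d) {
        params[[paste0(key, ".W")]] <<-
          init(c(s$kernel, s$kernel, cin, s$filters),
               s$kernel^2 * cin)
      } else {
        params[[paste0(key, ".W")]] <<-
          init(c(s$kernel, cin, s$filters), s$kernel * cin)
      }
      params[[paste0(key, ".b")]] <<- numeric(s$filters)
      params[[sprintf("%s.bn%d.gamma", prefix, b)]] <<- rep(1, s$filters)
      params[[sprintf("%s.bn%d.beta", prefix, b)]] <<- numeric(s$filters)
      bn_stats[[sprintf("%s.bn%d", prefix, b)]] <<-
        list(mean = numeric(s$filters), var = rep(1, s$filters))
      cin <- s$filters
    }
  }
  with_seed(seed, {
    add_branch("resp", spec1, 1L, FALSE)
    add_branch("heart", spec1, 1L, FALSE)
    add_branch("face", spec2, 3L, TRUE)
    H <- gru_units
    for (gate in c("z", "r", "h")) {
      params[[paste0("gru.W", gate)]] <- init(c(fused_dim, H), fused_dim)
      params[[paste0("gru.U", gate)]] <- init(c(H, H), H)
      params[[paste0("gru.b", gate)]] <- numeric(H)
    }
    params[["out.W"]] <- init(c(H, n_classes), H)
    params[["out.b"]] <- numeric(n_classes)
  })

  structure(list(
    params = params, bn_stats = bn_stats,
    spec = list(input_length = input_length, image_size = image_size,
                n_keyframes = n_keyframes, n_classes = n_classes,
                gru_units = gru_units, T_out = T_out,
                fused_dim = fused_dim, spec1 = spec1, spec2 = spec2,
                labels = c("relaxed", "happy", "sad", "angry"))
  ), class = "emotion_net")
}

#' @export
print.emotion_net <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<emotion_net> series %d, %d keyframes of %dpx -> T=%d, fused %d, GRU %d, %d classes (%s parameters)\n",
              x$spec$input_length, x$spec$n_keyframes, x$spec$image_size,
              x$spec$T_out, x$spec$fused_dim, x$spec$gru_units,
              x$spec$n_classes, format(np, big.mark = ",")))
  invisible(x)
}

## Per-block lengths of a branch (after conv, after pool), one side.
branch_shapes <- function(len, spec) {
  lens <- integer(0)
  for (s in spec) {
    len <- conv_out_len(len, s$conv_stride)
    len <- pool_out_len(len, s$pool)
    lens <- c(lens, len)
  }
  list(len = lens)
}

## Forward through one branch. X: [N, L, C] or [N, H, W, C].
branch_forward <- function(params, bn_stats, prefix, spec, X, two_d,
                           training) {
  caches <- vector("list", length(spec))
  for (b in seq_along(spec)) {
    s <- spec[[b]]
    W <- params[[sprintf("%s.c%d.W", prefix, b)]]
    bb <- params[[sprintf("%s.c%d.b", prefix, b)]]
    cv <- if (two_d) conv2d_forward(X, W, bb, s$conv_stride)
          else conv1d_forward(X, W, bb, s$conv_stride)
    pl <- if (two_d) maxpool2d_forward(cv$out, s$pool)
          else maxpool1d_forward(cv$out, s$pool)
    key <- sprintf("%s.bn%d", prefix, b)
    bn <- batchnorm_forward(pl$out, params[[paste0(key, ".gamma")]],
                            params[[paste0(key, ".beta")]],
                            bn_stats[[key]], training)
    bn_stats[[key]] <- bn$stats
    ac <- elu_forward(bn$out)
    caches[[b]] <- list(conv = cv$cache, pool = pl$cache, bn = bn$cache,
                        elu = ac$cache)
    X <- ac$out
  }
  list(out = X, caches = caches, bn_stats = bn_stats)
}

branch_backward <- function(params, prefix, spec, caches, dY, two_d) {
  grads <- list()
  for (b in rev(seq_along(spec))) {
    cc <- caches[[b]]
    dY <- elu_backward(cc$elu, dY)
    bnb <- batchnorm_backward(cc$bn, dY)
    key <- sprintf("%s.bn%d", prefix, b)
    grads[[paste0(key, ".gamma")]] <- bnb$dgamma
    grads[[paste0(key, ".beta")]] <- bnb$dbeta
    dY <- if (two_d) maxpool2d_backward(cc$pool, bnb$dx)
          else maxpool1d_backward(cc$pool, bnb$dx)
    cvb <- if (two_d) conv2d_backward(cc$conv, dY)
           else conv1d_backward(cc$conv, dY)
    grads[[sprintf("%s.c%d.W", prefix, b)]] <- cvb$dW
    grads[[sprintf("%s.c%d.b", prefix, b)]] <- cvb$db
    dY <- cvb$dx
  }
  list(grads = grads, dx = dY)
}

## Nearest-index map from the keyframe axis (length f) to the fused temporal
## axis (length t).
face_resample_index <- function(t_len, f_len) {
  pmin(f_len, pmax(1L, as.integer(round((seq_len(t_len) - 0.5) *
                                          f_len / t_len + 0.5))))
}

#' Forward pass of the emotion network
#'
#' @param model An [emotion_net()].
#' @param batch List with `resp` (`[N x L]`), `heart` (`[N x L]`) and
#'   `faces` (`[N x F x S x S x 3]`).
#' @param training Batch-norm mode; training mode also returns caches for
#'   backpropagation and updated running statistics.
#' @param ablate Optional character vector among `"resp"`, `"heart"`,
#'   `"face"`: the named branch features are zeroed before fusion (used to
#'   probe how informative each modality is).
#' @return List with `probs` (`[N x n_classes]`), `logits`, and (when
#'   `training`) `caches` and `bn_stats`.
#' @export
net_forward <- function(model, batch, training = FALSE, ablate = character()) {
  p <- model$params
  sp <- model$spec
  N <- nrow(batch$resp)
  Xr <- array(batch$resp, c(N, ncol(batch$resp), 1))
  Xh <- array(batch$heart, c(N, ncol(batch$heart), 1))
  Fd <- dim(batch$faces)
  stopifnot(length(Fd) == 5)
  Xf <- batch$faces
  dim(Xf) <- c(Fd[1] * Fd[2], Fd[3], Fd[4], Fd[5])

  bs <- model$bn_stats
  br <- branch_forward(p, bs, "resp", sp$spec1, Xr, FALSE, training)
  bs <- br$bn_stats
  bh <- branch_forward(p, bs, "heart", sp$spec1, Xh, FALSE, training)
  bs <- bh$bn_stats
  ## Face frames run through the 2-D branch as one big batch [N*F, S, S, 3].
  ## Note the flatten above interleaves N within F (N fastest), so a row n
  ## of the [N, F, C] reshape below recovers sample n's frames in order.
  bf <- branch_forward(p, bs, "face", sp$spec2, Xf, TRUE, training)
  bs <- bf$bn_stats

  fdim <- dim(bf$out)                       # [N*F, h, w, 96]
  gap <- apply(bf$out, c(1, 4), mean)       # [N*F, 96]
  face_feats <- gap
  dim(face_feats) <- c(Fd[1], Fd[2], dim(gap)[2])   # [N, F, 96]

  Tt <- dim(br$out)[2]
  fmap <- face_resample_index(Tt, Fd[2])
  face_seq <- face_feats[, fmap, , drop = FALSE]     # [N, T, 96]

  rout <- br$out; hout <- bh$out; fout <- face_seq
  if ("resp" %in% ablate) rout <- rout * 0
  if ("heart" %in% ablate) hout <- hout * 0
  if ("face" %in% ablate) fout <- fout * 0
  fused <- array(0, c(N, Tt, sp$fused_dim))
  c1 <- dim(rout)[3]
  c2f <- dim(fout)[3]
  fused[, , seq_len(c1)] <- rout
  fused[, , c1 + seq_len(c1)] <- hout
  fused[, , 2 * c1 + seq_len(c2f)] <- fout

  gp <- list(Wz = p[["gru.Wz"]], Uz = p[["gru.Uz"]], bz = p[["gru.bz"]],
             Wr = p[["gru.Wr"]], Ur = p[["gru.Ur"]], br = p[["gru.br"]],
             Wh = p[["gru.Wh"]], Uh = p[["gru.Uh"]], bh = p[["gru.bh"]])
  gr <- gru_forward(fused, gp)
  dn <- dense_forward(gr$out, p[["out.W"]], p[["out.b"]])
  probs <- softmax(dn$out)

  res <- list(probs = probs, logits = dn$out)
  if (training) {
    res$caches <- list(resp = br$caches, heart = bh$caches,
                       face = bf$caches, gru = gr$cache, dense = dn$cache,
                       fdim = fdim, Fd = Fd, fmap = fmap, Tt = Tt, c1 = c1,
                       c2 = c2f, ablate = ablate)
    res$bn_stats <- bs
  }
  res
}

## Backward pass; returns the full gradient list.
net_backward <- function(model, fwd, dlogits) {
  p <- model$params
  sp <- model$spec
  cc <- fwd$caches
  dnb <- dense_backward(cc$dense, dlogits)
  grads <- list("out.W" = dnb$dW, "out.b" = dnb$db)
  grb <- gru_backward(cc$gru, dnb$dx)
  for (gate in c("z", "r", "h")) {
    grads[[paste0("gru.W", gate)]] <- grb$grads[[paste0("W", gate)]]
    grads[[paste0("gru.U", gate)]] <- grb$grads[[paste0("U", gate)]]
    grads[[paste0("gru.b", gate)]] <- grb$grads[[paste0("b", gate)]]
  }
  dfused <- grb$dx                          # [N, T, fused]
  c1 <- cc$c1; c2 <- cc$c2; Tt <- cc$Tt; Fd <- cc$Fd
  drout <- dfused[, , seq_len(c1), drop = FALSE]
  dhout <- dfused[, , c1 + seq_len(c1), drop = FALSE]
  dfout <- dfused[, , 2 * c1 + seq_len(c2), drop = FALSE]
  if ("resp" %in% cc$ablate) drout <- drout * 0
  if ("heart" %in% cc$ablate) dhout <- dhout * 0
  if ("face" %in% cc$ablate) dfout <- dfout * 0

  ## undo nearest-index resampling: scatter-add over the time axis
  dface_feats <- array(0, c(Fd[1], Fd[2], c2))
  for (t in seq_len(Tt)) {
    f <- cc$fmap[t]
    dface_feats[, f, ] <- dface_feats[, f, ] + dfout[, t, ]
  }
  dgap <- dface_feats
  dim(dgap) <- c(Fd[1] * Fd[2], c2)
  ## undo global average pooling
  fdim <- cc$fdim
  dconvf <- array(0, fdim)
  scale <- 1 / (fdim[2] * fdim[3])
  for (ch in seq_len(fdim[4]))
    dconvf[, , , ch] <- array(rep(dgap[, ch], fdim[2] * fdim[3]),
                              fdim[1:3]) * scale

  gf <- branch_backward(p, "face", sp$spec2, cc$face, dconvf, TRUE)
  gh <- branch_backward(p, "heart", sp$spec1, cc$heart, dhout, FALSE)
  gr2 <- branch_backward(p, "resp", sp$spec1, cc$resp, drout, FALSE)
  c(grads, gf$grads, gh$grads, gr2$grads)
}

#' Assemble dataset samples into model input batches
#'
#' Stacks series into matrices and keyframe stacks into a 5-D array, scales
#' the series by fixed physical constants (respiration by 1/10 mm, heartbeat
#' by 1/1 mm) so both enter at order one while amplitude differences between
#' emotions remain visible, and encodes labels as integers.
#'
#' @param samples List of dataset samples (see [make_dataset()]).
#' @param labels Class label ordering.
#' @return List with `resp`, `heart`, `faces`, `y` (integer labels or NULL).
#' @export
as_model_batch <- function(samples,
                           labels = c("relaxed", "happy", "sad", "angry")) {
  N <- length(samples)
  L <- length(samples[[1]]$resp$values)
  kd <- dim(samples[[1]]$keyframes)
  resp <- matrix(0, N, L)
  heart <- matrix(0, N, L)
  faces <- array(0, c(N, kd[1], kd[2], kd[3], kd[4]))
  y <- integer(N)
  for (i in seq_len(N)) {
    s <- samples[[i]]
    resp[i, ] <- s$resp$values / 10
    heart[i, ] <- s$heart$values / 1
    faces[i, , , , ] <- s$keyframes
    y[i] <- match(s$label, labels)
  }
  list(resp = resp, heart = heart, faces = faces,
       y = if (anyNA(y)) NULL else y)
}

#' Train the emotion network
#'
#' Mini-batch Adam on softmax cross-entropy. Deterministic for a fixed seed
#' (weight init, shuffling). Returns the parameters of the epoch with the
#' best validation accuracy.
#'
#' @param model An [emotion_net()].
#' @param train_samples,val_samples Lists of dataset samples.
#' @param epochs,batch_size,lr Optimization settings.
#' @param seed Seed for shuffling.
#' @param verbose Print per-epoch progress.
#' @return The trained `emotion_net` with a `history` data.frame attached
#'   (`epoch`, `loss`, `val_accuracy`).
#' @export
train_emotion_net <- function(model, train_samples, val_samples = NULL,
                              epochs = 30, batch_size = 16, lr = 1e-3,
                              seed = 1, verbose = FALSE) {
  tb <- as_model_batch(train_samples, model$spec$labels)
  vb <- if (length(val_samples)) as_model_batch(val_samples,
                                                model$spec$labels)
  N <- nrow(tb$resp)
  opt <- adam_init(model$params)
  best <- list(acc = -Inf, params = model$params, bn = model$bn_stats)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     val_accuracy = numeric())
  order_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, epochs))
  for (ep in seq_len(epochs)) {
    ord <- with_seed(order_seeds[ep], sample.int(N))
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1, N, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, N)]
      batch <- list(resp = tb$resp[idx, , drop = FALSE],
                    heart = tb$heart[idx, , drop = FALSE],
                    faces = tb$faces[idx, , , , , drop = FALSE])
      fwd <- net_forward(model, batch, training = TRUE)
      model$bn_stats <- fwd$bn_stats
      sx <- softmax_xent(fwd$logits, tb$y[idx])
      grads <- net_backward(model, fwd, sx$dlogits)
      upd <- adam_step(model$params, grads, opt, lr = lr)
      model$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + sx$loss
      nb <- nb + 1L
    }
    vacc <- NA_real_
    if (!is.null(vb)) {
      pv <- net_forward(model, vb, training = FALSE)
      vacc <- mean(max.col(pv$probs) == vb$y)
      if (vacc >= best$acc) {
        best <- list(acc = vacc, params = model$params,
                     bn = model$bn_stats)
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / nb,
                                   val_accuracy = vacc))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val acc %s", ep,
                      ep_loss / nb,
                      ifelse(is.na(vacc), "-", sprintf("%.3f", vacc))))
  }
  if (!is.null(vb) && is.finite(best$acc)) {
    model$params <- best$params
    model$bn_stats <- best$bn
  }
  model$history <- hist
  model
}

#' Predict emotions for samples
#'
#' @param model A trained [emotion_net()].
#' @param samples List of dataset samples (labels, if present, are ignored).
#' @param ablate Optional modality ablation, see [net_forward()].
#' @return List with `probs` (`[N x 4]`, rows sum to 1) and `labels`
#'   (character argmax).
#' @export
predict_emotion <- function(model, samples, ablate = character()) {
  b <- as_model_batch(samples, model$spec$labels)
  fwd <- net_forward(model, b, training = FALSE, ablate = ablate)
  list(probs = fwd$probs,
       labels = model$spec$labels[max.col(fwd$probs)])
}

#' Save / load an emotion network as JSON + flat weights
#'
#' The architecture goes to `<path>.json`; parameters and batch-norm
#' statistics go to `<path>.bin` as little-endian float64 in a documented
#' order.
#' @param model An `emotion_net`. @param path Basename (no extension).
#' @return `path`, invisibly.
#' @export
save_emotion_net <- function(model, path) {
  meta <- list(spec = model$spec[c("input_length", "image_size",
                                   "n_keyframes", "n_classes", "gru_units",
                                   "labels")],
               param_names = names(model$params),
               param_dims = lapply(model$params,
                                   function(p) dim(p) %||% length(p)),
               bn_names = names(model$bn_stats))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  for (p in model$params) writeBin(as.numeric(p), con, size = 8,
                                   endian = "little")
  for (s in model$bn_stats) {
    writeBin(as.numeric(s$mean), con, size = 8, endian = "little")
    writeBin(as.numeric(s$var), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' @rdname save_emotion_net
#' @export
load_emotion_net <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"),
                             simplifyVector = TRUE)
  sp <- meta$spec
  model <- emotion_net(sp$input_length, sp$image_size, sp$n_keyframes,
                       sp$n_classes, sp$gru_units, seed = 1)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  for (nm in meta$param_names) {
    dims <- meta$param_dims[[nm]]
    n <- prod(dims)
    v <- readBin(con, numeric(), n, size = 8, endian = "little")
    model$params[[nm]] <- if (length(dims) > 1) array(v, dims) else v
  }
  for (nm in meta$bn_names) {
    nc <- length(model$bn_stats[[nm]]$mean)
    model$bn_stats[[nm]]$mean <- readBin(con, numeric(), nc, size = 8,
                                         endian = "little")
    model$bn_stats[[nm]]$var <- readBin(con, numeric(), nc, size = 8,
                                        endian = "little")
  }
  model
}
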