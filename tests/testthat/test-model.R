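## Independent layer-arithmetic oracle: 'same' convolution yields
## ceil(len/stride); floor-mode pooling yields floor(len/pool) with a single
## truncated window when the input is shorter than the pool.
oracle_lengths <- function(len, blocks) {
  out <- integer(0)
  for (b in blocks) {
    len <- as.integer(ceiling(len / b$conv_stride))
    len <- if (len < b$pool) 1L else len %/% b$pool
    out <- c(out, len)
  }
  out
}

test_that("both branches reproduce the layer-arithmetic oracle", {
  expect_equal(oracle_lengths(1200, branch_spec_1d()), c(300, 150, 37, 9))
  expect_equal(oracle_lengths(227, branch_spec_2d()), c(113, 56, 14, 3))

  model <- emotion_net(input_length = 1200, image_size = 227,
                       n_keyframes = 2, seed = 1)
  expect_equal(model$spec$T_out, 9)
  expect_equal(model$spec$fused_dim, 64 + 64 + 96)

  set.seed(1)
  X <- array(rnorm(2 * 1200), c(2, 1200, 1))
  br <- remotion:::branch_forward(model$params, model$bn_stats, "resp",
                                  branch_spec_1d(), X, FALSE, FALSE)
  expect_equal(dim(br$out), c(2, 9, 64))
  Xi <- array(runif(2 * 227 * 227 * 3), c(2, 227, 227, 3))
  bf <- remotion:::branch_forward(model$params, model$bn_stats, "face",
                                  branch_spec_2d(), Xi, TRUE, FALSE)
  expect_equal(dim(bf$out), c(2, 3, 3, 96))
})

test_that("parameter counts match closed-form block arithmetic", {
  model <- emotion_net(1200, 227, 8, seed = 1)
  p <- model$params
  expect_equal(length(p[["resp.c1.W"]]) + length(p[["resp.c1.b"]]),
               5 * 1 * 16 + 16)                       # 96
  expect_equal(length(p[["face.c1.W"]]) + length(p[["face.c1.b"]]),
               3 * 3 * 3 * 32 + 32)                   # 896
  gru_total <- sum(vapply(grep("^gru\\.", names(p), value = TRUE),
                          function(nm) length(p[[nm]]), numeric(1)))
  expect_equal(gru_total, 3 * (224 * 64 + 64 * 64 + 64))  # 55488
  expect_equal(length(p[["out.W"]]) + length(p[["out.b"]]), 64 * 4 + 4)
})

test_that("zero input produces zero pre-batch-norm activations", {
  model <- emotion_net(80, 16, 2, seed = 2)
  X <- array(0, c(3, 80, 1))
  cv <- remotion:::conv1d_forward(X, model$params[["resp.c1.W"]],
                                  model$params[["resp.c1.b"]], 1)
  expect_true(all(cv$out == 0))
})

test_that("softmax output is a probability vector and predictions repeat", {
  model <- emotion_net(80, 16, 2, seed = 3)
  set.seed(9)
  batch <- list(resp = matrix(rnorm(2 * 80), 2),
                heart = matrix(rnorm(2 * 80), 2),
                faces = array(runif(2 * 2 * 16 * 16 * 3),
                              c(2, 2, 16, 16, 3)))
  f1 <- net_forward(model, batch)
  f2 <- net_forward(model, batch)
  expect_equal(rowSums(f1$probs), c(1, 1), tolerance = 1e-6)
  expect_true(all(f1$probs >= 0))
  expect_identical(f1$probs, f2$probs)
})

test_that("analytic gradients match finite differences", {
  ## input_length 432 keeps a temporal axis of 3, so the GRU recurrence
  ## (U matrices, reset gate) is genuinely exercised
  model <- emotion_net(432, 16, 2, seed = 4)
  set.seed(21)
  N <- 2
  batch <- list(resp = matrix(rnorm(N * 432), N),
                heart = matrix(rnorm(N * 432), N),
                faces = array(runif(N * 2 * 16 * 16 * 3),
                              c(N, 2, 16, 16, 3)))
  y <- c(2L, 4L)
  loss_at <- function(m) {
    f <- net_forward(m, batch, training = TRUE)
    remotion:::softmax_xent(f$logits, y)$loss
  }
  fwd <- net_forward(model, batch, training = TRUE)
  sx <- remotion:::softmax_xent(fwd$logits, y)
  grads <- remotion:::net_backward(model, fwd, sx$dlogits)
  eps <- 1e-5
  for (nm in c("resp.c2.W", "heart.bn1.gamma", "face.c3.W", "gru.Uz",
               "gru.bh", "out.W")) {
    p <- model$params[[nm]]
    for (r in 1:3) {
      i <- sample(length(p), 1)
      m2 <- model; m2$params[[nm]][i] <- p[i] + eps
      m3 <- model; m3$params[[nm]][i] <- p[i] - eps
      num <- (loss_at(m2) - loss_at(m3)) / (2 * eps)
      ana <- grads[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("every trainable tensor receives gradient on a random batch", {
  model <- emotion_net(432, 16, 2, seed = 5)
  set.seed(31)
  N <- 4
  batch <- list(resp = matrix(rnorm(N * 432), N),
                heart = matrix(rnorm(N * 432), N),
                faces = array(runif(N * 2 * 16 * 16 * 3),
                              c(N, 2, 16, 16, 3)))
  fwd <- net_forward(model, batch, training = TRUE)
  sx <- remotion:::softmax_xent(fwd$logits, sample(1:4, N, replace = TRUE))
  grads <- remotion:::net_backward(model, fwd, sx$dlogits)
  expect_setequal(names(grads), names(model$params))
  for (nm in names(grads))
    expect_true(any(grads[[nm]] != 0), info = nm)
})

test_that("training is seed-deterministic and reduces the loss", {
  ds <- make_dataset(4, duration = 20, image_size = 16, n_keyframes = 2,
                     seed = 6)
  mk <- function() emotion_net(input_length = 400, image_size = 16,
                               n_keyframes = 2, seed = 6)
  m1 <- train_emotion_net(mk(), ds$samples, epochs = 5, seed = 6)
  m2 <- train_emotion_net(mk(), ds$samples, epochs = 5, seed = 6)
  expect_identical(m1$params, m2$params)
  expect_lt(m1$history$loss[5], m1$history$loss[1])
})

test_that("checkpoints round-trip through save and load", {
  ds <- make_dataset(2, duration = 20, image_size = 16, n_keyframes = 2,
                     seed = 8)
  m <- emotion_net(400, 16, 2, seed = 8)
  m <- train_emotion_net(m, ds$samples, epochs = 2, seed = 8)
  path <- file.path(tempdir(), "ckpt")
  save_emotion_net(m, path)
  m2 <- load_emotion_net(path)
  p1 <- predict_emotion(m, ds$samples)
  p2 <- predict_emotion(m2, ds$samples)
  expect_equal(p1$probs, p2$probs, tolerance = 1e-12)
})

test_that("fusing all modalities beats ablated models across seeds", {
  accs <- matrix(NA_real_, 5, 4,
                 dimnames = list(NULL, c("full", "resp", "heart", "face")))
  for (s in 1:5) {
    ds <- make_dataset(8, duration = 20, image_size = 16, n_keyframes = 2,
                       seed = 100 + s)
    sp <- split_protocols(ds$manifest, "person_dependent",
                          val_frac = 0.15, test_frac = 0.25,
                          seed = 100 + s)
    m <- emotion_net(400, 16, 2, seed = 100 + s)
    m <- train_emotion_net(m, ds$samples[sp$train], ds$samples[sp$val],
                           epochs = 10, seed = 100 + s)
    truth <- vapply(ds$samples[sp$test], `[[`, character(1), "label")
    accs[s, "full"] <- mean(predict_emotion(m, ds$samples[sp$test])$labels
                            == truth)
    for (ab in c("resp", "heart", "face"))
      accs[s, ab] <- mean(predict_emotion(m, ds$samples[sp$test],
                                          ablate = ab)$labels == truth)
  }
  ## each modality carries information: zeroing it costs accuracy on average
  expect_gt(mean(accs[, "full"] - accs[, "face"]), 0)
  expect_gt(mean(accs[, "full"] - pmin(accs[, "resp"], accs[, "heart"])), 0)
  expect_gt(mean(accs[, "full"]), 0.5)
})
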