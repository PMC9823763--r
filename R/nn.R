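## Minimal tensor-layer toolkit: 1-D/2-D convolution ('same' padding),
## max pooling (floor mode; a window larger than the input truncates),
## batch normalization, ELU, GRU, dense, softmax cross-entropy, Adam.
## Every forward returns list(out, cache); every backward consumes the cache
## and the upstream gradient and returns dx plus parameter gradients.
## Arrays are batch-first: [N, L, C] in 1-D, [N, H, W, C] in 2-D, so a
## dim() reshape to [N * spatial, C] is contiguous and feeds BLAS directly.

## ---- shape arithmetic ------------------------------------------------------

#' Output length of a 'same'-padded strided convolution
#' @param len Input length. @param stride Stride.
#' @return `ceiling(len / stride)`.
#' @export
conv_out_len <- function(len, stride) as.integer(ceiling(len / stride))

#' Output length of floor-mode max pooling
#'
#' Non-overlapping windows of `pool`; a trailing partial window is dropped,
#' except that an input shorter than `pool` is pooled as a single truncated
#' window.
#' @param len Input length. @param pool Window size (stride equals window).
#' @return Pooled length.
#' @export
pool_out_len <- function(len, pool) {
  if (len < pool) 1L else as.integer(len %/% pool)
}

## ---- conv1d ----------------------------------------------------------------

conv1d_forward <- function(X, W, b, stride) {
  d <- dim(X); N <- d[1]; L <- d[2]; Cin <- d[3]
  k <- dim(W)[1]; Cout <- dim(W)[3]
  Lo <- conv_out_len(L, stride)
  pad <- max((Lo - 1L) * stride + k - L, 0L)
  pl <- pad %/% 2L
  Xp <- array(0, c(N, L + pad, Cin))
  Xp[, pl + seq_len(L), ] <- X
  Ymat <- matrix(0, N * Lo, Cout)
  base <- (seq_len(Lo) - 1L) * stride
  Xmats <- vector("list", k)
  for (j in seq_len(k)) {
    Xj <- Xp[, base + j, , drop = FALSE]
    dim(Xj) <- c(N * Lo, Cin)
    Xmats[[j]] <- Xj
    Ymat <- Ymat + Xj %*% matrix(W[j, , ], Cin, Cout)
  }
  Ymat <- sweep(Ymat, 2, b, `+`)
  out <- Ymat
  dim(out) <- c(N, Lo, Cout)
  list(out = out, cache = list(Xmats = Xmats, dims = d, k = k, pl = pl,
                               pad = pad, stride = stride, Lo = Lo, W = W))
}

conv1d_backward <- function(cache, dY) {
  d <- cache$dims; N <- d[1]; L <- d[2]; Cin <- d[3]
  W <- cache$W; k <- cache$k; Lo <- cache$Lo
  Cout <- dim(W)[3]
  dYm <- dY
  dim(dYm) <- c(N * Lo, Cout)
  dW <- array(0, dim(W))
  dXp <- array(0, c(N, L + cache$pad, Cin))
  base <- (seq_len(Lo) - 1L) * cache$stride
  for (j in seq_len(k)) {
    dW[j, , ] <- crossprod(cache$Xmats[[j]], dYm)
    contrib <- dYm %*% t(matrix(W[j, , ], Cin, Cout))
    dim(contrib) <- c(N, Lo, Cin)
    dXp[, base + j, ] <- dXp[, base + j, , drop = FALSE] + contrib
  }
  dX <- dXp[, cache$pl + seq_len(L), , drop = FALSE]
  list(dx = dX, dW = dW, db = colSums(dYm))
}

## ---- conv2d ----------------------------------------------------------------

conv2d_forward <- function(X, W, b, stride) {
  d <- dim(X); N <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  kh <- dim(W)[1]; kw <- dim(W)[2]; Cout <- dim(W)[4]
  Ho <- conv_out_len(H, stride); Wo <- conv_out_len(Wd, stride)
  ph <- max((Ho - 1L) * stride + kh - H, 0L); pht <- ph %/% 2L
  pw <- max((Wo - 1L) * stride + kw - Wd, 0L); pwl <- pw %/% 2L
  Xp <- array(0, c(N, H + ph, Wd + pw, Cin))
  Xp[, pht + seq_len(H), pwl + seq_len(Wd), ] <- X
  Ymat <- matrix(0, N * Ho * Wo, Cout)
  rb <- (seq_len(Ho) - 1L) * stride
  cb <- (seq_len(Wo) - 1L) * stride
  Xmats <- vector("list", kh * kw)
  idx <- 0L
  for (jw in seq_len(kw)) for (jh in seq_len(kh)) {
    idx <- idx + 1L
    Xj <- Xp[, rb + jh, cb + jw, , drop = FALSE]
    dim(Xj) <- c(N * Ho * Wo, Cin)
    Xmats[[idx]] <- Xj
    Ymat <- Ymat + Xj %*% matrix(W[jh, jw, , ], Cin, Cout)
  }
  Ymat <- sweep(Ymat, 2, b, `+`)
  out <- Ymat
  dim(out) <- c(N, Ho, Wo, Cout)
  list(out = out, cache = list(Xmats = Xmats, dims = d, kh = kh, kw = kw,
                               pht = pht, pwl = pwl, ph = ph, pw = pw,
                               stride = stride, Ho = Ho, Wo = Wo, W = W))
}

conv2d_backward <- function(cache, dY) {
  d <- cache$dims; N <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  W <- cache$W; Cout <- dim(W)[4]
  Ho <- cache$Ho; Wo <- cache$Wo
  dYm <- dY
  dim(dYm) <- c(N * Ho * Wo, Cout)
  dW <- array(0, dim(W))
  dXp <- array(0, c(N, H + cache$ph, Wd + cache$pw, Cin))
  rb <- (seq_len(Ho) - 1L) * cache$stride
  cb <- (seq_len(Wo) - 1L) * cache$stride
  idx <- 0L
  for (jw in seq_len(cache$kw)) for (jh in seq_len(cache$kh)) {
    idx <- idx + 1L
    dW[jh, jw, , ] <- crossprod(cache$Xmats[[idx]], dYm)
    contrib <- dYm %*% t(matrix(W[jh, jw, , ], Cin, Cout))
    dim(contrib) <- c(N, Ho, Wo, Cin)
    dXp[, rb + jh, cb + jw, ] <-
      dXp[, rb + jh, cb + jw, , drop = FALSE] + contrib
  }
  dX <- dXp[, cache$pht + seq_len(H), cache$pwl + seq_len(Wd), ,
            drop = FALSE]
  list(dx = dX, dW = dW, db = colSums(dYm))
}

## ---- max pooling -----------------------------------------------------------

maxpool1d_forward <- function(X, pool) {
  d <- dim(X); N <- d[1]; L <- d[2]; C <- d[3]
  Lo <- pool_out_len(L, pool)
  pe <- if (L < pool) L else pool           # effective (possibly truncated)
  base <- (seq_len(Lo) - 1L) * pool
  best <- array(-Inf, c(N, Lo, C))
  arg <- array(1L, c(N, Lo, C))
  for (j in seq_len(pe)) {
    cur <- X[, base + j, , drop = FALSE]
    upd <- cur > best
    best[upd] <- cur[upd]
    arg[upd] <- j
  }
  list(out = best, cache = list(dims = d, pool = pool, Lo = Lo, pe = pe,
                                arg = arg))
}

maxpool1d_backward <- function(cache, dY) {
  d <- cache$dims
  dX <- array(0, d)
  base <- (seq_len(cache$Lo) - 1L) * cache$pool
  for (j in seq_len(cache$pe)) {
    mask <- cache$arg == j
    sl <- dX[, base + j, , drop = FALSE]
    sl[mask] <- dY[mask]
    dX[, base + j, ] <- sl
  }
  dX
}

maxpool2d_forward <- function(X, pool) {
  d <- dim(X); N <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  Ho <- pool_out_len(H, pool); Wo <- pool_out_len(Wd, pool)
  peh <- if (H < pool) H else pool
  pew <- if (Wd < pool) Wd else pool
  rb <- (seq_len(Ho) - 1L) * pool
  cb <- (seq_len(Wo) - 1L) * pool
  best <- array(-Inf, c(N, Ho, Wo, C))
  arg <- array(1L, c(N, Ho, Wo, C))
  idx <- 0L
  for (jw in seq_len(pew)) for (jh in seq_len(peh)) {
    idx <- idx + 1L
    cur <- X[, rb + jh, cb + jw, , drop = FALSE]
    upd <- cur > best
    best[upd] <- cur[upd]
    arg[upd] <- idx
  }
  list(out = best, cache = list(dims = d, pool = pool, Ho = Ho, Wo = Wo,
                                peh = peh, pew = pew, arg = arg))
}

maxpool2d_backward <- function(cache, dY) {
  d <- cache$dims
  dX <- array(0, d)
  rb <- (seq_len(cache$Ho) - 1L) * cache$pool
  cb <- (seq_len(cache$Wo) - 1L) * cache$pool
  idx <- 0L
  for (jw in seq_len(cache$pew)) for (jh in seq_len(cache$peh)) {
    idx <- idx + 1L
    mask <- cache$arg == idx
    sl <- dX[, rb + jh, cb + jw, , drop = FALSE]
    sl[mask] <- dY[mask]
    dX[, rb + jh, cb + jw, ] <- sl
  }
  dX
}

## ---- batch normalization ---------------------------------------------------

## X: [N, ..., C]; normalizes per channel over batch and spatial dims.
batchnorm_forward <- function(X, gamma, beta, stats, training,
                              momentum = 0.1, eps = 1e-5) {
  d <- dim(X); C <- d[length(d)]; M <- prod(d) / C
  Xm <- X
  dim(Xm) <- c(M, C)
  if (training) {
    mu <- colMeans(Xm)
    var <- colMeans(Xm^2) - mu^2
    stats$mean <- (1 - momentum) * stats$mean + momentum * mu
    stats$var <- (1 - momentum) * stats$var + momentum * var
  } else {
    mu <- stats$mean
    var <- stats$var
  }
  istd <- 1 / sqrt(var + eps)
  xhat <- sweep(sweep(Xm, 2, mu, `-`), 2, istd, `*`)
  Ym <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  out <- Ym
  dim(out) <- d
  list(out = out, stats = stats,
       cache = list(xhat = xhat, istd = istd, gamma = gamma, dims = d,
                    training = training))
}

batchnorm_backward <- function(cache, dY) {
  d <- cache$dims; C <- d[length(d)]; M <- prod(d) / C
  dYm <- dY
  dim(dYm) <- c(M, C)
  xhat <- cache$xhat
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  if (cache$training) {
    mdy <- colMeans(dYm)
    mdyx <- colMeans(dYm * xhat)
    dXm <- sweep(dYm, 2, mdy, `-`) - sweep(xhat, 2, mdyx, `*`)
    dXm <- sweep(dXm, 2, cache$gamma * cache$istd, `*`)
  } else {
    dXm <- sweep(dYm, 2, cache$gamma * cache$istd, `*`)
  }
  dX <- dXm
  dim(dX) <- d
  list(dx = dX, dgamma = dgamma, dbeta = dbeta)
}

## ---- activations -----------------------------------------------------------

elu_forward <- function(X, alpha = 1) {
  neg <- X < 0
  Y <- X
  Y[neg] <- alpha * (exp(X[neg]) - 1)
  list(out = Y, cache = list(neg = neg, Y = Y, alpha = alpha))
}

elu_backward <- function(cache, dY) {
  dX <- dY
  dX[cache$neg] <- dY[cache$neg] * (cache$Y[cache$neg] + cache$alpha)
  dX
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- GRU -------------------------------------------------------------------

## X: [N, T, D]; returns the final hidden state [N, H].
## Gates: z = sig(x Wz + h Uz + bz), r = sig(x Wr + h Ur + br),
## htilde = tanh(x Wh + (r * h) Uh + bh), h' = (1 - z) * h + z * htilde.
## One bias set per gate: 3 (D H + H^2 + H) parameters.
gru_forward <- function(X, p) {
  d <- dim(X); N <- d[1]; Tt <- d[2]; D <- d[3]
  H <- ncol(p$Wz)
  h <- matrix(0, N, H)
  steps <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    xt <- matrix(X[, t, ], N, D)
    z <- sigmoid(xt %*% p$Wz + h %*% p$Uz +
                 matrix(p$bz, N, H, byrow = TRUE))
    r <- sigmoid(xt %*% p$Wr + h %*% p$Ur +
                 matrix(p$br, N, H, byrow = TRUE))
    rh <- r * h
    hh <- tanh(xt %*% p$Wh + rh %*% p$Uh +
               matrix(p$bh, N, H, byrow = TRUE))
    hnew <- (1 - z) * h + z * hh
    steps[[t]] <- list(x = xt, hprev = h, z = z, r = r, rh = rh, hh = hh)
    h <- hnew
  }
  list(out = h, cache = list(steps = steps, dims = d, p = p))
}

gru_backward <- function(cache, dh) {
  d <- cache$dims; N <- d[1]; Tt <- d[2]; D <- d[3]
  p <- cache$p
  g <- lapply(p, function(x) array(0, dim = dim(x) %||% length(x)))
  dX <- array(0, d)
  for (t in rev(seq_len(Tt))) {
    s <- cache$steps[[t]]
    dz <- dh * (s$hh - s$hprev)
    dhh <- dh * s$z
    dhprev <- dh * (1 - s$z)
    dhh_pre <- dhh * (1 - s$hh^2)
    g$Wh <- g$Wh + crossprod(s$x, dhh_pre)
    g$Uh <- g$Uh + crossprod(s$rh, dhh_pre)
    g$bh <- g$bh + colSums(dhh_pre)
    drh <- dhh_pre %*% t(p$Uh)
    dr <- drh * s$hprev
    dhprev <- dhprev + drh * s$r
    dz_pre <- dz * s$z * (1 - s$z)
    dr_pre <- dr * s$r * (1 - s$r)
    g$Wz <- g$Wz + crossprod(s$x, dz_pre)
    g$Uz <- g$Uz + crossprod(s$hprev, dz_pre)
    g$bz <- g$bz + colSums(dz_pre)
    g$Wr <- g$Wr + crossprod(s$x, dr_pre)
    g$Ur <- g$Ur + crossprod(s$hprev, dr_pre)
    g$br <- g$br + colSums(dr_pre)
    dhprev <- dhprev + dz_pre %*% t(p$Uz) + dr_pre %*% t(p$Ur)
    dxt <- dz_pre %*% t(p$Wz) + dr_pre %*% t(p$Wr) + dhh_pre %*% t(p$Wh)
    dX[, t, ] <- dxt
    dh <- dhprev
  }
  list(dx = dX, grads = g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- dense + softmax cross-entropy ----------------------------------------

dense_forward <- function(X, W, b) {
  Y <- X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE)
  list(out = Y, cache = list(X = X, W = W))
}

dense_backward <- function(cache, dY) {
  list(dx = dY %*% t(cache$W), dW = crossprod(cache$X, dY),
       db = colSums(dY))
}

softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## Mean cross-entropy and its gradient wrt logits.
softmax_xent <- function(logits, y) {
  N <- nrow(logits)
  probs <- softmax(logits)
  eps <- 1e-12
  loss <- -mean(log(probs[cbind(seq_len(N), y)] + eps))
  dlogits <- probs
  dlogits[cbind(seq_len(N), y)] <- dlogits[cbind(seq_len(N), y)] - 1
  list(loss = loss, probs = probs, dlogits = dlogits / N)
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
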