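## Independent brute-force VMD oracle: a naive per-bin loop transcription of
## the Wiener-filter mode update and power-centroid frequency update, with
## the same mirroring, initialization and stopping rule as the package
## implementation but no vectorization. Used to pin the frequency-domain
## implementation down to numerical identity.

vmd_naive <- function(x, rate, k, alpha = 2000, tau = 0, tol = 1e-7,
                      max_iter = 500) {
  n <- length(x)
  half <- n %/% 2
  xm <- c(rev(x[1:half]), x, rev(x[(n - half + 1):n]))
  TT <- length(xm)
  hT <- TT %/% 2
  fp <- stats::fft(xm)[1:hT]
  nu <- (0:(hT - 1)) / TT
  omega <- 0.25 * seq_len(k) / k
  u <- matrix(0 + 0i, k, hT)
  lam <- rep(0 + 0i, hT)
  iter <- 0
  udiff <- Inf
  while (iter < max_iter && udiff > tol) {
    iter <- iter + 1
    uprev <- u
    for (kk in seq_len(k)) {
      for (j in seq_len(hT)) {
        so <- 0 + 0i
        for (ii in seq_len(k)) if (ii != kk) so <- so + u[ii, j]
        u[kk, j] <- (fp[j] - so + lam[j] / 2) /
          (1 + 2 * alpha * (nu[j] - omega[kk])^2)
      }
      num <- 0; den <- 0
      for (j in seq_len(hT)) {
        p <- Mod(u[kk, j])^2
        num <- num + nu[j] * p
        den <- den + p
      }
      if (den > 0) omega[kk] <- num / den
    }
    if (tau != 0)
      for (j in seq_len(hT)) lam[j] <- lam[j] + tau * (sum(u[, j]) - fp[j])
    udiff <- 0
    for (kk in seq_len(k)) {
      nn2 <- sum(Mod(u[kk, ] - uprev[kk, ])^2)
      dd <- sum(Mod(uprev[kk, ])^2)
      udiff <- udiff + nn2 / (dd + .Machine$double.eps)
    }
  }
  ord <- order(omega)
  modes <- matrix(0, n, k)
  for (m in seq_len(k)) {
    uf <- rep(0 + 0i, TT)
    uf[1:hT] <- u[ord[m], ]
    if (hT > 1) uf[TT:(TT - hT + 2)] <- Conj(uf[2:hT])
    modes[, m] <- (Re(stats::fft(uf, inverse = TRUE)) / TT)[
      (half + 1):(half + n)]
  }
  list(modes = modes, center_freqs = omega[ord] * rate, iter = iter)
}
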