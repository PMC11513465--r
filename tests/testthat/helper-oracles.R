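# Independent oracles used across the suite. These re-derive expected
# values by brute force and must not call the implementation paths they
# check.

# Direct-summation oracle for the central difference convolution: six
# nested loops over output location and kernel offsets.
cdcOracle <- function(x, w, b, theta, variant) {
  d <- dim(x); kd <- dim(w)
  out <- array(0, dim = c(d[1:3], kd[5]))
  rt <- kd[1] %/% 2; rh <- kd[2] %/% 2; rw <- kd[3] %/% 2
  for (co in seq_len(kd[5])) for (t in seq_len(d[1]))
    for (h in seq_len(d[2])) for (ww in seq_len(d[3])) {
      s <- b[co]
      for (ci in seq_len(kd[4])) for (dt in -rt:rt)
        for (dh in -rh:rh) for (dw in -rw:rw) {
          wgt <- w[dt + rt + 1, dh + rh + 1, dw + rw + 1, ci, co]
          tt <- t + dt; hh <- h + dh; wv <- ww + dw
          if (tt >= 1 && tt <= d[1] && hh >= 1 && hh <= d[2] &&
              wv >= 1 && wv <= d[3])
            s <- s + wgt * x[tt, hh, wv, ci]
          inR <- switch(variant, spatiotemporal = TRUE,
                        temporal = dt != 0, vanilla = FALSE)
          if (inR) s <- s - theta * x[t, h, ww, ci] * wgt
        }
      out[t, h, ww, co] <- s
    }
  out
}

# Naive per-pixel bicubic (Keys a = -0.5) downscaling oracle: direct 2-D
# evaluation with clamped edges and half-pixel center alignment.
bicubicOracle <- function(img, L) {
  a <- -0.5
  kern <- function(s) {
    s <- abs(s)
    if (s <= 1) (a + 2) * s^3 - (a + 3) * s^2 + 1
    else if (s < 2) a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a
    else 0
  }
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    sy <- (i - 0.5) * n / L - 0.5
    sx <- (j - 0.5) * m / L - 0.5
    acc <- 0
    for (dy in (floor(sy) - 1):(floor(sy) + 2))
      for (dx in (floor(sx) - 1):(floor(sx) + 2)) {
        wy <- kern(sy - dy); wx <- kern(sx - dx)
        yy <- min(max(dy, 0), n - 1); xx <- min(max(dx, 0), m - 1)
        acc <- acc + wy * wx * img[yy + 1, xx + 1]
      }
    out[i, j] <- acc
  }
  out
}

# FFT-based analytic signal (Hilbert transform) for instantaneous
# frequency extraction.
analyticSignal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- rep(0, n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

instFreqHz <- function(x, rate_hz) {
  ph <- Arg(analyticSignal(x))
  dp <- diff(ph)
  dp <- (dp + pi) %% (2 * pi) - pi   # unwrap increments
  dp * rate_hz / (2 * pi)
}

# raw (unpadded) periodogram argmax frequency
periodogramArgmax <- function(x, rate_hz) {
  n <- length(x)
  p <- Mod(fft(x - mean(x)))^2
  half <- floor(n / 2)
  f <- (seq_len(half)) * rate_hz / n
  f[which.max(p[2:(half + 1)])]
}

# small synthetic clip for preprocessing / pipeline tests
tinyScene <- function(..., duration_s = 4) {
  sceneConfig(frame_size = c(24, 24), duration_s = duration_s,
              frame_rate = 10, ...)
}

tinyClip <- function(hr = 72, rr = 15, seed = 3, scene = tinyScene()) {
  rp <- respirationParams(rr_bpm = rr)
  pp <- pulseParams(hr_bpm = hr)
  resp <- generateRespiration(rp, scene$duration_s, scene$frame_rate,
                              seed = seed)
  pulse <- generatePulse(pp, resp, scene$duration_s, scene$frame_rate)
  list(clip = renderScene(scene, pulse, resp), pulse = pulse, resp = resp)
}
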