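# Preprocessing: raw clips -> the network's two inputs.
#
# Motion input: per-pixel normalized frame differences
#   (V(t+1) - V(t)) / (V(t+1) + V(t) + eps)
# which cancels the static illumination I0 and the dominant reflectance
# constant, making the representation invariant to a global intensity gain.
# Appearance input: standardized downscaled frames, which retain the spatial
# layout the attention branch needs. Spatial averaging (the downscale) comes
# first to reduce camera quantization noise, then the difference is taken.

#' Bicubic downscale of a clip to L x L pixels
#'
#' Separable cubic-convolution resampling (Keys kernel, a = -0.5) with
#' half-pixel center alignment and edge clamping, applied per frame and
#' channel; results are clamped to `[0, 1]`.
#'
#' @param clip a [VideoClip-class].
#' @param L output side length in pixels (>= 4, at most the input side).
#' @return a downscaled [VideoClip-class] (skin mask dropped).
#' @export
downscaleClip <- function(clip, L) {
  d <- dim(clip@frames)
  if (L < 4) stop("L must be at least 4")
  if (L > d[2] || L > d[3]) stop("L larger than the input frame side")
  My <- cubicResampleMatrix(d[2], L)
  Mx <- cubicResampleMatrix(d[3], L)
  out <- array(0, dim = c(d[1], L, L, 3))
  for (ch in 1:3) for (t in seq_len(d[1]))
    out[t, , , ch] <- My %*% clip@frames[t, , , ch] %*% t(Mx)
  out[out < 0] <- 0
  out[out > 1] <- 1
  VideoClip(out, clip@frameRate, skinMask = NULL)
}

# 1-D cubic convolution (Keys 1981, a = -0.5) interpolation weights from an
# n-sample source grid to an m-sample target grid, with the half-pixel
# source/target center convention src = (dst + 0.5) * n/m - 0.5 and clamped
# (replicated) edges. Returns an m x n matrix.
cubicResampleMatrix <- function(n, m) {
  a <- -0.5
  kern <- function(s) {
    s <- abs(s)
    ifelse(s <= 1, (a + 2) * s^3 - (a + 3) * s^2 + 1,
           ifelse(s < 2, a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a, 0))
  }
  M <- matrix(0, m, n)
  scale <- n / m
  for (i in seq_len(m)) {
    src <- (i - 0.5) * scale - 0.5          # 0-based source coordinate
    j0 <- floor(src)
    for (j in (j0 - 1):(j0 + 2)) {
      w <- kern(src - j)
      jc <- min(max(j, 0), n - 1)           # clamp to the edge sample
      M[i, jc + 1] <- M[i, jc + 1] + w
    }
  }
  M
}

#' Normalized frame difference (motion representation)
#'
#' Element-wise `(V(t+1) - V(t)) / (V(t+1) + V(t) + eps_div)`; the raw
#' result is gain invariant (a clip and `g * clip` give the same output up
#' to `eps_div`). The raw differences are then clamped at
#' `clip_sd` standard deviations and standardized to zero mean / unit
#' variance over all elements.
#'
#' @param clip a [VideoClip-class] with `T >= 2` and nonnegative values.
#' @param eps_div denominator guard (default 1e-7).
#' @param clip_sd clamp threshold in SDs of the raw differences (default 3).
#' @param standardize if `FALSE`, return the raw (unclamped) differences.
#' @return a `(T-1, H, W, 3)` array.
#' @export
normalizedFrameDiff <- function(clip, eps_div = 1e-7, clip_sd = 3,
                                standardize = TRUE) {
  x <- clip@frames
  Tn <- dim(x)[1]
  if (Tn < 2) stop("need at least two frames")
  hi <- x[2:Tn, , , , drop = FALSE]
  lo <- x[1:(Tn - 1), , , , drop = FALSE]
  raw <- (hi - lo) / (hi + lo + eps_div)
  if (!standardize) return(raw)
  s <- sd(raw)
  if (s == 0) stop("degenerate input: all frame differences are zero")
  thr <- clip_sd * s
  n_clamped <- sum(abs(raw) > thr)
  if (n_clamped > 0.01 * length(raw))
    warning(sprintf("clamping affected %.2f%% of motion samples",
                    100 * n_clamped / length(raw)))
  raw[raw > thr] <- thr
  raw[raw < -thr] <- -thr
  (raw - mean(raw)) / sd(raw)
}

#' Standardized appearance input
#'
#' Per-clip, per-channel standardization (zero mean, unit variance over all
#' frames and pixels of a channel). Frame `t` is paired with motion sample
#' `t`, so the last frame is dropped: output has `T-1` frames.
#'
#' @param clip a [VideoClip-class].
#' @return a `(T-1, L, L, 3)` array.
#' @export
standardizeAppearance <- function(clip) {
  Tn <- dim(clip@frames)[1]
  x <- clip@frames[1:(Tn - 1), , , , drop = FALSE]
  for (ch in 1:3) {
    v <- x[, , , ch]
    s <- sd(v)
    if (s == 0) stop("degenerate input: zero-variance channel ", ch)
    x[, , , ch] <- (v - mean(v)) / s
  }
  x
}

#' Build the motion/appearance input pair for a clip
#'
#' Downscales to `L x L` first (spatial averaging reduces quantization
#' noise), then computes the normalized frame differences and the
#' standardized appearance frames.
#'
#' @param clip a [VideoClip-class].
#' @param L input side length (default 36).
#' @param eps_div,clip_sd forwarded to [normalizedFrameDiff()].
#' @return a [MotionAppearancePair-class].
#' @export
motionAppearance <- function(clip, L = 36, eps_div = 1e-7, clip_sd = 3) {
  small <- downscaleClip(clip, L)
  new("MotionAppearancePair",
      motion = normalizedFrameDiff(small, eps_div, clip_sd),
      appearance = standardizeAppearance(small),
      frameRate = clip@frameRate)
}

#' Training labels from ground-truth waveforms
#'
#' The network consumes frame differences, so the targets are the
#' standardized first differences of the pulse and respiration waveforms
#' (differentiation preserves the spectral peak location).
#'
#' @param pulse,resp [WaveformSeries-class] sampled at the clip frame rate.
#' @return a [LabelSeries-class] of length `T-1`.
#' @export
makeLabels <- function(pulse, resp) {
  if (length(pulse@samples) != length(resp@samples))
    stop("pulse and respiration waveforms must share length")
  stdDiff <- function(x) {
    d <- diff(x)
    s <- sd(d)
    if (s <= 1e-10 * max(abs(d), 1))
      stop("degenerate input: constant waveform derivative")
    (d - mean(d)) / s
  }
  new("LabelSeries", pulse = stdDiff(pulse@samples),
      resp = stdDiff(resp@samples), rateHz = pulse@rateHz)
}

#' Cut aligned training windows
#'
#' Slices the motion/appearance pair and the labels into aligned windows of
#' `T_win` samples every `stride` samples; the number of windows is
#' `floor((len - T_win) / stride) + 1`.
#'
#' @param pair a [MotionAppearancePair-class].
#' @param labels a [LabelSeries-class] (or `NULL` for inference windows).
#' @param T_win window length in samples.
#' @param stride hop between window starts (>= 1).
#' @return a list of windows, each `list(motion, appearance, pulse, resp,
#'   start)`; empty (with a warning) when `T_win` exceeds the length.
#' @export
windowPairs <- function(pair, labels = NULL, T_win, stride = T_win %/% 2L) {
  stopifnot(stride >= 1)
  len <- dim(pair@motion)[1]
  if (!is.null(labels) && length(labels@pulse) != len)
    stop("labels do not match the motion length")
  if (T_win > len) {
    warning("window longer than the clip; returning no windows")
    return(list())
  }
  starts <- seq(1L, len - T_win + 1L, by = stride)
  lapply(starts, function(s) {
    idx <- s:(s + T_win - 1L)
    list(motion = pair@motion[idx, , , , drop = FALSE],
         appearance = pair@appearance[idx, , , , drop = FALSE],
         pulse = if (is.null(labels)) NULL else labels@pulse[idx],
         resp = if (is.null(labels)) NULL else labels@resp[idx],
         start = s)
  })
}
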