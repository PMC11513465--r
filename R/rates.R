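# Rate estimation and evaluation metrics.
#
# The recovered (derivative) waveform is band-pass filtered with a
# zero-phase second-order Butterworth filter and the rate is read off as
# the highest peak of the zero-padded periodogram restricted to the band.
# Differentiation and scaling do not move an in-band spectral peak, so the
# estimator is invariant to both.

#' Band specification for rate estimation
#'
#' @param low_hz,high_hz passband edges, `0 < low < high` and `high` below
#'   the Nyquist frequency of the signal the band is used on.
#' @param order Butterworth filter order (default 2).
#' @return validated list.
#' @export
bandSpec <- function(low_hz, high_hz, order = 2) {
  stopifnot(low_hz > 0, high_hz > low_hz, order >= 1)
  list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order))
}

#' Heart-rate band preset: 0.75-2.5 Hz (45-150 bpm)
#' @return a [bandSpec()].
#' @export
hrBand <- function() bandSpec(0.75, 2.5)

#' Respiration-rate band preset: 0.08-0.5 Hz (4.8-30 breaths/min)
#' @return a [bandSpec()].
#' @export
rrBand <- function() bandSpec(0.08, 0.5)

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (`filtfilt`) filtering with a second-order Butterworth
#' design: zero phase distortion, squared magnitude response. Output length
#' equals input length.
#'
#' @param x numeric signal.
#' @param rate_hz sampling rate.
#' @param band a [bandSpec()].
#' @return filtered signal.
#' @export
bandpassFilter <- function(x, rate_hz, band = hrBand()) {
  nyq <- rate_hz / 2
  if (band$high_hz >= nyq) stop("band edge at or above the Nyquist frequency")
  if (length(x) <= 3 * band$order)
    stop("signal too short for the filter order")
  bf <- signal::butter(band$order, c(band$low_hz, band$high_hz) / nyq,
                       type = "pass")
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

# squared-magnitude response |H(f)|^2 of the Butterworth design at given
# frequencies; forward-backward filtering applies this twice in power
butterPowerGain <- function(freq, rate_hz, band) {
  bf <- signal::butter(band$order, c(band$low_hz, band$high_hz) /
                         (rate_hz / 2), type = "pass")
  z <- exp(-1i * 2 * pi * freq / rate_hz)
  H <- vapply(z, function(zz)
    sum(bf$b * zz^(seq_along(bf$b) - 1)) /
      sum(bf$a * zz^(seq_along(bf$a) - 1)), complex(1))
  Mod(H)^2
}

# zero-padded periodogram: power at nfft/2 + 1 nonnegative frequencies
periodogramFFT <- function(x, rate_hz, nfft_min = 2048) {
  n <- length(x)
  nfft <- max(nfft_min, 2^ceiling(log2(n)))
  xp <- c(x - mean(x), rep(0, nfft - n))
  sp <- fft(xp)
  half <- nfft %/% 2 + 1
  list(freq = (seq_len(half) - 1) * rate_hz / nfft,
       power = Mod(sp[seq_len(half)])^2 / n,
       resolution = rate_hz / nfft)
}

#' Estimate a physiological rate from a waveform
#'
#' Band-pass filters the signal, computes a zero-padded periodogram
#' (>= `nfft_min` points for sub-bpm resolution on short windows) and takes
#' the highest in-band peak: `bpm = 60 * argmax frequency`. The in-band
#' periodogram is compensated by the filter's known power response so that
#' the magnitude tilt of the Butterworth edges cannot displace the peak of
#' a tone near a band edge; this keeps the estimate within half a spectral
#' bin for any in-band pure tone.
#'
#' @param x numeric signal (waveform or its derivative).
#' @param rate_hz sampling rate.
#' @param band a [bandSpec()]; the window must cover at least `min_cycles`
#'   cycles of the band's low edge.
#' @param nfft_min minimum FFT length (default 2048).
#' @param min_cycles required cycles of `band$low_hz` in the window
#'   (default 4). Whole-clip evaluation on short recordings relaxes this
#'   (to 0.5) for the wide respiration band, whose 0.08 Hz low edge would
#'   otherwise demand 50 s windows even for breaths at 0.2-0.4 Hz.
#' @return a [RateEstimate-class].
#' @export
estimateRate <- function(x, rate_hz, band = hrBand(), nfft_min = 2048,
                         min_cycles = 4) {
  if (length(x) / rate_hz < min_cycles / band$low_hz)
    stop("window too short: need at least ", min_cycles,
         " cycles of the band's low edge")
  xf <- bandpassFilter(x, rate_hz, band)
  pg <- periodogramFFT(xf, rate_hz, nfft_min)
  inb <- pg$freq >= band$low_hz & pg$freq <= band$high_hz
  if (!any(inb)) stop("no spectral bins inside the band")
  fb <- pg$freq[inb]
  # undo the filter's in-band power shaping (|H|^2 applied twice)
  pb <- pg$power[inb] / butterPowerGain(fb, rate_hz, band)^2
  pk <- fb[which.max(pb)]
  new("RateEstimate", bpm = 60 * pk, peakHz = pk, freq = fb, power = pb,
      resolutionHz = pg$resolution)
}

#' Agreement metrics between estimated and reference rates
#'
#' MAE, RMSE and Pearson r over paired per-clip rates, plus Bland-Altman
#' bias (mean of estimated - reference) and 95% limits of agreement
#' (bias +/- 1.96 SD of the differences). With fewer than 2 pairs, or when
#' a constant series makes the correlation undefined, `pearsonR` is `NA`.
#'
#' @param est_bpm,true_bpm equal-length numeric vectors.
#' @return a [MetricsReport-class].
#' @export
rateMetrics <- function(est_bpm, true_bpm) {
  if (length(est_bpm) != length(true_bpm)) stop("length mismatch")
  if (length(est_bpm) < 1) stop("empty input")
  d <- est_bpm - true_bpm
  r <- if (length(d) >= 2 && sd(est_bpm) > 0 && sd(true_bpm) > 0)
    cor(est_bpm, true_bpm) else NA_real_
  sdd <- if (length(d) >= 2) sd(d) else 0
  new("MetricsReport",
      maeBpm = mean(abs(d)), rmseBpm = sqrt(mean(d^2)), pearsonR = r,
      bias = mean(d), loaLow = mean(d) - 1.96 * sdd,
      loaHigh = mean(d) + 1.96 * sdd, n = length(d))
}

#' Bland-Altman plot of rate agreement
#'
#' Differences (estimated - reference) against pair means, with the bias
#' and 95% limits of agreement drawn as horizontal lines.
#'
#' @param est_bpm,true_bpm paired rates.
#' @param file optional PNG path; when given the plot is written there.
#' @param ... forwarded to [graphics::plot()].
#' @return (invisibly) the [MetricsReport-class].
#' @importFrom graphics abline plot
#' @importFrom grDevices png dev.off
#' @export
blandAltmanPlot <- function(est_bpm, true_bpm, file = NULL, ...) {
  rep_ <- rateMetrics(est_bpm, true_bpm)
  if (!is.null(file)) {
    png(file, width = 640, height = 480)
    on.exit(dev.off())
  }
  plot((est_bpm + true_bpm) / 2, est_bpm - true_bpm,
       xlab = "Mean of estimated and reference (bpm)",
       ylab = "Estimated - reference (bpm)", pch = 19, ...)
  abline(h = rep_@bias, lty = 1)
  abline(h = c(rep_@loaLow, rep_@loaHigh), lty = 2)
  invisible(rep_)
}
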