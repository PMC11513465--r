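#' @import methods
#' @importFrom stats rnorm runif sd fft cor
#' @importFrom utils write.csv read.csv head tail
#' @useDynLib cdcrppg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' VideoClip: a T x H x W x 3 stack of RGB frames
#'
#' Container for a facial-video clip as normalized float intensities in
#' \eqn{[0, 1]} with a known frame rate. Synthetic clips carry the boolean
#' skin mask used to render them so recovery quality can be audited;
#' real clips have `skinMask = NULL`.
#'
#' @slot frames numeric array, dim `(T, H, W, 3)`, values in `[0, 1]`.
#' @slot frameRate sampling rate of the frame sequence in Hz.
#' @slot skinMask `H x W` logical matrix or `NULL`.
#'
#' @seealso [renderScene()], [downscaleClip()]
#' @export
setClass("VideoClip",
  representation(frames = "array", frameRate = "numeric",
                 skinMask = "matrixOrNULL"),
  prototype(skinMask = NULL))

setValidity("VideoClip", function(object) {
  d <- dim(object@frames)
  if (length(d) != 4L || d[4] != 3L)
    return("frames must be a (T, H, W, 3) array")
  if (d[1] < 2L) return("a clip needs at least 2 frames")
  if (anyNA(object@frames) || any(!is.finite(object@frames)))
    return("frames contain NA/Inf")
  if (min(object@frames) < 0 || max(object@frames) > 1)
    return("frame intensities must lie in [0, 1]")
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    return("frameRate must be a positive scalar")
  if (!is.null(object@skinMask)) {
    if (!is.logical(object@skinMask)) return("skinMask must be logical")
    if (!identical(dim(object@skinMask), d[2:3]))
      return("skinMask must be H x W")
  }
  TRUE
})

#' WaveformSeries: a per-frame physiological signal
#'
#' One sample per video frame; `kind` records whether the series is a
#' blood-volume pulse or a respiration wave.
#'
#' @slot samples numeric vector of waveform samples (arbitrary units).
#' @slot rateHz sampling rate in Hz.
#' @slot kind `"pulse"` or `"respiration"`.
#'
#' @export
setClass("WaveformSeries",
  representation(samples = "numeric", rateHz = "numeric", kind = "character"))

setValidity("WaveformSeries", function(object) {
  if (length(object@samples) < 1L) return("empty waveform")
  if (any(!is.finite(object@samples))) return("waveform contains NA/Inf")
  if (length(object@rateHz) != 1L || object@rateHz <= 0)
    return("rateHz must be a positive scalar")
  if (!object@kind %in% c("pulse", "respiration"))
    return("kind must be 'pulse' or 'respiration'")
  TRUE
})

#' MotionAppearancePair: the network's two inputs
#'
#' Motion input: per-pixel normalized frame differences (illumination
#' invariant), clamped and standardized. Appearance input: standardized
#' downscaled frames, one per motion sample (frames `1..T-1`).
#'
#' @slot motion numeric array `(T-1, L, L, 3)`.
#' @slot appearance numeric array `(T-1, L, L, 3)`.
#' @slot frameRate Hz.
#'
#' @seealso [motionAppearance()]
#' @export
setClass("MotionAppearancePair",
  representation(motion = "array", appearance = "array", frameRate = "numeric"))

setValidity("MotionAppearancePair", function(object) {
  dm <- dim(object@motion); da <- dim(object@appearance)
  if (length(dm) != 4L || length(da) != 4L)
    return("motion and appearance must be 4-d arrays")
  if (!identical(dm, da)) return("motion and appearance shapes differ")
  if (dm[2] != dm[3]) return("spatial dimensions must be square (L x L)")
  if (any(!is.finite(object@motion)) || any(!is.finite(object@appearance)))
    return("non-finite values in inputs")
  TRUE
})

#' LabelSeries: standardized first-difference training targets
#'
#' @slot pulse numeric vector, length `T-1`, zero mean / unit variance.
#' @slot resp numeric vector, length `T-1`, zero mean / unit variance.
#' @slot rateHz Hz.
#' @export
setClass("LabelSeries",
  representation(pulse = "numeric", resp = "numeric", rateHz = "numeric"))

setValidity("LabelSeries", function(object) {
  if (length(object@pulse) != length(object@resp))
    return("pulse and resp labels must share length")
  if (any(!is.finite(object@pulse)) || any(!is.finite(object@resp)))
    return("non-finite label values")
  TRUE
})

#' RateEstimate: spectral-peak rate of a recovered waveform
#'
#' @slot bpm estimated rate in beats (breaths) per minute.
#' @slot peakHz frequency of the in-band power-spectrum peak, `bpm / 60`.
#' @slot freq numeric vector of in-band spectrum frequencies (Hz).
#' @slot power periodogram power at `freq`.
#' @slot resolutionHz spectral bin width `rateHz / Nfft`.
#' @export
setClass("RateEstimate",
  representation(bpm = "numeric", peakHz = "numeric", freq = "numeric",
                 power = "numeric", resolutionHz = "numeric"))

setValidity("RateEstimate", function(object) {
  if (abs(object@bpm - 60 * object@peakHz) > 1e-9)
    return("bpm must equal 60 * peakHz")
  if (length(object@freq) != length(object@power))
    return("freq and power lengths differ")
  TRUE
})

#' MetricsReport: agreement between estimated and reference rates
#'
#' MAE, RMSE and Pearson r over paired per-clip rates, plus Bland-Altman
#' bias and 95% limits of agreement (bias +/- 1.96 SD of differences,
#' differences taken as estimated - reference).
#'
#' @slot maeBpm mean absolute error (bpm).
#' @slot rmseBpm root mean squared error (bpm).
#' @slot pearsonR Pearson correlation of estimated vs reference rates
#'   (`NA` when fewer than 2 pairs or a constant series makes r undefined).
#' @slot bias mean difference (bpm).
#' @slot loaLow,loaHigh limits of agreement (bpm).
#' @slot n number of pairs.
#' @export
setClass("MetricsReport",
  representation(maeBpm = "numeric", rmseBpm = "numeric", pearsonR = "numeric",
                 bias = "numeric", loaLow = "numeric", loaHigh = "numeric",
                 n = "integer"))

setValidity("MetricsReport", function(object) {
  if (object@rmseBpm < object@maeBpm - 1e-9)
    return("RMSE cannot be smaller than MAE")
  TRUE
})

#' RppgModel: the dual-branch CDC attention network
#'
#' Holds the network configuration (see [networkConfig()]) and all
#' learnable parameter tensors. Use [buildModel()] to construct,
#' [forwardModel()] for inference and [trainModel()] for fitting.
#'
#' @slot config list produced by [networkConfig()].
#' @slot params named list of parameter arrays.
#' @export
setClass("RppgModel",
  representation(config = "list", params = "list"))

# ---- show methods -----------------------------------------------------

setMethod("show", "VideoClip", function(object) {
  d <- dim(object@frames)
  cat(sprintf("VideoClip: %d frames, %dx%d px, %.3g fps (%.2f s)%s\n",
              d[1], d[2], d[3], object@frameRate, d[1] / object@frameRate,
              if (is.null(object@skinMask)) ""
              else sprintf(", skin mask (%d px)", sum(object@skinMask))))
})

setMethod("show", "WaveformSeries", function(object) {
  cat(sprintf("WaveformSeries (%s): %d samples @ %.3g Hz, range [%.3g, %.3g]\n",
              object@kind, length(object@samples), object@rateHz,
              min(object@samples), max(object@samples)))
})

setMethod("show", "MotionAppearancePair", function(object) {
  d <- dim(object@motion)
  cat(sprintf("MotionAppearancePair: %d samples, %dx%d px, %.3g fps\n",
              d[1], d[2], d[3], object@frameRate))
})

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf("RateEstimate: %.2f bpm (peak %.4g Hz, bin width %.4g Hz)\n",
              object@bpm, object@peakHz, object@resolutionHz))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport over %d pairs:\n  MAE %.3f bpm | RMSE %.3f bpm | r %s\n  Bland-Altman bias %.3f bpm, LoA [%.3f, %.3f]\n",
    object@n, object@maeBpm, object@rmseBpm,
    ifelse(is.na(object@pearsonR), "NA", sprintf("%.3f", object@pearsonR)),
    object@bias, object@loaLow, object@loaHigh))
})

setMethod("show", "RppgModel", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf(
    "RppgModel: %s 3D-CDC (theta=%.2g), channels %s, L=%d, tasks {%s}, %d parameters\n",
    object@config$variant, object@config$theta,
    paste(object@config$channels, collapse = "/"), object@config$L,
    paste(object@config$tasks, collapse = ", "), np))
})

# ---- accessors --------------------------------------------------------

#' @rdname VideoClip-class
#' @param object a `VideoClip`, `WaveformSeries` or `MotionAppearancePair`.
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname VideoClip-class
#' @export
setMethod("frames", "VideoClip", function(object) object@frames)

#' @rdname VideoClip-class
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname VideoClip-class
#' @export
setMethod("frameRate", "VideoClip", function(object) object@frameRate)
#' @rdname VideoClip-class
#' @export
setMethod("frameRate", "MotionAppearancePair", function(object) object@frameRate)

#' @rdname VideoClip-class
#' @export
setGeneric("skinMask", function(object) standardGeneric("skinMask"))
#' @rdname VideoClip-class
#' @export
setMethod("skinMask", "VideoClip", function(object) object@skinMask)

#' @rdname WaveformSeries-class
#' @param object a `WaveformSeries`.
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname WaveformSeries-class
#' @export
setMethod("samples", "WaveformSeries", function(object) object@samples)

#' @rdname WaveformSeries-class
#' @export
setGeneric("rateHz", function(object) standardGeneric("rateHz"))
#' @rdname WaveformSeries-class
#' @export
setMethod("rateHz", "WaveformSeries", function(object) object@rateHz)

#' @rdname MotionAppearancePair-class
#' @param object a `MotionAppearancePair`.
#' @export
setGeneric("motionInput", function(object) standardGeneric("motionInput"))
#' @rdname MotionAppearancePair-class
#' @export
setMethod("motionInput", "MotionAppearancePair", function(object) object@motion)

#' @rdname MotionAppearancePair-class
#' @export
setGeneric("appearanceInput", function(object) standardGeneric("appearanceInput"))
#' @rdname MotionAppearancePair-class
#' @export
setMethod("appearanceInput", "MotionAppearancePair",
          function(object) object@appearance)

#' Constructor for VideoClip
#'
#' @param frames `(T, H, W, 3)` array in `[0, 1]`.
#' @param frameRate Hz.
#' @param skinMask optional `H x W` logical matrix.
#' @return a [VideoClip-class] object.
#' @export
VideoClip <- function(frames, frameRate, skinMask = NULL) {
  new("VideoClip", frames = frames, frameRate = frameRate, skinMask = skinMask)
}

#' Constructor for WaveformSeries
#'
#' @param samples numeric vector.
#' @param rateHz Hz.
#' @param kind `"pulse"` or `"respiration"`.
#' @return a [WaveformSeries-class] object.
#' @export
WaveformSeries <- function(samples, rateHz, kind = "pulse") {
  new("WaveformSeries", samples = samples, rateHz = rateHz, kind = kind)
}
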