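# Synthetic facial-video simulator.
#
# Runs the dichromatic skin reflection model forward: each skin pixel is
#   V(t) = I0 * (1 + Psi(t)) * (C + Phi(t) + P(t) + Rsp(t)) + noise
# where I0 is the static illumination, C the static per-channel skin
# reflectance, Psi a slow multiplicative illumination variation (plus a
# sinusoidal motion disturbance), Phi the time-varying specular component,
# P the blood-volume pulse, Rsp a small additive respiration baseline and
# the noise term models camera quantization. Background pixels follow the
# same expression with the physiological terms switched off, so the only
# spatial structure separating skin from background is the pulse itself.

#' Pulse generator parameters
#'
#' @param hr_bpm mean heart rate, beats/min (must lie in `[40, 180]`).
#' @param harmonic_amps relative amplitudes of the fundamental and higher
#'   harmonics; the fundamental must be positive. The default adds a second
#'   harmonic at 0.3, in the range reported for contact PPG (the dicrotic
#'   shoulder); 0.3 also keeps the fundamental spectrally dominant in the
#'   first-difference representation the network regresses, where harmonic
#'   k gains a factor k (0.3 x 2 = 0.6 < 1).
#' @param rsa_depth fractional frequency modulation of the cardiac cycle at
#'   the respiratory frequency (respiratory sinus arrhythmia), in `[0, 0.2]`.
#' @param amplitude peak pulse amplitude in normalized intensity units.
#' @return validated parameter list.
#' @export
pulseParams <- function(hr_bpm = 75, harmonic_amps = c(1, 0.3),
                        rsa_depth = 0.05, amplitude = 0.01) {
  stopifnot(hr_bpm >= 40, hr_bpm <= 180,
            length(harmonic_amps) >= 1, all(harmonic_amps >= 0),
            harmonic_amps[1] > 0,
            rsa_depth >= 0, rsa_depth <= 0.2, amplitude >= 0)
  list(hr_bpm = hr_bpm, harmonic_amps = harmonic_amps,
       rsa_depth = rsa_depth, amplitude = amplitude)
}

#' Respiration generator parameters
#'
#' @param rr_bpm mean respiration rate, breaths/min (in `[6, 30]`).
#' @param amplitude intensity-modulation amplitude of the additive
#'   respiration baseline on skin pixels.
#' @return validated parameter list.
#' @export
respirationParams <- function(rr_bpm = 15, amplitude = 0.005) {
  stopifnot(rr_bpm >= 6, rr_bpm <= 30, amplitude >= 0)
  list(rr_bpm = rr_bpm, amplitude = amplitude)
}

#' Scene configuration for the skin reflection renderer
#'
#' All amplitudes are in normalized intensity units. The default pulse-free
#' disturbances (illumination drift `psi_amp`, specular flicker `phi_amp`,
#' motion term `motion_amp`, sensor noise `noise_sigma`) are set so that the
#' per-pixel pulse SNR is near 1: recovery then requires spatial pooling,
#' which is what the network is supposed to learn.
#'
#' @param i0 static illumination: a scalar or an `H x W` matrix.
#' @param c_skin length-3 static skin reflectance per RGB channel.
#' @param psi_amp amplitude of the slow illumination variation.
#' @param psi_freq_hz its frequency (kept at or below 0.3 Hz).
#' @param phi_amp amplitude of the time-varying specular component.
#' @param phi_freq_hz its frequency.
#' @param motion_amp amplitude of the non-physiological motion disturbance.
#' @param motion_freq_hz its frequency.
#' @param noise_sigma SD of additive Gaussian camera noise.
#' @param skin_ellipse ellipse `(cx, cy, rx, ry)` as fractions of the frame
#'   defining the skin region.
#' @param frame_rate Hz.
#' @param duration_s clip length in seconds.
#' @param frame_size `c(H, W)` in pixels.
#' @param seed RNG seed for phases and noise.
#' @return validated configuration list.
#' @export
sceneConfig <- function(i0 = 1.0, c_skin = c(0.55, 0.45, 0.40),
                        psi_amp = 0.02, psi_freq_hz = 0.10,
                        phi_amp = 0.01, phi_freq_hz = 0.23,
                        motion_amp = 0.005, motion_freq_hz = 0.35,
                        noise_sigma = 0.002,
                        skin_ellipse = c(0.5, 0.5, 0.32, 0.40),
                        frame_rate = 20, duration_s = 10,
                        frame_size = c(64, 64), seed = 1L) {
  stopifnot(length(c_skin) == 3, all(c_skin > 0),
            psi_amp >= 0, phi_amp >= 0, motion_amp >= 0, noise_sigma >= 0,
            psi_freq_hz <= 0.3, frame_rate > 0, duration_s > 0,
            length(frame_size) == 2, all(frame_size >= 4),
            length(skin_ellipse) == 4, all(skin_ellipse > 0))
  if (is.matrix(i0)) stopifnot(identical(dim(i0), as.integer(frame_size)))
  else stopifnot(length(i0) == 1, i0 > 0)
  cfg <- list(i0 = i0, c_skin = c_skin, psi_amp = psi_amp,
              psi_freq_hz = psi_freq_hz, phi_amp = phi_amp,
              phi_freq_hz = phi_freq_hz, motion_amp = motion_amp,
              motion_freq_hz = motion_freq_hz, noise_sigma = noise_sigma,
              skin_ellipse = skin_ellipse, frame_rate = frame_rate,
              duration_s = duration_s, frame_size = as.integer(frame_size),
              seed = as.integer(seed))
  msk <- ellipseMask(cfg)
  if (!any(msk) || all(msk))
    stop("skin mask must be non-empty and strictly smaller than the frame")
  cfg
}

ellipseMask <- function(cfg) {
  H <- cfg$frame_size[1]; W <- cfg$frame_size[2]
  e <- cfg$skin_ellipse
  y <- (seq_len(H) - 0.5) / H
  x <- (seq_len(W) - 0.5) / W
  outer(y, x, function(yy, xx)
    ((xx - e[1]) / e[3])^2 + ((yy - e[2]) / e[4])^2 <= 1)
}

#' Generate a respiration waveform
#'
#' A zero-mean sinusoid at `rr_bpm / 60` Hz, optionally with a mild random
#' phase walk (`jitter_sd` radians per sample) to avoid a perfectly
#' deterministic breath cycle.
#'
#' @param params from [respirationParams()].
#' @param duration_s,rate_hz length and sampling rate of the series.
#' @param seed RNG seed.
#' @param jitter_sd SD of per-sample phase-increment jitter (radians).
#' @return a [WaveformSeries-class] of kind `"respiration"`.
#' @export
generateRespiration <- function(params, duration_s, rate_hz, seed = 1L,
                                jitter_sd = 0) {
  if (duration_s <= 0 || rate_hz <= 0)
    stop("duration_s and rate_hz must be positive")
  n <- round(duration_s * rate_hz)
  tt <- (seq_len(n) - 1) / rate_hz
  phase <- 2 * pi * (params$rr_bpm / 60) * tt
  if (jitter_sd > 0) {
    set.seed(as.integer(seed))
    phase <- phase + cumsum(rnorm(n, 0, jitter_sd))
  }
  x <- params$amplitude * sin(phase)
  if (params$amplitude > 0) x <- x - mean(x)
  WaveformSeries(x, rate_hz, "respiration")
}

#' Generate a blood-volume pulse waveform with RSA coupling
#'
#' The pulse is a sum of harmonics of an instantaneous cardiac phase whose
#' frequency is \eqn{f_{hr} (1 + d \cdot r(t))} where `d` is `rsa_depth` and
#' `r(t)` is the respiration wave normalized to unit peak: respiratory sinus
#' arrhythmia, the rhythmic fluctuation of the cardiac cycle at the
#' breathing frequency. With `rsa_depth = 0` the output is independent of
#' the respiration content. The result is zero-mean with peak amplitude
#' `params$amplitude`.
#'
#' @param params from [pulseParams()].
#' @param resp a respiration [WaveformSeries-class] covering the same
#'   duration at the same rate.
#' @param duration_s,rate_hz length and sampling rate.
#' @param seed RNG seed (reserved; generation is currently deterministic
#'   given `params` and `resp`).
#' @return a [WaveformSeries-class] of kind `"pulse"`.
#' @export
generatePulse <- function(params, resp, duration_s, rate_hz, seed = 1L) {
  n <- round(duration_s * rate_hz)
  if (!is(resp, "WaveformSeries") || length(resp@samples) != n ||
      abs(resp@rateHz - rate_hz) > 1e-9)
    stop("respiration series does not match the requested duration and rate")
  r <- resp@samples
  if (params$rsa_depth > 0 && max(abs(r)) > 0) r <- r / max(abs(r))
  finst <- (params$hr_bpm / 60) * (1 + params$rsa_depth * r)
  phase <- 2 * pi * cumsum(finst) / rate_hz
  phase <- phase - phase[1]
  x <- rep(0, n)
  for (k in seq_along(params$harmonic_amps))
    x <- x + params$harmonic_amps[k] * sin(k * phase)
  x <- x - mean(x)
  pk <- max(abs(x))
  if (pk > 0) x <- params$amplitude * x / pk
  WaveformSeries(x, rate_hz, "pulse")
}

#' Render a synthetic clip from the skin reflection model
#'
#' Skin pixels follow
#' `i0 * (1 + psi(t)) * (c_skin + phi(t) + pulse(t) + resp(t)) + noise`;
#' background pixels use the same expression with the pulse and respiration
#' terms forced to zero. `psi` is a slow sinusoid plus the sinusoidal motion
#' disturbance at `motion_freq_hz`; `phi` is a low-frequency specular
#' sinusoid. Phases are drawn from the seeded RNG. Pixel values are clipped
#' to `[0, 1]`; a warning is raised when clipping touches more than 5% of
#' skin samples (the signal is then likely saturated).
#'
#' @param cfg from [sceneConfig()].
#' @param pulse,resp [WaveformSeries-class] objects, one sample per frame.
#' @return a [VideoClip-class] with the skin mask attached.
#' @export
renderScene <- function(cfg, pulse, resp) {
  n <- round(cfg$duration_s * cfg$frame_rate)
  if (length(pulse@samples) != n || length(resp@samples) != n)
    stop("waveform lengths must match the configured frame count")
  H <- cfg$frame_size[1]; W <- cfg$frame_size[2]
  msk <- ellipseMask(cfg)
  i0 <- if (is.matrix(cfg$i0)) cfg$i0 else matrix(cfg$i0, H, W)
  tt <- (seq_len(n) - 1) / cfg$frame_rate

  set.seed(cfg$seed)
  ph <- runif(3, 0, 2 * pi)
  psi <- cfg$psi_amp * sin(2 * pi * cfg$psi_freq_hz * tt + ph[1]) +
    cfg$motion_amp * sin(2 * pi * cfg$motion_freq_hz * tt + ph[2])
  phi <- cfg$phi_amp * sin(2 * pi * cfg$phi_freq_hz * tt + ph[3])
  physio <- pulse@samples + resp@samples

  i0v <- as.vector(i0)              # length H*W
  i0skin <- i0v * as.vector(msk)
  frames <- array(0, dim = c(n, H, W, 3))
  for (ch in 1:3) {
    base <- (1 + psi) * (cfg$c_skin[ch] + phi)       # per-frame, everywhere
    extra <- (1 + psi) * physio                      # per-frame, skin only
    frames[, , , ch] <- outer(base, i0v) + outer(extra, i0skin)
  }
  if (cfg$noise_sigma > 0)
    frames <- frames + rnorm(length(frames), 0, cfg$noise_sigma)

  # fraction of *skin* samples clipped: replicate the mask over (t, ch)
  skin_rep <- rep(rep(as.vector(msk), each = n), 3)
  n_skin_clip <- sum((frames < 0 | frames > 1) & skin_rep)
  if (n_skin_clip > 0.05 * sum(msk) * n * 3)
    warning("clipping affects >5% of skin samples; signal likely saturated")
  frames[frames < 0] <- 0
  frames[frames > 1] <- 1
  VideoClip(frames, cfg$frame_rate, skinMask = msk)
}

#' Write a reproducible synthetic dataset to disk
#'
#' Draws per-clip heart and respiration rates uniformly from the given
#' ranges, renders each clip and writes a tuple per clip: the clip tensor
#' (lossless RDS container, or MP4 when `format = "mp4"` and ffmpeg is
#' available), the pulse and respiration waveforms as 2-column CSV
#' (`time_s,value`) and a metadata JSON. A manifest JSON listing files and
#' true rates is returned (and written) and is byte-identical across calls
#' with the same seed.
#'
#' @param n_clips number of clips (0 gives an empty manifest, no files).
#' @param out_dir output directory, created if needed.
#' @param hr_range,rr_range uniform sampling ranges (bpm).
#' @param scene base [sceneConfig()]; its seed is re-derived per clip.
#' @param pulse_template,resp_template parameter templates; the rates are
#'   overwritten per clip.
#' @param seed master seed.
#' @param format `"rds"` (lossless) or `"mp4"` (requires ffmpeg; 8-bit).
#' @return (invisibly) the manifest as a list; also written to
#'   `out_dir/manifest.json`.
#' @export
makeDataset <- function(n_clips, out_dir, hr_range = c(48, 120),
                        rr_range = c(10, 25), scene = sceneConfig(),
                        pulse_template = pulseParams(),
                        resp_template = respirationParams(),
                        seed = 1L, format = c("rds", "mp4")) {
  format <- match.arg(format)
  stopifnot(n_clips >= 0, hr_range[1] >= 40, hr_range[2] <= 180,
            hr_range[1] < hr_range[2], rr_range[1] >= 6, rr_range[2] <= 30,
            rr_range[1] < rr_range[2])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  set.seed(as.integer(seed))
  hrs <- runif(n_clips, hr_range[1], hr_range[2])
  rrs <- runif(n_clips, rr_range[1], rr_range[2])
  clips <- vector("list", n_clips)
  for (i in seq_len(n_clips)) {
    clip_seed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    pp <- pulse_template; pp$hr_bpm <- hrs[i]
    rp <- resp_template;  rp$rr_bpm <- rrs[i]
    cfg <- scene; cfg$seed <- clip_seed
    resp <- generateRespiration(rp, cfg$duration_s, cfg$frame_rate,
                                seed = clip_seed)
    pulse <- generatePulse(pp, resp, cfg$duration_s, cfg$frame_rate,
                           seed = clip_seed)
    clip <- renderScene(cfg, pulse, resp)

    stem <- sprintf("clip_%03d", i)
    clip_file <- file.path(out_dir, paste0(stem, if (format == "rds") ".rds" else ".mp4"))
    if (format == "rds") saveRDS(clip, clip_file, compress = FALSE)
    else writeVideoClip(clip, clip_file)
    tt <- (seq_len(length(pulse@samples)) - 1) / cfg$frame_rate
    write.csv(data.frame(time_s = tt, value = pulse@samples),
              file.path(out_dir, paste0(stem, "_pulse.csv")), row.names = FALSE)
    write.csv(data.frame(time_s = tt, value = resp@samples),
              file.path(out_dir, paste0(stem, "_resp.csv")), row.names = FALSE)
    meta <- list(hr_bpm = hrs[i], rr_bpm = rrs[i],
                 frame_rate = cfg$frame_rate, duration_s = cfg$duration_s,
                 seed = clip_seed)
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = 10),
               file.path(out_dir, paste0(stem, "_meta.json")))
    clips[[i]] <- list(clip = basename(clip_file),
                       pulse = paste0(stem, "_pulse.csv"),
                       resp = paste0(stem, "_resp.csv"),
                       hr_bpm = hrs[i], rr_bpm = rrs[i],
                       frame_rate = cfg$frame_rate)
  }
  manifest <- list(n_clips = n_clips, seed = as.integer(seed),
                   format = format, clips = clips)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = 10,
                              pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Read a manifest written by [makeDataset()]
#' @param dir dataset directory containing `manifest.json`.
#' @return the manifest list, with a `dir` element added.
#' @export
readManifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir)
  m <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  m$dir <- dir
  m
}

#' Load one clip (and its waveforms) referenced by a manifest entry
#' @param manifest from [readManifest()].
#' @param i clip index.
#' @return list with `clip` ([VideoClip-class]), `pulse`, `resp`
#'   ([WaveformSeries-class]) and the true rates.
#' @export
loadClip <- function(manifest, i) {
  e <- manifest$clips[[i]]
  path <- file.path(manifest$dir, e$clip)
  clip <- if (grepl("\\.rds$", path)) readRDS(path)
          else readVideoClip(path, e$frame_rate)
  pu <- read.csv(file.path(manifest$dir, e$pulse))
  re <- read.csv(file.path(manifest$dir, e$resp))
  list(clip = clip,
       pulse = WaveformSeries(pu$value, e$frame_rate, "pulse"),
       resp = WaveformSeries(re$value, e$frame_rate, "respiration"),
       hr_bpm = e$hr_bpm, rr_bpm = e$rr_bpm)
}
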