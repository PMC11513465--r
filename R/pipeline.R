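# Orchestration: dataset generation, training, evaluation, ablation and the
# optional compression-robustness harness. Every run writes a resolved
# configuration snapshot next to its outputs so no result depends on
# unlogged state.

#' Assemble a run configuration
#'
#' Defaults reproduce the package's desk-scale study conditions: 20 fps,
#' 10 s clips, 36 x 36 input, 32-sample windows with half-window stride,
#' reduced channel preset, Huber loss, Adadelta at learning rate 1.
#'
#' @param dataset_dir directory holding a [makeDataset()] manifest.
#' @param out_dir output directory for checkpoints/metrics.
#' @param checkpoint checkpoint path (for `runEval`).
#' @param network from [networkConfig()].
#' @param loss from [lossConfig()].
#' @param L,T_win,stride preprocessing geometry; `stride` is the hop between
#'   training windows (default `T_win`, non-overlapping).
#' @param eval_stride hop between inference windows (default `T_win / 2`;
#'   overlapping predictions are averaged sample-wise when stitching).
#' @param hr_band,rr_band [bandSpec()] presets.
#' @param epochs,batch_size,lr training hyperparameters.
#' @param val_fraction fraction of clips held out for validation.
#' @param resume_from optional checkpoint path; training continues from its
#'   weights (with a fresh optimizer state).
#' @param seed global seed, propagated to every stochastic component.
#' @return config list.
#' @export
runConfig <- function(dataset_dir = NULL, out_dir = tempfile("run"),
                      checkpoint = NULL, resume_from = NULL,
                      network = networkConfigReduced(),
                      loss = lossConfig("huber"),
                      L = 36, T_win = 32, stride = T_win,
                      eval_stride = T_win %/% 2L,
                      hr_band = hrBand(), rr_band = rrBand(),
                      epochs = 5, batch_size = 4, lr = 1.0,
                      val_fraction = 1 / 6, seed = 1L) {
  stopifnot(T_win >= 4, stride >= 1, eval_stride >= 1, epochs >= 1,
            batch_size >= 1, val_fraction >= 0, val_fraction < 1)
  list(dataset_dir = dataset_dir, out_dir = out_dir, checkpoint = checkpoint,
       resume_from = resume_from,
       network = network, loss = loss, L = as.integer(L),
       T_win = as.integer(T_win), stride = as.integer(stride),
       eval_stride = as.integer(eval_stride),
       hr_band = hr_band, rr_band = rr_band, epochs = as.integer(epochs),
       batch_size = as.integer(batch_size), lr = lr,
       val_fraction = val_fraction, seed = as.integer(seed))
}

#' Load a run configuration from YAML
#'
#' Scalar fields override the [runConfig()] defaults; `network` and `loss`
#' sub-maps are forwarded to [networkConfig()] and [lossConfig()].
#'
#' @param path YAML file.
#' @return config list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("network", "loss", "hr_band", "rr_band"))]
  if (!is.null(y$network)) args$network <- do.call(networkConfig, y$network)
  if (!is.null(y$loss)) args$loss <- do.call(lossConfig, y$loss)
  if (!is.null(y$hr_band)) args$hr_band <- do.call(bandSpec, y$hr_band)
  if (!is.null(y$rr_band)) args$rr_band <- do.call(bandSpec, y$rr_band)
  do.call(runConfig, args)
}

snapshotConfig <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 10,
                              pretty = TRUE, null = "null", force = TRUE),
             file.path(out_dir, "config_snapshot.json"))
}

# preprocess every clip of a manifest into aligned windows
datasetWindows <- function(manifest, cfg, with_labels = TRUE,
                           stride = cfg$stride) {
  out <- list()
  for (i in seq_along(manifest$clips)) {
    loaded <- tryCatch(loadClip(manifest, i), error = function(e) e)
    if (inherits(loaded, "error")) {
      warning("skipping clip ", i, ": ", conditionMessage(loaded))
      next
    }
    pair <- motionAppearance(loaded$clip, L = cfg$L)
    labels <- if (with_labels) makeLabels(loaded$pulse, loaded$resp) else NULL
    wins <- windowPairs(pair, labels, T_win = cfg$T_win, stride = stride)
    out[[length(out) + 1]] <- list(clip_index = i, windows = wins,
                                   pair = pair, labels = labels,
                                   hr_bpm = loaded$hr_bpm,
                                   rr_bpm = loaded$rr_bpm,
                                   rate_hz = loaded$clip@frameRate)
  }
  if (length(out) == 0) stop("empty dataset: no readable clips")
  out
}

#' Train a model on a synthetic-dataset manifest
#'
#' Splits clips into train/validation (the last `val_fraction` of clips,
#' a fixed clip-level split), preprocesses, windows, trains with Adadelta
#' and writes the checkpoint (`checkpoint.rds` + JSON sidecar with the
#' network config), a per-epoch loss CSV and a config snapshot.
#'
#' @param cfg from [runConfig()]; `dataset_dir` must hold a manifest.
#' @return `list(model, history, checkpoint)`.
#' @export
runTrain <- function(cfg) {
  manifest <- readManifest(cfg$dataset_dir)
  snapshotConfig(cfg, cfg$out_dir)
  clips <- datasetWindows(readManifest(cfg$dataset_dir), cfg)
  n_val <- floor(length(clips) * cfg$val_fraction)
  val_idx <- if (n_val > 0) tail(seq_along(clips), n_val) else integer(0)
  tr <- unlist(lapply(clips[setdiff(seq_along(clips), val_idx)],
                      `[[`, "windows"), recursive = FALSE)
  va <- unlist(lapply(clips[val_idx], `[[`, "windows"), recursive = FALSE)
  if (length(tr) == 0) stop("no training windows")
  message(sprintf("training on %d windows (%d validation)",
                  length(tr), length(va)))
  model <- buildModel(cfg$network, seed = cfg$seed)
  if (!is.null(cfg$resume_from)) {
    prev <- loadCheckpoint(cfg$resume_from)
    model <- prev
  }
  fit <- trainModel(model, tr, va, lossCfg = cfg$loss, epochs = cfg$epochs,
                    batch_size = cfg$batch_size, lr = cfg$lr,
                    seed = cfg$seed)
  ckpt <- file.path(cfg$out_dir, "checkpoint.rds")
  saveRDS(list(params = fit$model@params, config = fit$model@config,
               history = fit$history), ckpt)
  writeLines(jsonlite::toJSON(fit$model@config, auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(cfg$out_dir, "checkpoint_config.json"))
  write.csv(fit$history, file.path(cfg$out_dir, "history.csv"),
            row.names = FALSE)
  list(model = fit$model, history = fit$history, checkpoint = ckpt)
}

#' Load a checkpoint written by [runTrain()]
#' @param path the `checkpoint.rds` file.
#' @return an [RppgModel-class].
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  new("RppgModel", config = ck$config, params = ck$params)
}

# overlap-average windowed predictions into one full-length waveform
stitchPredictions <- function(model, wins, len, task) {
  acc <- rep(0, len); cnt <- rep(0, len)
  for (w in wins) {
    pred <- forwardModel(model, w$motion, w$appearance)[[task]]
    idx <- w$start:(w$start + length(pred) - 1)
    acc[idx] <- acc[idx] + pred
    cnt[idx] <- cnt[idx] + 1
  }
  acc / pmax(cnt, 1)
}

#' Evaluate a trained model on a dataset
#'
#' For each clip: windowed inference, sample-wise overlap averaging of the
#' predicted derivative waveform, band-pass filtering and spectral-peak
#' rate estimation per task; then aggregate agreement metrics. Writes a
#' per-clip CSV and a metrics JSON when `cfg$out_dir` is set.
#'
#' @param cfg from [runConfig()]; needs `dataset_dir` and either
#'   `checkpoint` or a `model` argument.
#' @param model optionally, an already-loaded [RppgModel-class].
#' @return `list(hr, rr, per_clip)`: [MetricsReport-class] objects (rr
#'   `NULL` for single-task models) and the per-clip data.frame.
#' @export
runEval <- function(cfg, model = NULL) {
  if (is.null(model)) {
    if (is.null(cfg$checkpoint)) stop("no checkpoint or model given")
    model <- loadCheckpoint(cfg$checkpoint)
  }
  clips <- datasetWindows(readManifest(cfg$dataset_dir), cfg,
                          with_labels = FALSE,
                          stride = if (is.null(cfg$eval_stride)) cfg$stride
                                   else cfg$eval_stride)
  multi <- "respiration" %in% model@config$tasks
  rows <- lapply(clips, function(cl) {
    len <- dim(cl$pair@motion)[1]
    hr_hat <- estimateRate(
      stitchPredictions(model, cl$windows, len, "pulse"),
      cl$rate_hz, cfg$hr_band, min_cycles = 0.5)@bpm
    rr_hat <- if (multi) estimateRate(
      stitchPredictions(model, cl$windows, len, "respiration"),
      cl$rate_hz, cfg$rr_band, min_cycles = 0.5)@bpm else NA_real_
    data.frame(clip = cl$clip_index, hr_true = cl$hr_bpm, hr_est = hr_hat,
               rr_true = cl$rr_bpm, rr_est = rr_hat)
  })
  tab <- do.call(rbind, rows)
  hr <- rateMetrics(tab$hr_est, tab$hr_true)
  rr <- if (multi) rateMetrics(tab$rr_est, tab$rr_true) else NULL
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(tab, file.path(cfg$out_dir, "per_clip.csv"), row.names = FALSE)
    met <- list(hr = list(mae = hr@maeBpm, rmse = hr@rmseBpm,
                          r = hr@pearsonR, bias = hr@bias,
                          loa = c(hr@loaLow, hr@loaHigh)))
    if (multi) met$rr <- list(mae = rr@maeBpm, rmse = rr@rmseBpm,
                              r = rr@pearsonR)
    writeLines(jsonlite::toJSON(met, auto_unbox = TRUE, digits = 10,
                                pretty = TRUE),
               file.path(cfg$out_dir, "metrics.json"))
  }
  list(hr = hr, rr = rr, per_clip = tab)
}

#' Train/evaluate an ablation grid on one seeded dataset
#'
#' Variants of the full model with one module changed at a time: CDC vs
#' vanilla convolution, attention on/off, multi- vs single-task, or
#' alternative losses. Each variant trains from the same seed on the same
#' training manifest and is evaluated on the same test manifest.
#'
#' @param cfg base [runConfig()] (its `dataset_dir` is the training set).
#' @param test_dir manifest directory for evaluation.
#' @param variants named list; each element is a list of overrides with any
#'   of `variant`, `attention`, `tasks`, `loss_name`, `alpha`, `beta`.
#' @return data.frame with one row per variant (HR/RR MAE, RMSE, r).
#' @export
runAblation <- function(cfg, test_dir,
                        variants = list(
                          full = list(),
                          vanilla_conv = list(variant = "vanilla"),
                          no_attention = list(attention = FALSE),
                          single_task = list(tasks = "pulse", beta = 0))) {
  rows <- lapply(names(variants), function(nm) {
    v <- variants[[nm]]
    net <- cfg$network
    if (!is.null(v$variant)) net$variant <- v$variant
    if (!is.null(v$attention)) net$attention <- v$attention
    if (!is.null(v$tasks)) net$tasks <- v$tasks
    loss <- cfg$loss
    if (!is.null(v$loss_name)) loss$name <- v$loss_name
    if (!is.null(v$alpha)) loss$alpha <- v$alpha
    if (!is.null(v$beta)) loss$beta <- v$beta
    vcfg <- cfg
    vcfg$network <- net
    vcfg$loss <- loss
    vcfg$out_dir <- file.path(cfg$out_dir, nm)
    fit <- runTrain(vcfg)
    vcfg$dataset_dir <- test_dir
    ev <- runEval(vcfg, model = fit$model)
    data.frame(variant = nm,
               hr_mae = ev$hr@maeBpm, hr_rmse = ev$hr@rmseBpm,
               hr_r = ev$hr@pearsonR,
               rr_mae = if (is.null(ev$rr)) NA_real_ else ev$rr@maeBpm,
               rr_r = if (is.null(ev$rr)) NA_real_ else ev$rr@pearsonR)
  })
  tab <- do.call(rbind, rows)
  write.csv(tab, file.path(cfg$out_dir, "ablation.csv"), row.names = FALSE)
  tab
}

# ---- video I/O and the compression harness (requires ffmpeg) ----------

ffmpegPath <- function() {
  p <- Sys.which("ffmpeg")
  if (!nzchar(p))
    stop("this feature requires the external 'ffmpeg' encoder on PATH; ",
         "it is an optional dependency of the compression harness")
  p
}

#' Write a clip as an H.264 video file (requires ffmpeg)
#'
#' Frames are quantized to 8 bits and piped to ffmpeg as raw RGB video.
#' In-memory clips stay float; quantization happens only here.
#'
#' @param clip a [VideoClip-class].
#' @param path output file (`.mp4`/`.avi`).
#' @param bitrate_kbps target bitrate; `NULL` uses lossless-leaning default
#'   (crf 0).
#' @return `path`, invisibly.
#' @export
writeVideoClip <- function(clip, path, bitrate_kbps = NULL) {
  ff <- ffmpegPath()
  d <- dim(clip@frames)
  raw_path <- tempfile(fileext = ".rgb")
  on.exit(unlink(raw_path))
  # (T,H,W,3) -> per frame row-major H x W x 3 interleaved bytes
  q <- as.integer(round(clip@frames * 255))
  con <- file(raw_path, "wb")
  for (t in seq_len(d[1])) {
    fr <- q[t, , , ]                      # (H, W, 3)
    writeBin(as.raw(as.vector(aperm(fr, c(3, 2, 1)))), con)
  }
  close(con)
  qual <- if (is.null(bitrate_kbps)) c("-crf", "0")
          else c("-b:v", sprintf("%dk", as.integer(bitrate_kbps)))
  args <- c("-y", "-f", "rawvideo", "-pixel_format", "rgb24",
            "-video_size", sprintf("%dx%d", d[3], d[2]),
            "-framerate", sprintf("%.6f", clip@frameRate),
            "-i", raw_path, "-c:v", "libx264", "-pix_fmt", "yuv420p",
            qual, path)
  status <- system2(ff, args, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("ffmpeg encoding failed")
  invisible(path)
}

#' Read a video file into a VideoClip (requires ffmpeg)
#'
#' @param path video file.
#' @param frame_rate frame rate to stamp on the clip (videos written by
#'   [writeVideoClip()] carry it in the container, but raw decode needs it).
#' @return a [VideoClip-class].
#' @export
readVideoClip <- function(path, frame_rate) {
  ff <- ffmpegPath()
  probe <- system2(ff, c("-i", path, "-hide_banner"), stdout = TRUE,
                   stderr = TRUE)
  dim_line <- grep("Video:", probe, value = TRUE)[1]
  m <- regmatches(dim_line, regexpr("[0-9]+x[0-9]+", dim_line))
  wh <- as.integer(strsplit(m, "x")[[1]])
  raw_path <- tempfile(fileext = ".rgb")
  on.exit(unlink(raw_path))
  status <- system2(ff, c("-y", "-i", path, "-f", "rawvideo",
                          "-pix_fmt", "rgb24", raw_path),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("ffmpeg decoding failed")
  bytes <- readBin(raw_path, "raw", file.size(raw_path))
  W <- wh[1]; H <- wh[2]
  Tn <- length(bytes) / (W * H * 3)
  if (Tn != round(Tn)) stop("unexpected raw video size")
  x <- as.integer(bytes) / 255
  arr <- array(x, dim = c(3, W, H, Tn))       # interleaved, row-major frames
  VideoClip(aperm(arr, c(4, 3, 2, 1)), frame_rate)
}

#' Re-encode a video at a target bitrate (requires ffmpeg)
#'
#' H.264 re-encoding at `bitrate_kbps` (default 250 kb/s, the compression
#' level of the hardest public benchmark); returns a decodable clip with
#' the same frame count and rate, enabling before/after-compression
#' comparisons on synthetic data.
#'
#' @param path source video file.
#' @param bitrate_kbps target bitrate in kb/s.
#' @param out output path (default: `<path>_250kbps.mp4` style sibling).
#' @return the output path, invisibly.
#' @export
reencodeClip <- function(path, bitrate_kbps = 250, out = NULL) {
  ff <- ffmpegPath()
  if (is.null(out))
    out <- sub("(\\.[a-zA-Z0-9]+)$",
               sprintf("_%dkbps.mp4", as.integer(bitrate_kbps)), path)
  status <- system2(ff, c("-y", "-i", path, "-c:v", "libx264", "-b:v",
                          sprintf("%dk", as.integer(bitrate_kbps)), out),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("ffmpeg re-encoding failed")
  invisible(out)
}
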