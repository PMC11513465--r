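# Dual-branch motion/appearance attention network.
#
# Motion branch: conv1 -> conv2 -> (soft attention from appearance conv2)
#   -> avg pool 1x2x2 -> dropout -> conv3 -> conv4 -> (attention from
#   appearance conv4) -> pool -> dropout -> per-time-step flatten ->
#   dense(hidden, tanh) -> dropout -> one linear head per task, one output
#   per time step. Pooling is spatial only, so the temporal length is
#   preserved end to end.
# Appearance branch: mirrors conv1-conv4 (with the same pooling) but lacks
#   the last three layers (flatten+dense, dropout, heads); it feeds the two
#   1x1x1-conv attention heads.
#
# All convolutions are CDC operators (see cdc3d); swapping the variant to
# "vanilla" changes no shapes and no parameter counts, which is what makes
# the CDC-vs-plain-3D ablation well posed. Backpropagation is written out
# by hand and verified against finite differences in the test suite.

#' Network configuration
#'
#' The published description fixes the input side (36), the pooling/dropout
#' placement and the attention positions ("right before the pooling
#' layers"); channel widths, kernel, dense width, theta and the activation
#' are package defaults exposed here.
#'
#' @param L input side length; must be divisible by 4 (two 1x2x2 pools).
#' @param channels 4 conv widths (default `c(32, 32, 64, 64)`; the reduced
#'   test preset is `c(8, 8, 16, 16)`).
#' @param kernel 3 odd ints, default `c(3, 3, 3)`.
#' @param theta CDC intensity/gradient trade-off in `[0, 1]` (default 0.6).
#' @param variant `"temporal"` (default), `"spatiotemporal"` or `"vanilla"`.
#' @param hidden dense width (default 128).
#' @param tasks `c("pulse")` or `c("pulse", "respiration")`.
#' @param dropout three rates: after each pool and before the heads.
#' @param attention logical; `FALSE` replaces each mask by uniform weights
#'   with the same per-frame spatial sum (the ablation variant).
#' @return validated config list.
#' @export
networkConfig <- function(L = 36, channels = c(32, 32, 64, 64),
                          kernel = c(3, 3, 3), theta = 0.6,
                          variant = c("temporal", "spatiotemporal", "vanilla"),
                          hidden = 128, tasks = c("pulse", "respiration"),
                          dropout = c(0.25, 0.25, 0.5), attention = TRUE) {
  variant <- match.arg(variant)
  stopifnot(L %% 4 == 0, L >= 8, length(channels) == 4, all(channels >= 1),
            length(kernel) == 3, all(kernel %% 2 == 1),
            theta >= 0, theta <= 1, hidden >= 1,
            all(tasks %in% c("pulse", "respiration")), length(tasks) >= 1,
            length(dropout) == 3, all(dropout >= 0 & dropout < 1))
  list(L = as.integer(L), channels = as.integer(channels),
       kernel = as.integer(kernel), theta = theta, variant = variant,
       hidden = as.integer(hidden), tasks = tasks, dropout = dropout,
       attention = isTRUE(attention))
}

#' Reduced test preset of [networkConfig()]
#' @param ... overrides forwarded to [networkConfig()].
#' @return config list with channels 8/8/16/16.
#' @export
networkConfigReduced <- function(...) {
  networkConfig(channels = c(8, 8, 16, 16), ...)
}

glorot <- function(dims) {
  k <- prod(dims[seq_len(length(dims) - 2)])
  fan_in <- k * dims[length(dims) - 1]
  fan_out <- k * dims[length(dims)]
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

#' Build the dual-branch model
#'
#' Initializes all weights (Glorot uniform, biases zero) from the seed.
#'
#' @param cfg from [networkConfig()].
#' @param seed RNG seed for initialization.
#' @return an [RppgModel-class].
#' @export
buildModel <- function(cfg, seed = 1L) {
  set.seed(as.integer(seed))
  k <- cfg$kernel
  ch <- cfg$channels
  featdim <- (cfg$L %/% 4L)^2 * ch[4]
  convW <- function(cin, cout) glorot(c(k[1], k[2], k[3], cin, cout))
  dense <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(runif(nin * nout, -lim, lim), nin, nout)
  }
  params <- list(
    mW1 = convW(3, ch[1]),     mb1 = rep(0, ch[1]),
    mW2 = convW(ch[1], ch[2]), mb2 = rep(0, ch[2]),
    mW3 = convW(ch[2], ch[3]), mb3 = rep(0, ch[3]),
    mW4 = convW(ch[3], ch[4]), mb4 = rep(0, ch[4]),
    aW1 = convW(3, ch[1]),     ab1 = rep(0, ch[1]),
    aW2 = convW(ch[1], ch[2]), ab2 = rep(0, ch[2]),
    aW3 = convW(ch[2], ch[3]), ab3 = rep(0, ch[3]),
    aW4 = convW(ch[3], ch[4]), ab4 = rep(0, ch[4]),
    atW1 = array(glorot(c(1, 1, 1, ch[2], 1)), dim = c(1, 1, 1, ch[2], 1)),
    atb1 = 0,
    atW2 = array(glorot(c(1, 1, 1, ch[4], 1)), dim = c(1, 1, 1, ch[4], 1)),
    atb2 = 0,
    Wh = dense(featdim, cfg$hidden), bh = rep(0, cfg$hidden))
  for (task in cfg$tasks) {
    params[[paste0("headW_", task)]] <- dense(cfg$hidden, 1L)
    params[[paste0("headb_", task)]] <- 0
  }
  new("RppgModel", config = cfg, params = params)
}

# ---- primitive layers -------------------------------------------------

sigmoidFn <- function(z) 1 / (1 + exp(-z))

# 1x1x1 single-output convolution over channels: (T,H,W,C) -> (T,H,W)
lin1x1 <- function(a, wvec, b) {
  d <- dim(a)
  z <- matrix(a, prod(d[1:3]), d[4]) %*% wvec + b
  array(z, dim = d[1:3])
}

# spatial 1x2x2 average pooling
avgPool2 <- function(x) {
  d <- dim(x)
  i1 <- seq(1, d[2], by = 2); i2 <- i1 + 1
  j1 <- seq(1, d[3], by = 2); j2 <- j1 + 1
  (x[, i1, j1, , drop = FALSE] + x[, i2, j1, , drop = FALSE] +
     x[, i1, j2, , drop = FALSE] + x[, i2, j2, , drop = FALSE]) / 4
}

avgPool2Backward <- function(dout, dimIn) {
  dx <- array(0, dim = dimIn)
  d <- dim(dout)
  i1 <- seq(1, dimIn[2], by = 2); i2 <- i1 + 1
  j1 <- seq(1, dimIn[3], by = 2); j2 <- j1 + 1
  g <- dout / 4
  dx[, i1, j1, ] <- g; dx[, i2, j1, ] <- g
  dx[, i1, j2, ] <- g; dx[, i2, j2, ] <- g
  dx
}

# per-frame L1 mask normalization: mask = (H*W/2) * s / sum_hw(s)
maskNormalize <- function(s) {
  d <- dim(s)
  k <- d[2] * d[3] / 2
  ms <- matrix(s, d[1])
  array(k * ms / rowSums(ms), dim = d)
}

#' Soft attention mask applied to motion features
#'
#' The mask is the sigmoid of a 1x1x1 convolution of the appearance feature
#' map, L1-normalized per frame and scaled by \eqn{H_j W_j / 2}, so its
#' spatial sum is exactly \eqn{H_j W_j / 2} on every frame. The masked
#' motion features are `mask * motion_feat`, broadcast over channels.
#'
#' @param appearance_feat `(T, H, W, C)` appearance feature map.
#' @param head `list(w, b)`: `w` a length-`C` vector (or `(1,1,1,C,1)`
#'   array), `b` a scalar.
#' @param motion_feat `(T, H, W, C')` motion feature map sharing `T, H, W`.
#' @return `list(masked, mask)`.
#' @export
softAttention <- function(appearance_feat, head, motion_feat) {
  da <- dim(appearance_feat); dm <- dim(motion_feat)
  if (!all(da[1:3] == dm[1:3]))
    stop("appearance and motion feature maps must share (T, H, W)")
  wvec <- as.vector(head$w)
  if (length(wvec) != da[4]) stop("attention kernel does not match channels")
  s <- sigmoidFn(lin1x1(appearance_feat, wvec, head$b))
  mask <- maskNormalize(s)
  list(masked = motion_feat * as.vector(mask), mask = mask)
}

# backward through mask normalization + sigmoid + 1x1x1 conv.
# dmask: (T,H,W); s: sigmoid output; a: appearance features; wvec weights.
attentionBackward <- function(dmask, s, a, wvec) {
  d <- dim(s)
  k <- d[2] * d[3] / 2
  ms <- matrix(s, d[1]); mdm <- matrix(dmask, d[1])
  S <- rowSums(ms)
  A <- rowSums(mdm * ms)
  ds <- k / S * (mdm - A / S)            # rows recycled per frame
  ds <- array(as.vector(ds), dim = d)
  dz <- ds * s * (1 - s)
  P <- prod(d)
  dzv <- as.vector(dz)
  amat <- matrix(a, P, dim(a)[4])
  list(dw = as.vector(crossprod(amat, dzv)),
       db = sum(dzv),
       da = array(outer(dzv, wvec), dim = dim(a)))
}

dropoutMask <- function(n, p) {
  if (p <= 0) return(NULL)
  (runif(n) >= p) / (1 - p)
}

applyMask <- function(x, m) if (is.null(m)) x else x * as.vector(m)

# ---- forward / backward ----------------------------------------------

# Full forward pass. train = TRUE draws dropout masks from the current RNG
# and caches every intermediate needed by modelBackward.
modelForward <- function(model, motion, appearance, train = FALSE) {
  if (anyNA(motion) || anyNA(appearance) ||
      any(!is.finite(motion)) || any(!is.finite(appearance)))
    stop("NaN/Inf in network input")
  p <- model@params
  cfg <- model@config
  spec <- function(w) list(weights = w, theta = cfg$theta,
                           variant = cfg$variant)
  Tn <- dim(motion)[1]
  cache <- list(motion = motion, appearance = appearance, train = train)

  useAtt <- cfg$attention
  if (useAtt) {
    a1 <- tanh(cdc3d(appearance, spec(p$aW1), p$ab1))
    a2 <- tanh(cdc3d(a1, spec(p$aW2), p$ab2))
    s1 <- sigmoidFn(lin1x1(a2, as.vector(p$atW1), p$atb1))
    mask1 <- maskNormalize(s1)
    ap <- avgPool2(a2)
    a3 <- tanh(cdc3d(ap, spec(p$aW3), p$ab3))
    a4 <- tanh(cdc3d(a3, spec(p$aW4), p$ab4))
    s2 <- sigmoidFn(lin1x1(a4, as.vector(p$atW2), p$atb2))
    mask2 <- maskNormalize(s2)
    cache[c("a1", "a2", "s1", "ap", "a3", "a4", "s2")] <-
      list(a1, a2, s1, ap, a3, a4, s2)
  } else {
    # uniform weights with the same per-frame spatial sum (H*W/2)
    mask1 <- array(0.5, dim = c(Tn, cfg$L, cfg$L))
    mask2 <- array(0.5, dim = c(Tn, cfg$L %/% 2L, cfg$L %/% 2L))
  }
  cache$mask1 <- mask1; cache$mask2 <- mask2

  x1 <- tanh(cdc3d(motion, spec(p$mW1), p$mb1))
  x2 <- tanh(cdc3d(x1, spec(p$mW2), p$mb2))
  x2m <- x2 * as.vector(mask1)
  p1 <- avgPool2(x2m)
  dm1 <- if (train) dropoutMask(length(p1), cfg$dropout[1]) else NULL
  d1 <- applyMask(p1, dm1)
  x3 <- tanh(cdc3d(d1, spec(p$mW3), p$mb3))
  x4 <- tanh(cdc3d(x3, spec(p$mW4), p$mb4))
  x4m <- x4 * as.vector(mask2)
  p2 <- avgPool2(x4m)
  dm2 <- if (train) dropoutMask(length(p2), cfg$dropout[2]) else NULL
  d2 <- applyMask(p2, dm2)
  Fm <- matrix(d2, Tn)
  h <- tanh(sweep(Fm %*% p$Wh, 2, p$bh, "+"))
  dm3 <- if (train) dropoutMask(length(h), cfg$dropout[3]) else NULL
  hd <- applyMask(h, dm3)
  out <- list()
  for (task in cfg$tasks)
    out[[task]] <- drop(hd %*% p[[paste0("headW_", task)]]) +
      p[[paste0("headb_", task)]]

  cache[c("x1", "x2", "x2m", "p1", "dm1", "d1", "x3", "x4", "x4m",
          "p2", "dm2", "d2", "h", "dm3", "hd")] <-
    list(x1, x2, x2m, p1, dm1, d1, x3, x4, x4m, p2, dm2, d2, h, dm3, hd)
  list(pred = out, cache = cache)
}

# Backward pass: dpred is a named list of per-task output gradients
# (each length T). Returns the gradient list (same names as params).
modelBackward <- function(model, cache, dpred) {
  p <- model@params
  cfg <- model@config
  spec <- function(w) list(weights = w, theta = cfg$theta,
                           variant = cfg$variant)
  g <- list()
  Tn <- dim(cache$motion)[1]

  dhd <- matrix(0, Tn, cfg$hidden)
  for (task in cfg$tasks) {
    dy <- dpred[[task]]
    if (is.null(dy)) next
    wname <- paste0("headW_", task); bname <- paste0("headb_", task)
    g[[wname]] <- crossprod(cache$hd, dy)
    g[[bname]] <- sum(dy)
    dhd <- dhd + dy %*% t(p[[wname]])
  }
  dh <- if (is.null(cache$dm3)) dhd else dhd * as.vector(cache$dm3)
  dzh <- dh * (1 - cache$h^2)
  Fm <- matrix(cache$d2, Tn)
  g$Wh <- crossprod(Fm, dzh)
  g$bh <- colSums(dzh)
  dd2 <- array(dzh %*% t(p$Wh), dim = dim(cache$d2))
  dp2 <- if (is.null(cache$dm2)) dd2 else dd2 * as.vector(cache$dm2)
  dx4m <- avgPool2Backward(dp2, dim(cache$x4m))

  dmask2 <- array(rowSums(matrix(dx4m * cache$x4, ncol = dim(cache$x4)[4])),
                  dim = dim(cache$mask2))
  dx4 <- dx4m * as.vector(cache$mask2)
  dz4 <- dx4 * (1 - cache$x4^2)
  b4 <- cdc3dBackward(cache$x3, spec(p$mW4), dz4)
  g$mW4 <- b4$dw; g$mb4 <- b4$db
  dz3 <- b4$dx * (1 - cache$x3^2)
  b3 <- cdc3dBackward(cache$d1, spec(p$mW3), dz3)
  g$mW3 <- b3$dw; g$mb3 <- b3$db
  dd1 <- b3$dx
  dp1 <- if (is.null(cache$dm1)) dd1 else dd1 * as.vector(cache$dm1)
  dx2m <- avgPool2Backward(dp1, dim(cache$x2m))
  dmask1 <- array(rowSums(matrix(dx2m * cache$x2, ncol = dim(cache$x2)[4])),
                  dim = dim(cache$mask1))
  dx2 <- dx2m * as.vector(cache$mask1)
  dz2 <- dx2 * (1 - cache$x2^2)
  b2 <- cdc3dBackward(cache$x1, spec(p$mW2), dz2)
  g$mW2 <- b2$dw; g$mb2 <- b2$db
  dz1 <- b2$dx * (1 - cache$x1^2)
  b1 <- cdc3dBackward(cache$motion, spec(p$mW1), dz1, need_dx = FALSE)
  g$mW1 <- b1$dw; g$mb1 <- b1$db

  if (cfg$attention) {
    at2 <- attentionBackward(dmask2, cache$s2, cache$a4, as.vector(p$atW2))
    g$atW2 <- array(at2$dw, dim = dim(p$atW2)); g$atb2 <- at2$db
    da4 <- at2$da
    dza4 <- da4 * (1 - cache$a4^2)
    ba4 <- cdc3dBackward(cache$a3, spec(p$aW4), dza4)
    g$aW4 <- ba4$dw; g$ab4 <- ba4$db
    dza3 <- ba4$dx * (1 - cache$a3^2)
    ba3 <- cdc3dBackward(cache$ap, spec(p$aW3), dza3)
    g$aW3 <- ba3$dw; g$ab3 <- ba3$db
    da2_pool <- avgPool2Backward(ba3$dx, dim(cache$a2))
    at1 <- attentionBackward(dmask1, cache$s1, cache$a2, as.vector(p$atW1))
    g$atW1 <- array(at1$dw, dim = dim(p$atW1)); g$atb1 <- at1$db
    da2 <- da2_pool + at1$da
    dza2 <- da2 * (1 - cache$a2^2)
    ba2 <- cdc3dBackward(cache$a1, spec(p$aW2), dza2)
    g$aW2 <- ba2$dw; g$ab2 <- ba2$db
    dza1 <- ba2$dx * (1 - cache$a1^2)
    ba1 <- cdc3dBackward(cache$appearance, spec(p$aW1), dza1, need_dx = FALSE)
    g$aW1 <- ba1$dw; g$ab1 <- ba1$db
  }
  g
}

#' Run the network on a motion/appearance window (inference)
#'
#' Deterministic (dropout disabled). Returns one predicted derivative value
#' per time step for each configured task.
#'
#' @param model an [RppgModel-class].
#' @param motion,appearance `(T, L, L, 3)` arrays, or a
#'   [MotionAppearancePair-class] as `motion` (then `appearance` is taken
#'   from it).
#' @return named list of numeric vectors (one per task).
#' @export
forwardModel <- function(model, motion, appearance = NULL) {
  if (is(motion, "MotionAppearancePair")) {
    appearance <- motion@appearance
    motion <- motion@motion
  }
  modelForward(model, motion, appearance, train = FALSE)$pred
}

#' Number of learnable parameters
#' @param model an [RppgModel-class].
#' @return integer count.
#' @export
parameterCount <- function(model) {
  sum(vapply(model@params, length, integer(1)))
}

# ---- training ---------------------------------------------------------

adadeltaInit <- function(params) {
  list(Eg = lapply(params, function(x) x * 0),
       Edx = lapply(params, function(x) x * 0))
}

adadeltaUpdate <- function(params, grads, state, lr = 1.0, rho = 0.95,
                           eps = 1e-7) {
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$Eg[[nm]] <- rho * state$Eg[[nm]] + (1 - rho) * gr^2
    dx <- -sqrt(state$Edx[[nm]] + eps) / sqrt(state$Eg[[nm]] + eps) * gr
    state$Edx[[nm]] <- rho * state$Edx[[nm]] + (1 - rho) * dx^2
    params[[nm]] <- params[[nm]] + lr * dx
  }
  list(params = params, state = state)
}

windowLossGrad <- function(model, w, lossCfg, train = TRUE) {
  fw <- modelForward(model, w$motion, w$appearance, train = train)
  cfg <- model@config
  dpred <- list()
  lv <- 0
  lp <- lossValueGrad(w$pulse, fw$pred$pulse, lossCfg)
  lv <- lv + lossCfg$alpha * lp$value
  dpred$pulse <- lossCfg$alpha * lp$grad
  if ("respiration" %in% cfg$tasks && lossCfg$beta > 0) {
    lr_ <- lossValueGrad(w$resp, fw$pred$respiration, lossCfg)
    lv <- lv + lossCfg$beta * lr_$value
    dpred$respiration <- lossCfg$beta * lr_$grad
  }
  list(value = lv, fw = fw, dpred = dpred)
}

#' Train the model with Adadelta
#'
#' Mini-batch training with the Adadelta optimizer (learning rate 1.0,
#' rho 0.95, epsilon 1e-7 — the optimizer's standard defaults apart from
#' the learning rate). Records per-epoch training and validation loss and
#' keeps the parameters with the best validation loss. Fully seeded:
#' shuffling and dropout draw from one RNG stream initialized from `seed`.
#'
#' @param model an [RppgModel-class] from [buildModel()].
#' @param windows list of training windows from [windowPairs()].
#' @param val_windows list of validation windows (may be empty; the
#'   training loss is then used for checkpoint selection).
#' @param lossCfg from [lossConfig()].
#' @param epochs number of passes over the windows.
#' @param batch_size windows per optimizer step.
#' @param lr Adadelta learning rate (default 1.0).
#' @param seed RNG seed.
#' @return `list(model, history)`: the best-validation model and a
#'   data.frame with per-epoch `train_loss` and `val_loss`.
#' @export
trainModel <- function(model, windows, val_windows = list(),
                       lossCfg = lossConfig("huber"), epochs = 5,
                       batch_size = 4, lr = 1.0, seed = 1L) {
  if (length(windows) == 0) stop("empty training set")
  set.seed(as.integer(seed))
  params <- model@params
  state <- adadeltaInit(params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = params)

  for (ep in seq_len(epochs)) {
    ord <- sample(length(windows))
    batch_losses <- c()
    i <- 1
    while (i <= length(ord)) {
      idx <- ord[i:min(i + batch_size - 1, length(ord))]
      i <- i + batch_size
      acc <- NULL
      bl <- 0
      for (j in idx) {
        model@params <- params
        r <- windowLossGrad(model, windows[[j]], lossCfg, train = TRUE)
        if (!is.finite(r$value))
          stop("divergent loss (NaN/Inf) at epoch ", ep)
        bl <- bl + r$value
        gr <- modelBackward(model, r$fw$cache, r$dpred)
        if (is.null(acc)) acc <- gr
        else for (nm in names(gr)) acc[[nm]] <- acc[[nm]] + gr[[nm]]
      }
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(idx)
      up <- adadeltaUpdate(params, acc, state, lr = lr)
      params <- up$params
      state <- up$state
      batch_losses <- c(batch_losses, bl / length(idx))
    }
    model@params <- params
    vl <- if (length(val_windows) > 0) {
      mean(vapply(val_windows, function(w)
        windowLossGrad(model, w, lossCfg, train = FALSE)$value, numeric(1)))
    } else mean(batch_losses)
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = mean(batch_losses),
                                         val_loss = vl))
    if (vl < best$loss) best <- list(loss = vl, params = params)
  }
  model@params <- best$params
  list(model = model, history = history)
}
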