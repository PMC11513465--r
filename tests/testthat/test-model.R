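tinyNet <- function(...) networkConfig(L = 8, channels = c(2, 2, 2, 2),
                                       hidden = 4, dropout = c(0, 0, 0), ...)
randIn <- function(Tn, L) array(rnorm(Tn * L * L * 3), dim = c(Tn, L, L, 3))

test_that("soft attention mask sums to H*W/2 per frame", {
  set.seed(1)
  af <- randIn(3, 8)
  mf <- array(rnorm(3 * 8 * 8 * 2), dim = c(3, 8, 8, 2))
  head <- list(w = rnorm(3), b = 0.2)
  at <- softAttention(af, head, mf)
  sums <- apply(at$mask, 1, sum)
  expect_equal(sums, rep(8 * 8 / 2, 3), tolerance = 1e-10)
  expect_equal(at$masked, mf * as.vector(at$mask), tolerance = 1e-12)

  # sigmoid output constant 0.5 (zero weights): every mask entry is 0.5
  at0 <- softAttention(af, list(w = rep(0, 3), b = 0), mf)
  expect_equal(as.vector(at0$mask), rep(0.5, 3 * 64), tolerance = 1e-12)

  # concentration limit: one dominant pixel absorbs almost all the weight
  af1 <- array(-40, dim = c(1, 4, 4, 1))
  af1[1, 2, 3, 1] <- 40
  at1 <- softAttention(af1, list(w = 1, b = 0), array(1, dim = c(1, 4, 4, 1)))
  expect_equal(at1$mask[1, 2, 3], 4 * 4 / 2, tolerance = 1e-6)

  expect_error(softAttention(af, head, array(0, dim = c(3, 4, 4, 2))),
               "share")
})

test_that("model shapes follow the configuration contract", {
  cfg <- tinyNet()
  model <- buildModel(cfg, seed = 1)
  out <- forwardModel(model, randIn(6, 8), randIn(6, 8))
  expect_named(out, c("pulse", "respiration"))
  expect_length(out$pulse, 6)
  expect_length(out$respiration, 6)

  m1 <- buildModel(tinyNet(tasks = "pulse"), seed = 1)
  out1 <- forwardModel(m1, randIn(6, 8), randIn(6, 8))
  expect_named(out1, "pulse")

  # any window length is accepted (per-time-step heads share weights)
  out2 <- forwardModel(model, randIn(11, 8), randIn(11, 8))
  expect_length(out2$pulse, 11)

  expect_error(networkConfig(L = 10), "L")
})

test_that("zero motion input yields appearance-independent output", {
  model <- buildModel(tinyNet(), seed = 2)
  z <- array(0, dim = c(5, 8, 8, 3))
  o1 <- forwardModel(model, z, randIn(5, 8))
  o2 <- forwardModel(model, z, 10 * randIn(5, 8))
  expect_equal(o1$pulse, o2$pulse, tolerance = 1e-12)
  expect_error(forwardModel(model, z * NA, randIn(5, 8)), "NaN")
})

test_that("inference is deterministic; training dropout is not a no-op", {
  model <- buildModel(tinyNet(), seed = 3)
  M <- randIn(5, 8); A <- randIn(5, 8)
  expect_identical(forwardModel(model, M, A), forwardModel(model, M, A))

  mdrop <- buildModel(networkConfig(L = 8, channels = c(2, 2, 2, 2),
                                    hidden = 4), seed = 3)
  set.seed(10)
  f1 <- cdcrppg:::modelForward(mdrop, M, A, train = TRUE)$pred$pulse
  set.seed(11)
  f2 <- cdcrppg:::modelForward(mdrop, M, A, train = TRUE)$pred$pulse
  expect_false(isTRUE(all.equal(f1, f2)))
})

test_that("forward pass equals a manual composition of the primitives", {
  cfg <- tinyNet()
  model <- buildModel(cfg, seed = 4)
  p <- model@params
  set.seed(5)
  M <- randIn(4, 8); A <- randIn(4, 8)
  spec <- function(w) cdcKernelSpec(w, theta = cfg$theta,
                                    variant = cfg$variant)
  pool <- function(x) (x[, c(1, 3, 5, 7), c(1, 3, 5, 7), , drop = FALSE] +
                         x[, c(2, 4, 6, 8), c(1, 3, 5, 7), , drop = FALSE] +
                         x[, c(1, 3, 5, 7), c(2, 4, 6, 8), , drop = FALSE] +
                         x[, c(2, 4, 6, 8), c(2, 4, 6, 8), , drop = FALSE]) / 4
  pool2 <- function(x) (x[, c(1, 3), c(1, 3), , drop = FALSE] +
                          x[, c(2, 4), c(1, 3), , drop = FALSE] +
                          x[, c(1, 3), c(2, 4), , drop = FALSE] +
                          x[, c(2, 4), c(2, 4), , drop = FALSE]) / 4

  a1 <- tanh(cdc3d(A, spec(p$aW1), p$ab1))
  a2 <- tanh(cdc3d(a1, spec(p$aW2), p$ab2))
  x1 <- tanh(cdc3d(M, spec(p$mW1), p$mb1))
  x2 <- tanh(cdc3d(x1, spec(p$mW2), p$mb2))
  at1 <- softAttention(a2, list(w = as.vector(p$atW1), b = p$atb1), x2)
  p1 <- pool(at1$masked)
  ap <- pool(a2)
  a3 <- tanh(cdc3d(ap, spec(p$aW3), p$ab3))
  a4 <- tanh(cdc3d(a3, spec(p$aW4), p$ab4))
  x3 <- tanh(cdc3d(p1, spec(p$mW3), p$mb3))
  x4 <- tanh(cdc3d(x3, spec(p$mW4), p$mb4))
  at2 <- softAttention(a4, list(w = as.vector(p$atW2), b = p$atb2), x4)
  p2 <- pool2(at2$masked)
  Fm <- matrix(p2, 4)
  h <- tanh(sweep(Fm %*% p$Wh, 2, p$bh, "+"))
  yp <- drop(h %*% p$headW_pulse) + p$headb_pulse

  got <- forwardModel(model, M, A)
  expect_equal(got$pulse, yp, tolerance = 1e-10)
})

test_that("model backprop matches finite differences on every group", {
  cfg <- tinyNet()
  model <- buildModel(cfg, seed = 6)
  set.seed(7)
  M <- randIn(4, 8); A <- randIn(4, 8)
  yp <- rnorm(4); yr <- rnorm(4)
  lossOf <- function(params) {
    m2 <- model; m2@params <- params
    fw <- cdcrppg:::modelForward(m2, M, A, train = FALSE)
    huberLoss(yp, fw$pred$pulse) + huberLoss(yr, fw$pred$respiration)
  }
  fw <- cdcrppg:::modelForward(model, M, A, train = FALSE)
  dpred <- list(pulse = cdcrppg:::huberGrad(yp, fw$pred$pulse),
                respiration = cdcrppg:::huberGrad(yr, fw$pred$respiration))
  g <- cdcrppg:::modelBackward(model, fw$cache, dpred)
  eps <- 1e-5
  for (nm in names(g)) {
    idx <- if (length(model@params[[nm]]) <= 3)
      seq_along(model@params[[nm]]) else sample(length(model@params[[nm]]), 3)
    for (i in idx) {
      pp <- model@params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- model@params; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (lossOf(pp) - lossOf(pm)) / (2 * eps)
      expect_equal(as.vector(g[[nm]])[i], fd, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("training runs, records history, and is seed-reproducible", {
  cfg <- tinyNet()
  set.seed(20)
  wins <- lapply(1:4, function(i)
    list(motion = randIn(6, 8), appearance = randIn(6, 8),
         pulse = rnorm(6), resp = rnorm(6)))
  m <- buildModel(cfg, seed = 1)
  fit <- trainModel(m, wins, epochs = 1, batch_size = 2, seed = 5)
  expect_equal(nrow(fit$history), 1)
  expect_true(is.finite(fit$history$train_loss))

  fit2 <- trainModel(m, wins, epochs = 1, batch_size = 2, seed = 5)
  expect_identical(fit$model@params, fit2$model@params)

  fit3 <- trainModel(m, wins, epochs = 1, batch_size = 2, seed = 6)
  expect_false(identical(fit$model@params, fit3$model@params))

  expect_error(trainModel(m, list(), epochs = 1), "empty")
})

test_that("loss trends downward on a learnable synthetic signal", {
  # motion windows carry the target pattern; five epochs must beat one
  cfg <- tinyNet()
  set.seed(30)
  mkwin <- function() {
    y <- sin(2 * pi * (1:6) / 4 + runif(1, 0, 2 * pi))
    mo <- array(0.05 * rnorm(6 * 8 * 8 * 3), dim = c(6, 8, 8, 3)) + y
    list(motion = mo, appearance = randIn(6, 8), pulse = y, resp = y)
  }
  wins <- lapply(1:8, function(i) mkwin())
  m <- buildModel(cfg, seed = 2)
  f1 <- trainModel(m, wins, epochs = 1, batch_size = 2, seed = 9)
  f5 <- trainModel(m, wins, epochs = 5, batch_size = 2, seed = 9)
  expect_lt(tail(f5$history$train_loss, 1), f1$history$train_loss[1])
})

test_that("attention-off models preserve shapes and the mask-sum identity", {
  cfg_on <- tinyNet()
  cfg_off <- tinyNet(attention = FALSE)
  m_on <- buildModel(cfg_on, seed = 1)
  m_off <- buildModel(cfg_off, seed = 1)
  M <- randIn(4, 8); A <- randIn(4, 8)
  fw <- cdcrppg:::modelForward(m_off, M, A)
  expect_length(fw$pred$pulse, 4)
  # uniform replacement mask keeps the same per-frame spatial sum
  expect_equal(apply(fw$cache$mask1, 1, sum), rep(8 * 8 / 2, 4))
  expect_equal(apply(fw$cache$mask2, 1, sum), rep(4 * 4 / 2, 4))
  expect_equal(parameterCount(m_on), parameterCount(m_off))
})
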