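constantClip <- function(value, Tn = 4, side = 8, rate = 10) {
  VideoClip(array(value, dim = c(Tn, side, side, 3)), rate)
}

test_that("bicubic downscale preserves constants and matches the identity", {
  cc <- constantClip(0.4)
  out <- downscaleClip(cc, 4)
  expect_equal(frames(out), array(0.4, dim = c(4, 4, 4, 3)))

  tc <- tinyClip()
  same <- downscaleClip(tc$clip, dim(frames(tc$clip))[2])
  expect_equal(frames(same), frames(tc$clip), tolerance = 1e-9)

  expect_error(downscaleClip(tc$clip, 3), "at least 4")
  expect_error(downscaleClip(tc$clip, 999), "larger")
})

test_that("bicubic downscale matches a naive per-pixel oracle", {
  set.seed(5)
  # checkerboard mixed with noise exercises both kernel lobes
  img <- (matrix(runif(8 * 8), 8, 8) +
            outer(1:8, 1:8, function(i, j) (i + j) %% 2)) / 2.5
  arr <- array(0, dim = c(2, 8, 8, 3))
  for (t in 1:2) for (ch in 1:3) arr[t, , , ch] <- img
  out <- downscaleClip(VideoClip(arr, 10), 4)
  expect_equal(out@frames[1, , , 1], pmin(pmax(bicubicOracle(img, 4), 0), 1),
               tolerance = 1e-6)
})

test_that("normalized frame difference follows its closed form", {
  # pixel stepping 0.2 -> 0.3 gives 0.1 / 0.5 = 0.2
  fr <- array(0.2, dim = c(2, 4, 4, 3))
  fr[2, , , ] <- 0.3
  raw <- normalizedFrameDiff(VideoClip(fr, 10), standardize = FALSE)
  expect_equal(as.vector(raw), rep(0.2, 48), tolerance = 1e-5)

  # constant clip: numerator vanishes
  raw0 <- normalizedFrameDiff(constantClip(0.5), standardize = FALSE)
  expect_true(all(raw0 == 0))
  expect_error(normalizedFrameDiff(constantClip(0.5)), "degenerate")
  expect_error(normalizedFrameDiff(constantClip(0)), "degenerate")
})

test_that("raw motion representation is invariant to intensity gain", {
  tc <- tinyClip(scene = tinyScene(noise_sigma = 0.001))
  # rescale so that a gain of 10 still fits in [0, 1]
  fr <- frames(tc$clip) * (0.1 / max(frames(tc$clip)))
  base <- normalizedFrameDiff(VideoClip(fr, 10), standardize = FALSE)
  for (g in c(0.5, 2, 10)) {
    out <- normalizedFrameDiff(VideoClip(g * fr, 10), standardize = FALSE)
    expect_equal(out, base, tolerance = 1e-5)
  }
})

test_that("standardized motion and appearance have the stated moments", {
  tc <- tinyClip()
  mo <- suppressWarnings(normalizedFrameDiff(tc$clip))
  expect_equal(mean(mo), 0, tolerance = 1e-9)
  expect_equal(sd(mo), 1, tolerance = 1e-9)

  ap <- standardizeAppearance(tc$clip)
  Tn <- dim(frames(tc$clip))[1]
  expect_equal(dim(ap)[1], Tn - 1)
  for (ch in 1:3) {
    expect_equal(mean(ap[, , , ch]), 0, tolerance = 1e-9)
    expect_equal(sd(ap[, , , ch]), 1, tolerance = 1e-9)
  }
  # positive affine transforms leave the output unchanged
  f2 <- pmin(pmax(frames(tc$clip) * 0.4 + 0.2, 0), 1)
  ap2 <- standardizeAppearance(VideoClip(f2, 10))
  expect_equal(ap2, ap, tolerance = 1e-9)
  # the output is a fixed point of per-channel standardization
  for (ch in 1:3) {
    v <- ap[, , , ch]
    expect_equal((v - mean(v)) / sd(v), v, tolerance = 1e-6)
  }
  expect_error(standardizeAppearance(constantClip(0.3)), "degenerate")
})

test_that("labels are standardized first differences with intact spectra", {
  fs <- 30; n <- 300
  tt <- (seq_len(n) - 1) / fs
  pulse <- WaveformSeries(sin(2 * pi * 1.2 * tt), fs, "pulse")
  resp <- WaveformSeries(sin(2 * pi * 0.3 * tt), fs, "respiration")
  lab <- makeLabels(pulse, resp)
  expect_length(lab@pulse, n - 1)
  expect_equal(mean(lab@pulse), 0, tolerance = 1e-12)
  expect_equal(sd(lab@pulse), 1, tolerance = 1e-12)
  expect_equal(periodogramArgmax(lab@pulse, fs), 1.2, tolerance = 0.05)

  ramp <- WaveformSeries(seq(0, 1, length.out = n), fs, "pulse")
  expect_error(makeLabels(ramp, resp), "degenerate")
})

test_that("window slicing follows the count formula and stays aligned", {
  tc <- tinyClip()
  pair <- motionAppearance(tc$clip, L = 12)
  labels <- makeLabels(tc$pulse, tc$resp)
  len <- dim(motionInput(pair))[1]

  w1 <- windowPairs(pair, labels, T_win = len, stride = 10)
  expect_length(w1, 1)

  # len = 39 here; emulate the enumeration formula on several strides
  for (st in c(5, 13, len)) {
    w <- windowPairs(pair, labels, T_win = 13, stride = st)
    expect_length(w, floor((len - 13) / st) + 1)
  }
  w <- windowPairs(pair, labels, T_win = 13, stride = 13)
  expect_equal(dim(w[[2]]$motion)[1], 13)
  expect_equal(w[[2]]$pulse, labels@pulse[14:26])
  expect_equal(w[[2]]$appearance, appearanceInput(pair)[14:26, , , ,
                                                        drop = FALSE])

  expect_warning(w0 <- windowPairs(pair, labels, T_win = len + 1, stride = 1),
                 "longer")
  expect_length(w0, 0)
})

test_that("motionAppearance couples the two branches consistently", {
  tc <- tinyClip()
  pair <- motionAppearance(tc$clip, L = 12)
  expect_s4_class(pair, "MotionAppearancePair")
  expect_identical(dim(motionInput(pair)), dim(appearanceInput(pair)))
  expect_equal(dim(motionInput(pair))[2], 12)
  expect_equal(frameRate(pair), frameRate(tc$clip))
})
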