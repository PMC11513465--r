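test_that("respiration generator produces a zero-mean sinusoid at rr/60 Hz", {
  r <- generateRespiration(respirationParams(rr_bpm = 15, amplitude = 0.01),
                           duration_s = 20, rate_hz = 10)
  expect_equal(periodogramArgmax(samples(r), 10), 0.25, tolerance = 1e-8)
  expect_equal(mean(samples(r)), 0, tolerance = 1e-12)

  z <- generateRespiration(respirationParams(amplitude = 0), 5, 10)
  expect_true(all(samples(z) == 0))

  j1 <- generateRespiration(respirationParams(), 5, 10, seed = 9,
                            jitter_sd = 0.02)
  j2 <- generateRespiration(respirationParams(), 5, 10, seed = 9,
                            jitter_sd = 0.02)
  expect_identical(samples(j1), samples(j2))
  expect_error(generateRespiration(respirationParams(), -1, 10),
               "positive")
})

test_that("pulse generator peaks at the heart rate and respects RSA coupling", {
  resp <- generateRespiration(respirationParams(rr_bpm = 15), 10, 20)
  # bin-aligned pure sinusoid: 60 bpm over 10 s at 20 Hz
  p <- generatePulse(pulseParams(hr_bpm = 60, harmonic_amps = 1,
                                 rsa_depth = 0), resp, 10, 20)
  expect_equal(periodogramArgmax(samples(p), 20), 1.0, tolerance = 1e-9)
  expect_equal(mean(samples(p)), 0, tolerance = 1e-12)

  # with coupling off, the output is invariant to respiration content
  resp2 <- generateRespiration(respirationParams(rr_bpm = 25), 10, 20)
  p2 <- generatePulse(pulseParams(hr_bpm = 60, harmonic_amps = 1,
                                  rsa_depth = 0), resp2, 10, 20)
  expect_identical(samples(p), samples(p2))

  expect_error(generatePulse(pulseParams(), resp, 5, 20), "match")
})

test_that("RSA modulates the instantaneous frequency at the breathing rate", {
  fs <- 50; dur <- 40
  resp <- generateRespiration(respirationParams(rr_bpm = 15), dur, fs)
  p <- generatePulse(pulseParams(hr_bpm = 72, harmonic_amps = 1,
                                 rsa_depth = 0.05), resp, dur, fs)
  fi <- instFreqHz(samples(p), fs)
  fi <- fi[100:(length(fi) - 100)]          # drop edge transients
  f0 <- 72 / 60
  # modulation frequency: spectral peak of the instantaneous-frequency trace
  expect_equal(periodogramArgmax(fi - mean(fi), fs), 0.25, tolerance = 0.02)
  # modulation depth relative to the carrier
  depth <- (max(fi) - min(fi)) / 2 / f0
  expect_equal(depth, 0.05, tolerance = 0.01)
  expect_equal(mean(fi), f0, tolerance = 0.01)
})

test_that("renderer is static when all time-varying amplitudes are zero", {
  sc <- tinyScene(psi_amp = 0, phi_amp = 0, motion_amp = 0, noise_sigma = 0)
  resp <- generateRespiration(respirationParams(amplitude = 0),
                              sc$duration_s, sc$frame_rate)
  pulse <- generatePulse(pulseParams(amplitude = 0), resp,
                         sc$duration_s, sc$frame_rate)
  clip <- renderScene(sc, pulse, resp)
  fr <- frames(clip)
  for (t in 2:dim(fr)[1]) expect_equal(fr[t, , , ], fr[1, , , ])
})

test_that("mean skin trace reproduces the pulse when disturbances are off", {
  sc <- tinyScene(psi_amp = 0, phi_amp = 0, motion_amp = 0, noise_sigma = 0)
  resp <- generateRespiration(respirationParams(amplitude = 0),
                              sc$duration_s, sc$frame_rate)
  pulse <- generatePulse(pulseParams(hr_bpm = 72), resp,
                         sc$duration_s, sc$frame_rate)
  clip <- renderScene(sc, pulse, resp)
  msk <- skinMask(clip)
  tr <- apply(frames(clip)[, , , 2], 1, function(f) mean(f[msk]))
  expect_gte(abs(cor(tr - mean(tr), samples(pulse))), 0.99)
  # background pixels carry no pulse
  bg <- apply(frames(clip)[, , , 2], 1, function(f) mean(f[!msk]))
  expect_lt(sd(bg), 1e-12)
})

test_that("rendering is linear in pulse amplitude and equivariant to gain", {
  sc <- tinyScene(psi_amp = 0, phi_amp = 0, motion_amp = 0, noise_sigma = 0)
  resp <- generateRespiration(respirationParams(amplitude = 0),
                              sc$duration_s, sc$frame_rate)
  p1 <- generatePulse(pulseParams(hr_bpm = 80, amplitude = 0.005), resp,
                      sc$duration_s, sc$frame_rate)
  p2 <- generatePulse(pulseParams(hr_bpm = 80, amplitude = 0.010), resp,
                      sc$duration_s, sc$frame_rate)
  trace <- function(p) {
    clip <- renderScene(sc, p, resp)
    msk <- skinMask(clip)
    tr <- apply(frames(clip)[, , , 1], 1, function(f) mean(f[msk]))
    tr - mean(tr)
  }
  t1 <- trace(p1); t2 <- trace(p2)
  expect_equal(max(abs(t2 - 2 * t1)) / max(abs(t2)), 0, tolerance = 1e-6)

  # scaling i0 by g scales frames by g (before clipping; noise off)
  g <- 0.5
  sc_g <- tinyScene(i0 = g, psi_amp = 0, phi_amp = 0, motion_amp = 0,
                    noise_sigma = 0)
  c1 <- renderScene(sc, p1, resp)
  cg <- renderScene(sc_g, p1, resp)
  expect_equal(frames(cg), g * frames(c1), tolerance = 1e-12)
})

test_that("spectral peak of the skin trace matches the heart rate", {
  sc <- sceneConfig(psi_amp = 0, phi_amp = 0, motion_amp = 0,
                    noise_sigma = 0, frame_size = c(24, 24))
  resp <- generateRespiration(respirationParams(amplitude = 0), 10, 20)
  pulse <- generatePulse(pulseParams(hr_bpm = 90, harmonic_amps = 1,
                                     rsa_depth = 0), resp, 10, 20)
  clip <- renderScene(sc, pulse, resp)
  msk <- skinMask(clip)
  tr <- apply(frames(clip)[, , , 2], 1, function(f) mean(f[msk]))
  # one raw frequency bin = 1/duration = 0.1 Hz
  expect_equal(periodogramArgmax(tr, 20), 90 / 60, tolerance = 0.1)
})

test_that("rendering is deterministic given config and seed", {
  tc1 <- tinyClip(seed = 11, scene = tinyScene(seed = 11))
  tc2 <- tinyClip(seed = 11, scene = tinyScene(seed = 11))
  expect_identical(frames(tc1$clip), frames(tc2$clip))
})

test_that("renderer warns when the signal saturates", {
  sc <- tinyScene(i0 = 1.9, noise_sigma = 0)   # pushes skin pixels past 1
  resp <- generateRespiration(respirationParams(), sc$duration_s,
                              sc$frame_rate)
  pulse <- generatePulse(pulseParams(amplitude = 0.05), resp,
                         sc$duration_s, sc$frame_rate)
  expect_warning(renderScene(sc, pulse, resp), "saturated")
  expect_error(sceneConfig(skin_ellipse = c(0.5, 0.5, 5, 5)), "mask")
})

test_that("dataset writer is reproducible and draws rates in range", {
  d0 <- file.path(tempfile(), "empty")
  m0 <- makeDataset(0, d0, seed = 1)
  expect_equal(m0$n_clips, 0)
  expect_length(list.files(d0, pattern = "clip"), 0)

  scene <- tinyScene()
  d1 <- tempfile(); d2 <- tempfile()
  makeDataset(5, d1, seed = 42, scene = scene)
  makeDataset(5, d2, seed = 42, scene = scene)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))

  m <- readManifest(d1)
  hrs <- vapply(m$clips, function(e) e$hr_bpm, numeric(1))
  rrs <- vapply(m$clips, function(e) e$rr_bpm, numeric(1))
  expect_length(unique(hrs), 5)
  expect_true(all(hrs >= 48 & hrs <= 120))
  expect_true(all(rrs >= 10 & rrs <= 25))

  lc <- loadClip(m, 2)
  expect_s4_class(lc$clip, "VideoClip")
  expect_equal(length(samples(lc$pulse)), dim(frames(lc$clip))[1])
  expect_equal(lc$hr_bpm, hrs[2])
})
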