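# cdcrppg

Remote photoplethysmography (rPPG) in R: recovery of pulse and respiration
waveforms from RGB facial video with a **temporal 3D central difference
convolutional attention network**, trained with a robust Huber loss in a
multi-task setting — plus a physics-based synthetic video simulator so the
entire method is trainable and testable on one CPU without access to
registration-gated video benchmarks.

## Who this is for

Researchers in camera-based physiological measurement (affective computing,
contactless health monitoring) who want a self-contained, inspectable
implementation of an efficient spatio-temporal rPPG recovery pipeline: the
skin-reflection preprocessing, the CDC operator, the dual-branch attention
architecture, the loss family, and the spectral rate estimators, each unit
individually testable against independent oracles.

## The method

A skin pixel is modeled by the dichromatic reflection model
`V(t) = I0 (1 + Psi(t)) (C + Phi(t) + P(t) + R(t)) + noise`, where the
blood-volume pulse `P(t)` is the ~1% signal of interest. Two network inputs
are derived per clip after bicubic downscaling to 36×36:

* **motion**: normalized frame differences
  `(V(t+1) − V(t)) / (V(t+1) + V(t))`, which cancel the static illumination
  `I0` and dominant reflectance `C` (gain invariant by construction);
* **appearance**: standardized frames, feeding soft attention masks
  `(Hj·Wj/2) · sigma(conv1x1x1(X_A)) / ||sigma(·)||_1` that reweight the
  motion features toward skin regions with stronger signal.

Every convolution is a 3D central difference convolution

```
CDC(l0) = sum_{ln in C} w(ln) x(l0+ln) + theta · ( −x(l0) · sum_{ln in R} w(ln) )
```

which aggregates temporal-gradient context at zero extra parameters
(`theta` in [0,1]; temporal variant by default). Two per-time-step linear
heads regress the standardized first-difference pulse and respiration
waveforms under the multi-task Huber objective
`alpha·L_huber(pulse) + beta·L_huber(resp)`, optimized with Adadelta
(learning rate 1.0). Heart and respiration rates are read out as the
highest peak of the band-restricted zero-padded periodogram after
zero-phase second-order Butterworth filtering (0.75–2.5 Hz for HR,
0.08–0.5 Hz for RR), and agreement is summarized by MAE / RMSE / Pearson r
and Bland–Altman limits.

The synthetic simulator runs the reflection model forward with respiratory
sinus arrhythmia coupling between the two waveforms, giving every clip an
exact ground truth. See `vignettes/cdcrppg-methods.Rmd` for the model,
parameter defaults and their rationale, and known limitations.

## Worked example

```r
library(cdcrppg)

scene <- sceneConfig(duration_s = 10, frame_rate = 20, seed = 7)
resp  <- generateRespiration(respirationParams(rr_bpm = 16), 10, 20, seed = 7)
pulse <- generatePulse(pulseParams(hr_bpm = 82), resp, 10, 20)
clip  <- renderScene(scene, pulse, resp)
clip
#> VideoClip: 200 frames, 64x64 px, 20 fps (10.00 s), skin mask (1640 px)

pair <- motionAppearance(clip, L = 36)   # the network's two inputs
pair
#> MotionAppearancePair: 199 samples, 36x36 px, 20 fps

# spectral read-out straight from the mean skin trace of the raw clip
msk   <- skinMask(clip)
trace <- apply(frames(clip)[, , , 2], 1, function(f) mean(f[msk]))
estimateRate(trace, frameRate(clip), hrBand())
#> RateEstimate: 81.45 bpm (peak 1.357 Hz, bin width 0.009766 Hz)
```

The raw spatial average already recovers 81.45 bpm against a true 82 bpm —
on a clean, motionless synthetic scene. The network earns its keep by
learning that pooling (and the harder cases) from data:

```r
train_dir <- tempfile(); test_dir <- tempfile()
makeDataset(60, train_dir, seed = 101)   # HR ~ U[48,120], RR ~ U[10,25]
makeDataset(20, test_dir,  seed = 202)

cfg <- runConfig(dataset_dir = train_dir, seed = 1)  # reduced preset, 5 epochs
fit <- runTrain(cfg)
cfg$dataset_dir <- test_dir
ev  <- runEval(cfg, model = fit$model)
ev$hr
#> MetricsReport over 20 pairs:
#>   MAE 0.245 bpm | RMSE 0.294 bpm | r 1.000
#>   Bland-Altman bias -0.009 bpm, LoA [-0.601, 0.583]
ev$rr
#> MetricsReport over 20 pairs:
#>   MAE 0.469 bpm | RMSE 0.585 bpm | r 0.989
#>   Bland-Altman bias -0.134 bpm, LoA [-1.280, 1.012]
```

That is: after 5 epochs on 60 synthetic clips (≈10 min on one CPU), the
held-out heart rate is recovered to 0.25 bpm MAE with r ≈ 1.0, and
respiration to 0.47 breaths/min — the multi-task heads read both vital
signs from one forward pass. `runAblation()` trains the
CDC-vs-vanilla-convolution, attention-off and single-task variants on the
same seeded data and tabulates the comparison; `blandAltmanPlot()` draws
the agreement plot.

A thin CLI over the same functions lives at `inst/scripts/rppg-cli.R`
(`synth`, `train`, `eval`, `ablate`, `compress-eval` subcommands).

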