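---
title: "Remote physiological signal recovery with cdcrppg: model, simulator and design choices"
author: "cdcrppg maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Remote physiological signal recovery with cdcrppg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cdcrppg)
```

## The problem

Remote photoplethysmography (rPPG) recovers the blood-volume pulse — and,
through it, heart rate — from ordinary RGB video of skin. Cardiac systole
and diastole modulate the light absorbed by skin tissue, producing intensity
changes on the order of 1% of the mean pixel value, buried under
illumination drift, motion, specular reflections and sensor noise. This
package implements an end-to-end recovery method: a dual-branch
convolutional network built on temporal 3D central difference convolution
(3D-CDC) that regresses the pulse *and* respiration derivative waveforms
from facial video, together with a forward simulator of the underlying skin
reflection physics so the whole method can be trained and validated at desk
scale without access to gated video benchmarks.

## The skin reflection model and the simulator

A skin pixel observed by a camera is modeled as

$$V(t) = I_0\,\bigl(1 + \Psi(t)\bigr)\,\bigl(C + \Phi(t) + P(t) + R(t)\bigr) + v_n(t)$$

where $I_0$ is the static illumination (scalar or per-pixel map), $C$ the
static per-channel skin reflectance, $\Psi$ a multiplicative intensity
variation (illumination drift plus motion disturbance), $\Phi$ the
time-varying specular component, $P$ the blood-volume pulse, $R$ a small
additive respiration baseline and $v_n$ camera noise. Background pixels
follow the same expression with $P$ and $R$ forced to zero, so nothing but
the physiological signal separates skin from background.

`renderScene()` runs this model forward. The functional forms of $\Psi$ and
$\Phi$ are not constrained by the physics beyond "slow and non-physiological",
so the simulator realizes them as low-frequency sinusoids (0.10 Hz and
0.23 Hz by default) plus a sinusoidal motion term at `motion_freq_hz`
(0.35 Hz); their phases are drawn from the scene seed.

The pulse `generatePulse()` is a harmonic series over an instantaneous
cardiac phase whose frequency is $f_{hr}\,(1 + d\,r(t))$ — respiratory
sinus arrhythmia (RSA) with fractional depth $d$ (default 0.05) driven by
the normalized respiration wave $r(t)$. Respiration therefore enters the
video twice: through RSA frequency modulation of the pulse and as the small
additive baseline $R(t)$ on skin pixels. That coupling is what makes
multi-task recovery of both signals from one video well posed.

### Default study conditions, and why

All defaults were fixed once, before the evaluation runs, at values a
practitioner would call physiologically and photometrically realistic:

* **Pulse amplitude 0.01** (1% of normalized intensity) — the upper end of
  real rPPG contrast, appropriate for an uncompressed synthetic benchmark.
* **Harmonics (1, 0.3)** — a second harmonic at 30% of the fundamental is
  within the range of contact PPG (the dicrotic shoulder). The network
  regresses *first differences*, where harmonic $k$ gains a factor $k$;
  0.3 keeps the fundamental spectrally dominant after differentiation
  ($0.3 \times 2 = 0.6 < 1$), so the spectral read-out of the ground-truth
  label itself is unambiguous. (A ratio of 0.5 would make the benchmark
  ill-posed: the differentiated label's periodogram peak could sit at
  twice the heart rate.)
* **Disturbances**: illumination drift 0.02, specular flicker 0.01, motion
  0.005, Gaussian noise SD 0.002 (≈ the quantization step of an 8-bit
  sensor). With these, the per-pixel SNR of the pulse in the motion
  representation is near 1 — single pixels are useless and the network must
  pool spatially, which is the behavior under test.
* **Geometry**: 64×64 frames, an axis-aligned skin ellipse covering ≈40% of
  the frame. No face rendering: the method needs a spatial region carrying
  the signal, not facial structure, since it uses no face detection or
  region-of-interest extraction.
* **Clips**: 20 fps, 10 s; heart rate uniform on [48, 120] bpm, respiration
  uniform on [10, 25] breaths/min.

Pixel values are floats in $[0,1]$; 8-bit quantization happens only when a
clip is written to a video container, so in-memory tests are exact.

What the simulator deliberately does **not** emulate: head pose and
non-rigid motion, skin-tone spectra beyond a per-channel reflectance
vector, spatially varying pulse arrival, video compression artifacts
(unless the optional ffmpeg harness is used), and sensor rolling shutter.
Passing the synthetic benchmark therefore demonstrates that the
architecture, losses, and estimators are implemented correctly and can
learn the physics they were designed around — not that the trained weights
transfer to real faces.

## Preprocessing: the motion/appearance inputs

Dividing the first derivative of $V(t)$ by its temporal mean cancels both
$I_0$ and the dominant constant $C$; discretely,

$$\frac{V(t+\Delta t) - V(t)}{V(t+\Delta t) + V(t)}$$

is the *normalized frame difference*, computed per pixel after bicubic
downscaling to $L \times L$ ($L = 36$; spatial averaging first, to reduce
quantization noise). It is exactly invariant to a global intensity gain — a
property the test suite checks for gains 0.5, 2 and 10. A small
$\epsilon_{div} = 10^{-7}$ guards empty denominators. Raw differences are
clamped at 3 standard deviations (outlier suppression; clamping touching
more than 1% of samples is logged) and standardized per clip. The clamp is
applied to the raw differences and standardization afterwards; the reverse
order would make the clamp threshold depend on its own output scale.

The appearance input is the standardized (per clip, per channel) downscaled
frame sequence; frame $t$ is paired with motion sample $t$, so the last
frame is dropped before standardization and the output moments are exactly
0/1. Labels are the standardized first differences of the ground-truth
waveforms, matching the differential nature of the motion input;
differentiation does not move spectral peaks, so rate read-outs are
unaffected.

## The network

Two branches with identical convolutional stems:

* **Motion branch** (input: normalized frame differences): conv1 → conv2 →
  soft attention ⊙ → 1×2×2 average pool → dropout 0.25 → conv3 → conv4 →
  soft attention ⊙ → pool → dropout 0.25 → per-time-step flatten →
  dense(128, tanh) → dropout 0.5 → one linear head per task, one output per
  frame step. Pooling is spatial only; the temporal length is preserved
  end to end.
* **Appearance branch** (input: standardized frames): conv1–conv4 with the
  same pooling but without the last three layers (flatten+dense, dropout,
  heads). Its only outputs are the attention masks.

Every convolution is a **3D central difference convolution**:

$$\mathrm{CDC}(l_0) = \sum_{l_n \in C} \omega(l_n)\,x(l_0 + l_n) \;+\;
\theta\Bigl(-x(l_0) \sum_{l_n \in R} \omega(l_n)\Bigr)$$

with $C$ the full receptive cube and $R$ the difference set. $\theta$
trades intensity against temporal-gradient information and adds no
parameters. The implementation uses the algebraically identical efficient
form $\mathrm{conv}(x) - \theta\, x \cdot \Sigma_R\omega$ (a pointwise
channel mix), which the tests verify against a six-nested-loop direct
summation oracle.

The **soft attention mask** at layer $j$ is

$$M_j = \frac{H_j W_j}{2} \cdot
\frac{\sigma(\omega_j X_A^j + b_j)}{\lVert \sigma(\omega_j X_A^j + b_j)\rVert_1}$$

(1×1×1 convolution, sigmoid, per-frame L1 normalization), applied
multiplicatively to the motion features right before each pooling stage.
The per-frame spatial sum of the mask is $H_j W_j / 2$ by construction — an
identity the suite asserts at initialization and during training. The
attention-off ablation replaces each mask by uniform weights of the same
spatial sum (constant 0.5), changing neither shapes nor parameter counts.

### Choices the architecture description leaves open

The published description fixes the input side (36×36), the
pooling/dropout placement, the attention positions and the Adadelta
learning rate (1.0), but not the channel widths, kernel size, $\theta$,
window length, dense width or activation. Package defaults, exposed in
`networkConfig()`:

| parameter | default | note |
|---|---|---|
| channels | 32/32/64/64 (reduced preset 8/8/16/16) | motion/appearance-attention lineage |
| kernel | 3×3×3 | smallest odd cube |
| $\theta$ | 0.6 | configurable in $[0,1]$ |
| variant | temporal ($R$ = offsets with $dt \ne 0$) | spatiotemporal kept for ablation |
| window `T_win` | 32 frames | 1.6 s at 20 fps |
| dense width | 128 | |
| activation | tanh | zero-preserving, bounded |

Whether the current-time spatial plane belongs in $R$ is ambiguous in the
operator's definition; both readings are implemented (`temporal` excludes
it, `spatiotemporal` includes it) and the default follows the temporal
variant the method is named after.

## Training

Manual backpropagation through the full graph (verified against central
finite differences in the test suite, for the convolution primitives and
for every parameter group of the assembled network) with **Adadelta** at
learning rate 1.0, $\rho = 0.95$, $\epsilon = 10^{-7}$ (the optimizer's
standard defaults otherwise). The multi-task objective is
$\alpha L_{pulse} + \beta L_{resp}$ with $\alpha = \beta = 1$; single-task
heart-rate mode sets $\beta = 0$. The default loss is **Huber** with
$\delta = 1$:

$$L_\delta(e) = \begin{cases} e^2/2 & |e| \le \delta \\
\delta(|e| - \delta/2) & |e| > \delta\end{cases}$$

quadratic near zero, linear in the tails, gradient bounded by $\delta$.
The full loss family — MAE, RMSE (root applied after the batch mean, so its
gradient carries a $1/\mathrm{rmse}$ factor), negative Pearson $1 - r$,
Huber, $\epsilon$-insensitive Huber ($\epsilon = 0.1$), and the unweighted
Huber + Pearson sum — is selectable by name, so the loss comparison is
runnable on synthetic data. The Huber+Pearson combination is an unweighted
sum because no weighting is specified anywhere; "negative Pearson" is
$1 - r$, the convention of the lineage this loss family comes from.

Early stopping by visual inspection of ten-fold cross-validation is not
automatable; instead a fixed clip-level validation split (last 1/6 of
training clips) selects the best-validation-loss checkpoint within a
config-set epoch budget. Training windows are non-overlapping
(`stride = T_win`); at inference, windows overlap by half and predictions
are averaged sample-wise before filtering.

## Rate estimation

Predicted derivative waveforms are filtered with a zero-phase
(forward–backward) second-order Butterworth band-pass — 0.75–2.5 Hz for
heart rate, 0.08–0.5 Hz for respiration — and the rate is
$60 \times \arg\max$ of the zero-padded periodogram (≥2048 points,
sub-bpm resolution) restricted to the band. Zero-phase filtering does not
move the spectral peak but stabilizes waveform overlays. Because the
squared Butterworth magnitude tilts the in-band spectrum, the periodogram
is compensated by the filter's known power response before the argmax;
with that correction an in-band pure tone is located within half a
spectral bin, including near the band edges, and the estimate is invariant
to scaling and differentiation of the input.

One precondition needed loosening: requiring four cycles of the band's
*low edge* would demand 50 s windows for the respiration band (0.08 Hz)
even for breaths at 0.2–0.4 Hz. `estimateRate()` keeps the 4-cycle default;
the whole-clip evaluation path passes `min_cycles = 0.5` so 10 s clips are
admissible. Agreement is reported as MAE, RMSE and Pearson r over per-clip
rates (per-clip, not concatenated-waveform, correlation), plus Bland–Altman
bias and 95% limits of agreement (bias ± 1.96 SD of the differences); with
fewer than two pairs or a degenerate series the correlation is reported as
`NA`, never fabricated.

## Numerical and degenerate-input policy

* Convolutions are zero-padded, stride 1, "same" size in all three
  dimensions.
* Weight init is Glorot uniform from the run seed; biases start at zero
  (so zero motion input provably yields appearance-independent output).
* All-zero clips, constant waveforms and zero-variance channels are
  rejected with explicit degenerate-input errors rather than producing
  NaNs; NaN inputs to the network are refused; a NaN loss aborts training
  with a diagnostic.
* Ties in the periodogram argmax resolve to the lowest frequency
  (`which.max`), deterministic across platforms.
* Every stochastic component (scene phases, noise, rate draws, weight
  init, shuffling, dropout) derives from an explicit seed; identical
  configuration + seed reproduces clips, manifests, weights and metrics
  bit for bit on one machine.

## Desk-scale problem sizes

The package's own evaluation — what `scripts/acceptance.R` and the
acceptance tests run — uses 60 training and 20 held-out clips (10 s,
20 fps, 64×64 rendered, 36×36 network input), the reduced channel preset
8/8/16/16, `T_win = 32`, batch size 4, and 5 training epochs. These sizes
were chosen as the smallest configuration on which the learning problem is
still honest (per-pixel SNR ≈ 1, disjoint train/test generator seeds); a
typical run recovers held-out heart rate with sub-bpm MAE and r ≈ 1.0, and
respiration within ~0.5 breaths/min. The ablation grid (CDC vs vanilla
convolution, attention on/off, multi- vs single-task) runs the same
pipeline at 12 training clips and 2 epochs and reports the direction of
each comparison.

## Known limitations

* The simulator's disturbances are narrowband sinusoids; real illumination
  and motion artifacts are broadband and non-stationary. Robustness
  conclusions beyond the modeled disturbances require real video.
* Appearance in the simulator is static apart from global modulation, so
  the attention task is easier than on moving faces.
* Training is CPU-bound R/C++; the configuration is sized for tens of
  clips, not for the full-scale public benchmarks.
* The compression harness requires an external `ffmpeg`; without it the
  functions fail with a clear message naming the dependency.
* Heart-rate variability and beat-by-beat analysis are out of scope; the
  estimator reports one average rate per clip.
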