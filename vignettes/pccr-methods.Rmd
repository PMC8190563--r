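---
title: "Methods: the pccr model eye, detection pipeline, and its limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the pccr model eye, detection pipeline, and its limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pccr)
```

`pccr` is a desk-top re-implementation of a binocular
pupil-center/corneal-reflection (PC-CR) video eye tracker. Because no
camera hardware is involved, every downstream algorithm is exercised
against a built-in model-eye simulator with exact per-frame ground truth.
This vignette documents the model, the parameters that matter, the
numerical choices, and — importantly — what a green test does *not*
establish.

## 1. The image-plane eye model

The simulator is deliberately a **2-D image-plane model**, not a
ray-traced eyeball: the tracker under test only ever consumes image-plane
quantities (dark-pixel centroids and bright-pixel centroids), so a
renderer that produces the correct image-plane geometry exercises every
line of the analysis code. Per frame and eye it draws, on a uniform
iris/sclera background (grey 120):

* a dark pupil disc (grey 20) of diameter `pupil_mm × M` pixels, centred
  at `frame center + gaze × pupil_travel × M` plus any pupil-decentration
  offset;
* a saturated CR disc (grey 255, default 0.59 mm ≈ 400 detected pixels)
  displaced from the *anatomical* pupil center by `−gaze/H × M`, so the
  PC-CR vector grows by `M/H ≈ 3.31 px` per degree;
* an eyelid occluder covering the top `1 − aperture` of the frame;
* additive Gaussian pixel noise, rounded and clipped to 0–255.

Disc edges are anti-aliased with a 1-px coverage ramp, which is what makes
noiseless sub-pixel centroids accurate to well under 0.05 px.

Key geometric constants (all in `optical_config()`): magnification
`M = 39.7 px/mm`, Hirschberg ratio `H = 12 deg/mm`, frame 640×480 at
395 Hz, screen at 540 mm, interpupillary distance 60 mm. The 60 mm value
is not printed anywhere in the source material; it is implied (to three
decimals) by the stated pair "540 mm ↔ 6.360°" since
`2·atan(30/540) = 6.3597°`, and is adopted as the default.

`pupil_travel` (0.175 mm/deg) sets how far the pupil image moves per
degree; only the *difference* between pupil and CR motion (fixed at `1/H`)
carries gaze information, so this constant is cosmetic for the analysis
but keeps rendered feature motion realistic.

## 2. Stimulus protocols and eye kinematics

Protocols are ordered segments (one fixation target each, screen point or
midline depth target). Choices the source material does not specify:

* **Saccades** between targets follow a minimum-jerk position profile
  (`10τ³ − 15τ⁴ + 6τ⁵`), default 12 frames ≈ 30 ms; in the amplitude-
  recovery tests the duration follows the main-sequence rule
  `21 + 2.2·A` ms.
* **Pupil light response**: first-order exponential with latency 250 ms
  and τ = 400 ms, from a 6 mm dark-adapted baseline to 4 mm under the
  grey-150 step. These are conventional textbook magnitudes, not values
  from the source; they are configurable and only their *order* matters
  for the artifact protocol (a slower pupil simply spreads the same
  regression over a different pupil range).
* **Blinks**: a linear eyelid sweep, 40 frames down + 40 frames up
  (≈100 ms each way). The truth `blink` flag is set exactly when the lid
  edge geometrically overlaps the pupil disc, which makes the flag
  consistent with what the renderer occludes.
* **Pupil-decentration artifact**: `offset = c × (pupil_mm − 4 mm)` with
  `c = 0.02 mm/mm`, applied with opposite horizontal sign in the two eyes.
  Mirroring is the configuration that turns a pure pupil response into an
  apparent vergence change of `2·c·H = 0.48 °/mm = 28.8 arcmin/mm`, which
  is exactly what the light-step regression is designed to catch.

## 3. Pixel noise: a prescribed calibration

The specification of this stated world fixes the noise model (additive
Gaussian per pixel) and prescribes choosing its SD so that the per-frame
SD of detected centroids falls in the empirically reported 0.2–0.5 px
band. A parameter sweep (200 repeated frames per condition, 4 mm and 6 mm
pupils) gave:

| noise SD (grey) | sd(dx) px | sd(dy) px |
|---|---|---|
| 8  | 0.16 | 0.19 |
| 12 | 0.22 | 0.20 |
| 15 | 0.22 | 0.21 |
| 20 | 0.24 | 0.23 |
| 25 | 0.24 | 0.25 |

Two things are worth recording. First, the dominant mechanism is not the
pupil (its 20 000-pixel centroid averages noise to ~0.02 px) but **CR
pixel dropout**: CR pixels sit at 255 and fall below the fixed 250
threshold with probability `Φ(−5/σ)`, so a large random subset of the
~400-pixel blob vanishes each frame. Second, the effect self-limits (the
shrinking denominator compensates), so the achievable band is roughly
0.16–0.25 px whatever σ is. `noise_sd = 20` was frozen as the default —
comfortably inside the band at both pupil sizes — *before* the acceptance
tests were written, and is not revisited. Because the 25-sample SD
estimator itself scatters by ±15 %, band tests average the running SD over
a stretch of ~100 windows rather than trusting one window.

What this generator does **not** emulate: iris texture, eyelashes,
specular reflections other than the CR, corneal asphericity, head/chin
slippage, and physiological fixational drift. A green noise-band test
therefore establishes that the *detector* reaches the reported stability
on clean geometry with sensor-like noise — not that it would on difficult
real footage.

## 4. Detection: two deliberate deviations

The thresholding rules are taken literally: pupil = pixels strictly below
`0.6 × mean(ROI)` (the ROI mean, one of two defensible readings of
"average image brightness"); CR = pixels ≥ 250 regardless of brightness.
Two refinements are ours:

1. **Largest-component filtering** (default) confines the pupil to one
   4-connected blob, implemented by run-length encoding of mask columns
   plus union–find. This makes stray dark corners harmless.
2. **Glint-hole filling.** The CR punches a ~400-pixel hole into the
   pupil mask. The hole sits off-center whenever the eye is rotated, so an
   unfilled mask drags the pupil centroid by `area_CR/area_pupil ≈ 2 %` of
   the PC-CR vector — a pure gain error that a per-eye calibration would
   silently absorb, but that breaks the nominal-conversion round-trip
   (0.24° error at 10° gaze against a 0.05° requirement). Enclosed
   complement components of the pupil blob are therefore re-filled before
   the centroid. `component = FALSE` ("raw" mode) disables both
   refinements for strict parity with the original all-dark-pixels
   procedure.

Validity gates (pupil ≥ 500 px, CR ≥ 20 px at reference optics, scaled by
`(M/39.7)²`) mark frames invalid rather than guessing; the stream
detector then re-seeds its ROI from the full frame.

## 5. Calibration and vergence anchoring

The fixation trigger converts PC-CR pixel SD to degrees through the
*nominal* 18.1 arcmin/px because no calibration exists yet at trigger
time — the only consistent reading of a degree threshold applied before
calibration. Four points over-determine the affine map (8 observations, 6
parameters); plain least squares is used. Target angles are
**screen-referenced (cyclopean)**: both eyes are calibrated against
`atan(offset/D)`, so on-screen fixation reads `left − right = 0` and the
absolute vergence is anchored by adding the geometric screen vergence.
This reproduces absolute staircase levels at depth targets to within
~2 arcmin (the residue is the tangent nonlinearity between eye rotation
`atan(30/d)` and its cyclopean readout, which cancels exactly at the
screen center by symmetry).

The timeout when fixation never stabilises (unspecified in the source) is
an error naming the offending point.

## 6. Quality analysis and artifact correction

Running statistics use trailing 25-sample windows (63 ms at 395 Hz).
Blink flags (windowed pupil-size SD > 0.2 mm, with detection-lost frames
counted as 0 mm pupil) are extended ±5 samples as a recovery margin.
The artifact regression uses samples from light-step onset to 600 ms
after offset; significance is a two-sided t-test at α = 0.05 (the source
says only "significantly different from zero"). The correction is centred
on the mean pupil of the fitting window so that it never shifts mean
vergence, and refitting the corrected series yields a slope of exactly
zero in the noiseless case (ordinary-least-squares orthogonality) — the
degenerate perfect-fit case where the t-statistic is 0/0 is asserted on
the slope, not on its p-value.

## 7. Metrics and the limits of velocity thresholding

Precision RMS is `sqrt(mean(θ_i²))` over consecutive valid samples,
computed per 1-s epoch and averaged across epochs (trailing partial
epochs dropped); precision SD is the per-epoch sample SD. Blink samples
are excluded together with one neighbour on each side.

Velocity is computed by **unfiltered central differences**, honouring the
original design's explicit avoidance of smoothing filters. The cost is
quantified honestly: at the default noise (~0.23 px ≈ 0.07° per sample)
the radial velocity noise is Rayleigh with σ ≈ 20 °/s, so the plumbing
velocity-threshold detector is reliable only for events of roughly 0.5°
and above; the original system used a trained neural network for exactly
this reason, and that component is out of scope here. Consequently:

* detector tests use ≥1–2° saccades with thresholds of 60–80 °/s;
* amplitude recovery across 0.2–8° is measured with `event_metrics()` on
  the *truth* intervals, with `endpoint_window = 20` samples averaged per
  endpoint. Single-sample endpoints (the literal "start point to last
  point" definition, the default `endpoint_window = 1`) carry a positive
  noise bias of `σ²/2A` — ≈40 % at 0.2° — which no amount of event
  repetition removes; endpoint averaging is standard microsaccade practice
  and brings the bias below 2 %.

## 8. Storage formats

Frame streams are written as directories of single-frame 8-bit grey PNGs
rather than multi-page TIFF: no TIFF reader/writer exists in the target R
toolchain, PNG round-trips 8-bit data losslessly through the `png`
package, and per-frame files keep streaming memory flat. All tabular
formats are comma-separated UTF-8 with '.' decimal; blink rows in the
recording are zeroed (as in the original file format) but carry an
explicit `blink` flag so zeros remain distinguishable from data.

## 9. Known limitations

* The simulator's linearity means calibration residuals are essentially
  zero by construction; nothing here validates the ±20° nonlinearity of
  real corneas (explicitly out of the linear calibration's range).
* Hardware-dependent precision/accuracy tables of the original system are
  not reproducible on synthetic data and are deliberately not targeted;
  the substituted criteria are parameter-recovery properties.
* `pupil_mm` from Eq.-1 areas is biased low by ~0.1 % (anti-aliased mask
  cut) — irrelevant for blink SD and artifact regression, which consume
  changes, not absolute size.
* Computer time in recordings is seconds since session start; no absolute
  clock is modelled.
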