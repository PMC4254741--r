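---
title: "Simulating and targeting automated laser axotomy in C. elegans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and targeting automated laser axotomy in C. elegans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axobot)
```

## The problem

Nerve-regeneration studies in *C. elegans* sever single ~300 nm touch-neuron
axons with femtosecond laser pulses and follow the regrowth. Doing this at
screening throughput requires a fully automated loop: a microfluidic chip
stages one L4 worm at a time, presses it against a sieve under a deflectable
membrane, and an image-processing pipeline finds the worm, the ALM soma, and
finally the axon, which a piezo stage aligns onto the fixed laser spot to
within about one camera pixel before the pulse train fires.

`axobot` re-implements that closed loop against a *virtual rig*: a worm
phantom with fully known ground truth, a rendering model for the 5x
bright-field and 63x fluorescence views, actuator models with quantization
and hysteresis, and a geometric ablation criterion. Because the ground truth
is known, every stage of the pipeline can be scored exactly, and the
automation's attrition bookkeeping and statistics can be reproduced.

## The four processing steps

1. **Worm localization (bright field, 5x).** A baseline frame of the empty,
   membrane-deflected trap is subtracted (absolute difference) from the
   snapshot of the trapped worm. The difference is thresholded inside the
   trap ROI (Otsu by default, with a `median + 3 MAD` noise floor; a fixed
   threshold can be configured), components under 300 px are discarded, and
   the area centroid of what remains is the worm position. A centroid within
   5% of the ROI boundary flushes the worm; otherwise the stage centres it.
2. **Soma search (fluorescence, 63x).** The focal plane steps 2.5 µm per
   frame into the body. Each frame is binarized at 8x its mean intensity and
   searched for a circular component with equivalent diameter 2–6 µm and
   circularity `4*pi*A/P^2 >= 0.6`. Ten failed frames flush the worm.
   Circularity uses a convex-hull perimeter (exact for digital discs) because
   sensor noise makes edge-count perimeters overshoot badly.
3. **Neuron verification.** A 0.7 µm piezo z-stack is acquired; each slice is
   filtered with a Laplacian-of-Gaussian kernel (σ = 2 px, truncated at 4σ,
   zero-sum, mirrored borders) and the slice with the highest variance of
   pixel intensity is the focus. Two 150x200 px ROIs flanking the soma are
   searched for a straight, near-horizontal line (orientation accumulator
   over ±30°, scored as a z-score of the line mean against the ROI
   background, with a segment-coverage requirement that rejects round
   blobs). No line on either side means the soma was the AVM, and the worm
   is flushed; otherwise the brighter line marks the anterior axon and the
   head direction.
4. **Axon targeting.** The stage moves 50 µm anterior, the axon is
   re-focused by maximizing the *mean* intensity in its neighbourhood (see
   below), and a proportional loop drives the piezo y-axis:
   `Δy = -Kp * e_k * pixel_size`, with `e_k` the sub-pixel row error of the
   intensity-weighted axon profile centroid at the spot column. The loop
   stops at |e| ≤ 1 px (convergence) or after 10 iterations (flush). The
   pulse train (300 pulses, 4 nJ) fires; the cut lands if the lateral error
   is within the 0.31 µm spot radius and the laser waist sits 0.5–0.9 µm
   below the visible focus.

## Key parameters

| parameter | default | units | why |
|---|---|---|---|
| camera pixel pitch | 6.45 | µm | sensor spec; gives 1.29 µm/px at 5x, 102 nm/px at 63x |
| LoG σ | 2 | px | matches ~300 nm axons at 102 nm/px |
| fine-focus step | 0.7 | µm | piezo stack spacing for Step 3 |
| coarse z-step | 2.5 | µm | Step 2 scan into the body |
| soma threshold | 8 | x mean | empirical cutoff; gain-invariant |
| diameter gate | 2–6 | µm | ALM soma size (diameter reading adopted) |
| `gain_kp` | 0.9 | – | inside the deadbeat-stable region `0 < Kp < 2`; not stated by the source system |
| piezo deadband | 0.1 | µm | hysteresis exists but is unquantified; 4 minimal steps |
| hit tolerance | 0.31 | µm | half the 620 nm 1/e² spot |
| laser z-offset | 0.7 | µm | middle of the working 0.5–0.9 µm band |
| rejection fractions | .10/.10/.091/.035 | of total | observed per-step attrition; leaves 67.4% success |

## What the simulator emulates — and what it does not

The phantom draws a ~600 µm L4 body, two ALM somas (the contralateral one
8–15 µm deeper), an AVM, and anterior processes toward the head with mild
meander; degenerate cases (mis-trapped worm, dark somas, AVM-only or weak
axon, axon beyond piezo reach) are drawn with the configured per-step
probabilities, so each manifests as a real image-level failure at the right
pipeline step.

Optics are a Gaussian-blur model: blur σ grows linearly with defocus
(`σ(dz) = 0.15 + 1.5·|dz|` µm). Two deliberate departures from pure
widefield physics:

* the blur slope was chosen so the soma-detection capture window is smaller
  than one 2.5 µm coarse step — this is the property that makes "nothing
  deeper than 25 µm is findable" a theorem of the simulator rather than an
  accident;
* axon intensity falls off *quadratically* with blur (defocused light is
  treated as lost out of the collection plane). Under strict in-plane flux
  conservation the Step-4 mean-intensity focus metric would be exactly flat
  in z and the procedure unfalsifiable.

Noise is Poisson shot noise at a configurable gain plus Gaussian read noise.
No diffraction, aberration, scattering, PDMS mechanics, or fluid dynamics is
modelled; the valve program is a symbolic, annotated trace. Wall-clock step
durations are *simulated* draws from configured gamma distributions (means
4.8/3.5/3.0/5.7 s; the Step-3 mean is not published and defaults to 3.0 s) —
the package makes no throughput claims. A green suite therefore establishes
the *algorithms and their decision logic* against known geometry, not
performance on real worms.

## Numerical choices

* Population (1/MN) variance for the focus metric; LoG kernel mean-corrected
  to sum exactly to zero; borders mirrored.
* Ties in `fine_focus`/`axon_focus` break to the lowest slice index.
* Piezo moves quantize to 25 nm, stage moves to 0.1 µm; a direction reversal
  (including the first move from rest) consumes the 0.1 µm deadband before
  net motion.
* Fisher's exact test uses the conventional two-sided small-p rule (sum of
  hypergeometric probabilities ≤ that of the observed table, with a 1e-7
  relative slack against floating-point ties); zero-margin tables return 1.
* `run_population` decides step outcomes from the phantom's ground-truth
  flags (`pipeline = "event"`) by default — the imaging pipeline and the
  flags agree by construction and by test, and population-scale statistics
  become tractable; `pipeline = "imaging"` runs the full closed loop.
* Tests run on a reduced sensor (same pitch and objectives, smaller chip):
  pixel geometry and all µm-denominated thresholds are unchanged.

## A worked population run

```{r}
cfg <- run_config()          # event-mode pipeline, published attrition
res <- run_population(350, cfg, seed = 1)
res$summary
```

The per-step rejection fractions are fractions of *all* processed worms
(they sum with the success fraction to 1), matching the published
bookkeeping `100 - 10 - 10 - 9.1 - 3.5 = 67.4`.

```{r}
summarize_reconnection(c(58, 111), c(46, 101))
summarize_reconnection(c(28, 41), c(45, 67))
```

## Known limitations

* The straight-edge detector assumes a trapped, straightened worm (axons
  within ±30° of horizontal); a strongly curled worm would defeat it — as it
  would the real system, which flushes such worms at Step 1.
* An ALM whose posterior process outshines the anterior one is
  misclassified by design ("the brightest axon usually indicates the head"):
  it surfaces as attrition, not as an error.
* The hysteresis model is a pure deadband; real piezo creep and
  history-dependent gain are not modelled.
* The TIFF support covers the package's own uncompressed float subset (plus
  8/16-bit unsigned reads), not arbitrary third-party files.
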