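---
title: "Contactless emotion recognition from radar vital signs and facial video: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{remotion methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

A frequency-modulated continuous-wave (FMCW) radar facing a seated person
receives, mixed down to the intermediate frequency (IF), a tone whose
frequency encodes the chest's range and whose phase encodes sub-wavelength
chest motion. For a sawtooth chirp of bandwidth $B$ and duration $T_c$
(slope $k = B/T_c$) and a chest at range $R = \Delta d + d(t)$,

$$ f_{IF} = \frac{2 k R}{c}, \qquad \varphi_{IF} = \frac{4\pi R}{\lambda}. $$

A 0.1 mm chest displacement at a 77 GHz carrier with a 50 MHz/us slope moves
$f_{IF}$ by only ~33 Hz — about $10^{-3}$ cycles across a 40 us chirp,
invisible in the spectrum — but rotates $\varphi_{IF}$ by ~18.5 degrees.
Phase, not frequency, therefore carries respiration and heartbeat, and the
whole extraction chain is built around it:

1. **MTI clutter removal.** Static reflectors (desks, laptops) put
   slow-time-constant energy in every range bin. For each fast-time
   position, every sliding window of $n$ consecutive frames estimates the
   static component as its mean; each sample's output is the average of
   its (sample − window mean) residuals over all windows containing it.
   This is used to *select* the target bin; the phase itself is read from
   the unfiltered profiles, because subtracting a complex constant from a
   rotating phasor distorts its argument.
2. **Range FFT.** Chirps within a frame are averaged (the chest moves on
   the 50 ms frame scale, not the microsecond chirp scale), a Hann window
   is applied along fast time and the FFT taken; real-valued (single-mixer)
   cubes keep the one-sided spectrum.
3. **Phase extraction.** The complex argument of the dominant bin per
   frame, unwrapped, scaled by $\lambda/4\pi$ into millimetres (mean
   removed), and low-passed with a fourth-order zero-phase Butterworth at
   3.3 Hz — just above the cardiac band. Two unwrapping rules are
   provided. The classical one shifts successive differences larger than
   $\pi$ by the nearest multiple of $2\pi$; it assumes the phase never
   moves more than $\pi$ per sample, which at a 20 Hz frame rate and
   77 GHz caps chest velocity near 15 mm/s — fast deep breathing exceeds
   that. The extraction chain therefore defaults to a *predictive* rule:
   each sample takes the $2\pi$ branch closest to a constant-velocity
   prediction from the two previous samples (the standard remedy in phase
   interferometry), which is exact as long as the phase *acceleration*
   stays below $\pi$ per sample squared — chest motion sits far inside
   that bound. A final zero-net-drift check removes the one remaining
   ambiguity, a velocity alias of a whole $2\pi$ per sample, using the
   physical prior that a seated subject does not drift over the record.
4. **Variational mode decomposition (VMD)** splits the displacement into
   band-limited modes; modes are routed into the respiration band
   [0.1, 0.6] Hz or the cardiac band [0.8, 3.3] Hz by their mean
   instantaneous frequency, the bands are reconstructed by summation, and
   each rate is read off a zero-padded, quadratically interpolated
   spectral peak.
5. **Video keyframes.** Within an 11-frame window the most stable frame
   (smallest summed chi-square histogram distance to its temporal
   neighbours) is kept; the window advances by 8 frames.
6. **Classifier.** Two four-block 1-D CNNs (respiration, heartbeat), one
   four-block 2-D CNN applied per keyframe, parallel feature fusion along
   a shared temporal axis, a 64-unit GRU, and a softmax over
   {relaxed, happy, sad, angry}.

## VMD: formulation and numerical choices

Each mode $u_k$ with centre frequency $\omega_k$ is updated in the
frequency domain by the Wiener-filter step

$$ \hat u_k^{n+1}(\omega) = \frac{\hat f(\omega) - \sum_{i \ne k} \hat u_i(\omega) + \hat\lambda(\omega)/2}{1 + 2\alpha (\omega - \omega_k)^2}, $$

and $\omega_k$ by the power-weighted centroid of $|\hat u_k|^2$ over the
positive frequencies, with optional dual ascent of step $\tau$ on
$\hat\lambda$. Choices that matter:

* **Mirror extension.** The signal is reflected by half its length at each
  end before the updates and cropped after — standard practice to curb
  edge ringing of the implicit periodicity.
* **Defaults** $\alpha = 2000$, $\tau = 0$ (no exact-reconstruction
  constraint: noise should *not* be forced back into the modes),
  `tol = 1e-7` on the summed relative squared mode update, 500 iterations
  maximum. Non-convergence sets a flag rather than failing.
* **Initialization.** Centre frequencies start uniformly spaced over
  $(0, \text{rate}/4]$. A permutation-robustness test guards against
  initialization sensitivity.
* **Mode-count selection.** Scanning $k$ upward, a decomposition is
  over-decomposed when two adjacent centres come within a ratio of 0.9 of
  each other (the scan stops there). Separately, a *spurious* mode — one
  that collects the broadband leakage skirt of a finite record rather than
  a physical oscillation — betrays itself by a flat spectrum; we reject
  decompositions holding a mode whose spectral concentration (largest
  power bin over total power) falls below 0.3. Pure stability rules
  cannot do this job: matching all centres at $k$ onto those at $k-1$
  rejects every genuinely discovered mode, while the reverse direction
  accepts leakage modes that persist across $k$. Concentration is the
  discriminator VMD's own objective suggests (modes are band-limited by
  construction), and it separates the two populations by more than a
  factor of two on all our synthetic cases. Centres of the last accepted
  decomposition must also persist (within 10% relative) in any larger
  accepted one.
* **Band routing.** The respiration and cardiac bands are closed
  intervals; a mode whose mean instantaneous frequency falls in the gap
  (0.6, 0.8) Hz joins neither. Mean instantaneous frequency is the mean
  derivative of the unwrapped analytic phase (FFT Hilbert transform) over
  the central 90% of samples.
* **Pipeline mode count.** For the simulated trials the extraction runs
  at a fixed $k = 6$: the displacement model holds respiration, heartbeat,
  one cardiac harmonic and broadband noise, and the dominant respiration
  line (its amplitude is 10x the cardiac one, 100x in energy) tends to
  absorb extra modes — with too few modes the weak cardiac tone may not
  get one at all. Six gives the weak components room, and is also where
  mode counts settle on real chest data in our experience with this class
  of signal.

## The synthetic-trial generator

Chest displacement is modelled as
$d(t) = A_r \sin(2\pi f_r t + \phi_r) + A_h \sin(2\pi f_h t + \phi_h) +
0.3\,A_h \sin(4\pi f_h t + 2\phi_h) + \varepsilon$, with
$\varepsilon \sim N(0, 0.05\,\text{mm})$ per sample by default. The
harmonic at $2 f_h$ makes the cardiac band reconstruction non-trivial.
Per-emotion parameter boxes (uniform draws; all synthetic conventions, the
literature prints no such parameters):

| emotion | breathing (Hz, mm) | heart rate (bpm) | face |
|---|---|---|---|
| relaxed | 0.15–0.25, 5–7 (slow, deep) | 60–70 | neutral mouth, level brows |
| happy | 0.25–0.35, 4–6 | 72–78 | strong smile, raised brows |
| sad | 0.20–0.30, 2–3.5 (shallow) | 66–74 | frown, drooping brows, narrowed eyes |
| angry | 0.40–0.55, 4–6 (fast) | 90–100 | flat mouth, sharply lowered brows |

The boxes deliberately overlap: happy and sad share most of their
heart-rate range and are told apart chiefly by facial geometry, so no
single modality separates all four classes — this is what makes the fusion
architecture testable (ablating a modality must cost accuracy).

Faces are procedural: an elliptical head, eyes with openness, slanted
eyebrows and a parabolic mouth whose curvature sign encodes smile vs
frown, plus per-frame positional jitter. The renderer carries the coarse
geometry that distinguishes expressions and *nothing else*: no texture,
lighting, identity, pose or occlusion. Passing tests on this data
demonstrate that the pipeline's machinery is correct — clutter removal,
phase recovery, decomposition, keyframing, fusion, optimization — not that
the classifier would reach any particular accuracy on real humans, where
inter-subject variability dominates.

Two signal paths exist for dataset generation: `"truth"` synthesizes the
respiration/heartbeat series directly from the drawn model (the
decomposition an ideal radar chain would recover), while `"radar"` runs
the full cube-simulation-and-extraction chain per trial at roughly 100x
the cost. Classification experiments use the former; the radar chain's
fidelity is established separately by the rate-recovery experiment, which
runs the full chain on 50+ trials and demands ≤1 bpm cardiac and ≤0.5
breaths/min respiratory error in ≥90% of them.

## Network conventions

The branch tables fix kernel/filter/stride per block; everything else is a
convention, chosen once:

* **'Same' convolution padding**, so strides alone control downsampling;
  a length-1200 series passes 1200 → 300 → 150 → 37 → 9, a 227 px
  keyframe 227 → 113 → 56 → 14 → 3.
* **Floor-mode max pooling** (stride = window, trailing partial window
  dropped); an input shorter than the window is pooled as a single
  truncated window.
* Block order convolution → pooling → batch normalization → ELU.
* The 2-D branch ends in a global average over space, one 96-vector per
  keyframe; the keyframe axis is nearest-index resampled to the 1-D
  branches' temporal axis (9 steps for 60 s series) and the three feature
  vectors are concatenated per step (respiration, heartbeat, face —
  64 + 64 + 96 = 224).
* **GRU** with a single bias set per gate,
  $h_t = (1 - z_t) h_{t-1} + z_t \tilde h_t$: $3(224 \cdot 64 + 64^2 + 64)
  = 55{,}488$ parameters; final state → dense → softmax(4).
* **Training**: Adam at $10^{-3}$, batch 16, cross-entropy,
  best-validation-accuracy checkpointing; all randomness (weights,
  shuffling) derives from one seed. Every layer's backward pass is
  verified against central finite differences.

## Problem sizes used by the test-suite experiments

These are the package's own choices for its synthetic studies: trials are
60 s at the 20 Hz frame rate (1200 samples); cube simulation uses 2 chirps
per frame (chirps within a frame are redundant for frame-scale motion —
this is purely a memory choice) and 256 samples per chirp; classification
runs use 50 trials per class, 32 px keyframes, 4 keyframes per trial and
12 epochs, which is several epochs past where validation accuracy
plateaus; the modality-ablation study uses 5 seeds at a deliberately
harder regime (8 trials per class, 16 px, 10 epochs) where fusion is not
saturated.

## Known limitations and numerical fine print

* The DFT phase at a fixed range bin carries, besides $4\pi R/\lambda$, a
  beat-frequency migration term of relative size about $B/2f_c$ (2.6% for
  the 4 GHz profile). Recovered displacement amplitudes inherit this small
  bias; correlations and rates are unaffected.
* Classical nearest-branch unwrapping aliases beyond ~15 mm/s of chest
  velocity at 77 GHz / 20 Hz; the predictive rule extends the limit to the
  acceleration bound, but genuinely jerky motion (coughs, posture shifts)
  would still break it. The amplitude-linearity property is claimed only
  in the smooth regime.
* Real-mixer (non-I/Q) cubes add image-leakage distortion to the
  extracted phase at large excursions; the analytic sensitivity
  experiment therefore runs on I/Q cubes, where the tone phase is exactly
  linear.
* `signal::filtfilt` starts from zero state; the low-pass pads the series
  by odd reflection before filtering and crops after, so constant inputs
  pass with unit gain.
* The face detector contract expects a cascade-style detector (boxes +
  confidence). The shipped brightness detector is only suitable for the
  synthetic renderer's bright-face-on-dark-background frames.
* LOOCV reports both the one-hot mean-squared error (the cross-validation
  formula honoured as printed) and 0/1 accuracy, because MSE on a
  classifier's probability vector is the less natural of the two.
* Precision and recall follow the standard one-vs-rest definitions
  (TP/(TP+FP), TP/(TP+FN)); the harmonic-mean F-score is only coherent
  with these.
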