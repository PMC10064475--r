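---
title: "The spatiotemporal energy model in motionEnergy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The spatiotemporal energy model in motionEnergy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motionEnergy)
```

## The model

First-order visual motion is motion defined by luminance: it can be
detected by linear spatiotemporal filtering followed by squaring, without
any feature tracking. `motionEnergy` implements this standard model in two
spatial dimensions plus time and adds a population readout, so that an
image sequence goes in and a per-pixel direction/magnitude field comes out.

The front end is a bank of `K` direction channels (default `K = 8`, every
45°). Each channel owns a pair of 3-D (x–y–t) kernels built from separable
parts:

* a **spatial Gabor quadrature pair** at the channel's orientation — a
  cosine-phase ("even") and a sine-phase ("odd") kernel sharing an
  isotropic Gaussian envelope. The even kernel is DC-corrected by
  subtracting an envelope-shaped offset (this preserves its 180° symmetry),
  and both are normalized to unit L2 norm so channel outputs are
  comparable;
* a **temporal biphasic pair**
  \(f_n(t) = (t/\tau)^n e^{-t/\tau}\left[\tfrac{1}{n!} -
  \tfrac{(t/\tau)^2}{(n+2)!}\right]\)
  with \(n = 3\) ("fast") and \(n = 5\) ("slow"), sampled causally at
  integer frame lags.

The four separable products are combined as

\[
k_{\mathrm{even}} = e \otimes f_{\text{fast}} - o \otimes f_{\text{slow}},
\qquad
k_{\mathrm{odd}} = o \otimes f_{\text{fast}} + e \otimes f_{\text{slow}},
\]

which tilts the quadrature pair in space-time: the sum of its two squared
responses — the **motion energy** \(E_k\) — is largest for stimuli drifting
along the channel's direction and is invariant to stimulus phase
(quadrature). Channels at \(\theta\) and \(\theta + 180^\circ\) share a
spatial pair (the odd kernel flips sign), which makes the **opponent
stage** \(O_k = E_k - E_{k+K/2}\) exactly antisymmetric. Static images and
counterphase gratings excite opposite channels equally and cancel here; a
drifting grating survives with the sign of its direction.

The **readout** is a rectified vector sum,
\(v = \sum_k \max(O_k, 0)\,(\cos\theta_k, \sin\theta_k)\): angle =
direction of \(v\), magnitude = \(\lVert v \rVert\). Where the magnitude is
exactly zero the direction is undefined and reported as `NA` — it is never
replaced by a fake angle. For display, hue encodes the angle on a color
wheel and brightness the magnitude (per-frame robust-max normalization by
default; a fixed absolute scale is available for quantitative comparisons
across conditions).

### Conventions

All angles use one **screen convention**: x rightward, y downward (image
rows), degrees measured from +x, increasing clockwise *as displayed*, in
(−180°, 180°]. With y pointing down, `atan2(dy, dx)` already produces this
convention, so a single helper (`screenAngle()`) is the only point where
vectors become angles. We chose this over an internal y-up mathematical
frame with a conversion layer at the image boundary: one convention used
everywhere removes the most common class of sign bugs, and the rotation
equivariance and ring-phase tests pin every sign down (a 90° clockwise
frame rotation must shift channels by exactly K/4; a clockwise-rotating
ring must decode to +90°).

## Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| `K` | 8 | – | direction channels, every 360/K° |
| `wavelengthPx` | 8 | px | spatial carrier wavelength |
| `sigmaPx` | 4 | px | Gabor envelope s.d. (σ/λ = 0.5 keeps quadrature leakage < 0.1%) |
| `kernelSize` | 15 | px | spatial support (≈ ±2σ) |
| `tauFrames` | 0.5 | frames | temporal time constant |
| `nTaps` | 11 | frames | temporal support (warm-up length T) |
| `normalize` | off | – | divisive contrast normalization |
| `magnitudeFloorFrac` | 0.1 | – | ring-analysis magnitude floor |

The temporal defaults deserve a note. A sampled biphasic filter must
contain *both* of its lobes and have decayed at its last tap, otherwise
truncation injects a spurious transient into every response;
`makeTemporalPair()` enforces a tail below 1% of the peak and exactly one
sign change, and raises the support-too-short parameter error otherwise
(for instance, 9 taps at τ = 1.5 truncate the slow lobe before its sign
change at t ≈ 6.5 frames, so that combination is rejected). τ = 0.5 with
11 taps satisfies both constraints and gives a compact warm-up (T = 11
frames), which matters for the 48-frame looming-ring demonstrations where
late frames carry the ring outside the field of view. With λ = 8 px this
bank prefers ≈ 1 px/frame (measured by the speed-sweep test: energy peaks
at a finite nonzero speed and falls off at 0 and at 4× the peak).

Divisive normalization (`O / (ε + \bar{E})`) is off by default on purpose:
the stepping-feet demonstration is about contrast — with normalization off,
energy scales as contrast² (asserted to 1e−5 relative) and lowering the
grating contrast measurably weakens the illusory modulation.

## Numerical choices

* **Spatial borders**: "same" correlation with *symmetric reflection*
  padding. Reflection avoids the spurious motion energy a zero border
  would create, and keeps the frame size constant. Implementation is
  FFT-based (padded to 5-smooth sizes) and is tested to ≈ 1e−14 against
  direct summation, and the whole engine against an independent
  brute-force 3-D convolution oracle.
* **Temporal borders**: causal and valid — the first output appears at
  frame T; no future leakage, no temporal padding.
* **Precision**: everything in R doubles; the oracle comparison tolerance
  (1e−5) is conservative by nine orders of magnitude.
* **Ties and degeneracies**: zero magnitude ⇒ `NA` angle, rendered
  achromatic; an annulus with no pixel above the magnitude floor returns
  the undefined-phase signal (`NA` phase, `nPixels = 0`) rather than a
  number.
* **Sub-pixel motion**: generators evaluate the analytic pattern at
  continuous coordinates each frame instead of shifting a rasterized
  template, so rigid motion is exact at any speed (the stepping-feet
  centroid test asserts exact per-frame displacement).

## What the synthetic stimuli emulate

The stimulus module provides everything the model needs to be exercised
without external data: drifting and counterphase gratings (analytic
probes with known spectra), the stepping-feet display (bright/dark feet
over a square-wave grating; the colored original is rendered as its
Rec.601 luminances, since the first-order pathway is luminance-driven),
textured annuli and Gabor-element rings of the Pinna–Brelstaff type, and a
random-walk camera jitter emulating fixational eye movements.

For ring stimuli the analysis reports a **ring phase**: the
magnitude-weighted circular mean of the decoded direction relative to the
local outward radial direction, clockwise positive. Pure expansion is the
0° reference, rigid clockwise rotation is +90°, counter-clockwise −90°,
and an equal mixture ±45°. Weighting by magnitude uses circular statistics
(never an arithmetic mean of angles), and the default floor of 0.1 of the
annulus maximum keeps background pixels out. How a human observer pools
phase over a ring is not specified by the perceptual literature this
taxonomy comes from; the weighting and floor here are package decisions,
chosen for robustness and exposed as parameters.

The looming Gabor rings reproduce the illusion's mechanism directly: each
micropattern is a small oriented aperture, so a local energy detector only
senses the velocity component along the carrier wave vector (the aperture
problem). With carriers tilted 45° clockwise from radial, a purely
expanding ring decodes to ≈ +45° — an illusory clockwise rotation with no
physical rotation in the stimulus; the measured value (+42.2°) sits a few
degrees short of the geometric 45° because the moving Gaussian envelope
also contributes a small genuinely-radial (phase-0) component. Mirrored
tilt gives the mirrored phase exactly.

Because the demonstration rings expand at 1 px/frame for 48 frames from
radius 40 px in a 128 px frame, the ring eventually outgrows the field of
view. The generator treats an out-of-frame ring as a parameter error by
default (the contract for measurement stimuli) and renders the visible
part when `allowClipping = TRUE` (the looming demos); the per-frame phase
measurements are pooled weighted by each frame's total decoded magnitude,
so late frames with little visible ring contribute almost nothing.

What passing these tests does *not* show: the synthetic stimuli are
noise-free, achromatic, and rigidly generated, so the tests say nothing
about photon noise, chromatic (second-order) motion, occlusion, or camera
optics in real video; the model itself remains first-order only (no
non-Fourier channels), and the CLI's frame-directory input simply treats
any real footage as a luminance sequence.

## Problem sizes used in the tests

Unit tests run on 16–64 px frames with a 9 px kernel bank; the end-to-end
demonstrations use the full 128 × 128 px, 48-frame geometry with the
default bank, the sizes at which the ring-phase numbers quoted above are
computed. The brute-force convolution oracle runs on 20 × 20 × 32 random
volumes — small enough for direct summation to stay honest and fast.

## Known limitations

* Single spatial scale by default. A multi-scale bank can be emulated by
  summing energies from several banks, but no convenience wrapper is
  provided.
* The opponent stage is the plain full-circle difference; no spatial
  pooling or motion-opponency gain control beyond the optional divisive
  normalization.
* `readFrames()`/`writeFrames()` speak PNG frame directories (plus a
  frame-rate sidecar); video containers are not read or written — decode
  video to frames with any external tool first.
* The legend's direction labels are tick marks, not rendered text.
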