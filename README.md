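# motionEnergy

An R implementation of the spatiotemporal (motion) energy model of
first-order visual motion perception, extended to two spatial dimensions
plus time, with a per-pixel direction decoder, a color-wheel renderer, and
the synthetic stimuli needed to demonstrate — and measure — classical
motion illusions such as the stepping feet and the Pinna–Brelstaff
rotating rings.

It is aimed at vision scientists and students who want to *see* what a
first-order motion front end extracts from an image sequence, and to turn
illusion demonstrations into numbers instead of screenshots.

## The model in brief

A bank of `K` direction channels (default 8, every 45°) filters the
incoming frame volume. Channel *k* holds a quadrature pair of 3-D kernels
built from an oriented spatial Gabor pair (even `e`, odd `o`) and a
fast/slow pair of causal biphasic temporal filters
`f_n(t) = (t/τ)^n e^{−t/τ} [1/n! − (t/τ)²/(n+2)!]` (n = 3, 5):

    k_even = e⊗f_fast − o⊗f_slow        k_odd = o⊗f_fast + e⊗f_slow

Motion **energy** is the phase-invariant squared quadrature response
`E_k = r_even² + r_odd²`; **opponent energy** differences opposite
directions, `O_k = E_k − E_{k+K/2}`, cancelling static and counterphase
input; a rectified vector sum `v = Σ_k max(O_k,0)(cos θ_k, sin θ_k)`
decodes a per-pixel flow field whose angle maps to hue on a color wheel.

For ring stimuli, the decoded field is collapsed into a **ring phase**:
the magnitude-weighted circular mean of motion direction relative to the
local outward radial direction (clockwise positive). Pure expansion = 0°,
rigid clockwise rotation = +90°, counter-clockwise = −90°, equal mixture =
±45°.

## Worked example

```r
library(motionEnergy)

bank <- buildFilterBank()
bank
#> FilterBank (spatiotemporal quadrature energy front end)
#>   K = 8 channels at: 0, 45, 90, 135, 180, 225, 270, 315 degrees
#>   spatial : Gabor wavelength 8 px, sigma 4 px, kernel 15 x 15
#>   temporal: biphasic pair (n = 3 fast / n = 5 slow), tau 0.5 frames, 11 taps

# A Pinna-Brelstaff ring: 16 Gabor micropatterns on a circle of radius
# 40 px, carriers tilted 45 deg clockwise from radial, expanding at
# 1 px/frame -- physically there is NO rotation in this stimulus.
res <- demoRingPhase("pinna_cw")
res$overall
#> PhaseMeasurement: phase +42.18 deg (cw+), resultant 0.992, n = 82692 px
```

The decoded phase of ≈ +45° is the illusory clockwise rotation the model
predicts for a purely looming ring of obliquely oriented elements: each
element is a small oriented aperture, so local detectors only sense the
motion component along the carrier (the aperture problem). Mirroring the
tilt (`"pinna_ccw"`) gives −42.18°; a rigidly rotating textured annulus
(`"rotation_cw"` / `"rotation_ccw"`) decodes to +90.00° / −90.00°, and the
radially-symmetric control (`"expansion"`) to 0.00°.

The stepping-feet illusion, quantified:

```r
hi <- demoSteppingFeet(backgroundContrast = 1)
lo <- demoSteppingFeet(backgroundContrast = 0.25)
hi$correlation            # -0.723  : the two feet "step" in anti-phase
hi$modulationDepth        # bright 0.98, dark 1.26
lo$modulationDepth        # bright 0.47, dark 0.54 : weaker at low contrast
```

Both feet translate at identical constant speed; the anti-phase energy
modulation, and its collapse when the grating contrast drops, is the
model's account of why the feet *appear* to step alternately and why the
illusion weakens on a low-contrast grating.

## Command-line tool

```sh
Rscript $(Rscript -e 'cat(system.file("cli","motiontool.R",package="motionEnergy"))') \
    demo --name pinna_cw --out demo_out/
```

Subcommands: `gen` (write a preset stimulus as a PNG frame directory),
`run` (stream frames → color-wheel PNGs, `--save-flow` for raw
angle/magnitude TSVs, `--legend` for the wheel inset), `analyze` (ring
phase as `key=value` output), `demo`, `describe`. A DCF config file
(`key: value`, keys as in `defaultConfig()`) sets bank and display
parameters; flags override it.

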