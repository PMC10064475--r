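Package: motionEnergy
Title: Spatiotemporal Energy Model of First-Order Visual Motion Perception
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the spatiotemporal (motion) energy model of
    first-order visual motion perception in two spatial dimensions plus
    time. Oriented quadrature pairs of Gabor filters are combined with
    biphasic temporal filters into direction-selective space-time kernels;
    squared quadrature responses give per-pixel, per-direction motion
    energy, and opposite-direction channels are differenced into opponent
    energy. A rectified vector-sum readout decodes a per-pixel flow field
    (direction and magnitude) which can be rendered on a color wheel. A
    stimulus module generates the classical probe and illusion stimuli
    (drifting and counterphase gratings, stepping feet, textured and
    Gabor-element rings of the Pinna-Brelstaff type, fixational-jitter
    camera motion), and a ring-analysis module quantifies perceived ring
    motion as a circular-mean phase relative to the local radial
    direction, so that illusory rotations of physically expanding rings
    can be measured rather than eyeballed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    png,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
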