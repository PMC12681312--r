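Package: epinav
Title: Motion- and Field-Corrected Navigated 3D-EPI fMRI at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, reconstruction and evaluation toolkit for
    motion-robust whole-brain 3D echo-planar (3D-EPI) BOLD fMRI with embedded
    volumetric navigators. Simulates multi-coil CAIPI-accelerated 3D-EPI
    acquisitions of a procedural brain phantom under rigid-body head motion
    and spatially linear B0 drift; reconstructs accelerated navigators with
    2D-GRAPPA and estimates per-frame head pose (multiresolution Gauss-Newton
    registration) and global plus linear field changes (navigator phase);
    solves a model-based conjugate-gradient reconstruction whose forward
    operator includes rigid motion, linear field evolution and receive
    sensitivities (with an uncorrected control mode); designs kT-point
    spatial-spectral parallel-transmit excitation pulses by regularized
    magnitude least squares with Bloch-simulation verification; and computes
    the resting-state quality metrics used to evaluate such acquisitions
    (tSNR, framewise displacement, DVARS, 36P confound expansion, CompCor,
    Butterworth band-pass denoising, ALFF, ReHo/KCC, functional
    connectivity).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
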