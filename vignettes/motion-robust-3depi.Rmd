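---
title: "Methods: motion- and field-corrected navigated 3D-EPI at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motion- and field-corrected navigated 3D-EPI at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(epinav)
```

`epinav` simulates, reconstructs and evaluates motion-robust whole-brain
3D-EPI BOLD acquisitions with embedded volumetric navigators. This vignette
is the package's account of the models it implements, the parameters that
matter, the numerical choices behind them, and what the synthetic studies do
and do not demonstrate.

## 1. Geometry and conventions

All volumes live on a `grid3d`: a right-handed world frame in mm, axes
aligned with the array axes, 0-based voxel indices, voxel `(i,j,k)` at
`origin + (i dx, j dy, k dz)`. A `rigid_transform` holds six head-pose
parameters — translations in mm, rotations in degrees about the world axes
*through the volume center*, applied in x→y→z order, then translation. The
Euler convention is not dictated by the physics; what matters is that the
simulator, the registration-based estimator and the reconstruction operator
share one convention, which they do by construction. Gimbal-degenerate
decompositions (|ry| = 90°) are reported as errors rather than silently
resolved; head motion never approaches them.

Resampling (`apply_rigid`) is pull-based trilinear interpolation (nearest
available) with zeros outside the field of view, implemented in C++ so that
the gather and its transpose (scatter) share interpolation weights exactly —
the reconstruction's conjugate-gradient solver requires a true adjoint pair,
and the dot-product test in the suite holds to ~1e-12.

k-space uses a centered, unitary FFT: DC at 0-based index `floor(N/2)`,
scaling `1/sqrt(N)` both ways, so the adjoint of the Fourier step is its
inverse.

## 2. The acquisition model

`build_caipi_pattern` samples the (ky,kz) phase-encode plane on a
controlled-aliasing lattice: every `Rz`-th kz plane, with the ky comb offset
by `caipi_shift * (kz/Rz) mod Ry`. The sampled fraction is `1/(Ry*Rz)` up to
boundary truncation. One kz plane splits into `n_interleaves` shots over
alternating ky lines; each shot occupies one TR, and each line carries an
acquisition time `te + (line counter − center) * echo_spacing`, placing the
echo-train center at TE. The vendor sequence's exact CAIPI shift and
interleaf ordering are not public; both are configurable, with shift 1 as
the default for imaging and navigator patterns.

The navigator schedule (`build_navigator_schedule`) plays a small number of
lines of its own CAIPI pattern inside each imaging TR. With the protocol
values — 48×32×24 navigator matrix, 4×2 acceleration, 8 lines per TR,
0.47 ms echo spacing, 39 ms TR — the schedule reproduces the protocol
arithmetic: 3.76 ms navigator readout per TR (under the 5 ms budget), 12 TRs
per navigator volume, one head-pose sample every 468 ms. `volume_timing`
gives the kz-segmented volume TR `(nz/Rz) * n_interleaves * tr`; at the
protocol's 120-plane matrix, Rz = 4, two interleaves and 39 ms TR this is
2.34 s, and two 150-volume runs make a 300-volume, ~12-minute session.
`protocol_summary()` computes all of these from the acquisition parameters.

Navigator line times include the navigator TE, and the schedule exposes
`nav_te` (echo-center time) — the scale that converts navigator phase to Hz.
Keeping simulation and estimation on the same clock matters more than the
absolute value.

## 3. Forward model and reconstruction

Per shot `s`, the encoding operator applies: the shot's rigid pose (pull
resampling), the receive sensitivity of each channel, the unitary FFT, the
shot's field evolution, and the pattern's sampling. The spatially linear
field term is treated exactly in k-space: a linear phase ramp
`exp(i 2π (g·r) t)` in the image domain is a shift of the sampled k-space
location by `g * FOV * t` — realized as trilinear interpolation of the
shot's k-space at the shifted coordinates, per ky line (all samples of a
line share its echo-train time; at the sub-Hz/mm drifts being modeled the
within-line time spread is negligible). The global term contributes the
scalar phase `exp(i 2π g0 t)`. Because gather and scatter share weights, the
coded adjoint is the exact conjugate transpose, verified by the dot-product
test on random states.

`reconstruct_volume` solves the Tikhonov-regularized normal equations
`(AᴴA + εI)x = Aᴴy` by conjugate gradients: relative-residual tolerance
1e-6, ε = 1e-6, default 40 iterations for series work. The motion-inclusive
normal operator is noticeably worse conditioned than the static one —
under-iterating the corrected mode is the main way to make it look bad, so
both modes always run with identical solver settings. The quadratic CG
objective is recorded per iteration and is non-increasing; a growing
residual aborts with diagnostics. "Uncorrected" mode is the identical solve
with identity states: same data, same solver, no knowledge of motion.

Shots are mapped to navigator frames by nearest acquisition mid-time
(linear interpolation available); the correction granularity is one state
per shot, matching the navigator cadence of the protocol.

## 4. Navigator processing

**GRAPPA.** Missing (ky,kz) lattice points are synthesized channel-by-channel
as learned linear combinations of acquired neighbors: per missing-offset
class, the 4 nearest acquired lattice points × 5 kx neighbors × all
channels, fit on a fully sampled central ACS block by least squares with
relative Tikhonov 1e-4. Calibration demands at least 4 equations per
unknown and reports the fit residual; acquired samples are never touched by
synthesis. On synthetic data whose coil k-spaces are exact integer k-space
shifts of one object (single-harmonic sensitivities) the kernel is exact
and reconstruction errors sit at numerical precision, which the suite
asserts.

**Registration.** Head pose is estimated per frame by minimizing masked SSD
between the (GRAPPA-reconstructed) frame magnitude and the first frame,
with damped Gauss-Newton on a 2-level downsample-by-2 pyramid, tolerance
1e-4 on the update norm, 50 iterations per level. The Jacobian uses central
finite differences on the six parameters (0.05 mm / 0.05°) — at ~10k-voxel
navigator resolution this is cheap, robust, and free of analytic-gradient
bookkeeping. The reference frame is the first navigator volume of the run
(configurable). The registration metric and pyramid depth are design
choices; SSD on noiseless synthetic magnitudes is well-behaved, and the
simulate-and-recover tests hold recovery to ≲0.05 mm / 0.05°.

**Field estimation.** After motion compensation by the estimated pose, the
frame-to-reference phase difference is fit by weighted least squares
(weights = product magnitude squared) to `[1, x, y, z]` in world mm, scaled
by `1/(2π nav_te)`. The estimator is exact on noiseless linear-phase
injections (asserted to 1e-6). No unwrapping is attempted: drifts at this
scale stay wrap-free, and a frame with >5% near-wrap voxels raises a
warning instead. Fixed-reference (not frame-to-frame) differencing is used
so errors do not accumulate.

## 5. kT-point spatial-spectral pulse design

The small-tip system matrix maps complex drives per (channel, kT point) to
radians of transverse flip at (voxel, frequency) pairs:
`i γ Δt B1_c(r) exp(i 2π k_k·r) exp(i 2π (f + b0(r)) (t_k − T))`, with
subpulse centers `t_k = (k−1/2)Δt`, pulse end `T`, γ/2π = 42.577 MHz/T, and
B1 maps in µT per unit drive. The default pulse is 3.8 ms long with 24 kT
points placed as ± pairs on a small lattice within ±2 cycles/FOV — the
symmetric-placement constraint is honored by construction and locations are
never mutated by the designer; how such locations are best chosen is left
open and overridable. The spectral target puts the water passband
{−100, 0, +100} Hz at the nominal 10° flip and the fat stopband at the
10.5 T fat-water shift (≈ −1565 Hz) ± 100 Hz at zero, with equal weights.

`design_mls_pulse` runs variable exchange on the magnitude least-squares
relaxation: update the target phase `z ← exp(i arg(Ab))`, then solve the
regularized linear problem for `b`. The joint cost is non-increasing and
asserted on every run; the best iterate by cost is returned. λ can be given
or chosen by a 10-point logarithmic sweep that minimizes the magnitude
residual subject to pulse power ≤ 4× the CP-mode power at equal mean flip.
Initialization is the scaled CP mode (random available).

`bloch_simulate` verifies designs with a hard-pulse simulation — alternating
instantaneous rotations from the net per-point RF with free precession whose
sign convention matches the system matrix — so at 10° the Bloch flip agrees
with `|Ab|` within 2% (asserted). On the synthetic 16-channel transmit
fixture, whose CP mode is deliberately center-dominant and nonuniform
(CoV > 0.15 by construction), the designed pulse reduces the flip-angle CoV
far below the equal-mean-flip CP mode and suppresses mean fat-band flip
below 20% of nominal.

The transmit and receive map generators are smooth parametric fields
(Gaussian falloffs, ring geometry, propagation-like phase), not Biot-Savart
solutions: sufficient to exercise the algorithms, not physical predictions.

## 6. Resting-state metrics

The evaluation chain mirrors standard fMRI post-processing: volume
realignment of the reconstructed series (each volume registered to the
first and resampled back in a single interpolation), FD (Power's
formulation, 50 mm rotation radius — the convention under the usual 0.5 mm
outlier threshold), DVARS (standardized by the series' median raw DVARS;
the upstream pipelines' exact standardization is not published, so the
normalizer is documented and pluggable), outlier flagging (FD > 0.5 mm or
standardized DVARS > 1.5), 36P confound expansion (9 base signals +
derivatives + squares of all 18; 6 motion-only columns give 24P), CompCor
(DCT high-pass at 128 s, PCA, minimal components reaching 50% energy; the
temporal variant selects the top 2% most-variable voxels), zero-phase
second-order Butterworth band-pass of data *and* confounds (series are
demeaned before filtering — forward-backward filtering of a large DC offset
otherwise leaks edge transients into the passband), per-voxel OLS confound
regression, ALFF (z-normalize, FFT, single-sided power `|X|²/n`, mean root
power over in-band bins — band edges inclusive — times the voxel SD, so
ALFF scales linearly with fluctuation amplitude), ReHo (Kendall's W with
the standard tie correction over 27/19/7-voxel neighborhoods, truncated at
mask edges; adjacency lists generalize to vertex graphs), and parcel-mean
Pearson FC with `compare_fc` as the mean absolute off-diagonal difference.

## 7. The synthetic study: what it shows and what it cannot

The phantom is procedural — nested, boundary-perturbed ellipsoids with
piecewise-constant intensities — and every generator is a pure function of
its seed evaluated on the grid's world coordinates, so the same seed yields
geometrically consistent objects at imaging and navigator resolutions.
BOLD dynamics are sinusoids at parcel-specific frequencies inside spherical
"active" parcels plus white noise. Deliberately absent: physiological
noise, T1/spin-history effects, slice profiles, susceptibility distortion,
fine anatomical texture.

Problem sizes were chosen as the smallest that exercise the full
algorithms: navigator studies run on ~24³ grids with 16 channels;
reconstruction property tests on 16³ grids with 6–8 channels and 4-fold
CAIPI; the end-to-end demonstration session uses a 16³ imaging grid, a 16³
navigator, 16 volumes. The acceptance study uses the 48×44×36 / 4 mm
session geometry with navigators at half resolution, 20 frames, 16 coils,
smooth drift bounded at 2 mm / 2°. Short demo runs cannot resolve the
canonical 0.01–0.08 Hz band (their duration is seconds, not minutes), so
the demonstration sessions carry fluctuations in a band scaled to their run
length, and `metrics_session` falls back to the full resolvable band when
the configured one contains fewer than two FFT bins; the protocol-faithful
band remains the default everywhere else.

Two caveats matter when reading the paired corrected-vs-uncorrected
comparisons. First, they are qualitative analogs: group-level in-vivo
effect sizes depend on real anatomy, physiology and full preprocessing
pipelines that are out of scope here. Second, one comparison is genuinely
scale-sensitive: ReHo measures rank concordance, and reconstruction
artifacts that are *smooth at the scale of the ReHo neighborhood* are
shared across neighbors and therefore *raise* W in the uncorrected mode —
on a coarse, smooth phantom the uncorrected parcel ReHo can exceed even the
clean series' value, inverting the expected ordering. tSNR and residual-FD
comparisons are robust at every scale tested; the parcel-ReHo ordering
requires artifact structure finer than the neighborhood, i.e. grids closer
to the in-vivo regime.

## 8. Numerical choices and degenerate inputs

- Tikhonov ε = 1e-6 conditions the CG normal equations; GRAPPA uses 1e-4
  relative; the MLS solve refuses λ < 0 and flags singular systems.
- Zero-SD voxels yield 0 (flagged) in tSNR and ALFF; empty masks are
  errors; constant parcels produce NA FC entries with a warning;
  rank-deficient confound designs fall back to the pseudo-inverse with a
  warning.
- GRAPPA calibration rejects ACS blocks with fewer than 4 equations per
  unknown, reporting the counts; navigator schedules reject line counts not
  divisible by lines-per-TR, reporting the residue.
- Registration damping (Levenberg) guarantees monotone SSD; non-convergence
  warns but still returns the estimate, flagged.
- All randomness flows through explicit seeds; generators restore the
  caller's RNG state.
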