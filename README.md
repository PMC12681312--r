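# epinav

Motion- and field-corrected navigated 3D-EPI BOLD fMRI, at desk scale.

Whole-brain 3D gradient-echo EPI achieves high-resolution resting-state fMRI
at ultra-high field, but a 3D volume is encoded over seconds and across many
shots: rigid head motion and the B0 field drift it induces corrupt the
k-space data *within* each volume, where retrospective volume realignment
cannot reach. One remedy embeds a rapid low-resolution **volumetric
navigator** into every repetition time, tracks head pose and field state
continuously, and feeds both into a model-based reconstruction whose forward
operator knows about the motion. `epinav` implements that whole measurement
chain as an R package that runs on synthetic data on a laptop:

- **Acquisition model** — 3D-EPI phase-encode sampling on a 2D CAIPI lattice
  (`build_caipi_pattern`), kz-segmented multi-shot timing
  (`volume_timing`), and the embedded navigator schedule
  (`build_navigator_schedule`). `protocol_summary()` derives the headline
  protocol arithmetic from the sequence parameters.
- **Synthetic study** — procedural brain phantom, smooth complex receive and
  transmit maps, bounded motion / field-drift trajectories, BOLD-like
  coherent fluctuations (`make_phantom`, `make_coil_sensitivities`,
  `make_b1_transmit_maps`, `make_motion_trace`, `make_field_trace`,
  `simulate_bold_series`).
- **Navigator pipeline** — 2D-GRAPPA reconstruction of the accelerated
  navigators (`grappa_calibrate`, `grappa_reconstruct`), rigid pose
  estimation by multiresolution Gauss-Newton registration
  (`estimate_motion`), and global + linear field estimation from navigator
  phase (`estimate_field_change`).
- **Model-based reconstruction** — a per-shot encoding operator combining
  rigid motion, receive sensitivities and linear field evolution
  (`forward_model`, with an exact coded adjoint), solved by conjugate
  gradients (`reconstruct_volume`, `reconstruct_series`) in corrected or
  uncorrected mode on the same raw data.
- **pTx pulse design** — kT-point spatial-spectral parallel-transmit pulses
  for uniform water-selective excitation by regularized magnitude least
  squares (`build_system_matrix`, `design_mls_pulse`), verified by
  hard-pulse Bloch simulation (`bloch_simulate`), with AFI and hybrid B1+
  calibration (`afi_flip_angle`, `combine_hybrid_b1`).
- **Resting-state metrics** — tSNR, framewise displacement, DVARS, outlier
  flags, 36P confound expansion, CompCor, zero-phase Butterworth band-pass,
  confound regression, ALFF, ReHo (Kendall's W) and parcel functional
  connectivity.

## The model in brief

For shot $s$ of a volume, the acquired multi-coil samples are

$$y_{s,c} = P_s \, \Phi_s \, F \, C_c \, W_{T_s} \, x + \varepsilon$$

where $W_{T_s}$ resamples the image under the shot's rigid pose $T_s$
(6 parameters, estimated from the navigator magnitudes), $C_c$ applies the
receive sensitivity, $F$ is the (unitary) Fourier transform, $\Phi_s$
applies the shot's global + linear field evolution — a per-line phase
$e^{i 2\pi g_0 t}$ and a sub-voxel k-space shift $\Delta k = g \cdot
\mathrm{FOV} \cdot t$ estimated from the navigator phases — and $P_s$ reads
the CAIPI-sampled lines. The corrected series solves
$\min_x \lVert A x - y \rVert^2 + \epsilon \lVert x \rVert^2$ by CG,
volume by volume; the uncorrected control runs the identical solver with
identity states.

The pTx designer solves the regularized magnitude least-squares problem
$\min_b \lVert\,|A b| - m\,\rVert^2 + \lambda \lVert b \rVert^2$ over
complex drives $b$ per (channel, kT point), with a water passband at the
nominal flip angle and a fat stopband at the 10.5 T fat-water shift
(about −1565 Hz), by variable exchange.

## Worked example: navigator-based motion tracking

```r
library(epinav)

protocol_summary()[c("volume_tr_s", "nav_frame_interval_s",
                     "nav_duration_per_tr_s", "fat_shift_hz")]
#> $volume_tr_s            2.34
#> $nav_frame_interval_s   0.468
#> $nav_duration_per_tr_s  0.00376
#> $fat_shift_hz           -1565

# a 24 x 22 x 18 navigator grid over a 192 x 176 x 144 mm FOV,
# 16 receive channels, 4 x 2 blipped-CAIPI, 10 lines per TR
nav_grid <- grid3d(c(24, 22, 18), c(192, 176, 144) / c(24, 22, 18))
phantom  <- make_phantom(phantom_spec(nav_grid, n_tissues = 3, seed = 1))
coils    <- make_coil_sensitivities(nav_grid, n_channels = 16, seed = 2)
sched    <- build_navigator_schedule(nav_grid$shape, accel = c(4, 2),
                                     lines_per_tr = 10,
                                     echo_spacing = 0.47e-3,
                                     tr = 0.039, te = 0.008)
motion   <- make_motion_trace(10, max_translation_mm = 2,
                              max_rotation_deg = 2, style = "smooth_drift",
                              seed = 1, frame_interval = sched$frame_interval)

sim    <- simulate_navigator_frames(phantom$image, nav_grid, coils, sched,
                                    motion, acs_size = c(16, 12))
kernel <- grappa_calibrate(sim$acs, 4, 2, caipi_shift = 1)
est    <- navigator_pipeline(sim$frames, kernel, nav_grid,
                             nav_te = sched$nav_te, combine = coils,
                             frame_interval = sched$frame_interval)

err <- rigid_params(est$motion$frames) - rigid_params(motion$frames)
sprintf("RMS motion error: %.3f mm (translations), %.3f deg (rotations)",
        sqrt(mean(err[, 1:3]^2)), sqrt(mean(err[, 4:6]^2)))
#> "RMS motion error: 0.024 mm (translations), 0.051 deg (rotations)"
```

The navigator tracks a 2 mm / 2 degree smooth head drift to a few
hundredths of a millimeter and of a degree — comfortably below the
0.2 mm / 0.15 degree residual scale such navigated acquisitions aim for.
An end-to-end session (simulate, reconstruct both modes, evaluate) runs
from three calls:

```r
dir <- tempfile("session")
simulate_session(default_session_config(seed = 1), dir)
recon_session(dir, "corrected"); recon_session(dir, "uncorrected")
report <- metrics_session(dir)   # tSNR / FD / ALFF / ReHo / FC, both modes
```

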