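# Shared small fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_grid <- function() grid3d(c(16, 16, 16), c(8, 8, 8))

small_phantom <- function() {
  fixture("small_phantom", function() {
    make_phantom(phantom_spec(small_grid(), 3, seed = 7))
  })
}

small_coils <- function(n = 8) {
  fixture(paste0("coils", n), function() {
    make_coil_sensitivities(small_grid(), n, seed = 3)
  })
}

# random rigid transform with bounded amplitudes
random_rigid <- function(tmax = 2, rmax = 10) {
  rigid_transform(runif(1, -tmax, tmax), runif(1, -tmax, tmax),
                  runif(1, -tmax, tmax), runif(1, -rmax, rmax),
                  runif(1, -rmax, rmax), runif(1, -rmax, rmax))
}

random_complex_image <- function(grid) {
  n <- prod(grid$shape)
  array(complex(real = rnorm(n), imaginary = rnorm(n)), grid$shape)
}

# navigator fixture shared by GRAPPA / registration / acceptance tests:
# 24 x 24 x 16 navigator grid over the 192 x 176 x 144 mm FOV, 16 channels,
# 4 x 2 blipped-CAIPI schedule, smooth-drift motion <= 2 mm / 2 deg
nav_session <- function() {
  fixture("nav_session", function() {
    ng <- grid3d(c(24, 24, 16), c(192, 176, 144) / c(24, 24, 16))
    ph <- make_phantom(phantom_spec(ng, 3, seed = 7))
    coils <- make_coil_sensitivities(ng, 16, seed = 3)
    sched <- build_navigator_schedule(c(24, 24, 16), c(4, 2), 8, 0.47e-3,
                                      0.039, te = 0.008)
    motion <- make_motion_trace(8, 2, 2, "smooth_drift", seed = 5,
                                frame_interval = sched$frame_interval)
    sim <- simulate_navigator_frames(ph$image, ng, coils, sched, motion,
                                     acs_size = c(16, 12))
    kernel <- grappa_calibrate(sim$acs, 4, 2, 1)
    list(grid = ng, phantom = ph, coils = coils, sched = sched,
         motion = motion, sim = sim, kernel = kernel)
  })
}

# GRAPPA-exact construction: coil k-spaces that are integer-shifted copies of
# one object k-space (single-harmonic sensitivities), so missing lines are
# exact linear combinations of acquired neighbors
harmonic_kspace <- function(shape = c(12, 12, 8), harmonics = list(c(0, 0),
                                                                   c(0, 1))) {
  n <- prod(shape)
  obj <- array(complex(real = rnorm(n), imaginary = rnorm(n)), shape)
  # taper to zero at the phase-encode edges so shifted copies (and truncated
  # reconstruction kernels) stay exactly representable at the boundary
  wy <- exp(-((seq_len(shape[2]) - shape[2] / 2)^2) / 18)
  wz <- exp(-((seq_len(shape[3]) - shape[3] / 2)^2) / 8)
  wy[c(1, 2, shape[2] - 1, shape[2])] <- 0
  wz[c(1, shape[3])] <- 0
  win <- outer(wy, wz)
  for (i in seq_len(shape[1])) obj[i, , ] <- obj[i, , ] * win
  nc <- length(harmonics)
  ksp <- array(0i, dim = c(shape, nc))
  for (c in seq_len(nc)) {
    h <- harmonics[[c]]
    shifted <- obj
    if (h[1] != 0) {
      idx <- ((seq_len(shape[2]) - 1 - h[1]) %% shape[2]) + 1
      shifted <- shifted[, idx, , drop = FALSE]
    }
    if (h[2] != 0) {
      idx <- ((seq_len(shape[3]) - 1 - h[2]) %% shape[3]) + 1
      shifted <- shifted[, , idx, drop = FALSE]
    }
    ksp[, , , c] <- shifted
  }
  ksp
}

# pTx fixture: 16-channel transmit maps on a small grid with an ellipsoidal
# mask, default symmetric 24-point kT set and the water/fat spectral target
ptx_fixture <- function() {
  fixture("ptx_fixture", function() {
    g <- grid3d(c(16, 16, 16), c(12, 12, 11))
    ph <- make_phantom(phantom_spec(g, 1, seed = 2))
    b1 <- make_b1_transmit_maps(g, 16, seed = 4)
    b0 <- array(0, g$shape)
    kt <- default_kt_locations(grid_fov(g) / 1000, 24, 2)
    tgt <- spectral_target(10)
    A <- build_system_matrix(b1, b0, ph$mask, g, kt, 3.8e-3 / 24,
                             tgt$frequencies)
    list(grid = g, mask = ph$mask, b1 = b1, b0 = b0, kt = kt, target = tgt,
         A = A)
  })
}

expect_rigid_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a$par - b$par)), tol)
}

# tiny moving-session config that keeps the full simulate -> recon -> metrics
# chain fast enough for the suite
tiny_session_config <- function(seed = 11) {
  cfg <- default_session_config(seed)
  cfg$grid$shape <- c(16L, 16L, 16L)
  cfg$grid$voxel_mm <- c(12, 11, 9)
  cfg$accel <- c(2L, 2L)
  cfg$n_interleaves <- 1L
  cfg$n_coils <- 6L
  cfg$n_volumes <- 16L  # long enough to afford the 9 base nuisance signals
  cfg$nav$acs <- c(14L, 10L)
  # the 2.5 s demo run cannot resolve the canonical 0.01-0.08 Hz band
  # (volume TR 0.312 s, 8 volumes): scale the fluctuation band to the run so
  # the parcels carry measurable coherent dynamics
  cfg$bold$band <- c(0.3, 1.2)
  cfg
}

# full end-to-end session (simulated, both recon modes, metrics), built once
moving_session <- function() {
  fixture("moving_session", function() {
    dir <- file.path(tempdir(), "epinav-moving-session")
    unlink(dir, recursive = TRUE)
    simulate_session(tiny_session_config(), dir, quiet = TRUE)
    corrected <- recon_session(dir, "corrected", max_iter = 25, quiet = TRUE)
    uncorrected <- recon_session(dir, "uncorrected", max_iter = 25,
                                 quiet = TRUE)
    report <- metrics_session(dir, quiet = TRUE)
    list(dir = dir, corrected = corrected, uncorrected = uncorrected,
         report = report)
  })
}
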