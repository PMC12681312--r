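# Procedural synthetic fixtures: a brain-like phantom, smooth complex coil and
# transmit maps, motion/field trajectories and BOLD-like dynamics. Every
# generator derives its shape parameters from the seed and then evaluates a
# closed-form field on the grid's world coordinates, so the same seed yields
# geometrically consistent objects at any resolution (imaging vs navigator
# grids).

#' Specification of a procedural head phantom
#'
#' @param grid a [grid3d()]; every axis must have at least 16 voxels.
#' @param n_tissues number of nested tissue compartments (>= 1).
#' @param seed integer seed; identical specs produce bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid, n_tissues = 3, seed = 1) {
  stopifnot(inherits(grid, "grid3d"), n_tissues >= 1)
  if (any(grid$shape < 16L)) stop("phantom grid must be >= 16 voxels per axis")
  structure(list(grid = grid, n_tissues = as.integer(n_tissues),
                 seed = as.integer(seed)), class = "phantom_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a brain-like tissue phantom
#'
#' Builds an ellipsoidal "head" containing `n_tissues` nested, boundary-
#' perturbed compartments with distinct intensities in `[0, 1]`. The outermost
#' ellipsoid defines the brain mask.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (3D array, intensities in `[0,1]`), `mask`
#'   (logical 3D array), and `grid`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- spec$grid
  fov <- grid_fov(grid)
  ctr <- grid_center(grid)
  pts <- grid_coords(grid)
  x <- pts[, 1] - ctr[1]; y <- pts[, 2] - ctr[2]; z <- pts[, 3] - ctr[3]

  nt <- spec$n_tissues
  pars <- with_seed(spec$seed, {
    list(semi = c(0.40, 0.42, 0.38) * fov * runif(3, 0.95, 1.05),
         wob_amp = c(0, runif(nt - 1, 0.02, 0.06)),
         wob_freq = sample(2:4, nt, replace = TRUE),
         wob_phase = runif(nt, 0, 2 * pi),
         shrink = seq(1, 0.45, length.out = nt),
         off = rbind(0, matrix(runif(3 * (nt - 1), -0.04, 0.04), ncol = 3)))
  })

  theta <- atan2(y, x)
  phi <- atan2(z, sqrt(x^2 + y^2))
  levels <- if (nt == 1) 1 else seq(0.45, 1, length.out = nt)

  rho_head <- sqrt((x / pars$semi[1])^2 + (y / pars$semi[2])^2 +
                   (z / pars$semi[3])^2)
  mask_v <- rho_head <= 1
  img_v <- numeric(length(rho_head))
  for (t in seq_len(nt)) {
    s <- pars$shrink[t]
    cx <- pars$off[t, ] * fov
    wob <- 1 + pars$wob_amp[t] *
      sin(pars$wob_freq[t] * theta + pars$wob_phase[t]) * cos(2 * phi)
    rho <- sqrt(((x - cx[1]) / (s * pars$semi[1]))^2 +
                ((y - cx[2]) / (s * pars$semi[2]))^2 +
                ((z - cx[3]) / (s * pars$semi[3]))^2) / wob
    inside <- rho <= 1 & mask_v
    img_v[inside] <- levels[t]
  }
  if (nt == 1) img_v[mask_v] <- 1
  list(image = array(img_v, dim = grid$shape),
       mask = array(mask_v, dim = grid$shape),
       grid = grid)
}

# seeded channel geometry shared by receive and transmit map generators
channel_geometry <- function(n, seed, ring_radius, jitter) {
  with_seed(seed, {
    ga <- pi * (3 - sqrt(5))  # golden angle: spreads channels over the sphere
    i <- seq_len(n) - 0.5
    zc <- 1 - 2 * i / n
    r <- sqrt(pmax(0, 1 - zc^2))
    az <- ga * i + runif(n, -jitter, jitter)
    list(pos = cbind(ring_radius * r * cos(az), ring_radius * r * sin(az),
                     ring_radius * zc),
         phase0 = runif(n, 0, 2 * pi),
         kph = matrix(runif(3 * n, -1, 1), ncol = 3))
  })
}

#' Generate smooth complex receive coil sensitivity maps
#'
#' Channel sensitivities are Gaussian falloffs from channel positions spread
#' over a sphere around the object, with channel-specific global and linear
#' spatial phase. They are band-limited and their root-sum-of-squares is
#' strictly positive over the field of view. These are algorithm-validation
#' profiles, not Biot-Savart solutions.
#'
#' @param grid a [grid3d()].
#' @param n_channels number of receive channels (>= 1).
#' @param seed integer seed.
#' @param flat if `TRUE` with `n_channels = 1`, return a unit map.
#' @return An object of class `coil_profile_set`: list with `maps`
#'   (complex array `nx x ny x nz x n_channels`), `n_channels`, `grid`.
#' @export
make_coil_sensitivities <- function(grid, n_channels, seed = 1, flat = FALSE) {
  stopifnot(inherits(grid, "grid3d"), n_channels >= 1)
  shp <- c(grid$shape, n_channels)
  if (flat && n_channels == 1) {
    maps <- array(complex(real = 1, imaginary = 0), dim = shp)
    return(structure(list(maps = maps, n_channels = 1L, grid = grid),
                     class = "coil_profile_set"))
  }
  fov <- grid_fov(grid)
  ctr <- grid_center(grid)
  pts <- grid_coords(grid)
  geo <- channel_geometry(n_channels, seed, ring_radius = 0.62 * max(fov),
                          jitter = 0.2)
  sigma <- 0.55 * mean(fov)
  maps <- array(complex(1), dim = shp)
  for (c in seq_len(n_channels)) {
    d2 <- (pts[, 1] - ctr[1] - geo$pos[c, 1])^2 +
          (pts[, 2] - ctr[2] - geo$pos[c, 2])^2 +
          (pts[, 3] - ctr[3] - geo$pos[c, 3])^2
    mag <- 0.05 + exp(-d2 / (2 * sigma^2))
    ph <- geo$phase0[c] +
      2 * pi * (geo$kph[c, 1] * (pts[, 1] - ctr[1]) +
                geo$kph[c, 2] * (pts[, 2] - ctr[2]) +
                geo$kph[c, 3] * (pts[, 3] - ctr[3])) / (4 * max(fov))
    maps[, , , c] <- array(complex(modulus = mag, argument = ph),
                           dim = grid$shape)
  }
  structure(list(maps = maps, n_channels = as.integer(n_channels),
                 grid = grid), class = "coil_profile_set")
}

#' Generate smooth complex transmit (B1+) maps
#'
#' Transmit channels sit on an azimuthal ring around the head. Each channel's
#' intrinsic phase combines its circularly-polarized increment with a
#' propagation-like term proportional to the distance from the channel, so
#' the CP-mode combination interferes constructively at the volume center and
#' decoheres towards the periphery: the CP flip-angle profile is
#' center-dominant and substantially nonuniform, giving the pTx design work
#' to do.
#'
#' @param grid a [grid3d()].
#' @param n_tx number of transmit channels (>= 1).
#' @param seed integer seed.
#' @param flat if `TRUE` with `n_tx = 1`, return a constant unit map.
#' @return An object of class `b1_map_set`: list with `maps` (complex array
#'   `nx x ny x nz x n_tx`, flip angle per unit drive, normalized units),
#'   `n_tx`, `grid`.
#' @export
make_b1_transmit_maps <- function(grid, n_tx, seed = 1, flat = FALSE) {
  stopifnot(inherits(grid, "grid3d"), n_tx >= 1)
  shp <- c(grid$shape, n_tx)
  if (flat && n_tx == 1) {
    maps <- array(complex(real = 1, imaginary = 0), dim = shp)
    return(structure(list(maps = maps, n_tx = 1L, grid = grid),
                     class = "b1_map_set"))
  }
  fov <- grid_fov(grid)
  ctr <- grid_center(grid)
  pts <- grid_coords(grid)
  ring <- 0.55 * max(fov[1:2])
  jit <- with_seed(seed, list(az = runif(n_tx, -0.1, 0.1),
                              amp = runif(n_tx, 0.9, 1.1)))
  beta <- 2 * pi / (1.1 * max(fov))  # propagation phase, rad per mm
  maps <- array(complex(1), dim = shp)
  for (c in seq_len(n_tx)) {
    az <- 2 * pi * (c - 1) / n_tx + jit$az[c]
    pos <- ctr + c(ring * cos(az), ring * sin(az), 0)
    d <- sqrt((pts[, 1] - pos[1])^2 + (pts[, 2] - pos[2])^2 +
              (pts[, 3] - pos[3])^2)
    mag <- jit$amp[c] * exp(-d / (0.9 * max(fov)))
    ph <- -2 * pi * (c - 1) / n_tx + beta * d
    maps[, , , c] <- array(complex(modulus = mag, argument = ph),
                           dim = grid$shape)
  }
  structure(list(maps = maps, n_tx = as.integer(n_tx), grid = grid),
            class = "b1_map_set")
}

#' Circularly-polarized (CP) drive weights
#'
#' Unit-magnitude drives with phase increments of `2*pi/n_tx` across channels,
#' the birdcage-like default mode that pTx designs are compared against.
#'
#' @param n_tx number of transmit channels.
#' @return complex vector of length `n_tx`.
#' @export
cp_mode_weights <- function(n_tx) {
  complex(modulus = 1, argument = 2 * pi * (seq_len(n_tx) - 1) / n_tx)
}

smooth_bounded_trace <- function(n, n_par, max_amp, seed_offset, seed) {
  # integrated random walk, low-pass filtered, first frame pinned to 0,
  # rescaled so the largest |value| equals max_amp
  with_seed(seed + seed_offset, {
    m <- matrix(0, n, n_par)
    if (n > 1 && max_amp > 0) {
      for (j in seq_len(n_par)) {
        w <- cumsum(rnorm(n + 20))
        w <- stats::filter(w, rep(1 / 7, 7), sides = 2, circular = TRUE)
        w <- as.numeric(w)[11:(10 + n)]
        m[, j] <- w - w[1]
      }
      peak <- max(abs(m))
      if (peak > 0) m <- m * (max_amp / peak)
    }
    m
  })
}

#' Generate a rigid-body motion trajectory
#'
#' @param n_frames number of navigator frames (>= 1); frame 1 is always the
#'   identity reference pose.
#' @param max_translation_mm peak absolute translation over the trace.
#' @param max_rotation_deg peak absolute rotation over the trace.
#' @param style `"smooth_drift"` (low-pass-filtered integrated random walk) or
#'   `"step"` (single abrupt pose change at mid-series).
#' @param seed integer seed.
#' @param frame_interval seconds between navigator frames.
#' @return An object of class `motion_trace`: list with `frames` (list of
#'   [rigid_transform()]) and `frame_interval`.
#' @export
make_motion_trace <- function(n_frames, max_translation_mm = 1,
                              max_rotation_deg = 1,
                              style = c("smooth_drift", "step"),
                              seed = 1, frame_interval = 0.468) {
  style <- match.arg(style)
  stopifnot(n_frames >= 1, max_translation_mm >= 0, max_rotation_deg >= 0)
  if (style == "smooth_drift") {
    tr <- smooth_bounded_trace(n_frames, 3, max_translation_mm, 100, seed)
    ro <- smooth_bounded_trace(n_frames, 3, max_rotation_deg, 200, seed)
  } else {
    step <- with_seed(seed, {
      list(t = runif(3, 0.5, 1) * sample(c(-1, 1), 3, TRUE) * max_translation_mm,
           r = runif(3, 0.5, 1) * sample(c(-1, 1), 3, TRUE) * max_rotation_deg)
    })
    # normalize the largest component to the stated maximum
    if (max_translation_mm > 0) step$t <- step$t * (max_translation_mm / max(abs(step$t)))
    if (max_rotation_deg > 0) step$r <- step$r * (max_rotation_deg / max(abs(step$r)))
    mid <- floor(n_frames / 2) + 1
    tr <- matrix(0, n_frames, 3); ro <- matrix(0, n_frames, 3)
    if (n_frames >= 2) {
      tr[mid:n_frames, ] <- matrix(step$t, n_frames - mid + 1, 3, byrow = TRUE)
      ro[mid:n_frames, ] <- matrix(step$r, n_frames - mid + 1, 3, byrow = TRUE)
    }
  }
  frames <- lapply(seq_len(n_frames), function(i) {
    rigid_transform(tr[i, 1], tr[i, 2], tr[i, 3], ro[i, 1], ro[i, 2], ro[i, 3])
  })
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "motion_trace")
}

#' Generate a global + linear field drift trajectory
#'
#' Per-frame field state: global offset `g0` (Hz) and spatially linear
#' gradients `gx, gy, gz` (Hz/mm). Frame 1 is the zero reference.
#'
#' @param n_frames number of navigator frames.
#' @param max_g0_hz peak absolute global offset.
#' @param max_grad_hz_per_mm peak absolute linear gradient.
#' @param seed integer seed.
#' @param frame_interval seconds between frames.
#' @return An object of class `field_trace`: list with `g0`, `gx`, `gy`, `gz`
#'   numeric vectors and `frame_interval`.
#' @export
make_field_trace <- function(n_frames, max_g0_hz = 1,
                             max_grad_hz_per_mm = 0.01, seed = 1,
                             frame_interval = 0.468) {
  stopifnot(n_frames >= 1, max_g0_hz >= 0, max_grad_hz_per_mm >= 0)
  g0 <- smooth_bounded_trace(n_frames, 1, max_g0_hz, 300, seed)
  gr <- smooth_bounded_trace(n_frames, 3, max_grad_hz_per_mm, 400, seed)
  structure(list(g0 = g0[, 1], gx = gr[, 1], gy = gr[, 2], gz = gr[, 3],
                 frame_interval = frame_interval), class = "field_trace")
}

#' Construct a 4D time series object
#' @param data 4D array `nx x ny x nz x n_volumes`.
#' @param grid the spatial [grid3d()].
#' @param tr_volume volume repetition time in seconds.
#' @return An object of class `time_series_4d`.
#' @export
time_series_4d <- function(data, grid, tr_volume) {
  stopifnot(length(dim(data)) == 4, all(dim(data)[1:3] == grid$shape),
            dim(data)[4] >= 1, tr_volume > 0)
  structure(list(data = data, grid = grid, tr_volume = tr_volume),
            class = "time_series_4d")
}

#' @export
print.time_series_4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("time_series_4d: %d x %d x %d voxels, %d volumes, TR %.3g s\n",
              d[1], d[2], d[3], d[4], x$tr_volume))
  invisible(x)
}

#' Simulate a BOLD-like resting-state series on a phantom
#'
#' Adds regionally coherent band-limited fluctuations inside seeded "active"
#' parcels (spherical regions in the mask) on top of the static phantom, plus
#' white Gaussian noise. Fluctuations are sinusoids at parcel-specific
#' frequencies drawn inside `band`, scaled to `amplitude` times the local
#' baseline intensity.
#'
#' @param phantom output of [make_phantom()] (or a list with `image`, `mask`,
#'   `grid`).
#' @param n_volumes number of time points (>= 8).
#' @param tr_volume_s volume TR in seconds.
#' @param band frequency band (Hz) for the fluctuations; must lie below the
#'   Nyquist frequency `1/(2*tr_volume_s)`.
#' @param amplitude fractional fluctuation amplitude (e.g. 0.05 = 5%).
#' @param noise_sd white-noise SD in image-intensity units.
#' @param n_parcels number of coherent parcels.
#' @param seed integer seed.
#' @return list with `series` ([time_series_4d()]), `parcel_labels` (integer
#'   3D array, 0 = background), `gt_amplitude` (3D array of true fluctuation
#'   amplitudes), and `parcel_freqs` (Hz per parcel).
#' @export
simulate_bold_series <- function(phantom, n_volumes, tr_volume_s,
                                 band = c(0.01, 0.08), amplitude = 0.05,
                                 noise_sd = 0.01, n_parcels = 4, seed = 1) {
  stopifnot(n_volumes >= 8, tr_volume_s > 0)
  nyq <- 1 / (2 * tr_volume_s)
  if (band[2] >= nyq) {
    stop(sprintf("fluctuation band [%g, %g] Hz exceeds Nyquist %g Hz",
                 band[1], band[2], nyq))
  }
  grid <- phantom$grid
  maskv <- which(phantom$mask)
  pts <- grid_coords(grid)
  fov <- grid_fov(grid)
  par <- with_seed(seed, {
    list(centers = pts[sample(maskv, n_parcels), , drop = FALSE],
         freqs = runif(n_parcels, band[1], band[2]),
         phases = runif(n_parcels, 0, 2 * pi))
  })
  labels <- integer(prod(grid$shape))
  rad <- 0.12 * mean(fov)
  for (p in seq_len(n_parcels)) {
    d2 <- (pts[, 1] - par$centers[p, 1])^2 + (pts[, 2] - par$centers[p, 2])^2 +
          (pts[, 3] - par$centers[p, 3])^2
    labels[d2 <= rad^2 & as.vector(phantom$mask)] <- p
  }
  base <- as.vector(phantom$image)
  amp <- numeric(length(base))
  amp[labels > 0] <- amplitude * base[labels > 0]
  tgrid <- (seq_len(n_volumes) - 1) * tr_volume_s
  data <- with_seed(seed + 1, {
    arr <- array(0, dim = c(grid$shape, n_volumes))
    for (v in seq_len(n_volumes)) {
      sig <- base
      for (p in seq_len(n_parcels)) {
        inp <- labels == p
        sig[inp] <- sig[inp] + amp[inp] *
          sin(2 * pi * par$freqs[p] * tgrid[v] + par$phases[p])
      }
      if (noise_sd > 0) sig <- sig + rnorm(length(sig), sd = noise_sd)
      arr[, , , v] <- sig
    }
    arr
  })
  list(series = time_series_4d(data, grid, tr_volume_s),
       parcel_labels = array(labels, dim = grid$shape),
       gt_amplitude = array(amp, dim = grid$shape),
       parcel_freqs = par$freqs)
}
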