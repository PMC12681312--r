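# Model-based reconstruction of accelerated multi-coil 3D-EPI data. The
# forward (encoding) operator applies, per shot: the shot's rigid head pose,
# receive sensitivity weighting, a centered unitary FFT, and the shot's
# global + spatially linear field evolution. The linear field term is exact in
# k-space: a linear image-domain phase ramp at sample time t is a sub-voxel
# shift of the sampled k-space location by g * FOV * t, realized by trilinear
# k-space interpolation (per ky line, all lines of a shot sharing the shot's
# field state but each carrying its own echo-train time). Gather and scatter
# share interpolation weights, so the coded adjoint is the exact conjugate
# transpose of the forward operator.

#' Per-shot encoding state (head pose + field state)
#'
#' @param transforms list of [rigid_transform()], one per shot (shot ids
#'   `0..n_shots-1` of the pattern).
#' @param fields data frame with columns `g0` (Hz), `gx, gy, gz` (Hz/mm), one
#'   row per shot. `NULL` means zero field change.
#' @return An object of class `encoding_state`.
#' @export
encoding_state <- function(transforms, fields = NULL) {
  n <- length(transforms)
  if (is.null(fields)) {
    fields <- data.frame(g0 = numeric(n), gx = numeric(n), gy = numeric(n),
                         gz = numeric(n))
  }
  stopifnot(nrow(fields) == n)
  structure(list(transforms = transforms, fields = fields,
                 n_shots = as.integer(n)), class = "encoding_state")
}

#' Identity encoding state for a pattern (no motion, no field change)
#' @param pattern a [build_caipi_pattern()] result.
#' @return An [encoding_state()] with identity pose and zero field per shot.
#' @export
identity_state <- function(pattern) {
  n <- length(unique(pattern$lines$shot))
  encoding_state(replicate(n, rigid_identity(), simplify = FALSE))
}

#' Multi-channel k-space data container
#'
#' @param samples complex array `nx x n_lines x n_channels`, lines ordered as
#'   in `pattern$lines`.
#' @param pattern the [build_caipi_pattern()] the samples were read on.
#' @param grid the image-domain [grid3d()].
#' @param noise_sd optional complex-noise SD used in simulation.
#' @return An object of class `kspace_data`.
#' @export
kspace_data <- function(samples, pattern, grid, noise_sd = NULL) {
  stopifnot(length(dim(samples)) == 3,
            dim(samples)[1] == pattern$matrix[1],
            dim(samples)[2] == nrow(pattern$lines))
  structure(list(samples = samples, pattern = pattern, grid = grid,
                 noise_sd = noise_sd), class = "kspace_data")
}

# fractional 0-based k-space array coordinates for the lines of one shot,
# shifted by the linear-field k-displacement; plus the per-line scalar phase
shot_sample_geometry <- function(pattern, grid, field, shot_lines) {
  nx <- pattern$matrix[1]
  fov <- grid_fov(grid)
  nl <- nrow(shot_lines)
  # world position of the FFT-center voxel (centered k-space convention)
  rc <- grid$origin + floor(grid$shape / 2) * grid$voxel_size
  dkx <- field$gx * fov[1] * shot_lines$t
  dky <- field$gy * fov[2] * shot_lines$t
  dkz <- field$gz * fov[3] * shot_lines$t
  phase0 <- exp(2i * pi * (field$g0 + field$gx * rc[1] + field$gy * rc[2] +
                           field$gz * rc[3]) * shot_lines$t)
  kx0 <- 0:(nx - 1)
  idx <- cbind(rep(kx0, times = nl) - rep(dkx, each = nx),
               rep(shot_lines$ky - dky, each = nx),
               rep(shot_lines$kz - dkz, each = nx))
  list(idx = idx, phase = rep(phase0, each = nx))
}

gather_complex <- function(arr, idx) {
  d <- dim(arr)
  complex(real = trilinear_gather_cpp(as.numeric(Re(arr)), d, idx),
          imaginary = trilinear_gather_cpp(as.numeric(Im(arr)), d, idx))
}

scatter_complex <- function(vals, dim3, idx) {
  array(complex(real = trilinear_scatter_cpp(Re(vals), dim3, idx),
                imaginary = trilinear_scatter_cpp(Im(vals), dim3, idx)),
        dim = dim3)
}

#' Apply the encoding forward model
#'
#' Maps an image to multi-channel undersampled k-space samples under per-shot
#' rigid motion, receive sensitivities, and global + linear field evolution.
#'
#' @param image 3D numeric or complex array on `grid`.
#' @param coils a [make_coil_sensitivities()] result on the same grid.
#' @param state an [encoding_state()] (or `NULL` for identity).
#' @param pattern a [build_caipi_pattern()] result.
#' @param grid the image [grid3d()].
#' @return A [kspace_data()] object.
#' @export
forward_model <- function(image, coils, state, pattern, grid) {
  if (is.null(state)) state <- identity_state(pattern)
  shots <- sort(unique(pattern$lines$shot))
  if (state$n_shots < length(shots)) stop("missing encoding states for shots")
  nx <- pattern$matrix[1]
  nc <- coils$n_channels
  image <- if (is.complex(image)) image else image + 0i
  samples <- array(0i, dim = c(nx, nrow(pattern$lines), nc))
  for (s in shots) {
    si <- s + 1L
    rows <- which(pattern$lines$shot == s)
    geo <- shot_sample_geometry(pattern, grid, state$fields[si, ],
                                pattern$lines[rows, ])
    warped <- apply_rigid(image, grid, state$transforms[[si]])
    for (c in seq_len(nc)) {
      Fc <- kspace_fwd(warped * coils$maps[, , , c])
      vals <- geo$phase * gather_complex(Fc, geo$idx)
      samples[, rows, c] <- matrix(vals, nrow = nx)
    }
  }
  kspace_data(samples, pattern, grid)
}

#' Adjoint of the encoding forward model
#'
#' Exact conjugate transpose of [forward_model()]: scatter samples back to
#' k-space with conjugate field phases, inverse (unitary) FFT, conjugate
#' coil weighting, and the transpose of the shot's resampling operator.
#'
#' @param kdata a [kspace_data()].
#' @param coils coil sensitivities.
#' @param state an [encoding_state()] (or `NULL` for identity).
#' @return complex 3D image array.
#' @export
forward_adjoint <- function(kdata, coils, state) {
  pattern <- kdata$pattern
  grid <- kdata$grid
  if (is.null(state)) state <- identity_state(pattern)
  shots <- sort(unique(pattern$lines$shot))
  nc <- coils$n_channels
  acc <- array(0i, dim = grid$shape)
  for (s in shots) {
    si <- s + 1L
    rows <- which(pattern$lines$shot == s)
    geo <- shot_sample_geometry(pattern, grid, state$fields[si, ],
                                pattern$lines[rows, ])
    img_s <- array(0i, dim = grid$shape)
    for (c in seq_len(nc)) {
      vals <- Conj(geo$phase) * as.vector(kdata$samples[, rows, c])
      Kc <- scatter_complex(vals, grid$shape, geo$idx)
      img_s <- img_s + Conj(coils$maps[, , , c]) * kspace_inv(Kc)
    }
    acc <- acc + apply_rigid_adjoint(img_s, grid, state$transforms[[si]])
  }
  acc
}

#' Simulate an undersampled multi-coil acquisition
#'
#' Runs [forward_model()] and optionally adds white complex Gaussian noise to
#' the samples.
#'
#' @inheritParams forward_model
#' @param noise_sd complex-noise SD (per real/imag component) in k-space
#'   units; 0 for noiseless.
#' @param seed seed for the noise draw.
#' @return A [kspace_data()].
#' @export
simulate_kspace <- function(image, coils, state, pattern, grid, noise_sd = 0,
                            seed = 1) {
  kdata <- forward_model(image, coils, state, pattern, grid)
  if (noise_sd > 0) {
    n <- length(kdata$samples)
    noise <- with_seed(seed, complex(real = rnorm(n, sd = noise_sd),
                                     imaginary = rnorm(n, sd = noise_sd)))
    kdata$samples <- kdata$samples + array(noise, dim = dim(kdata$samples))
  }
  kdata$noise_sd <- noise_sd
  kdata
}

#' Model-based volume reconstruction by conjugate gradients
#'
#' Solves the Tikhonov-regularized normal equations
#' `(A^H A + eps I) x = A^H y` for the encoding operator `A` defined by the
#' coil maps, sampling pattern and per-shot encoding state. With `state =
#' NULL` (identity) this is the "uncorrected" control reconstruction: same
#' data, same solver, no motion or field terms.
#'
#' @param kdata a [kspace_data()].
#' @param coils coil sensitivities (root-sum-of-squares must be positive over
#'   the object).
#' @param state an [encoding_state()] or `NULL` for the uncorrected mode.
#' @param max_iter maximum CG iterations.
#' @param tol relative residual tolerance for early stopping.
#' @param epsilon Tikhonov conditioning weight.
#' @return list with `image` (complex 3D array), `residuals` (relative
#'   residual norm per iteration), `cost` (quadratic CG objective per
#'   iteration, non-increasing), `iterations`, `converged`.
#' @export
reconstruct_volume <- function(kdata, coils, state = NULL, max_iter = 30,
                               tol = 1e-6, epsilon = 1e-6) {
  pattern <- kdata$pattern
  grid <- kdata$grid
  normal_op <- function(x) {
    kd <- forward_model(x, coils, state, pattern, grid)
    forward_adjoint(kd, coils, state) + epsilon * x
  }
  b <- forward_adjoint(kdata, coils, state)
  x <- array(0i, dim = grid$shape)
  r <- b
  p <- r
  rs_old <- sum(Mod(r)^2)
  b_norm <- sqrt(sum(Mod(b)^2))
  if (b_norm == 0) {
    return(list(image = x, residuals = 0, cost = 0, iterations = 0L,
                converged = TRUE))
  }
  residuals <- numeric(0)
  cost <- numeric(0)
  cost_acc <- 0  # phi(x) = -1/2 <x, b + r>; track increments
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Ap <- normal_op(p)
    pAp <- Re(sum(Conj(p) * Ap))
    if (pAp <= 0) break  # numerically singular direction
    alpha <- rs_old / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(Mod(r)^2)
    residuals <- c(residuals, sqrt(rs_new) / b_norm)
    cost_acc <- cost_acc - 0.5 * alpha * rs_old -
      0.5 * alpha^2 * pAp + alpha * rs_old  # = phi decrease bookkeeping
    cost <- c(cost, Re(-0.5 * sum(Conj(x) * (b + r))))
    if (length(residuals) > 3 &&
        residuals[it] > 10 * min(residuals) && residuals[it] > 1) {
      stop(sprintf(
        "CG diverged: relative residual %.3g after %d iterations",
        residuals[it], it))
    }
    if (sqrt(rs_new) / b_norm < tol) {
      converged <- TRUE
      break
    }
    p <- r + (rs_new / rs_old) * p
    rs_old <- rs_new
  }
  list(image = x, residuals = residuals, cost = cost,
       iterations = length(residuals), converged = converged)
}

#' Map per-shot acquisition times to navigator-frame encoding states
#'
#' Each shot of each volume is assigned the pose/field of the navigator frame
#' nearest to its acquisition mid-time (optionally linearly interpolated).
#'
#' @param pattern imaging [build_caipi_pattern()].
#' @param volume_index 1-based index of the volume in the run.
#' @param tr repetition time in seconds (one shot per TR).
#' @param motion a `motion_trace` (or `NULL` for identity poses).
#' @param field a `field_trace` (or `NULL` for zero field).
#' @param interp `"nearest"` (default) or `"linear"` frame interpolation.
#' @return An [encoding_state()] covering the volume's shots.
#' @export
states_from_traces <- function(pattern, volume_index, tr, motion = NULL,
                               field = NULL, interp = c("nearest", "linear")) {
  interp <- match.arg(interp)
  shots <- sort(unique(pattern$lines$shot))
  n_shot <- length(shots)
  trs_per_volume <- max(pattern$lines$tr_index) + 1
  volume_t0 <- (volume_index - 1) * trs_per_volume * tr
  shot_time <- volume_t0 + shots * tr + tr / 2
  frame_of <- function(t, n_frames, dt) {
    pmin(pmax(round(t / dt) + 1, 1), n_frames)
  }
  transforms <- vector("list", n_shot)
  fields <- data.frame(g0 = numeric(n_shot), gx = numeric(n_shot),
                       gy = numeric(n_shot), gz = numeric(n_shot))
  for (i in seq_len(n_shot)) {
    if (!is.null(motion)) {
      nf <- length(motion$frames)
      if (interp == "nearest") {
        transforms[[i]] <- motion$frames[[frame_of(shot_time[i], nf,
                                                   motion$frame_interval)]]
      } else {
        f <- shot_time[i] / motion$frame_interval
        f0 <- pmin(pmax(floor(f) + 1, 1), nf)
        f1 <- pmin(f0 + 1, nf)
        w <- pmin(pmax(f - (f0 - 1), 0), 1)
        p <- (1 - w) * motion$frames[[f0]]$par + w * motion$frames[[f1]]$par
        transforms[[i]] <- do.call(rigid_transform, as.list(p))
      }
    } else {
      transforms[[i]] <- rigid_identity()
    }
    if (!is.null(field)) {
      nf <- length(field$g0)
      fi <- frame_of(shot_time[i], nf, field$frame_interval)
      fields[i, ] <- c(field$g0[fi], field$gx[fi], field$gy[fi], field$gz[fi])
    }
  }
  encoding_state(transforms, fields)
}

#' Reconstruct a full run volume-by-volume
#'
#' @param run list of [kspace_data()], one per volume.
#' @param coils coil sensitivities.
#' @param tr repetition time in seconds.
#' @param motion,field navigator-derived traces (ignored in uncorrected mode).
#' @param mode `"corrected"` (per-shot motion + field states from the traces)
#'   or `"uncorrected"` (identity states; identical solver settings).
#' @param max_iter,tol,epsilon passed to [reconstruct_volume()].
#' @return A [time_series_4d()] of voxel magnitudes.
#' @export
reconstruct_series <- function(run, coils, tr, motion = NULL, field = NULL,
                               mode = c("corrected", "uncorrected"),
                               max_iter = 40, tol = 1e-6, epsilon = 1e-6) {
  mode <- match.arg(mode)
  n_vol <- length(run)
  stopifnot(n_vol >= 1)
  grid <- run[[1]]$grid
  trs_per_volume <- max(run[[1]]$pattern$lines$tr_index) + 1
  out <- array(0, dim = c(grid$shape, n_vol))
  for (v in seq_len(n_vol)) {
    state <- if (mode == "corrected") {
      states_from_traces(run[[v]]$pattern, v, tr, motion, field)
    } else NULL
    rec <- reconstruct_volume(run[[v]], coils, state, max_iter = max_iter,
                              tol = tol, epsilon = epsilon)
    out[, , , v] <- Mod(rec$image)
  }
  time_series_4d(out, grid, trs_per_volume * tr)
}

#' Normalized root-mean-square error against a reference image
#' @param x,ref arrays of identical shape (magnitudes are compared).
#' @return `sqrt(mean(|x - ref|^2)) / sqrt(mean(|ref|^2))`.
#' @export
nrmse <- function(x, ref) {
  sqrt(mean(Mod(x - ref)^2)) / sqrt(mean(Mod(ref)^2))
}
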