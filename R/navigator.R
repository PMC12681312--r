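# Navigator processing: 2D-GRAPPA reconstruction of the accelerated
# low-resolution navigator volumes, rigid head-pose estimation by
# multiresolution Gauss-Newton registration of navigator magnitudes, and
# global + linear field-change estimation from navigator phase.

# coset class of an absolute (ky, kz) index on the CAIPI lattice
# {(ky, kz): kz = Rz*j, ky = shift*j + Ry*i}; (0,0) means acquired
caipi_class <- function(ky, kz, Ry, Rz, shift) {
  j <- kz %/% Rz
  cz <- kz %% Rz
  cy <- (ky - shift * j) %% Ry
  cbind(cy, cz)
}

# source offsets (dy, dz) for a missing class: the n_src nearest acquired
# lattice points, deterministic tie-break by (dz, dy)
grappa_source_offsets <- function(cy, cz, Ry, Rz, shift, n_src = 4) {
  cand <- expand.grid(dy = -(Ry + 1):(Ry + 1), dz = -Rz:Rz)
  cls <- caipi_class(cy + cand$dy, cz + cand$dz, Ry, Rz, shift)
  acq <- cls[, 1] == 0 & cls[, 2] == 0
  cand <- cand[acq, ]
  ord <- order(cand$dy^2 + cand$dz^2, cand$dz, cand$dy)
  cand[ord[seq_len(min(n_src, nrow(cand)))], , drop = FALSE]
}

#' Calibrate a 2D-GRAPPA kernel from fully sampled autocalibration data
#'
#' Fits, for every missing-offset class of the CAIPI lattice, a
#' Tikhonov-regularized least-squares kernel that predicts the missing
#' k-space value of every channel from acquired-lattice neighbors (a block of
#' `kx_span` read-direction neighbors by the `n_src_yz` nearest acquired
#' phase-encode lattice points, across all channels).
#'
#' @param acs complex array `ax x ay x az x nc`, a fully sampled central
#'   k-space block.
#' @param Ry,Rz acceleration factors of the pattern to be reconstructed.
#' @param caipi_shift CAIPI shift of that pattern.
#' @param kx_span number of kx source neighbors (odd; default 5).
#' @param n_src_yz number of acquired (ky,kz) lattice sources (default 4,
#'   i.e. a 2x2 neighborhood on the lattice).
#' @param tikhonov relative Tikhonov regularization of the fit.
#' @return An object of class `grappa_kernel`: per-class weights, source
#'   geometry, acceleration, and the relative fit residual per class.
#' @export
grappa_calibrate <- function(acs, Ry, Rz, caipi_shift = 1, kx_span = 5,
                             n_src_yz = 4, tikhonov = 1e-4) {
  stopifnot(length(dim(acs)) == 4, kx_span %% 2 == 1)
  d <- dim(acs)
  nc <- d[4]
  dxs <- -(kx_span %/% 2):(kx_span %/% 2)
  classes <- expand.grid(cy = 0:(Ry - 1), cz = 0:(Rz - 1))
  classes <- classes[!(classes$cy == 0 & classes$cz == 0), , drop = FALSE]
  kernels <- list()
  for (ci in seq_len(nrow(classes))) {
    cy <- classes$cy[ci]; cz <- classes$cz[ci]
    src <- grappa_source_offsets(cy, cz, Ry, Rz, caipi_shift, n_src_yz)
    # valid sliding-window target positions inside the ACS block
    xr <- (1 - min(dxs)):(d[1] - max(dxs))
    yr <- (1 - min(src$dy)):(d[2] - max(src$dy))
    zr <- (1 - min(src$dz)):(d[3] - max(src$dz))
    n_eq <- length(xr) * length(yr) * length(zr)
    n_unk <- nc * nrow(src) * length(dxs)
    if (n_eq < 4 * n_unk) {
      stop(sprintf(
        "ACS too small for GRAPPA class (%d,%d): %d equations for %d unknowns (need >= %d)",
        cy, cz, n_eq, n_unk, 4 * n_unk))
    }
    S <- matrix(0i, n_eq, n_unk)
    col <- 0L
    for (c in seq_len(nc)) {
      for (m in seq_len(nrow(src))) {
        for (dx in dxs) {
          col <- col + 1L
          S[, col] <- as.vector(acs[xr + dx, yr + src$dy[m],
                                    zr + src$dz[m], c])
        }
      }
    }
    Tg <- matrix(0i, n_eq, nc)
    for (c in seq_len(nc)) Tg[, c] <- as.vector(acs[xr, yr, zr, c])
    ShS <- crossprod(Conj(S), S)
    lam <- tikhonov * mean(Re(diag(ShS)))
    W <- solve(ShS + lam * diag(n_unk), crossprod(Conj(S), Tg))
    resid <- sqrt(sum(Mod(S %*% W - Tg)^2)) / sqrt(sum(Mod(Tg)^2))
    kernels[[ci]] <- list(cy = cy, cz = cz, src = src, weights = W,
                          residual = resid)
  }
  structure(list(kernels = kernels, accel = c(Ry = Ry, Rz = Rz),
                 caipi_shift = caipi_shift, kx_span = kx_span, nc = nc),
            class = "grappa_kernel")
}

#' @export
print.grappa_kernel <- function(x, ...) {
  cat(sprintf(
    "grappa_kernel: R = %d x %d (shift %d), %d channels, %d missing classes, max fit residual %.3g\n",
    x$accel[1], x$accel[2], x$caipi_shift, x$nc, length(x$kernels),
    max(vapply(x$kernels, function(k) k$residual, 0))))
  invisible(x)
}

#' Convert line-list k-space data to a zero-filled full-grid array
#' @param kdata a [kspace_data()].
#' @return complex array `nx x ny x nz x nc` with unsampled entries zero.
#' @export
kspace_to_array <- function(kdata) {
  m <- kdata$pattern$matrix
  nc <- dim(kdata$samples)[3]
  arr <- array(0i, dim = c(m, nc))
  ky <- kdata$pattern$lines$ky + 1L
  kz <- kdata$pattern$lines$kz + 1L
  for (c in seq_len(nc)) {
    for (l in seq_along(ky)) arr[, ky[l], kz[l], c] <- kdata$samples[, l, c]
  }
  arr
}

#' Reconstruct an accelerated navigator frame with 2D-GRAPPA
#'
#' Synthesizes every missing (ky,kz) line channel-by-channel from acquired
#' neighbors using a calibrated kernel, then inverse-FFTs each channel.
#' Acquired samples are preserved verbatim.
#'
#' @param ksp complex array `nx x ny x nz x nc`, zero-filled undersampled
#'   k-space on the CAIPI lattice the kernel was calibrated for.
#' @param kernel a [grappa_calibrate()] result.
#' @param combine `"none"` (return channel images), or coil maps
#'   (`coil_profile_set` on the navigator grid) for conjugate-sensitivity
#'   combination, or `"adaptive"` for a global first-eigenvector combination.
#' @return list with `kspace` (filled k-space), `channels` (complex channel
#'   images) and, unless `combine = "none"`, `image` (combined complex
#'   image).
#' @export
grappa_reconstruct <- function(ksp, kernel, combine = "adaptive") {
  stopifnot(length(dim(ksp)) == 4, dim(ksp)[4] == kernel$nc)
  d <- dim(ksp)
  nx <- d[1]; ny <- d[2]; nz <- d[3]; nc <- d[4]
  Ry <- kernel$accel[1]; Rz <- kernel$accel[2]
  filled <- ksp
  dxs <- -(kernel$kx_span %/% 2):(kernel$kx_span %/% 2)
  grid_yz <- expand.grid(ky = 0:(ny - 1), kz = 0:(nz - 1))
  cls <- caipi_class(grid_yz$ky, grid_yz$kz, Ry, Rz, kernel$caipi_shift)
  for (kern in kernel$kernels) {
    sel <- which(cls[, 1] == kern$cy & cls[, 2] == kern$cz)
    if (!length(sel)) next
    my <- grid_yz$ky[sel]; mz <- grid_yz$kz[sel]
    n_m <- length(sel)
    n_unk <- ncol(kern$weights)  # not used; columns of S below
    S <- matrix(0i, nx * n_m, nrow(kern$weights))
    col <- 0L
    for (c in seq_len(nc)) {
      for (m in seq_len(nrow(kern$src))) {
        sy <- my + kern$src$dy[m]
        sz <- mz + kern$src$dz[m]
        ok <- sy >= 0 & sy < ny & sz >= 0 & sz < nz
        for (dx in dxs) {
          col <- col + 1L
          vals <- matrix(0i, nx, n_m)
          if (any(ok)) {
            for (i in which(ok)) {
              xs <- ((0:(nx - 1)) + dx) %% nx  # kx wraps (fully sampled axis)
              vals[, i] <- ksp[xs + 1L, sy[i] + 1L, sz[i] + 1L, c]
            }
          }
          S[, col] <- as.vector(vals)
        }
      }
    }
    synth <- S %*% kern$weights  # (nx*n_m) x nc
    for (c in seq_len(nc)) {
      vm <- matrix(synth[, c], nx, n_m)
      for (i in seq_len(n_m)) filled[, my[i] + 1L, mz[i] + 1L, c] <- vm[, i]
    }
  }
  channels <- array(0i, dim = d)
  for (c in seq_len(nc)) channels[, , , c] <- kspace_inv(filled[, , , c])
  out <- list(kspace = filled, channels = channels)
  if (!identical(combine, "none")) {
    out$image <- combine_channels(channels, combine)
  }
  out
}

#' Combine multi-channel complex images into one complex image
#'
#' With coil maps: conjugate-sensitivity weighted sum,
#' `sum(conj(S_c) I_c) / (sum |S_c|^2 + eps)` — phase-preserving, which the
#' field estimator needs. Without maps: global first-eigenvector (adaptive)
#' combination.
#'
#' @param channels complex array `nx x ny x nz x nc`.
#' @param method a `coil_profile_set`, or `"adaptive"`.
#' @return complex 3D array.
#' @export
combine_channels <- function(channels, method = "adaptive") {
  d <- dim(channels)
  nc <- d[4]
  if (inherits(method, "coil_profile_set")) {
    num <- array(0i, dim = d[1:3])
    den <- array(0, dim = d[1:3])
    for (c in seq_len(nc)) {
      num <- num + Conj(method$maps[, , , c]) * channels[, , , c]
      den <- den + Mod(method$maps[, , , c])^2
    }
    return(num / (den + 1e-6 * max(den)))
  }
  X <- matrix(channels, ncol = nc)
  M <- crossprod(Conj(X), X)
  v <- eigen(M, symmetric = TRUE)$vectors[, 1]
  array(X %*% Conj(v), dim = d[1:3])
}

# block-average downsample by 2 along every axis, with the matching grid
downsample2 <- function(vol, grid) {
  d <- dim(vol)
  nd <- ceiling(d / 2)
  pad <- array(0, dim = nd * 2)
  pad[1:d[1], 1:d[2], 1:d[3]] <- vol
  out <- (pad[seq(1, 2 * nd[1], 2), , , drop = FALSE] +
          pad[seq(2, 2 * nd[1], 2), , , drop = FALSE])
  out <- (out[, seq(1, 2 * nd[2], 2), , drop = FALSE] +
          out[, seq(2, 2 * nd[2], 2), , drop = FALSE])
  out <- (out[, , seq(1, 2 * nd[3], 2), drop = FALSE] +
          out[, , seq(2, 2 * nd[3], 2), drop = FALSE]) / 8
  g <- grid3d(nd, grid$voxel_size * 2,
              origin = grid$origin + grid$voxel_size / 2)
  list(vol = out, grid = g)
}

#' Estimate rigid head pose by multiresolution registration
#'
#' Finds the 6-parameter rigid transform `T` minimizing the masked
#' sum-of-squared differences `||apply_rigid(reference, T) - frame||^2` with
#' damped Gauss-Newton iterations on a coarse-to-fine (downsample-by-2)
#' pyramid. The Jacobian is taken by central finite differences on the six
#' parameters.
#'
#' @param frame magnitude image of the navigator frame to register.
#' @param reference magnitude image of the reference frame (same grid).
#' @param grid the navigator [grid3d()].
#' @param pyramid_levels number of resolution levels (default 2).
#' @param max_iter maximum Gauss-Newton iterations per level.
#' @param tol convergence threshold on the parameter-update norm.
#' @param init optional initial [rigid_transform()].
#' @return A [rigid_transform()] with attributes `converged` (logical) and
#'   `final_update` (last update norm). Non-convergence warns but still
#'   returns the estimate.
#' @export
estimate_motion <- function(frame, reference, grid, pyramid_levels = 2,
                            max_iter = 50, tol = 1e-4, init = NULL) {
  stopifnot(all(dim(frame) == grid$shape), all(dim(reference) == grid$shape))
  levels <- list(list(frame = frame, ref = reference, grid = grid))
  for (l in seq_len(pyramid_levels - 1)) {
    prev <- levels[[l]]
    df <- downsample2(prev$frame, prev$grid)
    dr <- downsample2(prev$ref, prev$grid)
    levels[[l + 1]] <- list(frame = df$vol, ref = dr$vol, grid = df$grid)
  }
  theta <- if (is.null(init)) numeric(6) else init$par
  converged <- TRUE
  upd <- Inf
  deltas <- c(rep(0.05, 3), rep(0.05, 3))  # mm / degrees FD step
  for (l in rev(seq_len(pyramid_levels))) {
    lv <- levels[[l]]
    msk <- lv$ref > 0.05 * max(lv$ref)
    fvec <- lv$frame[msk]
    warp_resid <- function(p) {
      t <- do.call(rigid_transform, as.list(p))
      apply_rigid(lv$ref, lv$grid, t)[msk] - fvec
    }
    r <- warp_resid(theta)
    cost <- sum(r^2)
    mu <- 1e-6
    lvl_converged <- FALSE
    for (it in seq_len(max_iter)) {
      J <- matrix(0, length(r), 6)
      for (j in 1:6) {
        pp <- theta; pp[j] <- pp[j] + deltas[j]
        pm <- theta; pm[j] <- pm[j] - deltas[j]
        J[, j] <- (warp_resid(pp) - warp_resid(pm)) / (2 * deltas[j])
      }
      H <- crossprod(J)
      g <- crossprod(J, r)
      step_ok <- FALSE
      for (k in 1:8) {
        delta <- tryCatch(
          solve(H + mu * diag(diag(H) + 1e-12), -g),
          error = function(e) NULL)
        if (is.null(delta)) { mu <- mu * 10; next }
        cand <- theta + as.numeric(delta)
        rc <- warp_resid(cand)
        if (sum(rc^2) < cost) {
          theta <- cand; r <- rc; cost <- sum(rc^2)
          mu <- max(mu / 3, 1e-9)
          step_ok <- TRUE
          break
        }
        mu <- mu * 10
      }
      upd <- if (step_ok) sqrt(sum(delta^2)) else 0
      if (!step_ok || upd < tol) { lvl_converged <- TRUE; break }
    }
    if (!lvl_converged) converged <- FALSE
  }
  if (!converged) {
    warning(sprintf(
      "estimate_motion did not converge (final update norm %.3g)", upd))
  }
  out <- do.call(rigid_transform, as.list(theta))
  attr(out, "converged") <- converged
  attr(out, "final_update") <- upd
  out
}

#' Estimate global and linear field change from navigator phase
#'
#' Motion-compensates the frame by the supplied pose, forms the phase
#' difference against the reference, and fits it (weighted least squares,
#' weights = product magnitude squared) to `[1, x, y, z]` in world mm,
#' scaled by `1/(2*pi*nav_te)` to Hz.
#'
#' @param frame,reference complex navigator images on `grid`.
#' @param grid navigator [grid3d()].
#' @param mask logical array of voxels used in the fit.
#' @param nav_te seconds from excitation to the navigator echo center.
#' @param motion the frame's [rigid_transform()] (identity if omitted).
#' @return An object of class `field_state`: list `g0` (Hz), `gx, gy, gz`
#'   (Hz/mm); attribute `wrap_warning` is `TRUE` when more than 5% of masked
#'   voxels approach the phase-wrap limit.
#' @export
estimate_field_change <- function(frame, reference, grid, mask, nav_te,
                                  motion = NULL) {
  stopifnot(nav_te > 0)
  if (!is.null(motion)) {
    frame <- apply_rigid(frame, grid, invert_rigid(motion,
                                                   grid_center(grid)))
  }
  prod_ <- frame * Conj(reference)
  dphi <- Arg(prod_)
  w <- Mod(prod_)^2
  mvec <- as.vector(mask) & as.vector(w) > 0
  wrap <- mean(abs(dphi[mvec]) > 0.9 * pi)
  pts <- grid_coords(grid)
  X <- cbind(1, pts[mvec, , drop = FALSE])
  y <- as.vector(dphi)[mvec] / (2 * pi * nav_te)
  wv <- as.vector(w)[mvec]
  XtW <- t(X * wv)
  beta <- solve(XtW %*% X, XtW %*% y)
  out <- structure(list(g0 = beta[1], gx = beta[2], gy = beta[3],
                        gz = beta[4]), class = "field_state")
  attr(out, "wrap_warning") <- wrap > 0.05
  if (wrap > 0.05) {
    warning(sprintf(
      "possible phase wrap: %.1f%% of masked voxels near the wrap limit",
      100 * wrap))
  }
  out
}

#' Run the full navigator pipeline over a set of frames
#'
#' GRAPPA-reconstructs every undersampled navigator frame, takes the first
#' frame as reference, and estimates per-frame rigid motion (magnitude
#' registration) and field change (phase fit).
#'
#' @param nav_ksp list of zero-filled undersampled navigator k-space arrays
#'   (`nx x ny x nz x nc`), one per frame.
#' @param kernel a calibrated [grappa_calibrate()] kernel.
#' @param grid navigator [grid3d()].
#' @param nav_te navigator echo time in seconds.
#' @param combine channel-combination method for [grappa_reconstruct()].
#' @param frame_interval seconds between frames (propagated to the traces).
#' @param estimate_field set `FALSE` to skip the field fit.
#' @return list with `motion` (a `motion_trace`), `field` (a `field_trace` or
#'   `NULL`), and `images` (list of combined complex frame images).
#' @export
navigator_pipeline <- function(nav_ksp, kernel, grid, nav_te = 0.01,
                               combine = "adaptive", frame_interval = 0.468,
                               estimate_field = TRUE) {
  n <- length(nav_ksp)
  images <- vector("list", n)
  for (f in seq_len(n)) {
    images[[f]] <- grappa_reconstruct(nav_ksp[[f]], kernel, combine)$image
  }
  ref <- images[[1]]
  ref_mag <- Mod(ref)
  mask <- ref_mag > 0.1 * max(ref_mag)
  frames <- vector("list", n)
  g0 <- gx <- gy <- gz <- numeric(n)
  frames[[1]] <- rigid_identity()
  for (f in seq_len(n)) {
    if (f > 1) {
      frames[[f]] <- estimate_motion(Mod(images[[f]]), ref_mag, grid)
    }
    if (estimate_field && f > 1) {
      fs <- estimate_field_change(images[[f]], ref, grid, mask, nav_te,
                                  motion = frames[[f]])
      g0[f] <- fs$g0; gx[f] <- fs$gx; gy[f] <- fs$gy; gz[f] <- fs$gz
    }
  }
  motion <- structure(list(frames = frames, frame_interval = frame_interval),
                      class = "motion_trace")
  field <- if (estimate_field) {
    structure(list(g0 = g0, gx = gx, gy = gy, gz = gz,
                   frame_interval = frame_interval), class = "field_trace")
  } else NULL
  list(motion = motion, field = field, images = images)
}

#' Simulate navigator acquisitions for a motion/field trajectory
#'
#' Each navigator frame is a forward-model acquisition of the phantom at the
#' frame's pose and field state on the (accelerated) navigator pattern.
#' Returns zero-filled full-grid k-space arrays ready for
#' [grappa_reconstruct()], plus a fully sampled central ACS block of the
#' reference frame for kernel calibration.
#'
#' @param image static phantom image on the navigator grid.
#' @param grid navigator [grid3d()].
#' @param coils navigator-grid coil sensitivities.
#' @param schedule a [build_navigator_schedule()] result.
#' @param motion a `motion_trace` (frame 1 must be identity).
#' @param field optional `field_trace`.
#' @param acs_size `(ky, kz)` extent of the ACS block.
#' @param noise_sd complex noise SD; 0 for noiseless.
#' @param seed noise seed.
#' @return list with `frames` (list of k-space arrays) and `acs`.
#' @export
simulate_navigator_frames <- function(image, grid, coils, schedule, motion,
                                      field = NULL, acs_size = c(16, 12),
                                      noise_sd = 0, seed = 1) {
  pattern <- schedule$pattern
  n <- length(motion$frames)
  n_shot <- length(unique(pattern$lines$shot))
  frames <- vector("list", n)
  for (f in seq_len(n)) {
    fields <- if (is.null(field)) NULL else {
      data.frame(g0 = rep(field$g0[f], n_shot), gx = rep(field$gx[f], n_shot),
                 gy = rep(field$gy[f], n_shot), gz = rep(field$gz[f], n_shot))
    }
    state <- encoding_state(rep(list(motion$frames[[f]]), n_shot), fields)
    kd <- simulate_kspace(image, coils, state, pattern, grid,
                          noise_sd = noise_sd, seed = seed + f)
    frames[[f]] <- kspace_to_array(kd)
  }
  # fully sampled central ACS block from the reference pose
  full <- array(0i, dim = c(grid$shape, coils$n_channels))
  for (c in seq_len(coils$n_channels)) {
    full[, , , c] <- kspace_fwd((image + 0i) * coils$maps[, , , c])
  }
  ny <- grid$shape[2]; nz <- grid$shape[3]
  y0 <- floor(ny / 2) - acs_size[1] %/% 2 + 1
  z0 <- floor(nz / 2) - acs_size[2] %/% 2 + 1
  acs <- full[, y0:(y0 + acs_size[1] - 1), z0:(z0 + acs_size[2] - 1), ,
              drop = FALSE]
  list(frames = frames, acs = acs)
}

#' Write motion and field traces as one TSV
#' @param motion a `motion_trace`.
#' @param field a `field_trace` (optional).
#' @param path output TSV path.
#' @export
write_trace_tsv <- function(motion, field = NULL, path) {
  m <- as.data.frame(rigid_params(motion$frames))
  m <- cbind(frame = seq_len(nrow(m)) - 1L, m)
  if (!is.null(field)) {
    m$g0 <- field$g0; m$gx <- field$gx; m$gy <- field$gy; m$gz <- field$gz
  }
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
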