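# kT-point spatial-spectral pTx pulse design: AFI + hybrid B1+ calibration,
# small-tip system matrix, regularized magnitude-least-squares design by
# variable exchange, and hard-pulse Bloch verification.
#
# Units: B1+ maps are in microtesla per unit drive; drives are dimensionless
# complex weights; kT-point locations are in cycles/m; the system matrix
# returns radians of flip per unit drive.

GAMMA_RAD_PER_S_PER_UT <- 2 * pi * 42.577  # 1H, rad/s per microtesla

#' Flip-angle map from actual flip-angle imaging (AFI)
#'
#' AFI interleaves two TRs with ratio `n = TR2/TR1`; the steady-state signal
#' ratio `r = S2/S1` yields the flip angle as
#' `alpha = arccos((r*n - 1) / (n - r))`.
#'
#' @param s1,s2 signal images from the short and long TR.
#' @param n TR ratio (> 1).
#' @return list with `fa` (degrees, 0 where invalid) and `valid` (logical
#'   array; voxels whose ratio leaves the arccos domain or with non-positive
#'   signal are masked out).
#' @export
afi_flip_angle <- function(s1, s2, n) {
  stopifnot(n > 1, all(dim(s1) == dim(s2)))
  valid <- s1 > 0 & s2 > 0
  r <- array(NA_real_, dim = dim(s1))
  r[valid] <- s2[valid] / s1[valid]
  arg <- (r * n - 1) / (n - r)
  valid <- valid & is.finite(arg) & arg >= -1 & arg <= 1 & (n - r) > 0
  fa <- array(0, dim = dim(s1))
  fa[valid] <- acos(pmin(pmax(arg[valid], -1), 1)) * 180 / pi
  list(fa = fa, valid = valid)
}

# forward AFI signal ratio for a given flip angle (degrees): used by tests
afi_signal_ratio <- function(alpha_deg, n) {
  ca <- cos(alpha_deg * pi / 180)
  (1 + n * ca) / (n + ca)
}

#' Combine absolute CP-mode and relative per-channel B1+ maps
#'
#' Hybrid B1+ mapping: a single absolute flip-angle map acquired in the CP
#' mode anchors the overall scale, while fast relative per-channel maps carry
#' the channel structure:
#' `abs_c = rel_c * absolute_cp / |sum_c w_c rel_c|` voxelwise.
#'
#' @param absolute_cp absolute CP-mode map (3D array, e.g. degrees or uT).
#' @param relative_maps complex array `nx x ny x nz x n_tx` of relative maps.
#' @param cp_weights complex CP drive weights per channel.
#' @param grid optional [grid3d()] carried into the result.
#' @return A `b1_map_set` whose CP combination has magnitude `absolute_cp`.
#'   Attribute `n_masked` counts voxels masked for a near-zero CP sum.
#' @export
combine_hybrid_b1 <- function(absolute_cp, relative_maps, cp_weights,
                              grid = NULL) {
  d <- dim(relative_maps)
  stopifnot(length(d) == 4, all(dim(absolute_cp) == d[1:3]),
            length(cp_weights) == d[4])
  cp_sum <- array(0i, dim = d[1:3])
  for (c in seq_len(d[4])) {
    cp_sum <- cp_sum + cp_weights[c] * relative_maps[, , , c]
  }
  den <- Mod(cp_sum)
  bad <- den < 1e-9 * max(den)
  den[bad] <- 1
  out <- array(0i, dim = d)
  for (c in seq_len(d[4])) {
    m <- relative_maps[, , , c] * absolute_cp / den
    m[bad] <- 0
    out[, , , c] <- m
  }
  res <- structure(list(maps = out, n_tx = d[4], grid = grid),
                   class = "b1_map_set")
  attr(res, "n_masked") <- sum(bad)
  res
}

#' Default symmetric kT-point locations
#'
#' A fixed set of `n_points` excitation-k-space locations placed as +/- pairs
#' on a small 3D lattice within `extent` cycles per field of view (the
#' origin's pair is itself, so it appears twice). Locations are returned in
#' cycles/m.
#'
#' @param fov_m field of view in meters (triple).
#' @param n_points number of points (even; default 24).
#' @param extent lattice extent in cycles per FOV.
#' @return matrix `n_points x 3` (cycles/m), symmetric about the origin.
#' @export
default_kt_locations <- function(fov_m, n_points = 24, extent = 2) {
  stopifnot(n_points %% 2 == 0)
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                c(0, 1, 1), c(0, 1, -1), c(2, 0, 0), c(1, 1, 1),
                c(0, 2, 0), c(0, 0, 2), c(2, 1, 0), c(1, 2, 0))
  base <- base[seq_len(n_points / 2), , drop = FALSE]
  base <- base * extent / max(abs(base))
  pts <- matrix(0, n_points, 3)
  pts[seq(1, n_points, 2), ] <- base
  pts[seq(2, n_points, 2), ] <- -base
  sweep(pts, 2, fov_m, "/")
}

#' Spatial-spectral excitation target
#'
#' Water passband at the nominal flip angle and fat stopband at zero, each
#' sampled on three points spanning a 200 Hz bandwidth in 100 Hz steps.
#'
#' @param nominal_fa_deg nominal water flip angle (degrees).
#' @param fat_shift_hz fat-water shift (default the 10.5 T value from
#'   [fat_water_shift_hz()]).
#' @param halfwidth_hz half-bandwidth of each band (default 100).
#' @return list with `frequencies` (Hz) and `target_fa` (degrees).
#' @export
spectral_target <- function(nominal_fa_deg = 10,
                            fat_shift_hz = fat_water_shift_hz(10.5),
                            halfwidth_hz = 100) {
  off <- c(-halfwidth_hz, 0, halfwidth_hz)
  list(frequencies = c(off, fat_shift_hz + off),
       target_fa = c(rep(nominal_fa_deg, 3), rep(0, 3)))
}

#' Small-tip spatial-spectral system matrix for kT-point pulses
#'
#' Rows are (frequency, masked voxel) pairs (frequency-major, voxels in mask
#' order); columns are (kT point, channel) pairs (point-major within
#' channel: column `(c-1)*n_points + k`). Entry:
#' `i * gamma * dt * B1_c(r) * exp(i 2 pi k_k . r) * exp(i 2 pi (f + b0(r)) (t_k - T))`
#' with subpulse centers `t_k = (k - 1/2) dt` and `T` the pulse end, so the
#' matrix maps complex drives to radians of transverse flip.
#'
#' @param b1 a `b1_map_set` (maps in uT per unit drive).
#' @param b0 off-resonance map in Hz (3D array).
#' @param mask logical 3D array of design voxels.
#' @param grid the [grid3d()] the maps live on (voxel positions in m are
#'   taken from its world coordinates / 1000).
#' @param kt_locations matrix `n_points x 3` in cycles/m.
#' @param subpulse_duration seconds per kT point.
#' @param freqs evaluation frequencies in Hz.
#' @return complex matrix `(n_freq * n_mask) x (n_tx * n_points)`, with
#'   attributes `n_vox`, `freqs`, `n_points`, `n_tx`.
#' @export
build_system_matrix <- function(b1, b0, mask, grid, kt_locations,
                                subpulse_duration, freqs) {
  stopifnot(inherits(b1, "b1_map_set"))
  d <- dim(b1$maps)
  stopifnot(all(dim(mask) == d[1:3]), all(dim(b0) == d[1:3]))
  n_tx <- d[4]
  n_pts <- nrow(kt_locations)
  dt <- subpulse_duration
  total <- n_pts * dt
  t_k <- (seq_len(n_pts) - 0.5) * dt
  mvec <- which(mask)
  n_vox <- length(mvec)
  pts_m <- grid_coords(grid)[mvec, , drop = FALSE] / 1000
  b0v <- as.vector(b0)[mvec]
  b1v <- matrix(0i, n_vox, n_tx)
  for (c in seq_len(n_tx)) b1v[, c] <- as.vector(b1$maps[, , , c])[mvec]
  spatial <- exp(2i * pi * (pts_m %*% t(kt_locations)))  # n_vox x n_pts
  n_freq <- length(freqs)
  A <- matrix(0i, n_freq * n_vox, n_tx * n_pts)
  for (fi in seq_len(n_freq)) {
    rows <- (fi - 1) * n_vox + seq_len(n_vox)
    for (k in seq_len(n_pts)) {
      spec <- exp(2i * pi * (freqs[fi] + b0v) * (t_k[k] - total))
      phase_k <- spatial[, k] * spec
      for (c in seq_len(n_tx)) {
        A[rows, (c - 1) * n_pts + k] <-
          1i * GAMMA_RAD_PER_S_PER_UT * dt * b1v[, c] * phase_k
      }
    }
  }
  attr(A, "n_vox") <- n_vox
  attr(A, "freqs") <- freqs
  attr(A, "n_points") <- n_pts
  attr(A, "n_tx") <- n_tx
  attr(A, "kt_locations") <- kt_locations
  attr(A, "subpulse_duration") <- subpulse_duration
  A
}

#' Construct a kT-point pulse object
#'
#' @param weights complex matrix `n_tx x n_points` of per-channel drives.
#' @param kt_locations matrix `n_points x 3` in cycles/m.
#' @param subpulse_duration seconds per point.
#' @return An object of class `kt_point_pulse`.
#' @export
kt_point_pulse <- function(weights, kt_locations, subpulse_duration) {
  stopifnot(ncol(weights) == nrow(kt_locations))
  structure(list(weights = weights, kt_locations = kt_locations,
                 subpulse_duration = subpulse_duration,
                 n_points = ncol(weights),
                 total_duration = ncol(weights) * subpulse_duration),
            class = "kt_point_pulse")
}

#' @export
print.kt_point_pulse <- function(x, ...) {
  cat(sprintf(
    "kt_point_pulse: %d channels x %d points, %.3g ms total (%.3g us/point)\n",
    nrow(x$weights), x$n_points, 1e3 * x$total_duration,
    1e6 * x$subpulse_duration))
  invisible(x)
}

# drive vector <-> weight matrix, matching build_system_matrix column order
weights_to_vec <- function(w) as.vector(t(w))
vec_to_weights <- function(b, n_tx, n_points) {
  t(matrix(b, n_points, n_tx))
}

#' Design a kT-point pulse by regularized magnitude least squares
#'
#' Variable-exchange iterations for
#' `min_b || |A b| - m ||^2 + lambda ||b||^2` relaxed as
#' `min_{b,z} || A b - m z ||^2 + lambda ||b||^2, |z| = 1`:
#' (i) `z <- exp(i arg(A b))`; (ii) `b <- argmin ||A b - m z||^2 +
#' lambda ||b||^2`. The joint cost is non-increasing across iterations; the
#' best iterate by cost is returned.
#'
#' @param A system matrix from [build_system_matrix()].
#' @param target_fa_rad target magnitude per row of `A` (radians, >= 0), or a
#'   [spectral_target()]-style list whose `target_fa` (degrees) is expanded
#'   across the mask voxels.
#' @param lambda regularization weight (>= 0), or `"auto"` for a 10-point
#'   logarithmic sweep that minimizes the magnitude residual subject to the
#'   pulse power not exceeding 4x the CP-mode power at equal mean flip.
#' @param n_iter variable-exchange iterations.
#' @param init `"cp"` (CP-mode phases, scaled to the mean target) or
#'   `"random"`.
#' @param seed seed for `init = "random"`.
#' @return list with `pulse` (a [kt_point_pulse()] carrying the best
#'   weights), `cost` (joint cost per iteration, non-increasing), `residual`
#'   (relative magnitude residual per iteration), `lambda`.
#' @export
design_mls_pulse <- function(A, target_fa_rad, lambda = 0, n_iter = 30,
                             init = c("cp", "random"), seed = 1) {
  init <- match.arg(init)
  n_tx <- attr(A, "n_tx")
  n_pts <- attr(A, "n_points")
  n_vox <- attr(A, "n_vox")
  if (is.list(target_fa_rad)) {
    target_fa_rad <- rep(target_fa_rad$target_fa * pi / 180, each = n_vox)
  }
  m <- as.numeric(target_fa_rad)
  stopifnot(length(m) == nrow(A), all(m >= 0))
  b_cp <- weights_to_vec(matrix(cp_mode_weights(n_tx), n_tx, n_pts))
  mean_resp <- mean(Mod(A %*% b_cp)[m > 0])
  if (mean_resp > 0) b_cp <- b_cp * mean(m[m > 0]) / mean_resp
  run_ve <- function(lam) {
    if (lam < 0) stop("lambda must be >= 0")
    AhA <- crossprod(Conj(A), A)
    reg <- AhA + lam * diag(ncol(A))
    if (rcond(Mod(reg)) < 1e-14) {
      stop("singular MLS solve: increase lambda")
    }
    b <- if (init == "cp") b_cp else {
      with_seed(seed, complex(real = rnorm(ncol(A)),
                              imaginary = rnorm(ncol(A))) *
                  sqrt(sum(Mod(b_cp)^2) / ncol(A)))
    }
    cost <- numeric(0)
    resid <- numeric(0)
    best <- list(cost = Inf, b = b)
    for (it in seq_len(n_iter)) {
      Ab <- A %*% b
      z <- exp(1i * Arg(Ab))
      b <- solve(reg, crossprod(Conj(A), m * z))
      Ab <- A %*% b
      ct <- sum(Mod(Ab - m * z)^2) + lam * sum(Mod(b)^2)
      cost <- c(cost, ct)
      resid <- c(resid, sqrt(sum((Mod(Ab) - m)^2)) /
                   max(sqrt(sum(m^2)), .Machine$double.eps))
      if (ct < best$cost) best <- list(cost = ct, b = b)
    }
    list(b = best$b, cost = cost, resid = resid)
  }
  if (identical(lambda, "auto")) {
    p_cp <- sum(Mod(b_cp)^2)
    lams <- 10^seq(-6, 3, length.out = 10) * max(1e-12, mean(Mod(A)^2) *
                                                   nrow(A) / ncol(A))
    best_l <- NULL
    for (lam in lams) {
      r <- run_ve(lam)
      if (sum(Mod(r$b)^2) <= 4 * p_cp &&
          (is.null(best_l) || tail(r$resid, 1) < tail(best_l$resid, 1))) {
        best_l <- r
        best_l$lambda <- lam
      }
    }
    if (is.null(best_l)) best_l <- c(run_ve(tail(lams, 1)),
                                     lambda = tail(lams, 1))
    r <- best_l
    lambda <- r$lambda
  } else {
    r <- run_ve(lambda)
  }
  list(pulse = kt_point_pulse(vec_to_weights(r$b, n_tx, n_pts),
                              kt_locations = attr(A, "kt_locations"),
                              subpulse_duration = attr(A, "subpulse_duration")),
       weights_vec = r$b, cost = r$cost, residual = r$resid, lambda = lambda)
}

#' Hard-pulse Bloch simulation of a kT-point pulse
#'
#' Alternates instantaneous rotations from the net complex RF per kT point
#' (`sum_c w_ck B1_c(r) exp(i 2 pi k_k . r)`) with free precession at
#' `f + b0(r)`, starting from magnetization +z. The flip angle is the angle
#' of the final magnetization from +z. Phase conventions match the small-tip
#' system matrix, so at low flip `|A b|` and the Bloch flip agree.
#'
#' @param pulse a [kt_point_pulse()] (or list with `weights`, `kt_locations`,
#'   `subpulse_duration`).
#' @param b1 a `b1_map_set` (uT per unit drive).
#' @param b0 off-resonance map in Hz.
#' @param grid the [grid3d()] of the maps.
#' @param mask logical array of voxels to simulate.
#' @param eval_freqs frequencies (Hz) to evaluate.
#' @return list with `fa` (matrix `n_mask_voxels x n_freq`, degrees), `mask`,
#'   `freqs`.
#' @export
bloch_simulate <- function(pulse, b1, b0, grid, mask, eval_freqs = 0) {
  W <- pulse$weights
  n_tx <- nrow(W)
  n_pts <- ncol(W)
  dt <- pulse$subpulse_duration
  stopifnot(dim(b1$maps)[4] == n_tx, dt > 0)
  mvec <- which(mask)
  n_vox <- length(mvec)
  pts_m <- grid_coords(grid)[mvec, , drop = FALSE] / 1000
  b0v <- as.vector(b0)[mvec]
  b1v <- matrix(0i, n_vox, n_tx)
  for (c in seq_len(n_tx)) b1v[, c] <- as.vector(b1$maps[, , , c])[mvec]
  spatial <- exp(2i * pi * (pts_m %*% t(pulse$kt_locations)))
  fa <- matrix(0, n_vox, length(eval_freqs))
  for (fi in seq_along(eval_freqs)) {
    dw <- 2 * pi * (eval_freqs[fi] + b0v)  # rad/s
    mx <- numeric(n_vox); my <- numeric(n_vox); mz <- rep(1, n_vox)
    precess <- function(ang) {
      # transverse phase evolves as exp(-i ang): matches the system matrix
      c1 <- cos(ang); s1 <- sin(ang)
      mx_new <- c1 * mx + s1 * my
      my <<- -s1 * mx + c1 * my
      mx <<- mx_new
    }
    for (k in seq_len(n_pts)) {
      precess(dw * dt / 2)
      b1eff <- as.vector(b1v %*% W[, k]) * spatial[, k]  # uT
      theta <- GAMMA_RAD_PER_S_PER_UT * dt * Mod(b1eff)  # rad
      psi <- Arg(b1eff)
      # rotation producing M_xy = +i * theta * exp(i psi) at small tip
      ux <- cos(psi); uy <- sin(psi)
      ct <- cos(theta); st <- sin(theta)
      dot <- ux * mx + uy * my
      mx_n <- ct * mx + st * (uy * mz) + (1 - ct) * dot * ux
      my_n <- ct * my + st * (-ux * mz) + (1 - ct) * dot * uy
      mz_n <- ct * mz + st * (ux * my - uy * mx)
      mx <- mx_n; my <- my_n; mz <- mz_n
      precess(dw * dt / 2)
    }
    fa[, fi] <- atan2(sqrt(mx^2 + my^2), mz) * 180 / pi
  }
  list(fa = fa, mask = mask, freqs = eval_freqs)
}

#' Coefficient of variation of a flip-angle distribution
#'
#' Population standard deviation divided by the mean over mask voxels.
#'
#' @param fa 3D flip-angle array, or a vector of in-mask values.
#' @param mask logical array (ignored when `fa` is a vector).
#' @return SD/mean as a fraction.
#' @export
flip_angle_cov <- function(fa, mask = NULL) {
  v <- if (is.null(mask)) as.numeric(fa) else fa[mask]
  if (!length(v)) stop("empty mask")
  mu <- mean(v)
  if (mu <= 0) stop("mean flip angle must be > 0")
  sqrt(mean((v - mu)^2)) / mu
}

#' Read complex transmit (B1+) maps from magnitude/phase NIfTI pairs
#'
#' @param magnitude_paths,phase_paths per-channel NIfTI paths (phase in
#'   radians).
#' @param grid optional [grid3d()] carried into the result.
#' @return A `b1_map_set`.
#' @export
read_b1_nifti <- function(magnitude_paths, phase_paths, grid = NULL) {
  stopifnot(length(magnitude_paths) == length(phase_paths))
  n_tx <- length(magnitude_paths)
  first <- RNifti::readNifti(magnitude_paths[1])
  maps <- array(0i, dim = c(dim(first), n_tx))
  for (c in seq_len(n_tx)) {
    m <- array(RNifti::readNifti(magnitude_paths[c]), dim = dim(first))
    p <- array(RNifti::readNifti(phase_paths[c]), dim = dim(first))
    maps[, , , c] <- complex(modulus = m, argument = p)
  }
  structure(list(maps = maps, n_tx = n_tx, grid = grid),
            class = "b1_map_set")
}

#' Serialize a designed pulse as a structured text file
#' @param pulse a [kt_point_pulse()].
#' @param path output path (plain text).
#' @export
write_pulse_txt <- function(pulse, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kT-point pulse: %d channels, %d points, dt %.6g s",
                     nrow(pulse$weights), pulse$n_points,
                     pulse$subpulse_duration), con)
  writeLines("point\tkx\tky\tkz\tchannel\tre\tim", con)
  for (k in seq_len(pulse$n_points)) {
    for (c in seq_len(nrow(pulse$weights))) {
      writeLines(sprintf("%d\t%.8g\t%.8g\t%.8g\t%d\t%.8g\t%.8g",
                         k, pulse$kt_locations[k, 1],
                         pulse$kt_locations[k, 2], pulse$kt_locations[k, 3],
                         c, Re(pulse$weights[c, k]),
                         Im(pulse$weights[c, k])), con)
    }
  }
  invisible(path)
}
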