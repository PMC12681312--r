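#' Define a 3D sampling grid
#'
#' A `grid3d` ties an array of voxels to world (scanner) coordinates. The
#' world frame is right-handed, axes aligned with the array axes, in mm;
#' voxel indices are 0-based, so voxel `(i,j,k)` sits at
#' `origin + (i*dx, j*dy, k*dz)`.
#'
#' @param shape integer triple `(nx, ny, nz)`, all >= 1.
#' @param voxel_size mm triple, all > 0.
#' @param origin world position (mm) of voxel index `(0,0,0)`. Default centers
#'   the grid on the world origin.
#' @return An object of class `grid3d`.
#' @export
grid3d <- function(shape, voxel_size = c(1, 1, 1), origin = NULL) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(shape) == 3, length(voxel_size) == 3)
  if (any(shape < 1L)) stop("all grid shape entries must be >= 1")
  if (any(voxel_size <= 0)) stop("all voxel sizes must be > 0")
  if (is.null(origin)) origin <- -(shape - 1) / 2 * voxel_size
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3)
  structure(list(shape = shape, voxel_size = voxel_size, origin = origin),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("grid3d: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  origin (mm): %.3g %.3g %.3g\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Field of view of a grid in mm
#' @param grid a [grid3d()].
#' @return mm triple `shape * voxel_size`.
#' @export
grid_fov <- function(grid) grid$shape * grid$voxel_size

#' World coordinate of the rotation center of a grid
#' @param grid a [grid3d()].
#' @return mm triple: the world position of the volume center.
#' @export
grid_center <- function(grid) grid$origin + (grid$shape - 1) / 2 * grid$voxel_size

# n x 3 matrix of world coordinates for every voxel (x fastest, R array order)
grid_coords <- function(grid) {
  s <- grid$shape
  xi <- grid$origin[1] + (0:(s[1] - 1)) * grid$voxel_size[1]
  yi <- grid$origin[2] + (0:(s[2] - 1)) * grid$voxel_size[2]
  zi <- grid$origin[3] + (0:(s[3] - 1)) * grid$voxel_size[3]
  cbind(rep(xi, times = s[2] * s[3]),
        rep(rep(yi, each = s[1]), times = s[3]),
        rep(zi, each = s[1] * s[2]))
}

#' Create a rigid-body transform
#'
#' Six-parameter head pose: translations in mm along world x/y/z and extrinsic
#' rotations in degrees about the world axes through the volume center,
#' applied in x -> y -> z order, then translation. As a point map,
#' `p' = Rz Ry Rx (p - c) + c + t` where `c` is the rotation center.
#'
#' @param tx,ty,tz translations in mm.
#' @param rx,ry,rz rotations in degrees (pitch, yaw, roll about x, y, z).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  p <- as.numeric(c(tx, ty, tz, rx, ry, rz))
  if (any(!is.finite(p))) stop("rigid transform parameters must be finite")
  names(p) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  structure(list(par = p), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: t = (%.4g, %.4g, %.4g) mm, r = (%.4g, %.4g, %.4g) deg\n",
              x$par[1], x$par[2], x$par[3], x$par[4], x$par[5], x$par[6]))
  invisible(x)
}

#' Identity rigid transform
#' @return A [rigid_transform()] with all six parameters zero.
#' @export
rigid_identity <- function() rigid_transform()

# 3x3 rotation matrix for angles in degrees, x -> y -> z extrinsic order
rotation_matrix <- function(rx, ry, rz) {
  a <- rx * pi / 180; b <- ry * pi / 180; c <- rz * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Homogeneous 4x4 matrix of a rigid transform
#'
#' @param t a [rigid_transform()].
#' @param center rotation center in world mm (default the world origin, which
#'   is the volume center for a default-origin [grid3d()]).
#' @return 4x4 homogeneous matrix mapping world points.
#' @export
rigid_matrix <- function(t, center = c(0, 0, 0)) {
  p <- t$par
  R <- rotation_matrix(p[4], p[5], p[6])
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- center - R %*% center + p[1:3]
  M
}

#' Recover the six rigid parameters from a 4x4 matrix
#'
#' Inverts [rigid_matrix()]. The Euler decomposition (x -> y -> z) is
#' degenerate when the y rotation reaches +/-90 degrees; that gimbal case is
#' reported as an error rather than silently resolved.
#'
#' @param M 4x4 homogeneous rigid matrix.
#' @param center rotation center used when the matrix was built.
#' @return A [rigid_transform()].
#' @export
rigid_from_matrix <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  sy <- -R[3, 1]
  if (abs(abs(sy) - 1) < 1e-9) {
    stop("gimbal-degenerate rotation (|ry| = 90 deg): Euler angles undefined")
  }
  ry <- asin(sy)
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  t <- M[1:3, 4] - center + R %*% center
  rigid_transform(t[1], t[2], t[3],
                  rx * 180 / pi, ry * 180 / pi, rz * 180 / pi)
}

#' Compose two rigid transforms
#'
#' `compose_rigid(a, b)` applies `b` first, then `a`, as point maps (the
#' matrix product of the homogeneous forms, decomposed back to 6 parameters).
#'
#' @param a,b [rigid_transform()] objects.
#' @param center shared rotation center in world mm.
#' @return A [rigid_transform()] with `rigid_matrix(out) == rigid_matrix(a) %*% rigid_matrix(b)`.
#' @export
compose_rigid <- function(a, b, center = c(0, 0, 0)) {
  rigid_from_matrix(rigid_matrix(a, center) %*% rigid_matrix(b, center),
                    center = center)
}

#' Invert a rigid transform
#' @param t a [rigid_transform()].
#' @param center rotation center in world mm.
#' @return The inverse transform: `compose_rigid(t, invert_rigid(t))` is identity.
#' @export
invert_rigid <- function(t, center = c(0, 0, 0)) {
  rigid_from_matrix(solve(rigid_matrix(t, center)), center = center)
}

# world-mm points (n x 3) -> fractional 0-based voxel indices (n x 3)
world_to_index <- function(pts, grid) {
  sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$voxel_size, "/")
}

# pull-resampling coordinates for apply_rigid: index coords of T^-1(x) for
# every output voxel of `grid`
pull_coords <- function(grid, t) {
  Minv <- solve(rigid_matrix(t, center = grid_center(grid)))
  pts <- grid_coords(grid)
  mapped <- pts %*% t(Minv[1:3, 1:3])
  mapped <- sweep(mapped, 2, Minv[1:3, 4], "+")
  world_to_index(mapped, grid)
}

resample_real <- function(vol, idx, interp) {
  dim3 <- dim(vol)
  out <- if (interp == "nearest") {
    nearest_gather_cpp(as.numeric(vol), dim3, idx)
  } else {
    trilinear_gather_cpp(as.numeric(vol), dim3, idx)
  }
  array(out, dim = dim3)
}

#' Resample a volume under a rigid transform
#'
#' Pull (inverse-map) resampling: the output at world point `x` is the input
#' sampled at `T^-1(x)`, so the object in the output appears moved by `T`.
#' Voxels mapped outside the field of view are set to 0. Complex volumes are
#' resampled component-wise.
#'
#' @param vol 3D numeric or complex array.
#' @param grid the [grid3d()] the volume lives on.
#' @param t a [rigid_transform()] (rotation about the volume center).
#' @param interp `"trilinear"` (default) or `"nearest"`.
#' @return A 3D array of the same type and shape as `vol`.
#' @export
apply_rigid <- function(vol, grid, t, interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(length(dim(vol)) == 3, all(dim(vol) == grid$shape))
  if (any(!is.finite(Re(vol))) || (is.complex(vol) && any(!is.finite(Im(vol))))) {
    stop("apply_rigid: input volume contains non-finite values")
  }
  idx <- pull_coords(grid, t)
  if (is.complex(vol)) {
    complex(real = resample_real(Re(vol), idx, interp),
            imaginary = resample_real(Im(vol), idx, interp))
  } else {
    resample_real(vol, idx, interp)
  }
}

# adjoint of apply_rigid(., grid, t, "trilinear"): exact transpose of the
# sparse interpolation operator (scatter with identical weights)
apply_rigid_adjoint <- function(vol, grid, t) {
  stopifnot(length(dim(vol)) == 3, all(dim(vol) == grid$shape))
  idx <- pull_coords(grid, t)
  dim3 <- grid$shape
  if (is.complex(vol)) {
    re <- trilinear_scatter_cpp(as.numeric(Re(vol)), dim3, idx)
    im <- trilinear_scatter_cpp(as.numeric(Im(vol)), dim3, idx)
    array(complex(real = re, imaginary = im), dim = dim3)
  } else {
    array(trilinear_scatter_cpp(as.numeric(vol), dim3, idx), dim = dim3)
  }
}

#' Convert a list of rigid transforms to a parameter matrix
#' @param frames list of [rigid_transform()].
#' @return n x 6 matrix with columns `trans_x..rot_z` (mm, degrees).
#' @export
rigid_params <- function(frames) {
  m <- do.call(rbind, lapply(frames, function(f) f$par))
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

#' Write motion parameters as a BIDS-style TSV
#'
#' One row per frame, columns `trans_x, trans_y, trans_z, rot_x, rot_y, rot_z`
#' in mm and degrees.
#'
#' @param frames list of [rigid_transform()] (or an n x 6 matrix).
#' @param path output file path.
#' @export
write_motion_tsv <- function(frames, path) {
  m <- if (is.matrix(frames)) frames else rigid_params(frames)
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read motion parameters from a TSV written by [write_motion_tsv()]
#' @param path TSV file path.
#' @return list of [rigid_transform()].
#' @export
read_motion_tsv <- function(path) {
  d <- read.delim(path, sep = "\t")
  lapply(seq_len(nrow(d)), function(i) {
    rigid_transform(d$trans_x[i], d$trans_y[i], d$trans_z[i],
                    d$rot_x[i], d$rot_y[i], d$rot_z[i])
  })
}
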