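# Resting-state evaluation chain: tSNR, framewise displacement, DVARS,
# outlier flagging, 36P confound expansion, CompCor, Butterworth band-pass
# denoising, ALFF, ReHo (Kendall's W) and functional connectivity.

# voxels x time matrix from a time_series_4d or 4D array
series_matrix <- function(series) {
  a <- if (inherits(series, "time_series_4d")) series$data else series
  stopifnot(length(dim(a)) == 4)
  matrix(a, ncol = dim(a)[4])
}

series_tr <- function(series, tr = NULL) {
  if (!is.null(tr)) return(tr)
  if (inherits(series, "time_series_4d")) return(series$tr_volume)
  stop("supply tr for plain arrays")
}

#' Temporal signal-to-noise ratio map
#'
#' Voxelwise mean of the time series divided by its (sample) standard
#' deviation. Voxels with zero temporal SD get 0 and are flagged.
#'
#' @param series a [time_series_4d()] or 4D array with >= 2 volumes.
#' @param mask optional logical 3D array; outside voxels are 0.
#' @return 3D array of tSNR values, with attribute `flagged` (logical array
#'   of zero-SD voxels inside the mask).
#' @export
tsnr <- function(series, mask = NULL) {
  X <- series_matrix(series)
  stopifnot(ncol(X) >= 2)
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1))
  out <- ifelse(sdv > 0, mu / ifelse(sdv > 0, sdv, 1), 0)
  d <- if (inherits(series, "time_series_4d")) dim(series$data) else dim(series)
  flagged <- sdv == 0
  if (!is.null(mask)) {
    out[!as.vector(mask)] <- 0
    flagged <- flagged & as.vector(mask)
  }
  res <- array(out, dim = d[1:3])
  attr(res, "flagged") <- array(flagged, dim = d[1:3])
  res
}

#' Framewise displacement (Power's formulation)
#'
#' `FD_t = sum |delta trans| + radius * sum |delta rot (rad)|`, the summed
#' absolute frame-to-frame change of the six rigid parameters with rotations
#' converted to arc length on a head-radius sphere. The first frame is 0.
#'
#' @param motion_params `n x 6` matrix (or data frame) of
#'   `trans_x..rot_z` in mm and degrees.
#' @param radius_mm rotation-to-translation radius (default 50 mm).
#' @return numeric vector of length `n`.
#' @export
framewise_displacement <- function(motion_params, radius_mm = 50) {
  m <- as.matrix(motion_params)
  stopifnot(ncol(m) == 6, nrow(m) >= 2)
  d <- abs(diff(m))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    radius_mm * rowSums(d[, 4:6, drop = FALSE] * pi / 180)
  c(0, fd)
}

#' DVARS: RMS frame-to-frame intensity change
#'
#' Root mean square, over masked voxels, of the temporal backward difference
#' of the series. The standardized variant divides by the median of the raw
#' trace (excluding the leading 0), so a typical frame has standardized
#' DVARS 1.
#'
#' @param series a [time_series_4d()] or 4D array.
#' @param mask logical 3D array (non-empty).
#' @param standardize return the median-normalized trace.
#' @return numeric vector (first frame 0).
#' @export
dvars <- function(series, mask, standardize = FALSE) {
  X <- series_matrix(series)
  mv <- as.vector(mask)
  if (!any(mv)) stop("empty mask")
  D <- diff(t(X[mv, , drop = FALSE]))  # (nt-1) x nvox
  raw <- c(0, sqrt(rowMeans(D^2)))
  if (!standardize) return(raw)
  med <- median(raw[-1])
  if (med == 0) return(raw)
  raw / med
}

#' Flag motion-outlier frames
#'
#' A frame is an outlier when FD exceeds `fd_thresh` (mm) or standardized
#' DVARS exceeds `dvars_thresh`.
#'
#' @param fd_trace framewise displacement trace.
#' @param std_dvars_trace standardized DVARS trace of equal length.
#' @param fd_thresh FD threshold in mm (default 0.5).
#' @param dvars_thresh standardized DVARS threshold (default 1.5).
#' @return logical vector.
#' @export
flag_motion_outliers <- function(fd_trace, std_dvars_trace, fd_thresh = 0.5,
                                 dvars_thresh = 1.5) {
  stopifnot(length(fd_trace) == length(std_dvars_trace))
  fd_trace > fd_thresh | std_dvars_trace > dvars_thresh
}

#' 36P (and 24P) confound expansion
#'
#' From 9 base signals (six motion parameters plus global/WM/CSF means):
#' base (9) + backward-difference temporal derivatives (9, first row 0) +
#' squares of all 18, for 36 columns. Six motion-only base columns yield the
#' 24P variant by the same arithmetic.
#'
#' @param base data frame or matrix of base confound columns (9 for 36P, 6
#'   for 24P).
#' @return data frame with stable ordering
#'   `<base>, <base>_derivative1, <base>_power2, <base>_derivative1_power2`.
#' @export
expand_confounds_36p <- function(base) {
  b <- as.matrix(base)
  if (!ncol(b) %in% c(6L, 9L)) {
    stop(sprintf("expected 9 (36P) or 6 (24P) base columns, got %d", ncol(b)))
  }
  nm <- colnames(b)
  if (is.null(nm)) nm <- paste0("c", seq_len(ncol(b)))
  der <- rbind(0, diff(b))
  out <- cbind(b, der, b^2, der^2)
  colnames(out) <- c(nm, paste0(nm, "_derivative1"), paste0(nm, "_power2"),
                     paste0(nm, "_derivative1_power2"))
  as.data.frame(out)
}

# discrete-cosine high-pass basis (SPM convention): columns with period
# longer than cutoff_s are removed by regression
dct_highpass <- function(X_t, tr, cutoff_s = 128) {
  n <- nrow(X_t)
  K <- floor(2 * n * tr / cutoff_s)
  if (K < 1) return(X_t)
  t0 <- seq_len(n) - 0.5
  B <- cbind(1, sapply(seq_len(K), function(k) cos(pi * k * t0 / n)))
  X_t - B %*% qr.solve(B, X_t)
}

#' CompCor nuisance components
#'
#' Discrete-cosine high-pass (default 128 s cutoff), then principal
#' components of the voxel-normalized series within the noise mask. The
#' temporal variant replaces the mask with the top `top_voxel_fraction`
#' highest-temporal-SD voxels inside it. The minimal number of components
#' whose cumulative singular-value energy reaches `variance_fraction` is
#' retained.
#'
#' @param series a [time_series_4d()] or 4D array.
#' @param mask logical 3D array (anatomical noise mask, or search region for
#'   the temporal variant).
#' @param variant `"temporal"` or `"anatomical"`.
#' @param variance_fraction cumulative explained-variance cutoff (default 0.5).
#' @param top_voxel_fraction fraction of most-variable voxels for the
#'   temporal variant (default 0.02).
#' @param highpass_cutoff_s DCT high-pass cutoff in seconds.
#' @param tr volume TR (taken from the series when available).
#' @return matrix `n_volumes x k` of component time series, with attributes
#'   `explained` (cumulative variance fractions) and `n_voxels`.
#' @export
compcor <- function(series, mask, variant = c("temporal", "anatomical"),
                    variance_fraction = 0.5, top_voxel_fraction = 0.02,
                    highpass_cutoff_s = 128, tr = NULL) {
  variant <- match.arg(variant)
  tr <- series_tr(series, tr)
  X <- series_matrix(series)
  mv <- which(as.vector(mask))
  if (!length(mv)) stop("empty mask")
  Xt <- dct_highpass(t(X[mv, , drop = FALSE]), tr, highpass_cutoff_s)
  if (variant == "temporal") {
    sds <- apply(Xt, 2, sd)
    n_top <- ceiling(top_voxel_fraction * length(mv))
    keep <- order(sds, decreasing = TRUE)[seq_len(n_top)]
    Xt <- Xt[, keep, drop = FALSE]
  }
  sds <- apply(Xt, 2, sd)
  nz <- sds > 0
  if (!any(nz)) stop("no variable voxels in CompCor mask")
  Z <- sweep(sweep(Xt[, nz, drop = FALSE], 2, colMeans(Xt[, nz, drop = FALSE])),
             2, sds[nz], "/")
  sv <- svd(Z)
  energy <- cumsum(sv$d^2) / sum(sv$d^2)
  k <- which(energy >= variance_fraction)[1]
  comp <- sv$u[, seq_len(k), drop = FALSE]
  attr(comp, "explained") <- energy[seq_len(k)]
  attr(comp, "n_voxels") <- ncol(Z)
  comp
}

#' Zero-phase Butterworth band-pass filter
#'
#' Second-order (by default) Butterworth band-pass applied forward-backward
#' (`signal::filtfilt`, zero phase) along time. Apply the identical filter
#' to the confound columns before nuisance regression.
#'
#' @param x a [time_series_4d()], 4D array, matrix (time in rows), or vector.
#' @param low,high band edges in Hz (default 0.01-0.08).
#' @param fs sampling frequency `1/TR` in Hz (taken from the series when
#'   available).
#' @param order filter order (default 2).
#' @return filtered object of the same type.
#' @export
bandpass_butterworth <- function(x, low = 0.01, high = 0.08, fs = NULL,
                                 order = 2) {
  if (inherits(x, "time_series_4d") && is.null(fs)) fs <- 1 / x$tr_volume
  if (is.null(fs)) stop("supply fs for plain inputs")
  if (high >= fs / 2) stop(sprintf("band edge %g Hz >= Nyquist %g Hz",
                                   high, fs / 2))
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  # demean first: forward-backward filtering of a large DC offset otherwise
  # leaks edge transients into the passband
  filt1 <- function(v) signal::filtfilt(bf, v - mean(v))
  if (inherits(x, "time_series_4d")) {
    X <- series_matrix(x)
    Xf <- t(apply(X, 1, filt1))
    return(time_series_4d(array(Xf, dim = dim(x$data)), x$grid, x$tr_volume))
  }
  if (is.array(x) && length(dim(x)) == 4) {
    X <- matrix(x, ncol = dim(x)[4])
    return(array(t(apply(X, 1, filt1)), dim = dim(x)))
  }
  if (is.matrix(x) || is.data.frame(x)) {
    xm <- as.matrix(x)
    out <- apply(xm, 2, filt1)
    colnames(out) <- colnames(xm)
    return(if (is.data.frame(x)) as.data.frame(out) else out)
  }
  filt1(x)
}

#' Regress nuisance confounds out of a series
#'
#' Per-voxel ordinary least squares with an intercept; returns the
#' residuals, which are orthogonal to every regressor. Rank-deficient
#' designs are handled by the pseudo-inverse and flagged with a warning.
#'
#' @param series a [time_series_4d()], 4D array or voxels-x-time matrix.
#' @param confounds matrix or data frame, `n_volumes` rows.
#' @return residual object of the same type as the input.
#' @export
regress_confounds <- function(series, confounds) {
  C <- as.matrix(confounds)
  is_ts <- inherits(series, "time_series_4d")
  X <- if (is_ts || (is.array(series) && length(dim(series)) == 4)) {
    series_matrix(series)
  } else as.matrix(series)  # voxels x time
  nt <- ncol(X)
  stopifnot(nrow(C) == nt)
  if (nt <= ncol(C) + 1) stop("need n_volumes > n_regressors")
  D <- cbind(1, C)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning(sprintf("rank-deficient confound design (rank %d of %d)",
                    qrD$rank, ncol(D)))
  }
  # residual maker applied to time dimension
  fitted <- t(qr.fitted(qrD, t(X)))
  R <- X - fitted
  if (is_ts) {
    return(time_series_4d(array(R, dim = dim(series$data)), series$grid,
                          series$tr_volume))
  }
  if (is.array(series) && length(dim(series)) == 4) {
    return(array(R, dim = dim(series)))
  }
  R
}

#' Amplitude of low-frequency fluctuation (ALFF)
#'
#' Per voxel: mean-center and SD-normalize the series, FFT, form the
#' single-sided power spectrum `|X_k|^2 / n`, average the square root of the
#' power over the in-band bins (band edges inclusive), and multiply by the
#' voxel's temporal SD to restore scale. Zero-SD voxels get 0 and are
#' flagged.
#'
#' @param series a denoised [time_series_4d()] or 4D array.
#' @param band frequency band in Hz (default 0.01-0.08).
#' @param fs sampling frequency in Hz (from the series when available).
#' @param mask optional logical array.
#' @return 3D ALFF map with attribute `flagged`.
#' @export
alff <- function(series, band = c(0.01, 0.08), fs = NULL, mask = NULL) {
  if (inherits(series, "time_series_4d") && is.null(fs)) {
    fs <- 1 / series$tr_volume
  }
  X <- series_matrix(series)
  n <- ncol(X)
  freqs <- (0:(n %/% 2)) * fs / n
  inband <- which(freqs >= band[1] & freqs <= band[2])
  if (length(inband) < 2) stop("fewer than 2 frequency bins in band")
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (n - 1))
  ok <- sdv > 0
  Z <- (X - mu) / ifelse(ok, sdv, 1)
  # FFT across time for all voxels at once
  P <- Mod(t(mvfft(t(Z))))^2 / n
  vals <- rowMeans(sqrt(P[, inband, drop = FALSE])) * sdv
  vals[!ok] <- 0
  if (!is.null(mask)) vals[!as.vector(mask)] <- 0
  d <- if (inherits(series, "time_series_4d")) dim(series$data) else dim(series)
  res <- array(vals, dim = d[1:3])
  attr(res, "flagged") <- array(!ok, dim = d[1:3])
  res
}

#' Kendall's coefficient of concordance (W)
#'
#' Concordance of `m` time series over `n` time points: each series is
#' ranked over time (average ranks for ties), `R_t` is the rank sum at time
#' `t`, and
#' `W = 12 sum_t (R_t - m(n+1)/2)^2 / (m^2 (n^3 - n) - m * sum T)` with the
#' standard tie correction `T = sum (t_j^3 - t_j)` over tie groups.
#'
#' @param X matrix `n_time x m_series`.
#' @return W in `[0, 1]`.
#' @export
kendall_w <- function(X) {
  n <- nrow(X)
  m <- ncol(X)
  stopifnot(n >= 2, m >= 2)
  ranks <- apply(X, 2, rank)
  Rt <- rowSums(ranks)
  Tsum <- sum(apply(ranks, 2, function(r) {
    tg <- table(r)
    sum(tg^3 - tg)
  }))
  denom <- m^2 * (n^3 - n) - m * Tsum
  if (denom <= 0) return(0)
  12 * sum((Rt - m * (n + 1) / 2)^2) / denom
}

neighborhood_offsets <- function(neighborhood) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  switch(as.character(neighborhood),
         "27" = g,
         "19" = g[abs(g$dx) + abs(g$dy) + abs(g$dz) <= 2, ],
         "7" = g[abs(g$dx) + abs(g$dy) + abs(g$dz) <= 1, ],
         stop("neighborhood must be 27, 19 or 7"))
}

#' Regional homogeneity (ReHo) by Kendall's W
#'
#' For every in-mask voxel, Kendall's coefficient of concordance of the time
#' series in its voxel neighborhood (27, 19 or 7 voxels, truncated at mask
#' edges to the members actually present). An adjacency list generalizes the
#' neighborhood to arbitrary vertex graphs.
#'
#' @param series a [time_series_4d()] or 4D array with >= 3 volumes.
#' @param mask logical 3D array.
#' @param neighborhood 27 (default), 19, 7, or a list mapping each in-mask
#'   voxel (linear index) to a vector of neighbor linear indices.
#' @return 3D ReHo map (W in `[0,1]`, 0 outside mask).
#' @export
reho_kcc <- function(series, mask, neighborhood = 27) {
  X <- series_matrix(series)
  stopifnot(ncol(X) >= 3)
  d <- if (inherits(series, "time_series_4d")) dim(series$data) else dim(series)
  dims <- d[1:3]
  out <- array(0, dim = dims)
  mv <- which(mask)
  if (is.list(neighborhood)) {
    for (v in mv) {
      nb <- unique(c(v, neighborhood[[as.character(v)]]))
      nb <- nb[nb %in% mv]
      if (length(nb) >= 2) out[v] <- kendall_w(t(X[nb, , drop = FALSE]))
    }
    return(out)
  }
  off <- neighborhood_offsets(neighborhood)
  coord <- arrayInd(mv, dims)
  mask_v <- as.vector(mask)
  for (i in seq_along(mv)) {
    nx <- coord[i, 1] + off$dx
    ny <- coord[i, 2] + off$dy
    nz <- coord[i, 3] + off$dz
    ok <- nx >= 1 & nx <= dims[1] & ny >= 1 & ny <= dims[2] &
      nz >= 1 & nz <= dims[3]
    lin <- nx[ok] + (ny[ok] - 1) * dims[1] + (nz[ok] - 1) * dims[1] * dims[2]
    lin <- lin[mask_v[lin]]
    if (length(lin) >= 2) {
      out[mv[i]] <- kendall_w(t(X[lin, , drop = FALSE]))
    }
  }
  out
}

#' Parcelwise functional connectivity matrix
#'
#' Pearson correlation of parcel-mean time series. Constant parcels produce
#' `NA` entries and a warning.
#'
#' @param series a denoised [time_series_4d()] or 4D array.
#' @param parcel_labels integer 3D array (0 = background).
#' @return symmetric correlation matrix with unit diagonal, one row/column
#'   per parcel label.
#' @export
fc_matrix <- function(series, parcel_labels) {
  X <- series_matrix(series)
  lab <- as.vector(parcel_labels)
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) < 2) stop("need >= 2 parcels")
  M <- sapply(ids, function(p) colMeans(X[lab == p, , drop = FALSE]))
  sds <- apply(M, 2, sd)
  if (any(sds == 0)) warning("constant parcel mean series: NA entries")
  fc <- suppressWarnings(cor(M))
  diag(fc) <- 1
  dimnames(fc) <- list(ids, ids)
  fc
}

#' Mean absolute difference between two connectivity matrices
#' @param a,b square matrices of equal size.
#' @return mean of `|a - b|` over off-diagonal entries.
#' @export
compare_fc <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  od <- row(a) != col(a)
  mean(abs(a - b)[od])
}
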