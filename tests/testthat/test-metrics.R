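test_that("tSNR equals the brute-force per-voxel computation", {
  set.seed(41)
  d <- c(4, 4, 2, 20)
  arr <- array(rnorm(prod(d), mean = 10, sd = 2), d)
  s <- time_series_4d(arr, grid3d(d[1:3]), 2)
  out <- tsnr(s)
  for (idx in list(c(1, 1, 1), c(3, 2, 2))) {
    v <- arr[idx[1], idx[2], idx[3], ]
    expect_equal(out[idx[1], idx[2], idx[3]], mean(v) / sd(v),
                 tolerance = 1e-12)
  }
  # constant voxel: flagged, value 0
  arr2 <- arr
  arr2[2, 2, 1, ] <- 7
  out2 <- tsnr(time_series_4d(arr2, grid3d(d[1:3]), 2))
  expect_equal(out2[2, 2, 1], 0)
  expect_true(attr(out2, "flagged")[2, 2, 1])
  # temporal mean 10 and SD 2 give exactly 5
  v <- 10 + 2 * as.numeric(scale(rnorm(20)))
  arr3 <- array(v, c(1, 1, 1, 20))
  expect_equal(as.numeric(tsnr(time_series_4d(arr3, grid3d(c(1, 1, 1)), 1))),
               5, tolerance = 1e-12)
})

test_that("framewise displacement follows Power's formulation", {
  m <- matrix(0, 5, 6)
  expect_equal(framewise_displacement(m), rep(0, 5))
  m2 <- m
  m2[3:5, 1] <- 0.3  # one-frame x-step of 0.3 mm
  fd <- framewise_displacement(m2)
  expect_equal(fd, c(0, 0, 0.3, 0, 0))
  m3 <- m
  m3[2:5, 4] <- 1  # 1 degree rotation at 50 mm radius
  expect_equal(framewise_displacement(m3)[2], 50 * pi / 180,
               tolerance = 1e-12)
})

test_that("DVARS measures RMS frame differences with median standardization", {
  d <- c(3, 3, 1, 10)
  mask <- array(TRUE, d[1:3])
  const <- time_series_4d(array(5, d), grid3d(d[1:3]), 1)
  expect_equal(dvars(const, mask), rep(0, 10))
  # uniform step of amplitude a at frame t: raw DVARS_t = a
  arr <- array(1, d)
  arr[, , , 6:10] <- 1.7
  expect_equal(dvars(time_series_4d(arr, grid3d(d[1:3]), 1), mask),
               c(rep(0, 5), 0.7, rep(0, 4)), tolerance = 1e-12)
  # standardized trace has median 1 by construction
  set.seed(5)
  noise <- time_series_4d(array(rnorm(prod(d)), d), grid3d(d[1:3]), 1)
  sdv <- dvars(noise, mask, standardize = TRUE)
  expect_equal(median(sdv[-1]), 1)
  expect_error(dvars(noise, array(FALSE, d[1:3])), "empty")
})

test_that("motion outliers are the OR of the two threshold exceedances", {
  expect_true(flag_motion_outliers(0.6, 1.0))
  expect_true(flag_motion_outliers(0.4, 1.6))
  expect_false(flag_motion_outliers(0.4, 1.0))
  expect_equal(flag_motion_outliers(c(0.6, 0.4, 0.4), c(1.0, 1.6, 1.0)),
               c(TRUE, TRUE, FALSE))
})

test_that("36P expansion has 36 stably ordered columns", {
  set.seed(6)
  base <- matrix(rnorm(20 * 9), 20, 9)
  colnames(base) <- c(paste0("rp", 1:6), "global_signal", "wm", "csf")
  out <- expand_confounds_36p(base)
  expect_equal(ncol(out), 36)
  expect_equal(colnames(out)[1:9], colnames(base))
  # derivative columns: backward difference with first row 0
  expect_equal(out$rp1_derivative1, c(0, diff(base[, 1])))
  expect_equal(out$wm_power2, base[, 8]^2)
  # derivative of a constant column is all zeros
  base2 <- base
  base2[, 3] <- 2
  expect_true(all(expand_confounds_36p(base2)$rp3_derivative1 == 0))
  # 6 motion columns give the 24P variant
  expect_equal(ncol(expand_confounds_36p(base[, 1:6])), 24)
  expect_error(expand_confounds_36p(base[, 1:5]), "base columns")
})

test_that("CompCor retains the minimal components reaching the variance cut", {
  d <- c(6, 6, 2, 30)
  mask <- array(TRUE, d[1:3])
  # rank-1 data in the mask: exactly one component
  set.seed(7)
  u <- rnorm(30)
  arr <- array(outer(rnorm(prod(d[1:3])), u), d)
  cc1 <- compcor(time_series_4d(arr, grid3d(d[1:3]), 2), mask,
                 variant = "anatomical", highpass_cutoff_s = 1e9)
  expect_equal(ncol(cc1), 1)
  # top-voxel count for the temporal variant
  arr2 <- array(rnorm(prod(d)), d)
  cc2 <- compcor(time_series_4d(arr2, grid3d(d[1:3]), 2), mask,
                 variant = "temporal", top_voxel_fraction = 0.02)
  expect_equal(attr(cc2, "n_voxels"), ceiling(0.02 * sum(mask)))
  # SVD oracle: cumulative energy crosses 0.5 exactly at k components
  cc3 <- compcor(time_series_4d(arr2, grid3d(d[1:3]), 2), mask,
                 variant = "anatomical", highpass_cutoff_s = 1e9)
  k <- ncol(cc3)
  expl <- attr(cc3, "explained")
  expect_gte(expl[k], 0.5)
  if (k > 1) expect_lt(expl[k - 1], 0.5)
})

test_that("Butterworth band-pass matches its analytic frequency response", {
  fs <- 1 / 2.34
  n <- 400
  t <- (0:(n - 1)) / fs
  # DC removed
  dc <- bandpass_butterworth(rep(3, n) + rnorm(n, sd = 1e-3), fs = fs)
  expect_lt(abs(mean(dc)), 1e-6 + 1e-3)
  # in-band 0.04 Hz sinusoid passes with gain > 0.9
  x04 <- sin(2 * pi * 0.04 * t)
  y04 <- bandpass_butterworth(x04, fs = fs)
  mid <- 100:300
  gain04 <- sqrt(mean(y04[mid]^2) / mean(x04[mid]^2))
  expect_gt(gain04, 0.9)
  # out-of-band 0.2 Hz sinusoid is suppressed below 0.1
  x2 <- sin(2 * pi * 0.2 * t)
  y2 <- bandpass_butterworth(x2, fs = fs)
  gain2 <- sqrt(mean(y2[mid]^2) / mean(x2[mid]^2))
  expect_lt(gain2, 0.1)
  # analytic |H(f)|^2 oracle for the forward-backward second-order filter
  bf <- signal::butter(2, c(0.01, 0.08) / (fs / 2), "pass")
  H <- function(f) {
    z <- exp(-2i * pi * f / fs)
    h <- sum(bf$b * z^(0:(length(bf$b) - 1))) /
      sum(bf$a * z^(0:(length(bf$a) - 1)))
    Mod(h)^2  # filtfilt applies the filter twice
  }
  expect_equal(gain04, H(0.04), tolerance = 0.02)
  expect_lt(abs(gain2 - H(0.2)), 0.02)
  expect_error(bandpass_butterworth(x2, high = 0.3, fs = fs), "Nyquist")
})

test_that("confound regression leaves residuals orthogonal to regressors", {
  set.seed(9)
  nt <- 30
  X <- matrix(rnorm(5 * nt), 5, nt)
  # regressing a series on itself leaves zero residual
  self <- regress_confounds(X[1, , drop = FALSE], cbind(X[1, ]))
  expect_lt(max(abs(self)), 1e-10)
  conf <- matrix(rnorm(nt * 3), nt, 3)
  R <- regress_confounds(X, conf)
  ip <- R %*% conf
  expect_lt(max(abs(ip)) / max(abs(X)), 1e-8)
  # hat-matrix oracle on a small problem
  D <- cbind(1, conf)
  P <- diag(nt) - D %*% solve(crossprod(D)) %*% t(D)
  expect_equal(R, X %*% P, tolerance = 1e-10)
  expect_warning(regress_confounds(X, cbind(conf, conf[, 1])), "rank")
  expect_error(regress_confounds(X[, 1:3], matrix(rnorm(9), 3, 3)), "n_volumes")
})

test_that("ALFF is band-selective and linear in fluctuation amplitude", {
  fs <- 1 / 2.34
  n <- 128
  t <- (0:(n - 1)) / fs
  d <- c(3, 1, 1, n)
  g <- grid3d(d[1:3])
  arr <- array(0, d)
  arr[1, 1, 1, ] <- 10 + sin(2 * pi * 0.04 * t)       # in-band
  arr[2, 1, 1, ] <- 10 + 2 * sin(2 * pi * 0.04 * t)   # doubled amplitude
  arr[3, 1, 1, ] <- 10 + sin(2 * pi * 0.15 * t)       # out-of-band
  s <- time_series_4d(arr, g, 2.34)
  a <- alff(s)
  expect_equal(a[2, 1, 1] / a[1, 1, 1], 2, tolerance = 1e-6)
  expect_gt(a[1, 1, 1], a[3, 1, 1])
  # constant series: 0 and flagged
  arr[1, 1, 1, ] <- 5
  a2 <- alff(time_series_4d(arr, g, 2.34))
  expect_equal(a2[1, 1, 1], 0)
  expect_true(attr(a2, "flagged")[1, 1, 1])
})

test_that("Kendall's W matches the closed forms and a brute-force oracle", {
  set.seed(10)
  x <- rnorm(12)
  # identical copies of a non-constant series: perfect concordance
  expect_equal(kendall_w(cbind(x, x, x)), 1)
  # two fully discordant rankings: W = 0
  expect_equal(kendall_w(cbind(1:8, 8:1)), 0)
  # 3 series x 4 timepoints toy vs independent brute-force evaluation
  X <- matrix(c(1, 2, 3, 4,
                2, 1, 4, 3,
                1, 3, 2, 4), 4, 3)
  brute <- function(X) {
    n <- nrow(X); m <- ncol(X)
    rk <- apply(X, 2, rank)
    Rt <- rowSums(rk)
    Tj <- 0
    for (j in 1:m) {
      for (tt in unique(rk[, j])) {
        cnt <- sum(rk[, j] == tt)
        Tj <- Tj + cnt^3 - cnt
      }
    }
    S <- sum((Rt - m * (n + 1) / 2)^2)
    12 * S / (m^2 * (n^3 - n) - m * Tj)
  }
  expect_equal(kendall_w(X), brute(X), tolerance = 1e-12)
  # ties included
  Xt <- matrix(c(1, 1, 2, 3, 2, 2, 1, 3, 3, 1, 2, 2), 4, 3)
  expect_equal(kendall_w(Xt), brute(Xt), tolerance = 1e-12)
})

test_that("KCC stays in [0, 1] over many random inputs", {
  set.seed(12)
  for (i in 1:400) {
    n <- sample(3:10, 1)
    m <- sample(2:8, 1)
    X <- matrix(sample(1:4, n * m, replace = TRUE) + rnorm(n * m, sd = 0.1),
                n, m)
    w <- kendall_w(X)
    expect_gte(w, 0)
    expect_lte(w, 1)
  }
})

test_that("ReHo is high inside coherent parcels and respects neighborhoods", {
  ph <- small_phantom()
  b <- simulate_bold_series(ph, 40, 2, amplitude = 0.1, noise_sd = 0.01,
                            seed = 13)
  rh <- reho_kcc(b$series, ph$mask)
  expect_true(all(rh >= 0 & rh <= 1))
  expect_gt(mean(rh[b$parcel_labels > 0]),
            mean(rh[ph$mask & b$parcel_labels == 0]))
  # neighborhood sizes
  expect_equal(nrow(epinav:::neighborhood_offsets(27)), 27)
  expect_equal(nrow(epinav:::neighborhood_offsets(19)), 19)
  expect_equal(nrow(epinav:::neighborhood_offsets(7)), 7)
  # adjacency-list input reproduces the voxel neighborhood on a toy case
  d <- c(2, 1, 1, 10)
  set.seed(14)
  arr <- array(rnorm(prod(d)), d)
  s2 <- time_series_4d(arr, grid3d(d[1:3]), 1)
  m2 <- array(TRUE, d[1:3])
  adj <- list("1" = 2L, "2" = 1L)
  ra <- reho_kcc(s2, m2, adj)
  expect_equal(ra[1, 1, 1], kendall_w(t(matrix(arr, 2, 10))),
               tolerance = 1e-12)
})

test_that("scaling invariances of ALFF and ReHo hold", {
  ph <- small_phantom()
  b <- simulate_bold_series(ph, 24, 2, amplitude = 0.1, noise_sd = 0.01,
                            seed = 15)
  scaled <- time_series_4d(3 * b$series$data, b$series$grid,
                           b$series$tr_volume)
  rh1 <- reho_kcc(b$series, ph$mask)
  rh3 <- reho_kcc(scaled, ph$mask)
  expect_equal(rh1, rh3, tolerance = 1e-12)
  a1 <- alff(b$series, fs = 1 / 2)
  a3 <- alff(scaled, fs = 1 / 2)
  expect_equal(3 * a1[ph$mask], a3[ph$mask], tolerance = 1e-9)
})

test_that("FC matrices are symmetric with unit diagonal and match cor()", {
  ph <- small_phantom()
  b <- simulate_bold_series(ph, 30, 2, amplitude = 0.1, noise_sd = 0.005,
                            seed = 16)
  fc <- fc_matrix(b$series, b$parcel_labels)
  expect_equal(fc, t(fc))
  expect_equal(unname(diag(fc)), rep(1, ncol(fc)))
  # parcels with identical series: off-diagonal 1
  d <- c(4, 1, 1, 12)
  arr <- array(rep(sin(1:12), each = 4), d)
  lab <- array(c(1L, 1L, 2L, 2L), d[1:3])
  fc2 <- fc_matrix(time_series_4d(arr, grid3d(d[1:3]), 1), lab)
  expect_equal(fc2[1, 2], 1)
  # brute-force 3-parcel oracle
  X <- epinav:::series_matrix(b$series)
  ids <- sort(unique(as.vector(b$parcel_labels[b$parcel_labels > 0])))
  M <- sapply(ids[1:3], function(p) {
    colMeans(X[as.vector(b$parcel_labels) == p, , drop = FALSE])
  })
  expect_equal(unname(fc[1:3, 1:3]), unname(cor(M)), tolerance = 1e-12)
  expect_equal(compare_fc(fc2, fc2), 0)
  expect_equal(compare_fc(matrix(c(1, 0.5, 0.5, 1), 2),
                          matrix(c(1, 0.1, 0.1, 1), 2)), 0.4)
})
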