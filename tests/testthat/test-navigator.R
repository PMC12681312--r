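test_that("GRAPPA calibration recovers exactly representable data", {
  set.seed(21)
  # coil k-spaces that are integer ky-shifts of one object k-space: missing
  # lines are exact linear combinations of acquired neighbors at Ry = 2
  ksp <- harmonic_kspace(c(12, 16, 10), list(c(0, 0), c(1, 0)))
  acs <- ksp[, 3:14, 2:9, , drop = FALSE]
  kern <- grappa_calibrate(acs, 2, 1, caipi_shift = 0, n_src_yz = 4,
                           tikhonov = 1e-12)
  expect_lt(max(vapply(kern$kernels, function(k) k$residual, 0)), 1e-8)
  # doubling the ACS amplitude leaves the weights unchanged
  kern2 <- grappa_calibrate(2 * acs, 2, 1, caipi_shift = 0, n_src_yz = 4,
                            tikhonov = 1e-12)
  expect_equal(kern$kernels[[1]]$weights, kern2$kernels[[1]]$weights,
               tolerance = 1e-8)
  # no acceleration: no missing-offset classes to fit
  kern0 <- grappa_calibrate(acs, 1, 1, caipi_shift = 0)
  expect_equal(length(kern0$kernels), 0)
  expect_error(grappa_calibrate(ksp[, 1:4, 1:3, , drop = FALSE], 2, 1,
                                caipi_shift = 0), "ACS too small")
})

test_that("GRAPPA reconstruction is exact on representable data and
           preserves acquired samples", {
  set.seed(22)
  ksp <- harmonic_kspace(c(12, 16, 10), list(c(0, 0), c(1, 0)))
  acs <- ksp[, 3:14, 2:9, , drop = FALSE]
  kern <- grappa_calibrate(acs, 2, 1, caipi_shift = 0, tikhonov = 1e-12)
  under <- ksp
  missing <- seq(2, 16, by = 2)  # 0-based odd ky are the missing class
  under[, missing, , ] <- 0i
  rec <- grappa_reconstruct(under, kern, combine = "none")
  # acquired samples preserved bit-exactly
  acq <- seq(1, 16, by = 2)
  expect_identical(rec$kspace[, acq, , ], ksp[, acq, , ])
  # synthesized interior lines match the fully sampled truth
  ref_img <- apply(ksp, 4, epinav:::kspace_inv)
  rec_img <- apply(rec$kspace, 4, epinav:::kspace_inv)
  err <- sqrt(sum(Mod(rec_img - ref_img)^2) / sum(Mod(ref_img)^2))
  expect_lt(err, 1e-6)
})

test_that("fully sampled navigator input is just the inverse FFT", {
  ns <- nav_session()
  full <- array(0i, dim = c(ns$grid$shape, 16))
  for (c in 1:16) {
    full[, , , c] <- epinav:::kspace_fwd((ns$phantom$image + 0i) *
                                           ns$coils$maps[, , , c])
  }
  kern0 <- grappa_calibrate(ns$sim$acs, 1, 1, caipi_shift = 0)
  rec <- grappa_reconstruct(full, kern0, combine = "none")
  for (c in c(1, 9)) {
    expect_equal(rec$channels[, , , c],
                 epinav:::kspace_inv(full[, , , c]), tolerance = 1e-12)
  }
})

test_that("motion estimation recovers known poses", {
  ns <- nav_session()
  ref <- Mod(epinav:::combine_channels(
    grappa_reconstruct(ns$sim$frames[[1]], ns$kernel, "none")$channels,
    ns$coils))
  # frame = reference: identity within tolerance
  t0 <- estimate_motion(ref, ref, ns$grid)
  expect_lt(max(abs(t0$par)), 1e-6)
  # known 2 mm x-translation, recovered within 0.1 mm
  moved <- apply_rigid(ref, ns$grid, rigid_transform(tx = 2))
  t1 <- estimate_motion(moved, ref, ns$grid)
  expect_lt(abs(t1$par["tx"] - 2), 0.1)
  expect_lt(max(abs(t1$par[-1])), 0.1)
  # known 3 degree rz rotation, recovered within 0.1 degree
  rot <- apply_rigid(ref, ns$grid, rigid_transform(rz = 3))
  t2 <- estimate_motion(rot, ref, ns$grid)
  expect_lt(abs(t2$par["rz"] - 3), 0.1)
})

test_that("field estimation is exact on noiseless linear phase", {
  ns <- nav_session()
  ref <- (ns$phantom$image + 0.01) + 0i
  mask <- ns$phantom$mask
  nav_te <- 0.008
  # identical frames: all-zero field state
  z <- estimate_field_change(ref, ref, ns$grid, mask, nav_te)
  expect_lt(max(abs(c(z$g0, z$gx, z$gy, z$gz))), 1e-12)
  # injected g0 = 3 Hz, gx = 0.05 Hz/mm (wrap-free): exact recovery
  pts <- epinav:::grid_coords(ns$grid)
  phase <- 2 * pi * (3 + 0.05 * pts[, 1]) * nav_te
  frame <- ref * array(exp(1i * phase), ns$grid$shape)
  est <- suppressWarnings(
    estimate_field_change(frame, ref, ns$grid, mask, nav_te))
  expect_equal(est$g0, 3, tolerance = 1e-6)
  expect_equal(est$gx, 0.05, tolerance = 1e-8)
  expect_lt(abs(est$gy), 1e-8)
  expect_lt(abs(est$gz), 1e-8)
})

test_that("field estimates are unbiased under complex noise", {
  ns <- nav_session()
  ref <- (ns$phantom$image + 0.01) + 0i
  mask <- ns$phantom$mask
  nav_te <- 0.008
  pts <- epinav:::grid_coords(ns$grid)
  phase <- 2 * pi * (1.5 + 0.02 * pts[, 2]) * nav_te
  frame0 <- ref * array(exp(1i * phase), ns$grid$shape)
  n <- prod(ns$grid$shape)
  g0s <- gys <- numeric(40)
  for (s in seq_len(40)) {
    set.seed(s)
    noise <- array(complex(real = rnorm(n, sd = 0.02),
                           imaginary = rnorm(n, sd = 0.02)), ns$grid$shape)
    est <- estimate_field_change(frame0 + noise, ref, ns$grid, mask, nav_te)
    g0s[s] <- est$g0
    gys[s] <- est$gy
  }
  # Monte-Carlo CI around the truth contains the mean estimate
  expect_lt(abs(mean(g0s) - 1.5), 3 * sd(g0s) / sqrt(40) + 1e-3)
  expect_lt(abs(mean(gys) - 0.02), 3 * sd(gys) / sqrt(40) + 1e-5)
})

test_that("wrap-prone phase differences raise a warning", {
  ns <- nav_session()
  ref <- (ns$phantom$image + 0.01) + 0i
  frame <- ref * exp(1i * 3)  # near-pi global phase
  expect_warning(
    estimate_field_change(frame, ref, ns$grid, ns$phantom$mask, 0.008),
    "wrap")
})

test_that("end-to-end navigator recovery meets the residual scale", {
  ns <- nav_session()
  est <- navigator_pipeline(ns$sim$frames, ns$kernel, ns$grid,
                            nav_te = ns$sched$nav_te, combine = ns$coils,
                            frame_interval = ns$sched$frame_interval)
  err <- rigid_params(est$motion$frames) - rigid_params(ns$motion$frames)
  rms_t <- sqrt(mean(err[, 1:3]^2))
  rms_r <- sqrt(mean(err[, 4:6]^2))
  expect_lte(rms_t, 0.2)
  expect_lte(rms_r, 0.15)
  # no injected field: estimated field states stay near zero
  expect_lt(max(abs(est$field$g0)), 0.5)
})
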