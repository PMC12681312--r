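test_that("forward model reduces to plain FFT sampling in the trivial case", {
  g <- small_grid()
  ph <- small_phantom()
  flat <- make_coil_sensitivities(g, 1, flat = TRUE)
  full <- build_caipi_pattern(g$shape, 1, 1, caipi_shift = 0)
  kd <- forward_model(ph$image, flat, NULL, full, g)
  K <- epinav:::kspace_fwd(ph$image + 0i)
  expect_equal(kspace_to_array(kd)[, , , 1], K, tolerance = 1e-12)
})

test_that("image translation obeys the Fourier shift theorem per sample", {
  g <- small_grid()
  ph <- small_phantom()
  flat <- make_coil_sensitivities(g, 1, flat = TRUE)
  full <- build_caipi_pattern(g$shape, 1, 1, caipi_shift = 0)
  # translation by one voxel along x: k-samples pick up exp(-2pi i kx / N)
  shift_state <- encoding_state(rep(list(rigid_transform(tx = 8)),
                                    length(unique(full$lines$shot))))
  kd0 <- forward_model(ph$image, flat, NULL, full, g)
  kd1 <- forward_model(ph$image, flat, shift_state, full, g)
  kx <- epinav:::k_values(16)
  expected_phase <- exp(-2i * pi * kx * 1 / 16)
  ratio <- kd1$samples[, 120, 1] / kd0$samples[, 120, 1]
  expect_equal(ratio, expected_phase, tolerance = 1e-9)
})

test_that("the coded adjoint matches the forward operator (dot-product test)", {
  g <- small_grid()
  coils <- small_coils(4)
  pat <- build_caipi_pattern(g$shape, 2, 2, caipi_shift = 1,
                             n_interleaves = 2, echo_spacing = 5e-4,
                             te = 0.01)
  n_shots <- length(unique(pat$lines$shot))
  set.seed(31)
  for (rep in 1:3) {
    # random encoding states drawn as in a random trace
    tfms <- replicate(n_shots, random_rigid(2, 5), simplify = FALSE)
    flds <- data.frame(g0 = runif(n_shots, -3, 3),
                       gx = runif(n_shots, -0.02, 0.02),
                       gy = runif(n_shots, -0.02, 0.02),
                       gz = runif(n_shots, -0.02, 0.02))
    st <- encoding_state(tfms, flds)
    x <- random_complex_image(g)
    Ax <- forward_model(x, coils, st, pat, g)
    y <- array(complex(real = rnorm(length(Ax$samples)),
                       imaginary = rnorm(length(Ax$samples))),
               dim(Ax$samples))
    Ahy <- forward_adjoint(kspace_data(y, pat, g), coils, st)
    lhs <- sum(Ax$samples * Conj(y))
    rhs <- sum(x * Conj(Ahy))
    denom <- sqrt(sum(Mod(Ax$samples)^2)) * sqrt(sum(Mod(y)^2))
    expect_lt(Mod(lhs - rhs) / denom, 1e-6)
  }
})

test_that("fully sampled single-coil reconstruction matches the inverse FFT", {
  g <- small_grid()
  ph <- small_phantom()
  flat <- make_coil_sensitivities(g, 1, flat = TRUE)
  full <- build_caipi_pattern(g$shape, 1, 1, caipi_shift = 0)
  kd <- forward_model(ph$image, flat, NULL, full, g)
  rec <- reconstruct_volume(kd, flat, NULL, max_iter = 10)
  expect_lt(nrmse(Mod(rec$image), ph$image), 1e-6)
})

test_that("CAIPI-undersampled reconstruction recovers the phantom", {
  g <- small_grid()
  ph <- small_phantom()
  coils <- small_coils(8)
  pat <- build_caipi_pattern(g$shape, 2, 2, caipi_shift = 1,
                             n_interleaves = 2, echo_spacing = 5e-4,
                             te = 0.01)
  kd <- simulate_kspace(ph$image, coils, NULL, pat, g)
  rec <- reconstruct_volume(kd, coils, NULL, max_iter = 25)
  expect_lt(nrmse(Mod(rec$image), ph$image), 0.05)
  # CG cost is non-increasing
  expect_true(all(diff(rec$cost) <= 1e-9 * abs(rec$cost[1])))
})

test_that("correcting with the true states beats ignoring a motion step", {
  g <- small_grid()
  ph <- small_phantom()
  coils <- small_coils(8)
  pat <- build_caipi_pattern(g$shape, 2, 2, caipi_shift = 1,
                             n_interleaves = 2, echo_spacing = 5e-4,
                             te = 0.01)
  n_shots <- length(unique(pat$lines$shot))
  # 2 mm / 2 deg step at mid-volume
  step <- rigid_transform(2, 0, 0, 0, 0, 2)
  tfms <- c(replicate(n_shots %/% 2, rigid_identity(), simplify = FALSE),
            replicate(n_shots - n_shots %/% 2, step, simplify = FALSE))
  st <- encoding_state(tfms)
  kd <- simulate_kspace(ph$image, coils, st, pat, g)
  rec_cor <- reconstruct_volume(kd, coils, st, max_iter = 30)
  rec_unc <- reconstruct_volume(kd, coils, NULL, max_iter = 30)
  e_cor <- nrmse(Mod(rec_cor$image), ph$image)
  e_unc <- nrmse(Mod(rec_unc$image), ph$image)
  expect_lt(e_cor, e_unc)
  # corrected recon with ground-truth states approaches the motion-free one
  kd0 <- simulate_kspace(ph$image, coils, NULL, pat, g)
  e_free <- nrmse(Mod(reconstruct_volume(kd0, coils, NULL,
                                         max_iter = 30)$image), ph$image)
  expect_lt(e_cor, 2 * e_free + 0.02)
})

test_that("series reconstruction maps shots to navigator frames", {
  g <- small_grid()
  ph <- small_phantom()
  coils <- small_coils(6)
  pat <- build_caipi_pattern(g$shape, 2, 2, caipi_shift = 1,
                             echo_spacing = 5e-4, te = 0.01)
  trs <- max(pat$lines$tr_index) + 1
  tr <- 0.039
  motion <- make_motion_trace(6, 1.5, 1.5, "smooth_drift", seed = 4,
                              frame_interval = trs * tr / 2)
  field <- make_field_trace(6, 1, 0.005, seed = 4,
                            frame_interval = trs * tr / 2)
  run <- lapply(1:3, function(v) {
    st <- states_from_traces(pat, v, tr, motion, field)
    simulate_kspace(ph$image, coils, st, pat, g, seed = v)
  })
  # zero traces: corrected and uncorrected coincide bit-for-bit
  run0 <- lapply(1:2, function(v) simulate_kspace(ph$image, coils, NULL,
                                                  pat, g, seed = v))
  zmot <- make_motion_trace(6, 0, 0, seed = 1, frame_interval = trs * tr / 2)
  zfld <- make_field_trace(6, 0, 0, seed = 1, frame_interval = trs * tr / 2)
  s_cor0 <- reconstruct_series(run0, coils, tr, zmot, zfld, "corrected",
                               max_iter = 8)
  s_unc0 <- reconstruct_series(run0, coils, tr, zmot, zfld, "uncorrected",
                               max_iter = 8)
  expect_identical(s_cor0$data, s_unc0$data)
  # volume count preserved and TR propagated
  s_cor <- reconstruct_series(run, coils, tr, motion, field, "corrected",
                              max_iter = 15)
  expect_equal(dim(s_cor$data)[4], 3)
  expect_equal(s_cor$tr_volume, trs * tr)
})

test_that("missing encoding states are rejected", {
  g <- small_grid()
  ph <- small_phantom()
  coils <- small_coils(4)
  pat <- build_caipi_pattern(g$shape, 2, 2, caipi_shift = 1,
                             n_interleaves = 2)
  st <- encoding_state(list(rigid_identity()))  # too few shots
  expect_error(forward_model(ph$image, coils, st, pat, g), "missing")
})
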