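test_that("AFI inverts its signal equation", {
  # round-trip through the AFI ratio r = (1 + n cos a)/(n + cos a)
  for (alpha in c(60, 10, 35)) {
    r <- epinav:::afi_signal_ratio(alpha, 5)
    s1 <- array(1, c(4, 4, 4))
    s2 <- array(r, c(4, 4, 4))
    out <- afi_flip_angle(s1, s2, 5)
    expect_equal(out$fa[1], alpha, tolerance = 1e-10)
    expect_true(all(out$valid))
  }
  expect_equal(epinav:::afi_signal_ratio(60, 5), 0.6363636, tolerance = 1e-6)
  # alpha -> 0 gives r -> 1 and FA 0
  out0 <- afi_flip_angle(array(1, c(2, 2, 2)), array(1, c(2, 2, 2)), 5)
  expect_equal(max(out0$fa), 0)
  # unphysical ratios are masked out
  bad <- afi_flip_angle(array(1, c(2, 2, 2)), array(2, c(2, 2, 2)), 5)
  expect_false(any(bad$valid))
  expect_error(afi_flip_angle(array(1, c(2, 2, 2)), array(1, c(2, 2, 2)), 1))
})

test_that("hybrid B1 combination is scale-invariant and CP-consistent", {
  set.seed(8)
  d <- c(6, 6, 4)
  nrel <- 4
  rel <- array(complex(real = rnorm(prod(d) * nrel),
                       imaginary = rnorm(prod(d) * nrel)), c(d, nrel))
  w <- cp_mode_weights(nrel)
  cp_abs <- array(0i, d)
  for (c in 1:nrel) cp_abs <- cp_abs + w[c] * rel[, , , c]
  # relative maps already absolute and CP-consistent: scale factor 1
  out <- combine_hybrid_b1(Mod(cp_abs), rel, w)
  expect_equal(out$maps, rel, tolerance = 1e-12)
  # doubling all relative maps leaves the output unchanged
  out2 <- combine_hybrid_b1(Mod(cp_abs), 2 * rel, w)
  expect_equal(out2$maps, out$maps, tolerance = 1e-12)
  # single channel, unit weight: output magnitude equals the absolute map
  one <- combine_hybrid_b1(array(2, d), rel[, , , 1, drop = FALSE], 1 + 0i)
  expect_equal(Mod(one$maps[, , , 1]), array(2, d), tolerance = 1e-12)
})

test_that("system matrix entries follow the small-tip phase model", {
  g <- grid3d(c(4, 4, 4), c(20, 20, 20))
  b1 <- list(maps = array(1 + 0i, c(4, 4, 4, 1)), n_tx = 1L, grid = g)
  class(b1) <- "b1_map_set"
  mask <- array(TRUE, c(4, 4, 4))
  b0 <- array(0, c(4, 4, 4))
  dt <- 1e-4
  # single kT point at k = 0, f = 0: constant column i*gamma*dt*B1
  A0 <- build_system_matrix(b1, b0, mask, g, matrix(0, 1, 3), dt, 0)
  expect_equal(dim(A0), c(64, 1))
  expected <- 1i * 2 * pi * 42.577 * dt
  expect_equal(unique(zapsmall(A0[, 1], 12)), zapsmall(expected, 12))
  # row phase at frequency f and point-time offset tau equals 2*pi*f*tau:
  # one point centered at t_1 = dt/2, pulse end T = dt, so tau = -dt/2
  f <- 500
  Af <- build_system_matrix(b1, b0, mask, g, matrix(0, 1, 3), dt, f)
  expect_equal(Arg(Af[1, 1] / A0[1, 1]), 2 * pi * f * (-dt / 2),
               tolerance = 1e-10)
  # shape: (|mask| * n_freq) x (n_tx * n_kt)
  fx <- ptx_fixture()
  expect_equal(dim(fx$A),
               c(sum(fx$mask) * length(fx$target$frequencies), 16 * 24))
})

test_that("kT locations are symmetric and never mutated by the designer", {
  kt <- default_kt_locations(c(0.192, 0.176, 0.144), 24, 2)
  expect_equal(kt[seq(1, 24, 2), ], -kt[seq(2, 24, 2), ],
               ignore_attr = TRUE)
  fx <- ptx_fixture()
  des <- design_mls_pulse(fx$A, fx$target, lambda = 1e-4, n_iter = 5)
  expect_identical(des$pulse$kt_locations, fx$kt)
})

test_that("MLS design solves the scalar case exactly and respects lambda", {
  # single uniform channel, one kT point, uniform target, lambda = 0:
  # closed-form scalar solution, relative magnitude residual ~ 0
  g <- grid3d(c(4, 4, 4), c(20, 20, 20))
  b1 <- structure(list(maps = array(1 + 0i, c(4, 4, 4, 1)), n_tx = 1L,
                       grid = g), class = "b1_map_set")
  mask <- array(TRUE, c(4, 4, 4))
  A <- build_system_matrix(b1, array(0, c(4, 4, 4)), mask, g,
                           matrix(0, 1, 3), 1e-4, 0)
  tgt <- rep(0.1745, 64)
  des <- design_mls_pulse(A, tgt, lambda = 0, n_iter = 5)
  expect_lt(tail(des$residual, 1), 1e-10)
  # very large lambda drives the drives (and the achieved flip) to zero
  fx <- ptx_fixture()
  big <- design_mls_pulse(fx$A, fx$target, lambda = 1e9, n_iter = 5)
  expect_lt(sqrt(sum(Mod(big$weights_vec)^2)), 1e-4)
  expect_lt(mean(Mod(fx$A %*% big$weights_vec)), 1e-4)
  expect_error(design_mls_pulse(fx$A, fx$target, lambda = -1), "lambda")
})

test_that("MLS cost is monotone and the design beats the CP mode", {
  fx <- ptx_fixture()
  des <- design_mls_pulse(fx$A, fx$target, lambda = 1e-4, n_iter = 25)
  expect_true(all(diff(des$cost) <= 1e-8 * des$cost[1]))
  # Bloch-verified flip-angle maps at the water frequency
  bl <- bloch_simulate(des$pulse, fx$b1, fx$b0, fx$grid, fx$mask, 0)
  cov_ptx <- sd(bl$fa[, 1]) / mean(bl$fa[, 1])
  # CP-mode pulse rescaled to the same mean flip angle
  cp_w <- matrix(cp_mode_weights(16), 16, 24) * 0.002
  bl_cp1 <- bloch_simulate(kt_point_pulse(cp_w, fx$kt, 3.8e-3 / 24),
                           fx$b1, fx$b0, fx$grid, fx$mask, 0)
  cp_w <- cp_w * mean(bl$fa[, 1]) / mean(bl_cp1$fa[, 1])
  bl_cp <- bloch_simulate(kt_point_pulse(cp_w, fx$kt, 3.8e-3 / 24),
                          fx$b1, fx$b0, fx$grid, fx$mask, 0)
  cov_cp <- sd(bl_cp$fa[, 1]) / mean(bl_cp$fa[, 1])
  expect_equal(mean(bl_cp$fa[, 1]), mean(bl$fa[, 1]), tolerance = 0.02)
  expect_lt(cov_ptx, cov_cp)
  # fat stopband: mean |FA| at the fat shift <= 20% of nominal
  bl_fat <- bloch_simulate(des$pulse, fx$b1, fx$b0, fx$grid, fx$mask,
                           fat_water_shift_hz(10.5))
  expect_lt(mean(bl_fat$fa[, 1]), 0.2 * 10)
})

test_that("Bloch simulation has the right limits and small-tip agreement", {
  fx <- ptx_fixture()
  # zero weights: no excitation
  z <- bloch_simulate(kt_point_pulse(matrix(0i, 16, 24), fx$kt, 3.8e-3 / 24),
                      fx$b1, fx$b0, fx$grid, fx$mask, 0)
  expect_equal(max(z$fa), 0)
  # constant on-resonance drive on a flat single channel: FA = gamma*B1*dt*n
  g <- grid3d(c(4, 4, 4), c(20, 20, 20))
  b1f <- structure(list(maps = array(1 + 0i, c(4, 4, 4, 1)), n_tx = 1L,
                        grid = g), class = "b1_map_set")
  amp <- 0.02
  n_pts <- 24
  dt <- 1e-4
  pl <- kt_point_pulse(matrix(amp + 0i, 1, n_pts), matrix(0, n_pts, 3), dt)
  bl <- bloch_simulate(pl, b1f, array(0, c(4, 4, 4)), g,
                       array(TRUE, c(4, 4, 4)), 0)
  expect_equal(bl$fa[1, 1],
               2 * pi * 42.577 * amp * dt * n_pts * 180 / pi,
               tolerance = 1e-8)
  # small-tip limit: Bloch FA within 2% of |A b| for a 10-degree design
  des <- design_mls_pulse(fx$A, fx$target, lambda = 1e-4, n_iter = 15)
  blw <- bloch_simulate(des$pulse, fx$b1, fx$b0, fx$grid, fx$mask, 0)
  nv <- attr(fx$A, "n_vox")
  fi <- which(fx$target$frequencies == 0)
  lin <- Mod(fx$A %*% des$weights_vec)[(fi - 1) * nv + seq_len(nv)] * 180 / pi
  expect_lt(max(abs(blw$fa[, 1] - lin) / pmax(lin, 1e-6)), 0.02)
})

test_that("flip-angle CoV matches a brute-force two-pass computation", {
  expect_equal(flip_angle_cov(array(3, c(4, 4, 4))), 0)
  # equal numbers of 1 and 3: SD/mean = 0.5 (population SD)
  expect_equal(flip_angle_cov(c(1, 3, 1, 3)), 0.5)
  set.seed(6)
  vals <- runif(200, 5, 15)
  mu <- sum(vals) / length(vals)
  sd2 <- sqrt(sum((vals - mu)^2) / length(vals))
  expect_equal(flip_angle_cov(vals), sd2 / mu, tolerance = 1e-12)
  expect_error(flip_angle_cov(numeric(0)), "empty")
})

test_that("pulse text serialization carries all weights and locations", {
  fx <- ptx_fixture()
  pl <- kt_point_pulse(matrix(complex(real = rnorm(16 * 24),
                                      imaginary = rnorm(16 * 24)), 16, 24),
                       fx$kt, 3.8e-3 / 24)
  path <- withr::local_tempfile(fileext = ".txt")
  write_pulse_txt(pl, path)
  tab <- read.delim(path, skip = 1)
  expect_equal(nrow(tab), 16 * 24)
  expect_equal(tab$re[1], Re(pl$weights[1, 1]), tolerance = 1e-6)
})
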