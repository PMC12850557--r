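test_that("spiral trajectories stay in the Nyquist box and reach its edge", {
  traj <- make_stack_of_spirals(n_interleaves = 24, grid_shape = c(32, 32))
  expect_true(all(abs(traj$coords) < 16))
  expect_gte(max(sqrt(rowSums(traj$coords^2))), 0.9 * 16)
  ## time nondecreasing within each readout
  by_ro <- split(traj$time, traj$readout_id)
  expect_true(all(vapply(by_ro, function(t) all(diff(t) >= 0), logical(1))))
})

test_that("golden-angle rotation is constant between successive interleaves", {
  traj <- make_stack_of_spirals(n_interleaves = 12, grid_shape = c(32, 32),
                                golden_angle = TRUE)
  K <- traj$samples_per_interleaf
  ang <- vapply(1:12, function(s)
    atan2(traj$coords[s * K, 2], traj$coords[s * K, 1]), numeric(1))
  dth <- diff(ang) %% (2 * pi)
  expect_lt(max(abs(dth - dth[1])), 1e-9)
  expect_equal(dth[1] * 180 / pi, 222.4922, tolerance = 1e-4)
})

test_that("uniform rotation fallback gives evenly spaced interleaves", {
  traj <- make_stack_of_spirals(n_interleaves = 4, grid_shape = c(32, 32),
                                golden_angle = FALSE)
  K <- traj$samples_per_interleaf
  ang <- sort(vapply(1:4, function(s)
    atan2(traj$coords[s * K, 2], traj$coords[s * K, 1]) %% (2 * pi),
    numeric(1)))
  expect_equal(diff(ang), rep(pi / 2, 3), tolerance = 1e-9)
})

test_that("3-D stacks replicate the spiral across kz partitions", {
  traj <- make_stack_of_spirals(n_interleaves = 6, n_kz = 8,
                                grid_shape = c(24, 24, 8))
  expect_equal(sort(unique(traj$coords[, 3])), seq(-4, 3))
  expect_error(make_stack_of_spirals(4, n_kz = 2, grid_shape = c(24, 24)),
               "2-D")
})

test_that("the navigator samples the breathing waveform on its cadence", {
  nav <- simulate_navigator(amplitude = 3, period_ms = 4000,
                            duration_ms = 12000, interval_ms = 120,
                            noise_sd = 0, seed = 1)
  expect_equal(unique(diff(nav$time)), 120)
  expect_equal(nav$value, 3 * sin(2 * pi * nav$time / 4000), tolerance = 1e-12)
  expect_error(simulate_navigator(1, duration_ms = 100, interval_ms = 0),
               "interval")
})

test_that("Hilbert phase of a noiseless navigator advances 2*pi per period", {
  nav <- simulate_navigator(amplitude = 2, period_ms = 4000,
                            duration_ms = 24000, interval_ms = 120)
  phi <- hilbert_phase(nav$value)
  up <- coilsketch:::unwrap_phase(phi)
  inner <- seq(round(length(up) * 0.15), round(length(up) * 0.85))
  slope <- coef(lm(up[inner] ~ nav$time[inner]))[2]
  expect_equal(as.numeric(slope), 2 * pi / 4000, tolerance = 0.05)
})

test_that("simulated acquisition obeys the seeding contract and the forward model", {
  ph <- make_dynamic_phantom(phantom_spec(grid_shape = c(24, 24),
                                          n_phases = 1, seed = 2))
  maps <- make_coil_maps(1, c(24, 24), uniform = TRUE)
  traj <- make_stack_of_spirals(n_interleaves = 8, grid_shape = c(24, 24),
                                samples_per_interleaf = 40)
  ## delta-image override: flat k-space magnitude for a uniform coil
  delta <- array(0 + 0i, c(24, 24, 1)); delta[13, 13, 1] <- 1
  raw <- simulate_acquisition(ph, maps, traj, noise_sd = 0, seed = 1,
                              image_override = delta)
  expect_lt(max(abs(abs(raw$kspace) - 1)), 1e-6)

  r1 <- simulate_acquisition(ph, maps, traj, noise_sd = 0.3, seed = 9)
  r2 <- simulate_acquisition(ph, maps, traj, noise_sd = 0.3, seed = 9)
  r3 <- simulate_acquisition(ph, maps, traj, noise_sd = 0.3, seed = 10)
  expect_identical(r1$kspace, r2$kspace)
  expect_false(identical(r1$kspace, r3$kspace))

  expect_error(
    simulate_acquisition(ph, maps,
                         make_stack_of_spirals(4, n_kz = 4,
                                               grid_shape = c(24, 24, 4)),
                         noise_sd = 0),
    "dimensionality")
})

test_that("adjoint images of noiseless simulated data correlate with the phantom", {
  fx <- fixture_small()
  r <- 1
  co <- fx$binned$coords[[r]]
  plan <- nufft_plan(co, dim(fx$phantom$images)[1:2])
  dcf <- pipe_menon_dcf(co, dim(fx$phantom$images)[1:2])
  C <- dim(fx$maps)[3]
  acc <- 0
  for (c in seq_len(C))
    acc <- acc + Conj(fx$maps[, , c]) *
      nufft_adjoint(dcf * fx$binned$kspace[[r]][c, ], plan)
  truth <- abs(get_phase(fx$phantom$images, r))
  expect_gt(cor(as.vector(abs(acc)), as.vector(truth)), 0.9)
})
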