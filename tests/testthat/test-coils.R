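test_that("SVD reordering is unitary, energy-ordered, and energy-preserving", {
  expect_equal(svd_reorder(matrix(rand_complex(40, seed = 1), 1))$mixing,
               matrix(1 + 0i, 1, 1), tolerance = 1e-12)
  expect_error(svd_reorder(matrix(0 + 0i, 3, 10)), "zero")

  ## two identical coils: all energy in the first virtual coil
  row <- rand_complex(200, seed = 2)
  b <- svd_reorder(rbind(row, row))
  expect_equal(b$energies[2] / b$energies[1], 0, tolerance = 1e-10)
  expect_lt(sum(abs(b$kspace[2, ])^2) / sum(abs(b$kspace[1, ])^2), 1e-10)

  fx <- fixture_small()
  bb <- svd_reorder(fx$raw$kspace)
  C <- nrow(fx$raw$kspace)
  expect_lt(max(abs(Conj(t(bb$mixing)) %*% bb$mixing - diag(C))), 1e-10)
  expect_true(all(diff(bb$energies) <= 1e-9))
  expect_equal(sum(abs(bb$kspace)^2), sum(abs(fx$raw$kspace)^2),
               tolerance = 1e-8)
})

test_that("compression keeps the top virtual coils and reports retained energy", {
  fx <- fixture_small()
  b <- svd_reorder(fx$raw$kspace)
  maps_v <- coilsketch:::mix_maps(fx$maps, b$mixing)
  C <- nrow(fx$raw$kspace)
  full <- compress_coils(b$kspace, maps_v, C)
  expect_identical(full$kspace, b$kspace)
  expect_equal(energy_fraction(b, C), 1)
  cmp <- compress_coils(b$kspace, maps_v, 3)
  expect_equal(dim(cmp$maps)[3], 3)
  expect_equal(energy_fraction(b, 3),
               sum(b$energies[1:3]) / sum(b$energies))
  expect_error(compress_coils(b$kspace, maps_v, C + 1), "C_prime")
})

test_that("sketch plans keep coil 1 and use scaled Rademacher rows", {
  C <- 15; CS <- 3; n_outer <- 6     # the default sketched configuration
  sp <- build_sketch_plan(C, CS, n_outer, seed = 4)
  expect_length(sp$sketches, n_outer)
  s <- 1 / sqrt(CS - 1)
  for (sk in sp$sketches) {
    expect_equal(dim(sk), c(CS, C))
    expect_equal(Re(sk[1, ]), c(1, rep(0, C - 1)))
    expect_true(all(sk[-1, 1] == 0))
    expect_true(all(abs(abs(sk[-1, -1]) - s) < 1e-12))
  }
  expect_false(identical(sp$sketches[[1]], sp$sketches[[2]]))
  expect_identical(sp$sketches,
                   build_sketch_plan(C, CS, n_outer, seed = 4)$sketches)
  expect_error(build_sketch_plan(4, 5, 2), "C_S")
  id <- build_sketch_plan(4, 4, 2, identity = TRUE)
  expect_equal(id$sketches[[1]], diag(4) + 0i)
})

test_that("E[sketch^H sketch] is the identity on the non-kept coils", {
  C <- 6; CS <- 3
  acc <- matrix(0 + 0i, C, C)
  n <- 10000
  sp <- build_sketch_plan(C, CS, n, seed = 11)
  for (sk in sp$sketches) acc <- acc + Conj(t(sk)) %*% sk
  acc <- acc / n
  se <- 1 / sqrt((CS - 1) * n)      # entrywise SE of a +/-1/(CS-1) product
  offdiag <- acc - diag(diag(acc))
  expect_lt(max(abs(offdiag[-1, -1])), 3 * se)
  expect_equal(Re(diag(acc)), rep(1, C), tolerance = 1e-10)
})

test_that("apply_sketch mixes maps and data consistently", {
  fx <- fixture_small()
  sk <- build_sketch_plan(4, 2, 1, seed = 2)$sketches[[1]]
  out <- apply_sketch(sk, maps = fx$maps, kspace = fx$binned$kspace)
  expect_equal(dim(out$maps)[3], 2)
  expect_equal(nrow(out$kspace[[1]]), 2)
  ## row 1 keeps virtual coil 1 verbatim
  expect_equal(out$maps[, , 1], fx$maps[, , 1])
  expect_equal(out$kspace[[1]][1, ], fx$binned$kspace[[1]][1, ])
})

test_that("eigenvector maps recover the true sensitivities on synthetic data", {
  fx <- fixture32()
  est <- estimate_maps(fx$binned, dim(fx$phantom$images)[1:2])
  tru <- fx$maps
  d <- dim(tru); C <- d[3]
  rss <- sqrt(apply(abs(tru)^2, 1:2, sum))
  expect_lte(max(sqrt(apply(abs(est)^2, 1:2, sum))), 1 + 1e-9)
  trun <- abs(tru) / array(rep(pmax(rss, 1e-12), C), d)
  sig <- apply(abs(fx$phantom$images), 1:2, mean)
  m3 <- array(sig > 0.5 * max(sig), d)
  err <- sqrt(mean((abs(est)[m3] - trun[m3])^2)) / sqrt(mean(trun[m3]^2))
  expect_lt(err, 0.05)
})

test_that("a single uniform coil yields a near-constant map on the support", {
  ph <- make_dynamic_phantom(phantom_spec(grid_shape = c(32, 32),
                                          n_phases = 1, seed = 5))
  maps <- make_coil_maps(1, c(32, 32), uniform = TRUE)
  traj <- make_stack_of_spirals(n_interleaves = 48, grid_shape = c(32, 32),
                                samples_per_interleaf = 96)
  raw <- simulate_acquisition(ph, maps, traj, noise_sd = 0, seed = 2)
  bn <- bin_dataset(raw, rep(1L, length(unique(raw$readout_id))), 1)
  est <- estimate_maps(bn, c(32, 32))
  sig <- abs(ph$images[, , 1])
  sup <- sig > 0.5 * max(sig)
  vals <- abs(est[, , 1])[sup]
  expect_lt(sd(vals) / mean(vals), 0.05)
})
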