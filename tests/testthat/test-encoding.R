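make_sense_instance <- function(N = c(16, 16), R = 2, C = 3, K = 300,
                                seed = 2) {
  withr::with_seed(seed, {
    coords <- lapply(seq_len(R), function(r)
      rbind(test_spiral(K / 3, min(N) / 2 - 0.6, th0 = 0.7 * r),
            test_spiral(K / 3, min(N) / 2 - 0.6, th0 = 0.7 * r + pi / 2),
            test_spiral(K / 3, min(N) / 2 - 0.6, th0 = 0.7 * r + pi)))
    plans <- lapply(coords, nufft_plan, grid_shape = N)
    maps <- array(complex(real = rnorm(prod(N) * C) / 3 + 1,
                          imaginary = rnorm(prod(N) * C) / 4), c(N, C))
    precond <- lapply(plans, function(p) runif(p$K, 0.5, 2))
    list(N = N, R = R, C = C, coords = coords, plans = plans, maps = maps,
         precond = precond)
  })
}

test_that("SENSE forward/adjoint are exact adjoints and reduce to the NUFFT", {
  inst <- make_sense_instance()
  x <- rand_stack(c(inst$N, inst$R), seed = 3)
  y <- lapply(inst$plans, function(p)
    matrix(rand_complex(inst$C * p$K), inst$C, p$K))
  Ax <- sense_forward(x, inst$maps, inst$plans, inst$precond)
  lhs <- sum(mapply(function(a, b) sum(Conj(a) * b), Ax, y))
  rhs <- sum(Conj(x) * sense_adjoint(y, inst$maps, inst$plans, inst$precond))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)

  ## single uniform coil, unit weights: plain NUFFT per phase
  umaps <- array(1 + 0i, c(inst$N, 1))
  Ax1 <- sense_forward(x, umaps, inst$plans)
  for (r in seq_len(inst$R))
    expect_equal(as.vector(Ax1[[r]]),
                 nufft_forward(x[, , r], inst$plans[[r]]), tolerance = 1e-12)

  expect_true(all(vapply(
    sense_forward(x * 0, inst$maps, inst$plans), function(m) all(m == 0),
    logical(1))))
  expect_error(sense_forward(x, inst$maps, inst$plans[1], inst$precond),
               "phase count|plans")
})

test_that("normal operator is batch-independent and matches a dense oracle", {
  inst <- make_sense_instance()
  x <- rand_stack(c(inst$N, inst$R), seed = 9)
  n_full <- normal_op(x, inst$maps, inst$plans, inst$precond,
                      coil_batch = inst$C)
  n_one <- normal_op(x, inst$maps, inst$plans, inst$precond, coil_batch = 1)
  expect_lt(max(abs(n_full - n_one)) / max(abs(n_full)), 1e-10)

  ## dense oracle on a tiny instance: 6x6 grid, C = 2, K = 40
  N <- c(6, 6); C <- 2; K <- 40
  withr::with_seed(4, {
    coords <- cbind(runif(K, -3, 2.99), runif(K, -3, 2.99))
    maps <- array(rand_complex(prod(N) * C), c(N, C))
    w <- runif(K, 0.5, 2)
  })
  plan <- nufft_plan(coords, N)
  idx <- arrayInd(seq_len(prod(N)), N)
  Fm <- exp(-2i * pi * (outer(coords[, 1], (idx[, 1] - 1 - 3) / 6) +
                        outer(coords[, 2], (idx[, 2] - 1 - 3) / 6)))
  A <- rbind(sqrt(w) * Fm %*% diag(as.vector(maps[, , 1])),
             sqrt(w) * Fm %*% diag(as.vector(maps[, , 2])))
  H <- Conj(t(A)) %*% A
  xv <- rand_complex(prod(N), seed = 5)
  want <- array(H %*% xv, c(N, 1))
  got <- normal_op(array(xv, c(N, 1)), maps, list(plan), list(w))
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-6)
})

test_that("Toeplitz embedding reproduces the normal operator", {
  inst <- make_sense_instance()
  kerns <- lapply(seq_len(inst$R), function(r)
    build_toeplitz_kernel(inst$coords[[r]], inst$precond[[r]], inst$N))
  x <- rand_stack(c(inst$N, inst$R), seed = 21)
  tx <- apply_toeplitz(x, kerns, inst$maps)
  nx <- normal_op(x, inst$maps, inst$plans, inst$precond)
  expect_lt(sqrt(sum(abs(tx - nx)^2) / sum(abs(nx)^2)), 1e-3)

  ## the kernel ignores the maps: the sketched operator reuses it exactly
  sk <- build_sketch_plan(inst$C, 2, 1, seed = 3)$sketches[[1]]
  maps_sk <- apply_sketch(sk, maps = inst$maps)$maps
  tx_sk <- apply_toeplitz(x, kerns, maps_sk)
  nx_sk <- normal_op(x, maps_sk, inst$plans, inst$precond)
  expect_lt(sqrt(sum(abs(tx_sk - nx_sk)^2) / sum(abs(nx_sk)^2)), 1e-3)
})

test_that("fully-sampled Cartesian Toeplitz kernel is a scaled identity", {
  N <- c(16, 16)
  g <- as.matrix(expand.grid(-8:7, -8:7))
  kern <- build_toeplitz_kernel(g, NULL, N)
  x <- rand_stack(N, seed = 6)
  tx <- coilsketch:::toeplitz_embed_apply(x, kern)
  expect_lt(max(abs(tx - prod(N) * x)) / prod(N), 1e-6)
})

test_that("k-space preconditioner weights are flat on Cartesian, positive and clustering on spirals", {
  N <- c(12, 12)
  g <- as.matrix(expand.grid(-6:5, -6:5))
  w <- kspace_preconditioner(g, N)
  expect_lt(sd(w) / mean(w), 1e-6)
  expect_true(all(is.finite(kspace_preconditioner(test_spiral(240, 5.4), N)) &
                    kspace_preconditioner(test_spiral(240, 5.4), N) > 0))

  ## dense spectral oracle on a well-sampled 16x16 spiral: the diagonal
  ## preconditioner reduces the condition estimate and clusters the
  ## spectrum near its peak
  N <- c(16, 16)
  co <- do.call(rbind, lapply(0:2, function(a)
    test_spiral(300, 7.4, th0 = 0.7 + a * pi / 2)))
  ws <- kspace_preconditioner(co, N)
  idx <- arrayInd(seq_len(prod(N)), N)
  Fm <- exp(-2i * pi * (outer(co[, 1], (idx[, 1] - 1 - 8) / 16) +
                        outer(co[, 2], (idx[, 2] - 1 - 8) / 16)))
  evals <- function(M) {
    e <- sort(Re(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
              decreasing = TRUE)
    e / max(e)
  }
  e0 <- evals(Conj(t(Fm)) %*% Fm)
  e1 <- evals(Conj(t(Fm)) %*% (ws * Fm))
  cnum <- function(e) 1 / min(e[e > 1e-9])
  expect_lte(cnum(e1), cnum(e0))
  expect_gt(mean(e1 > 0.1), mean(e0 > 0.1))
})

test_that("power method matches dense eigensolvers and normalization is idempotent", {
  expect_equal(power_method_maxeig(function(v) array(c(1, 2, 3) * v, 3), 3,
                                   n_iter = 60, seed = 2), 3,
               tolerance = 1e-6)
  H <- withr::with_seed(8, {
    A <- matrix(rand_complex(400), 20)
    Conj(t(A)) %*% A
  })
  lam <- power_method_maxeig(function(v) array(H %*% as.vector(v), 20), 20,
                             n_iter = 500, tol = 1e-12, seed = 3)
  expect_equal(lam, max(Re(eigen(H, only.values = TRUE)$values)),
               tolerance = 1e-4)
  expect_error(power_method_maxeig(function(v) v * 0, 4), "zero operator")

  inst <- make_sense_instance(N = c(12, 12), K = 150)
  ns <- normalize_system(inst$maps, inst$plans, inst$precond, seed = 1)
  lam2 <- power_method_maxeig(
    function(v) normal_op(v, inst$maps, inst$plans, ns$precond),
    c(inst$N, inst$R), n_iter = 60, seed = 1)
  expect_equal(lam2, 1, tolerance = 1e-3)
})
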