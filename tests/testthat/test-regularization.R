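test_that("finite differences vanish on constants and have an exact adjoint", {
  x <- array(3 + 2i, c(8, 8, 3))
  expect_true(all(finite_diff(x) == 0))
  for (circ in c(TRUE, FALSE)) {
    a <- rand_stack(c(8, 8, 3), seed = 1)
    b <- rand_stack(c(8, 8, 3, 3), seed = 2)
    lhs <- sum(Conj(finite_diff(a, circ)) * b)
    rhs <- sum(Conj(a) * finite_diff_adjoint(b, circ))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
  }
  ## a single-voxel step edge has exactly two nonzero spatial differences
  y <- array(0 + 0i, c(6, 6, 1))
  y[3, 3, 1] <- 1
  g <- finite_diff(y, circular_phase = FALSE)
  expect_equal(sum(g != 0), 4)             # +/- pairs along each spatial axis
  expect_equal(sum(abs(g[, , , 1]) > 0), 2)
  expect_equal(sum(abs(g[, , , 2]) > 0), 2)
})

test_that("complex soft-thresholding matches its closed form", {
  z <- rand_stack(c(5, 5), seed = 3)
  expect_identical(prox_l1(z, 0), z)
  expect_true(all(prox_l1(z, max(abs(z)) + 1) == 0))
  expect_equal(prox_l1(3 + 0i, 1), 2 + 0i)
  expect_equal(prox_l1(-3 + 0i, 1), -2 + 0i)
  ## shrinkage preserves phase and reduces modulus by tau
  big <- z[abs(z) > 0.5]
  out <- prox_l1(big, 0.2)
  expect_equal(abs(out), abs(big) - 0.2, tolerance = 1e-12)
  expect_equal(Arg(out), Arg(big), tolerance = 1e-12)
})

test_that("singular-value soft-thresholding is the exact nuclear-norm prox", {
  Y <- matrix(rand_complex(12, seed = 4), 3, 4)
  expect_identical(prox_nuclear(Y, 0), Y)
  s <- svd(Y)$d
  X <- prox_nuclear(Y, 0.5)
  expect_equal(svd(X)$d, pmax(s - 0.5, 0), tolerance = 1e-12)
  ## rank-1 full shrinkage
  r1 <- outer(rand_complex(3, seed = 5), rand_complex(4, seed = 6))
  expect_true(all(prox_nuclear(r1, svd(r1)$d[1] + 0.1) == 0))
  ## local optimality against random perturbations
  obj <- function(X) 0.5 * sum(abs(X - Y)^2) + 0.5 * sum(svd(X)$d)
  base <- obj(X)
  worse <- withr::with_seed(7, replicate(300, {
    P <- matrix(complex(real = rnorm(12, sd = 0.05),
                        imaginary = rnorm(12, sd = 0.05)), 3, 4)
    obj(X + P)
  }))
  expect_true(all(worse >= base - 1e-12))
  ## monotone nuclear norm and nonexpansive energy
  expect_lte(sum(svd(prox_nuclear(Y, 0.8))$d), sum(svd(X)$d))
  expect_lte(sqrt(sum(abs(X)^2)), sqrt(sum(abs(Y)^2)))
})

test_that("the forward-only motion-compensated prox collapses correctly", {
  grid <- c(12, 12)
  v <- rand_stack(grid, seed = 8)
  ## R = 1: plain nuclear prox of a single row
  one <- array(v, c(grid, 1))
  got <- moco_lr_prox(one, 0.3)
  want <- from_casorati(prox_nuclear(as_casorati(one), 0.3), grid)
  expect_equal(got, want, tolerance = 1e-12)
  ## static stack with identity motion: equals prox_nuclear row-for-row
  st <- array(rep(v, 3), c(grid, 3))
  zf <- lapply(1:3, function(r) lapply(1:3, function(p)
    array(0, c(grid, 2))))
  expect_equal(moco_lr_prox(st, 0.4, fields = zf),
               from_casorati(prox_nuclear(as_casorati(st), 0.4), grid),
               tolerance = 1e-14)
  bad <- zf; bad[[2]][[1]][1] <- NaN
  expect_error(moco_lr_prox(st, 0.4, fields = bad), "phase pair")
})

test_that("an aligned phantom stack is near rank-1 and barely shrunk", {
  ph <- make_dynamic_phantom(phantom_spec(grid_shape = c(32, 32),
                                          n_phases = 3,
                                          diaphragm_amplitude = 3, seed = 3))
  ## analytic fields: [[ref]][[p]] from the generator's geometry
  fields <- lapply(1:3, function(ref) lapply(1:3, function(p) {
    if (p == ref) return(array(0, c(32, 32, 2)))
    register(abs(get_phase(ph$images, p)), abs(get_phase(ph$images, ref)))
  }))
  s1 <- svd(as_casorati(ph$images), nu = 0, nv = 0)$d[1]
  out <- moco_lr_prox(ph$images, 0.003 * s1, fields = fields)
  for (p in 1:3) {
    err <- nrmse_masked(get_phase(out, p), get_phase(ph$images, p))
    expect_lt(err, 0.01)
  }
})

test_that("regularizer values match their closed forms", {
  x0 <- array(0 + 0i, c(6, 6, 2))
  for (k in c("none", "tv", "lr", "cgsense"))
    expect_equal(regularizer_value(x0, regularizer_spec(k, 0.3)), 0)
  v <- rand_stack(c(6, 6), seed = 9)
  st <- array(rep(v, 4), c(6, 6, 4))    # R identical volumes: rank 1
  expect_equal(regularizer_value(st, regularizer_spec("lr", 0.7)),
               0.7 * sqrt(4) * sqrt(sum(abs(v)^2)), tolerance = 1e-10)
  expect_equal(regularizer_value(array(5 + 0i, c(6, 6, 2)),
                                 regularizer_spec("tv", 1)), 0)
})
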