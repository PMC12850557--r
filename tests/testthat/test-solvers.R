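test_that("CG solves identity systems in one step and dense SPD systems exactly", {
  rhs <- rand_stack(c(4, 4), seed = 1)
  expect_equal(cg_solve(identity, rhs, 1), rhs, tolerance = 1e-12)

  H <- withr::with_seed(2, {
    A <- matrix(rand_complex(64), 8)
    Conj(t(A)) %*% A + diag(8)
  })
  b <- rand_complex(8, seed = 3)
  x <- cg_solve(function(v) array(H %*% as.vector(v), 8), array(b, 8), 8)
  expect_lt(max(abs(as.vector(x) - solve(H, b))), 1e-8)
  expect_error(cg_solve(function(v) v * NaN, rhs, 3), "finite")
})

test_that("FISTA with identity prox matches reference accelerated gradient descent", {
  H <- withr::with_seed(4, {
    A <- matrix(rnorm(100), 10)
    S <- crossprod(A)
    S / max(eigen(S)$values)
  })
  b <- withr::with_seed(5, rnorm(10))
  grad <- function(x) array(H %*% as.vector(x) - b, 10)
  got <- fista_solve(grad, function(z, tau) z, array(0 + 0i, 10), 40)
  ## independent reference: textbook Nesterov/FISTA recursion
  x <- rep(0, 10); z <- x; tk <- 1
  for (i in 1:40) {
    xn <- z - (H %*% z - b)
    restart <- sum((z - xn) * (xn - x)) > 0
    tn <- if (restart) 1 else (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- as.vector(xn + ((tk - 1) / tn) * (xn - x))
    x <- as.vector(xn); tk <- tn
  }
  expect_lt(max(abs(as.vector(got) - x)), 1e-10)
})

test_that("sketched gradient identities hold", {
  fx <- fixture_small()
  N <- dim(fx$phantom$images)[1:2]
  plans <- lapply(fx$binned$coords, nufft_plan, grid_shape = N)
  maps <- fx$maps
  C <- dim(maps)[3]
  full_normal <- function(x) normal_op(x, maps, plans)
  ahy <- sense_adjoint(fx$binned$kspace, maps, plans)
  xt <- rand_stack(c(N, fx$binned$R), seed = 6)
  anchor <- list(x_anchor = xt, full_grad_anchor = full_normal(xt) - ahy,
                 fresh = TRUE)

  ## at the anchor: equals the full gradient for ANY sketch
  for (s in 1:3) {
    sk <- build_sketch_plan(C, 2, 1, seed = s)$sketches[[1]]
    msk <- apply_sketch(sk, maps = maps)$maps
    skn <- function(x) normal_op(x, msk, plans)
    g <- sketched_gradient(xt, anchor, skn)
    expect_equal(g, anchor$full_grad_anchor, tolerance = 1e-12)
  }

  ## identity sketch: equals the full gradient everywhere
  x2 <- rand_stack(c(N, fx$binned$R), seed = 7)
  g_id <- sketched_gradient(x2, anchor, full_normal)
  expect_lt(max(abs(g_id - (full_normal(x2) - ahy))) / max(abs(g_id)), 1e-10)

  stale <- anchor; stale$fresh <- FALSE
  expect_error(sketched_gradient(x2, stale, full_normal), "stale")
})

test_that("sketched gradient matches a dense-matrix evaluation on a tiny instance", {
  N <- c(6, 6); C <- 3; K <- 45
  withr::with_seed(8, {
    coords <- cbind(runif(K, -3, 2.99), runif(K, -3, 2.99))
    maps <- array(rand_complex(prod(N) * C), c(N, C))
    y <- matrix(rand_complex(C * K), C, K)
  })
  plan <- nufft_plan(coords, N, width = 12)   # extra kernel accuracy for the
  idx <- arrayInd(seq_len(prod(N)), N)        # 1e-8 dense comparison
  Fm <- exp(-2i * pi * (outer(coords[, 1], (idx[, 1] - 1 - 3) / 6) +
                        outer(coords[, 2], (idx[, 2] - 1 - 3) / 6)))
  Amat <- do.call(rbind, lapply(1:C, function(c)
    Fm %*% diag(as.vector(maps[, , c]))))
  sk <- build_sketch_plan(C, 2, 1, seed = 9)$sketches[[1]]
  Ask <- do.call(rbind, lapply(1:2, function(r) {
    m <- matrix(0 + 0i, prod(N), 1)
    mm <- matrix(maps, prod(N), C) %*% sk[r, ]
    Fm %*% diag(as.vector(mm))
  }))
  xt <- rand_complex(prod(N), seed = 10)
  xx <- rand_complex(prod(N), seed = 11)
  dense <- Conj(t(Ask)) %*% (Ask %*% (xx - xt)) +
    Conj(t(Amat)) %*% (Amat %*% xt - as.vector(t(y)))
  msk <- apply_sketch(sk, maps = maps)$maps
  anchor <- list(
    x_anchor = array(xt, c(N, 1)),
    full_grad_anchor = normal_op(array(xt, c(N, 1)), maps, list(plan)) -
      sense_adjoint(list(y), maps, list(plan)),
    fresh = TRUE)
  got <- sketched_gradient(array(xx, c(N, 1)), anchor,
                           function(v) normal_op(v, msk, list(plan)))
  expect_lt(max(abs(as.vector(got) - dense)) / max(abs(dense)), 1e-8)
})

test_that("the default schedule runs 5 + 5*6 = 35 iterations and traces them", {
  cfg <- recon_config()
  expect_equal(cfg$n_initial + cfg$n_inner * cfg$n_outer, 35)
  expect_equal(cfg$pdhg_inner, 4L)
  ## the long-reference schedule counts 1000 total iterations
  expect_equal(5 + 5 * 199, 1000)
  fx <- fixture_small()
  res <- sketched_reconstruct(fx$binned, fx$maps,
                              recon_config(regularizer = "lr",
                                           solver = "fista", n_bins = 2,
                                           sketch_coils = 2L, n_initial = 2,
                                           n_inner = 2, n_outer = 2,
                                           pad_factor = 1, seed = 3))
  expect_equal(nrow(res$trace), 2 + 2 * 2)
  expect_true(all(diff(res$trace$seconds) >= 0))
})

test_that("zero data reconstructs to zero", {
  fx <- fixture_small()
  bd <- fx$binned
  bd$kspace <- lapply(bd$kspace, function(m) m * 0)
  res <- sketched_reconstruct(bd, fx$maps,
                              recon_config(regularizer = "lr",
                                           solver = "fista", n_bins = 2,
                                           sketch_coils = 0L, n_initial = 2,
                                           n_inner = 1, n_outer = 1,
                                           pad_factor = 1, svd_reorder = FALSE,
                                           seed = 1))
  expect_true(all(abs(res$images) == 0))
})

test_that("solver cross-checks agree at lambda = 0", {
  fx <- fixture_small()
  cfg <- recon_config(regularizer = "none", lambda = 0, solver = "cg",
                      n_bins = 2, sketch_coils = 0L, seed = 1)
  rcg <- sketched_reconstruct(fx$binned, fx$maps, cfg)
  rfi <- sketched_reconstruct(fx$binned, fx$maps,
                              modifyList(cfg, list(solver = "fista")))
  rpd <- sketched_reconstruct(fx$binned, fx$maps,
                              modifyList(cfg, list(solver = "pdhg")))
  expect_lt(nrmse_masked(rfi$images, rcg$images), 0.01)
  expect_lt(nrmse_masked(rpd$images, rcg$images), 0.01)
})

test_that("objective traces decrease monotonically after burn-in", {
  fx <- fixture_small()
  for (sv in c("cg", "fista", "pdhg")) {
    cfg <- recon_config(regularizer = if (sv == "cg") "none" else "lr",
                        lambda = if (sv == "cg") 0 else 0.1,
                        solver = sv, n_bins = 2, sketch_coils = 2L, seed = 2)
    tr <- sketched_reconstruct(fx$binned, fx$maps, cfg)$trace$objective
    burn <- 5
    wiggle <- diff(tr[-seq_len(burn)]) / tr[-seq_len(burn)][-1]
    expect_lt(max(wiggle), 0.01)
  }
})

test_that("a huge TV penalty smooths the reconstruction", {
  fx <- fixture_small()
  cfg <- recon_config(regularizer = "tv", solver = "pdhg", n_bins = 2,
                      sketch_coils = 0L, n_initial = 2, n_inner = 2,
                      n_outer = 2, seed = 1)
  strong <- sketched_reconstruct(fx$binned, fx$maps,
                                 modifyList(cfg, list(lambda = 1)))
  weak <- sketched_reconstruct(fx$binned, fx$maps,
                               modifyList(cfg, list(lambda = 1e-3)))
  tvn <- function(im) mean(abs(finite_diff(im))^2)
  expect_lt(tvn(strong$images), tvn(weak$images))
})
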