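## Iterative solvers and the coil-sketching driver.
##
## The composite objective is 0.5*||P^(1/2)(F S x - k)||^2 + g(x) with the
## system normalized so the largest eigenvalue of A^H A is 1. The sketched
## data-consistency gradient at outer anchor x_t is
##
##   grad_St(x) = A_St^H A_St (x - x_t) + [A^H A x_t - A^H y],
##
## where the bracketed full-operator term is computed once per outer
## iteration (with coil batching) and cached; at x = x_t the sketched
## gradient equals the full gradient exactly, for any sketch, and under the
## identity sketch it equals the full gradient everywhere.

#' Conjugate gradient for Hermitian positive semidefinite systems
#'
#' @param op Closure applying the system operator H.
#' @param rhs Right-hand side array b.
#' @param n_iter Number of iterations.
#' @param x0 Warm start (zeros if NULL).
#' @param callback Optional function(x, iter) invoked after each iteration.
#' @return Final iterate (same shape as rhs).
#' @export
cg_solve <- function(op, rhs, n_iter, x0 = NULL, callback = NULL) {
  x <- x0 %||% array(0 + 0i, dim(rhs))
  r <- rhs - op(x)
  p <- r
  rs <- Re(inner_prod(r, r))
  for (i in seq_len(n_iter)) {
    if (!is.finite(rs)) stop("CG residual is not finite")
    if (rs <= 0) { if (!is.null(callback)) callback(x, i); next }
    Hp <- op(p)
    alpha <- rs / Re(inner_prod(p, Hp))
    x <- x + alpha * p
    r <- r - alpha * Hp
    rs_new <- Re(inner_prod(r, r))
    p <- r + (rs_new / rs) * p
    rs <- rs_new
    if (!is.null(callback)) callback(x, i)
  }
  x
}

#' FISTA (accelerated proximal gradient) with momentum restart
#'
#' @param grad Closure returning the smooth-part gradient at x.
#' @param prox Closure `function(z, tau)` applying the proximal operator of
#'   `tau * g`.
#' @param x0 Start iterate.
#' @param n_iter Number of iterations.
#' @param step Gradient step size (1 for a normalized system).
#' @param lambda Regularization strength multiplying the prox threshold.
#' @param objective Optional closure for restart-on-increase and tracing.
#' @param callback Optional function(x, iter).
#' @return Final iterate.
#' @export
fista_solve <- function(grad, prox, x0, n_iter, step = 1, lambda = 0,
                        objective = NULL, callback = NULL) {
  x <- x0
  z <- x0
  tk <- 1
  obj_prev <- if (!is.null(objective)) objective(x0) else Inf
  for (i in seq_len(n_iter)) {
    x_new <- prox(z - step * grad(z), step * lambda)
    if (any(!is.finite(x_new))) stop("FISTA iterate diverged (non-finite)")
    restart <- FALSE
    if (!is.null(objective)) {
      obj <- objective(x_new)
      if (obj > 10 * max(obj_prev, .Machine$double.eps) && i > 2)
        stop("FISTA objective diverged")
      restart <- obj > obj_prev
      obj_prev <- min(obj, obj_prev)
    } else {
      restart <- Re(inner_prod(z - x_new, x_new - x)) > 0
    }
    tk_new <- if (restart) 1 else (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- x_new + ((tk - 1) / tk_new) * (x_new - x)
    x <- x_new
    tk <- tk_new
    if (!is.null(callback)) callback(x, i)
  }
  x
}

## Proximal operator of tau * lambda * TV by Chambolle dual iterations.
prox_tv <- function(z, tau, circular_phase = TRUE, n_iter = 20) {
  if (tau <= 0) return(z)
  d <- dim(z)
  naxes <- length(d)
  sigma <- 1 / (4 * naxes)
  p <- array(0 + 0i, c(d, naxes))
  for (i in seq_len(n_iter)) {
    u <- z - finite_diff_adjoint(p, circular_phase)
    g <- finite_diff(u, circular_phase)
    p <- p + sigma * g
    mag <- pmax(abs(p) / tau, 1)
    p <- p / mag
  }
  z - finite_diff_adjoint(p, circular_phase)
}

#' Preconditioned primal-dual hybrid gradient (PDHG)
#'
#' Chambolle-Pock splitting with the nonsmooth regularizer dualized
#' (`g(Kx)`, K the finite-difference operator for TV, identity otherwise)
#' and the smooth, normalized data-consistency term handled inside the
#' primal update by `pdhg_inner` gradient steps on the proximal subproblem.
#'
#' @param grad Closure for the data-consistency gradient.
#' @param reg A [regularizer_spec()].
#' @param x0 Start iterate.
#' @param n_iter Outer PDHG iterations.
#' @param pdhg_inner Gradient steps per primal update (default 4).
#' @param step Scaling of the primal/dual step sizes.
#' @param fields Motion-field table for the mocolr regularizer.
#' @param state Optional environment carrying the dual variable across calls.
#' @param callback Optional function(x, iter).
#' @return Final iterate.
#' @export
pdhg_solve <- function(grad, reg, x0, n_iter, pdhg_inner = 4, step = 1,
                       fields = NULL, state = NULL, callback = NULL) {
  tv <- reg$kind == "tv"
  naxes <- length(dim(x0))
  Lk2 <- if (tv) 4 * naxes else 1
  sigma <- step / sqrt(Lk2)
  tau <- step / sqrt(Lk2)
  eta <- 1 / (1 + 1 / tau)          # data Lipschitz 1 + proximal term
  fenv <- new.env(); fenv$fields <- fields
  proxg <- prox_for(reg, fields_env = fenv)
  x <- x0
  z <- if (!is.null(state) && !is.null(state$z)) state$z
       else if (tv) array(0 + 0i, c(dim(x0), naxes)) else array(0 + 0i, dim(x0))
  xbar <- x
  lam <- reg$lambda
  for (i in seq_len(n_iter)) {
    ## dual ascent on g*(z)
    if (tv) {
      z <- z + sigma * finite_diff(xbar, reg$circular_phase)
      z <- z / pmax(abs(z) / lam, 1)
    } else if (reg$kind != "none" && lam > 0) {
      u <- z + sigma * xbar
      z <- u - sigma * proxg(u / sigma, lam / sigma)
    }
    Ktz <- if (tv) finite_diff_adjoint(z, reg$circular_phase)
           else if (reg$kind != "none" && lam > 0) z else 0
    x_prev <- x
    for (j in seq_len(pdhg_inner))
      x <- x - eta * (grad(x) + Ktz + (x - x_prev) / tau)
    if (any(!is.finite(x))) stop("PDHG iterate diverged (non-finite)")
    xbar <- 2 * x - x_prev
    if (!is.null(state)) state$z <- z
    if (!is.null(callback)) callback(x, i)
  }
  x
}

#' Sketched data-consistency gradient
#'
#' Evaluates `A_St^H A_St (x - x_t) + [A^H A x_t - A^H y]` with the cached
#' full-gradient anchor. At the anchor the result equals the full gradient
#' exactly for any sketch.
#'
#' @param x Current iterate.
#' @param state List with `x_anchor`, `full_grad_anchor`, and `fresh = TRUE`
#'   (set FALSE when the anchor is stale, which is an error).
#' @param sketch_normal Closure applying `A_St^H A_St`.
#' @return Gradient stack.
#' @export
sketched_gradient <- function(x, state, sketch_normal) {
  if (!isTRUE(state$fresh))
    stop("sketched gradient requested with a stale full-gradient anchor")
  sketch_normal(x - state$x_anchor) + state$full_grad_anchor
}

## ---------------------------------------------------------------------------
## Reconstruction system assembly

## Pad the grid, scale coordinates onto the enlarged FOV, build plans,
## preconditioner, normalization, and (optionally) Toeplitz kernels.
build_recon_system <- function(binned, maps, config) {
  N <- as.integer(binned$grid_shape)
  d <- length(N)
  Np <- as.integer(2 * ceiling(N * config$pad_factor / 2))
  scale <- Np / N
  coords <- lapply(binned$coords, function(co)
    sweep(co, 2, scale, `*`))
  plans <- lapply(coords, nufft_plan, grid_shape = Np)
  C <- map_count(maps)
  maps_p <- array(0 + 0i, c(Np, C))
  for (c in seq_len(C))
    maps_p <- set_phase(maps_p, c, pad_center(get_coil(maps, c), Np))
  precond <- switch(config$precond %||% "frobenius",
    frobenius = lapply(coords, kspace_preconditioner, grid_shape = Np),
    dcf = lapply(coords, pipe_menon_dcf, grid_shape = Np),
    none = lapply(plans, function(p) rep(1, p$K)),
    stop("unknown preconditioner kind: ", config$precond))
  ns <- normalize_system(maps_p, plans, precond,
                         seed = derive_seed(config$seed %||% 1L, 5L))
  precond <- ns$precond
  y_pre <- lapply(seq_len(binned$R), function(r)
    sweep(binned$kspace[[r]], 2, sqrt(precond[[r]]), `*`))
  kernels <- if (isTRUE(config$toeplitz))
    lapply(seq_len(binned$R), function(r)
      build_toeplitz_kernel(coords[[r]], precond[[r]], Np))
  list(grid = N, grid_pad = Np, plans = plans, maps = maps_p,
       precond = precond, y_pre = y_pre, kernels = kernels,
       maxeig = ns$maxeig, R = binned$R)
}

## A^H y for (possibly sketched/compressed) maps and RAW k-space data:
## sense_adjoint supplies one sqrt(P), the pre-weighting the other, so the
## result is S^H F^H P k = A^H (P^{1/2} k).
system_ahy <- function(sys, maps, kspace) {
  y_pre <- lapply(seq_len(sys$R), function(r)
    sweep(kspace[[r]], 2, sqrt(sys$precond[[r]]), `*`))
  sense_adjoint(y_pre, maps, sys$plans, sys$precond)
}

## Normal-operator closure for given maps (Toeplitz-accelerated if built).
system_normal <- function(sys, maps, coil_batch = NULL) {
  if (!is.null(sys$kernels)) {
    function(x) apply_toeplitz(x, sys$kernels, maps)
  } else {
    function(x) normal_op(x, maps, sys$plans, sys$precond,
                          coil_batch = coil_batch)
  }
}

#' Full-objective value
#'
#' Data-consistency term with the full (never sketched) operator plus the
#' regularizer value.
#'
#' @param x Image stack on the (padded) reconstruction grid.
#' @param sys Internal system object from the reconstruction driver.
#' @param reg A [regularizer_spec()].
#' @param fields Motion-field table (mocolr only).
#' @return Nonnegative scalar.
#' @keywords internal
system_objective <- function(x, sys, reg, fields = NULL) {
  Ax <- sense_forward(x, sys$maps, sys$plans, sys$precond)
  dc <- 0
  for (r in seq_len(sys$R)) dc <- dc + sum(abs(Ax[[r]] - sys$y_pre[[r]])^2)
  0.5 * dc + regularizer_value(x, reg, fields = fields)
}

## ---------------------------------------------------------------------------
## Reconstruction driver

#' Coil-sketched (or conventional) iterative reconstruction
#'
#' Runs the full solve schedule: `n_initial` iterations on the top-`C_S`
#' SVD-compressed coils (warm start), then `n_outer` outer iterations each
#' drawing a fresh Rademacher sketch, recomputing the full-gradient anchor
#' once with coil batching, and running `n_inner` solver iterations on the
#' sketched subproblem. With `sketch_coils = 0` the same schedule runs with
#' the full operator throughout (the conventional reconstruction); with
#' `compress_coils = C'` the conventional schedule runs on the C'-coil
#' compressed system.
#'
#' @param binned A `binned_kspace`.
#' @param maps Sensitivity array on the acquisition grid (coil-last).
#' @param config A [recon_config()].
#' @param system Optional prebuilt system (from a previous run's `system`
#'   element) to reuse plans, preconditioner, and normalization across
#'   repeated solves of the same trajectory (e.g., pseudo-replicas);
#'   requires `svd_reorder = FALSE` and `compress_coils = 0`.
#' @param trace Record the full objective each iteration (default TRUE;
#'   disable for speed in replica loops).
#' @return List of class `recon_result`: `images` (complex stack cropped to
#'   the acquisition FOV), `images_padded`, `trace` (data.frame with
#'   iteration, objective, seconds), `config`, `basis` (coil reordering),
#'   `maxeig`, `system`.
#' @export
sketched_reconstruct <- function(binned, maps, config, system = NULL,
                                 trace = TRUE) {
  config <- validate_config(config, C = map_count(maps))
  reg <- regularizer_spec(
    kind = if (config$regularizer == "cgsense") "cgsense" else config$regularizer,
    lambda = config$lambda, moco_refresh = config$moco_refresh %||% 0)
  C <- map_count(maps)
  CS <- config$sketch_coils
  t0 <- proc.time()[["elapsed"]]

  ## SVD coil-energy reordering of data and maps (virtual-coil basis)
  basis <- NULL
  if (!is.null(system) &&
      (isTRUE(config$svd_reorder) || config$compress_coils > 0))
    stop("a prebuilt system requires svd_reorder = FALSE and no compression")
  if (isTRUE(config$svd_reorder %||% TRUE)) {
    basis <- svd_reorder(do.call(cbind, binned$kspace))
    binned$kspace <- lapply(binned$kspace, function(m)
      Conj(t(basis$mixing)) %*% m)
    maps <- mix_maps(maps, basis$mixing)
  }
  if (config$compress_coils > 0) {
    cmp <- compress_coils(binned$kspace, maps, config$compress_coils)
    binned$kspace <- cmp$kspace
    maps <- cmp$maps
    C <- config$compress_coils
    if (CS > C) stop("sketch_coils exceeds the compressed coil count")
  }

  sys <- system %||% build_recon_system(binned, maps, config)
  if (!is.null(system))
    sys$y_pre <- lapply(seq_len(binned$R), function(r)
      sweep(binned$kspace[[r]], 2, sqrt(sys$precond[[r]]), `*`))
  full_normal <- system_normal(sys, sys$maps,
                               coil_batch = if (CS > 0) CS else NULL)
  ahy_full <- system_ahy(sys, sys$maps, binned$kspace)
  x <- array(0 + 0i, c(sys$grid_pad, sys$R))

  fenv <- new.env(); fenv$fields <- NULL
  trace_env <- new.env()
  trace_env$rows <- list()
  iter_count <- 0L
  record <- function(xi) {
    iter_count <<- iter_count + 1L
    if (!isTRUE(trace)) return(invisible(NULL))
    obj <- system_objective(xi, sys, reg, fields = fenv$fields)
    trace_env$rows[[iter_count]] <-
      data.frame(iteration = iter_count, objective = obj,
                 seconds = proc.time()[["elapsed"]] - t0)
  }

  use_cg <- config$solver == "cg"
  ## Tikhonov term: folded into the CG system matrix, or handled by the
  ## proximal operator for the first-order solvers (never both).
  lam2 <- if (reg$kind == "cgsense" && use_cg) reg$lambda else 0
  proxfun <- if (!use_cg) {
    if (reg$kind == "tv")
      function(z, tau) prox_tv(z, tau, reg$circular_phase)
    else prox_for(reg, fields_env = fenv)
  }

  run_block <- function(x, n_it, grad, Hop, rhs, step) {
    if (n_it == 0) return(x)
    cb <- function(xi, i) record(xi)
    if (use_cg) {
      cg_solve(Hop, rhs, n_it, x0 = x, callback = cb)
    } else if (config$solver == "fista") {
      fista_solve(grad, proxfun, x, n_it, step = step, lambda = reg$lambda,
                  callback = cb)
    } else {
      pdhg_solve(grad, reg, x, n_it, pdhg_inner = config$pdhg_inner,
                 step = step, fields = fenv$fields, state = pdhg_state,
                 callback = cb)
    }
  }
  pdhg_state <- new.env()

  ## ----- initial phase: SVD-compressed (top-CS) or full
  if (config$n_initial > 0) {
    if (CS > 0) {
      cmp <- compress_coils(binned$kspace, sys$maps, CS)
      normal_i <- system_normal(sys, cmp$maps)
      ahy_i <- system_ahy(sys, cmp$maps, cmp$kspace)
    } else {
      normal_i <- full_normal
      ahy_i <- ahy_full
    }
    grad_i <- function(xi) normal_i(xi) - ahy_i + 2 * lam2 * xi
    Hop_i <- function(xi) normal_i(xi) + 2 * lam2 * xi
    x <- run_block(x, config$n_initial, grad_i, Hop_i, ahy_i, step = 1)
  }

  ## motion fields for mocolr: estimated from the warm start, cached
  refresh_fields <- function(xc) {
    if (reg$kind == "mocolr" && sys$R > 1)
      fenv$fields <- estimate_moco_fields(xc)
  }
  refresh_fields(x)

  sketch_plan <- if (CS > 0)
    build_sketch_plan(C, CS, config$n_outer,
                      seed = derive_seed(config$seed, 7L),
                      identity = isTRUE(config$identity_sketch))

  for (t in seq_len(config$n_outer)) {
    if (reg$kind == "mocolr" && reg$moco_refresh > 0 && t > 1 &&
        (t - 1) %% reg$moco_refresh == 0) refresh_fields(x)
    if (CS > 0) {
      sk <- sketch_plan$sketches[[t]]
      maps_sk <- apply_sketch(sk, maps = sys$maps)$maps
      sk_normal <- system_normal(sys, maps_sk)
      anchor <- list(x_anchor = x,
                     full_grad_anchor = full_normal(x) - ahy_full +
                       2 * lam2 * x,
                     fresh = TRUE)
      grad_t <- function(xi) sketched_gradient(xi, anchor, sk_normal) +
        2 * lam2 * (xi - anchor$x_anchor)
      Hop_t <- function(xi) sk_normal(xi) + 2 * lam2 * xi
      rhs_t <- sk_normal(x) + 2 * lam2 * x - anchor$full_grad_anchor
      ## inner step control: the sketched operator can exceed unit norm
      Lt <- power_method_maxeig(sk_normal, dim(x), n_iter = 8,
                                seed = derive_seed(config$seed, 70L + t))
      x <- run_block(x, config$n_inner, grad_t, Hop_t, rhs_t,
                     step = 1 / max(1, Lt))
    } else {
      grad_f <- function(xi) full_normal(xi) - ahy_full + 2 * lam2 * xi
      Hop_f <- function(xi) full_normal(xi) + 2 * lam2 * xi
      x <- run_block(x, config$n_inner, grad_f, Hop_f, ahy_full, step = 1)
    }
  }

  trace_df <- if (length(trace_env$rows)) do.call(rbind, trace_env$rows)
  structure(list(images = crop_stack(x, sys$grid),
                 images_padded = x, trace = trace_df, config = config,
                 basis = basis, maxeig = sys$maxeig, system = sys),
            class = "recon_result")
}

#' Conventional (full-operator) reconstruction
#'
#' The same schedule as [sketched_reconstruct()] with no sketching.
#'
#' @inheritParams sketched_reconstruct
#' @return A `recon_result`.
#' @export
conventional_reconstruct <- function(binned, maps, config) {
  config$sketch_coils <- 0L
  sketched_reconstruct(binned, maps, config)
}

## Crop the spatial part of a phase-last stack.
crop_stack <- function(x, grid) {
  R <- stack_phases(x)
  out <- array(0 + 0i, c(grid, R))
  for (r in seq_len(R))
    out <- set_phase(out, r, crop_center(get_phase(x, r), grid))
  out
}

#' Objective value of a reconstruction on its own system
#'
#' Rebuilds the (full-operator) system for a configuration and evaluates
#' the composite objective at an arbitrary image stack.
#'
#' @param x Image stack on the padded grid.
#' @param binned A `binned_kspace` (after any coil reordering applied by the
#'   driver, if comparing against a driver trace).
#' @param maps Sensitivity maps matching `binned`.
#' @param config A [recon_config()].
#' @return Scalar objective.
#' @export
objective_value <- function(x, binned, maps, config) {
  config <- validate_config(config, C = map_count(maps))
  reg <- regularizer_spec(kind = if (config$regularizer == "cgsense")
    "cgsense" else config$regularizer, lambda = config$lambda)
  sys <- build_recon_system(binned, maps, config)
  system_objective(x, sys, reg)
}
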