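## The measurement model A = P^{1/2} F S, block-diagonal over respiratory
## phases: per phase r and coil c, sqrt(w_r) * NUFFT(S_c * x_r). Sensitivity
## maps are a complex array with the coil on the LAST dimension; image stacks
## carry the phase on the last dimension; per-phase k-space blocks are
## C x K_r complex matrices.

map_count <- function(maps) dim(maps)[length(dim(maps))]
map_grid <- function(maps) dim(maps)[-length(dim(maps))]
get_coil <- function(maps, c) get_phase(maps, c)   # same phase-last layout

#' SENSE forward operator
#'
#' Applies the coil-weighted, preconditioned non-uniform Fourier encoding
#' to an image stack, phase by phase.
#'
#' @param x Complex image stack (spatial dims x R).
#' @param maps Complex sensitivity array (spatial dims x C).
#' @param plans List of R NUFFT plans, one per respiratory phase.
#' @param precond Optional list of R positive weight vectors (the diagonal
#'   preconditioner P); `sqrt(w)` is applied to the samples. NULL = ones.
#' @return List of R complex C x K_r matrices.
#' @export
sense_forward <- function(x, maps, plans, precond = NULL) {
  R <- stack_phases(x)
  if (length(plans) != R)
    stop("number of NUFFT plans (", length(plans), ") != phase count (", R, ")")
  C <- map_count(maps)
  lapply(seq_len(R), function(r) {
    xr <- get_phase(x, r)
    sw <- if (is.null(precond)) 1 else sqrt(precond[[r]])
    out <- matrix(0 + 0i, C, plans[[r]]$K)
    for (c in seq_len(C))
      out[c, ] <- sw * nufft_forward(get_coil(maps, c) * xr, plans[[r]])
    out
  })
}

#' SENSE adjoint operator
#'
#' Exact adjoint of [sense_forward()].
#'
#' @param y List of R complex C x K_r matrices.
#' @inheritParams sense_forward
#' @return Complex image stack.
#' @export
sense_adjoint <- function(y, maps, plans, precond = NULL) {
  R <- length(plans)
  C <- map_count(maps)
  grid <- plans[[1]]$grid
  x <- array(0 + 0i, c(grid, R))
  for (r in seq_len(R)) {
    sw <- if (is.null(precond)) 1 else sqrt(precond[[r]])
    acc <- array(0 + 0i, grid)
    for (c in seq_len(C))
      acc <- acc + Conj(get_coil(maps, c)) *
        nufft_adjoint(sw * y[[r]][c, ], plans[[r]])
    x <- set_phase(x, r, acc)
  }
  x
}

#' Normal operator A^H A with coil batching
#'
#' Computes `A^H A x` by accumulating over groups of `coil_batch` coils, so
#' peak intermediate storage scales with the batch size rather than the full
#' coil count. The result is independent of the batch size (summation
#' reordering only).
#'
#' @inheritParams sense_forward
#' @param coil_batch Number of coils per group (1..C).
#' @param toeplitz Optional list of R Toeplitz kernels from
#'   [build_toeplitz_kernel()]; when supplied the per-phase normal operator is
#'   evaluated by Cartesian FFTs on the embedded grid instead of paired NUFFTs.
#' @return Complex image stack.
#' @export
normal_op <- function(x, maps, plans, precond = NULL, coil_batch = NULL,
                      toeplitz = NULL) {
  C <- map_count(maps)
  coil_batch <- coil_batch %||% C
  if (coil_batch < 1 || coil_batch > C)
    stop("coil_batch must be in 1..C")
  R <- stack_phases(x)
  grid <- stack_grid(x)
  out <- array(0 + 0i, dim(x))
  groups <- split(seq_len(C), ceiling(seq_len(C) / coil_batch))
  for (r in seq_len(R)) {
    xr <- get_phase(x, r)
    w <- if (is.null(precond)) NULL else precond[[r]]
    acc <- array(0 + 0i, grid)
    for (g in groups) {
      for (c in g) {
        sc <- get_coil(maps, c)
        if (is.null(toeplitz)) {
          s <- nufft_forward(sc * xr, plans[[r]])
          if (!is.null(w)) s <- w * s
          acc <- acc + Conj(sc) * nufft_adjoint(s, plans[[r]])
        } else {
          acc <- acc + Conj(sc) * toeplitz_embed_apply(sc * xr, toeplitz[[r]])
        }
      }
    }
    out <- set_phase(out, r, acc)
  }
  out
}

#' Build a Toeplitz embedding kernel for the per-phase normal operator
#'
#' Precomputes the frequency-domain kernel D on a 2x zero-padded grid such
#' that `crop(IFFT(D * FFT(pad(x))))` equals `F^H P F x` up to NUFFT accuracy.
#' The kernel depends only on the trajectory and the preconditioner weights,
#' not on the coil sensitivities, so one kernel serves the full, compressed,
#' and sketched operators alike.
#'
#' @param coords K x d trajectory coordinates in grid units.
#' @param weights Positive per-sample weights (the full diagonal P, not its
#'   square root). NULL = ones.
#' @param grid_shape Image grid dimensions.
#' @return A kernel object (list with the complex frequency-domain kernel).
#' @export
build_toeplitz_kernel <- function(coords, weights = NULL, grid_shape) {
  N <- as.integer(grid_shape)
  coords <- as.matrix(coords)
  weights <- weights %||% rep(1, nrow(coords))
  plan2 <- nufft_plan(2 * coords, 2L * N)
  psf <- nufft_adjoint(as.complex(weights), plan2)
  list(kernel = fftnd(ifftshift(psf)), grid = N, n2 = 2L * N)
}

## Apply the embedded F^H P F to a single volume.
toeplitz_embed_apply <- function(vol, kern) {
  if (!identical(as.integer(dim(vol)), kern$grid))
    stop("image grid does not match the Toeplitz kernel grid")
  X <- fftnd(ifftshift(pad_center(vol, kern$n2)))
  crop_center(fftshift(ifftnd(X * kern$kernel)), kern$grid)
}

#' Apply the Toeplitz-approximated normal operator
#'
#' Per coil: multiply by the sensitivity, apply the embedded kernel, multiply
#' by the conjugate sensitivity, and sum over coils. No k-space interpolation
#' is performed.
#'
#' @param x Complex image stack.
#' @param kernels List of R kernels from [build_toeplitz_kernel()].
#' @param maps Sensitivity array.
#' @return Complex image stack approximating `A^H A x`.
#' @export
apply_toeplitz <- function(x, kernels, maps) {
  R <- stack_phases(x)
  C <- map_count(maps)
  out <- array(0 + 0i, dim(x))
  for (r in seq_len(R)) {
    xr <- get_phase(x, r)
    acc <- array(0 + 0i, stack_grid(x))
    for (c in seq_len(C)) {
      sc <- get_coil(maps, c)
      acc <- acc + Conj(sc) * toeplitz_embed_apply(sc * xr, kernels[[r]])
    }
    out <- set_phase(out, r, acc)
  }
  out
}

#' Single-channel k-space preconditioner
#'
#' Diagonal k-space weights computed from the trajectory alone, following the
#' Frobenius-optimal diagonal construction: the weight of sample i is
#' `psi(0) / sum_j |psi(k_i - k_j)|^2`, where `psi` is the Fourier transform
#' of the image-domain unit mask. The cross-correlation sum is evaluated with
#' two NUFFTs on a 2x grid. A density-compensation alternative is available
#' via [pipe_menon_dcf()].
#'
#' @param coords K x d trajectory coordinates.
#' @param grid_shape Image grid dimensions.
#' @return Positive weight vector of length K.
#' @export
kspace_preconditioner <- function(coords, grid_shape) {
  N <- as.integer(grid_shape)
  coords <- as.matrix(coords)
  n2 <- 2L * N
  plan2 <- nufft_plan(2 * coords, n2)
  ## PSF of the sampling pattern on the 2x grid
  B <- nufft_adjoint(rep(1 + 0i, nrow(coords)), plan2)
  ## autocorrelation of the unit image mask on the 2x grid
  m <- pad_center(array(1 + 0i, N), n2)
  Mf <- fftnd(ifftshift(m))
  r_ac <- fftshift(ifftnd(abs(Mf)^2))
  q <- Re(nufft_forward(r_ac * B, plan2))
  q <- pmax(q, max(q) * 1e-12)
  prod(N) / q
}

#' Pipe-Menon iterative density compensation
#'
#' Fixed-point iteration `w <- w / (C w)` where `C` is gridding followed by
#' degridding; converges to weights whose gridded density is flat.
#'
#' @inheritParams kspace_preconditioner
#' @param n_iter Number of fixed-point iterations.
#' @return Positive weight vector of length K.
#' @export
pipe_menon_dcf <- function(coords, grid_shape, n_iter = 15) {
  plan <- nufft_plan(as.matrix(coords), as.integer(grid_shape))
  w <- rep(1, plan$K)
  for (i in seq_len(n_iter)) {
    dens <- Re(spmul(plan$G, spmul(plan$Gt, as.complex(w))))
    dens <- pmax(dens, max(dens) * 1e-12)
    w <- w / dens
  }
  w / max(w)
}

#' Maximum-eigenvalue estimate by the power method
#'
#' @param op Closure applying a Hermitian PSD operator to a complex array.
#' @param shape Dimensions of the operator's domain.
#' @param n_iter Maximum number of power iterations (default 100).
#' @param tol Relative change in the Rayleigh quotient at which to stop.
#' @param seed Seed for the random start vector.
#' @return Real scalar estimate of the largest eigenvalue.
#' @export
power_method_maxeig <- function(op, shape, n_iter = 100, tol = 1e-9, seed = 1) {
  v <- with_seed(seed, array(complex(real = rnorm(prod(shape)),
                                     imaginary = rnorm(prod(shape))), shape))
  v <- v / l2norm(v)
  lam <- 0
  for (i in seq_len(n_iter)) {
    w <- op(v)
    nw <- l2norm(w)
    if (nw == 0) stop("power method applied to the zero operator")
    lam_new <- Re(inner_prod(v, w))
    if (i > 1 && abs(lam_new - lam) <= tol * abs(lam_new)) {
      lam <- lam_new
      break
    }
    lam <- lam_new
    v <- w / nw
  }
  lam
}

#' Normalize the encoding system to unit spectral norm
#'
#' Estimates the largest eigenvalue of `A^H A` by the power method and
#' rescales the preconditioner weights so that the rescaled system has
#' maximum eigenvalue 1 (so unit gradient steps are stable).
#'
#' @param maps Sensitivity array.
#' @param plans List of per-phase NUFFT plans.
#' @param precond List of per-phase weight vectors (ones if NULL).
#' @param n_iter Power iterations.
#' @param tol Stopping tolerance of the power method.
#' @param seed Seed for the power method start.
#' @return List with elements `precond` (rescaled weights) and `maxeig`
#'   (the pre-normalization estimate).
#' @export
normalize_system <- function(maps, plans, precond = NULL, n_iter = 60,
                             tol = 1e-7, seed = 1) {
  R <- length(plans)
  precond <- precond %||% lapply(plans, function(p) rep(1, p$K))
  shape <- c(plans[[1]]$grid, R)
  lam <- power_method_maxeig(
    function(v) normal_op(v, maps, plans, precond), shape,
    n_iter = n_iter, tol = tol, seed = seed)
  list(precond = lapply(precond, function(w) w / lam), maxeig = lam)
}
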