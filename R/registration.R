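## Motion operator M: multi-scale Horn-Schunck optical flow on magnitude
## images, and linear-interpolation warping. Fields are displacement arrays
## of shape c(grid, d): voxel x samples the moving image at x + u(x).
## Fields are non-diffeomorphic by design; no inverse field is ever
## computed (the forward-only proximal update depends on this).

## Gaussian smoothing by separable circular FFT convolution.
gauss_smooth <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  d <- dim(vol)
  out <- vol
  for (k in seq_along(d)) {
    n <- d[k]
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    g <- exp(-x^2 / (2 * sigma^2))
    g <- g / sum(g)
    shape <- rep(1L, length(d)); shape[k] <- n
    G <- array(rep(stats::fft(g), each = prod(d[seq_len(k - 1)])), d)
    out <- stats::fft(stats::fft(out) * G, inverse = TRUE) / prod(d)
  }
  if (is.complex(vol)) out else Re(out)
}

## Downsample by 2 (after light smoothing).
pyr_down <- function(vol) {
  d <- dim(vol)
  sm <- Re(gauss_smooth(vol, 0.9))
  nd <- pmax(4L, d %/% 2L)
  pts <- arrayInd(seq_len(prod(nd)), nd)
  for (k in seq_along(d)) pts[, k] <- (pts[, k] - 0.5) * d[k] / nd[k] + 0.5
  array(interp_linear(sm, pts), nd)
}

## Resample a displacement field onto a new grid, scaling displacements.
resize_field <- function(field, newgrid) {
  d <- dim(field)
  nd <- length(d) - 1L
  old <- d[seq_len(nd)]
  pts <- arrayInd(seq_len(prod(newgrid)), newgrid)
  for (k in seq_len(nd)) pts[, k] <- (pts[, k] - 0.5) * old[k] / newgrid[k] + 0.5
  out <- array(0, c(newgrid, nd))
  for (k in seq_len(nd)) {
    comp <- interp_linear(get_phase(field, k), pts) * newgrid[k] / old[k]
    out <- set_phase(out, k, array(comp, newgrid))
  }
  out
}

## Edge-replicated axis shift.
shift_axis <- function(x, k, by) {
  d <- dim(x)
  i <- pmin(pmax(seq_len(d[k]) + by, 1), d[k])
  idx <- rep(list(quote(expr = )), length(d))
  idx[[k]] <- i
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

central_grad <- function(x, k) (shift_axis(x, k, 1) - shift_axis(x, k, -1)) / 2

## Mean of the 2d axis neighbors (edge replicated).
neighbor_mean <- function(x) {
  d <- dim(x)
  acc <- 0
  for (k in seq_along(d)) acc <- acc + shift_axis(x, k, 1) + shift_axis(x, k, -1)
  acc / (2 * length(d))
}

#' Warp a volume by a displacement field
#'
#' Linear-interpolation resampling at `x + u(x)`; out-of-domain samples take
#' edge values. Linear in the image argument for a fixed field; complex
#' volumes are warped by warping real and imaginary parts with the same
#' field.
#'
#' @param volume Real or complex d-dimensional array.
#' @param field Displacement array `c(dim(volume), d)` in voxels.
#' @return Warped array of the same shape as `volume`.
#' @export
warp <- function(volume, field) {
  d <- dim(volume)
  nd <- length(d)
  if (!identical(as.integer(dim(field)), as.integer(c(d, nd))))
    stop("field shape does not match the volume")
  pts <- arrayInd(seq_len(prod(d)), d) * 1.0
  for (k in seq_len(nd)) pts[, k] <- pts[, k] + as.vector(get_phase(field, k))
  array(interp_linear(volume, pts), d)
}

## One pyramid level of warping Horn-Schunck: incremental flow updates
## solved by Jacobi iterations of the regularized normal equations.
hs_level <- function(fixed, moving, u, alpha, n_iter, n_warps) {
  d <- dim(fixed)
  nd <- length(d)
  for (w in seq_len(n_warps)) {
    mw <- warp(moving, u)
    grads <- lapply(seq_len(nd), function(k)
      (central_grad(mw, k) + central_grad(fixed, k)) / 2)
    It <- mw - fixed
    den <- alpha^2
    for (k in seq_len(nd)) den <- den + grads[[k]]^2
    du <- array(0, c(d, nd))
    for (it in seq_len(n_iter)) {
      dbar <- lapply(seq_len(nd), function(k) neighbor_mean(get_phase(du, k)))
      num <- It
      for (k in seq_len(nd)) num <- num + grads[[k]] * dbar[[k]]
      for (k in seq_len(nd))
        du <- set_phase(du, k, dbar[[k]] - grads[[k]] * num / den)
    }
    for (k in seq_len(nd))
      u <- set_phase(u, k,
                     gauss_smooth(get_phase(u, k) + get_phase(du, k), 0.6))
  }
  u
}

#' Estimate a displacement field by multi-scale optical flow
#'
#' Coarse-to-fine Horn-Schunck flow (at least 3 pyramid levels for grids
#' of 32+ voxels) minimizing intensity mismatch with a smoothness penalty.
#' Deterministic given its inputs. Complex inputs are registered on their
#' magnitudes.
#'
#' @param moving Volume to be deformed.
#' @param fixed Target volume.
#' @param alpha Smoothness weight relative to unit-normalized intensities
#'   (default 0.5).
#' @param n_levels Number of pyramid levels (default: automatic, >= 3 when
#'   the grid permits).
#' @param n_iter Jacobi iterations per warp (default 60).
#' @param n_warps Warp updates per level (default 3).
#' @return Displacement array `c(dim(fixed), d)` mapping `moving` onto
#'   `fixed` (voxel x of the result samples `moving` at `x + u(x)`).
#' @export
register <- function(moving, fixed, alpha = 0.5, n_levels = NULL,
                     n_iter = 60, n_warps = 3) {
  if (!identical(dim(moving), dim(fixed)))
    stop("moving and fixed volumes must share a shape")
  moving <- abs(moving); fixed <- abs(fixed)
  top <- max(fixed, moving)
  if (top > 0) { moving <- moving / top; fixed <- fixed / top }
  d <- dim(fixed)
  n_levels <- n_levels %||% max(3L, floor(log2(min(d) / 8)) + 1L)
  pyr_f <- list(fixed); pyr_m <- list(moving)
  for (l in seq_len(n_levels - 1)) {
    if (min(dim(pyr_f[[l]])) <= 6) break
    pyr_f[[l + 1]] <- pyr_down(pyr_f[[l]])
    pyr_m[[l + 1]] <- pyr_down(pyr_m[[l]])
  }
  L <- length(pyr_f)
  u <- array(0, c(dim(pyr_f[[L]]), length(d)))
  for (l in rev(seq_len(L))) {
    if (l < L) u <- resize_field(u, dim(pyr_f[[l]]))
    u <- hs_level(pyr_f[[l]], pyr_m[[l]], u, alpha, n_iter, n_warps)
  }
  if (any(!is.finite(u)))
    stop("registration produced a non-finite displacement field")
  u
}

#' Estimate all-to-reference motion fields for a stack
#'
#' For every reference phase, registers every other phase onto it; the
#' forward-only motion-compensated proximal update consumes the full table.
#'
#' @param x Complex or real image stack (phase-last).
#' @param ... Passed to [register()].
#' @return List over reference phases; element `[[ref]][[p]]` is the field
#'   warping phase p onto phase ref (`[[ref]][[ref]]` is zero).
#' @export
estimate_moco_fields <- function(x, ...) {
  R <- stack_phases(x)
  grid <- stack_grid(x)
  mags <- lapply(seq_len(R), function(p) abs(get_phase(x, p)))
  lapply(seq_len(R), function(ref) {
    lapply(seq_len(R), function(p) {
      if (p == ref) array(0, c(grid, length(grid)))
      else register(mags[[p]], mags[[ref]], ...)
    })
  })
}
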