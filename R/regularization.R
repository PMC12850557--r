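## Regularizers g(x) and their proximal operators: spatio-temporal total
## variation, low-rank (nuclear norm of the Casorati matrix), and
## motion-compensated low-rank with a forward-only proximal update.

#' Describe a regularizer
#'
#' @param kind One of "none", "cgsense" (Tikhonov `lambda*||x||_2^2`), "tv",
#'   "lr", "mocolr".
#' @param lambda Regularization strength (>= 0).
#' @param circular_phase Use circular differences along the phase axis for
#'   TV (breathing is cyclic; default TRUE).
#' @param moco_refresh Outer iterations between motion-field re-estimations
#'   (default 0 = estimate once and cache).
#' @return An object of class `regularizer_spec`.
#' @export
regularizer_spec <- function(kind = c("none", "cgsense", "tv", "lr", "mocolr"),
                             lambda = 0.1, circular_phase = TRUE,
                             moco_refresh = 0) {
  kind <- match.arg(kind)
  if (lambda < 0) stop("lambda must be >= 0")
  structure(list(kind = kind, lambda = lambda,
                 circular_phase = circular_phase,
                 moco_refresh = moco_refresh),
            class = "regularizer_spec")
}

## Zero the last slice along axis k (boundary convention of finite_diff).
zero_last <- function(x, k) {
  d <- dim(x)
  idx <- rep(list(quote(expr = )), length(d))
  idx[[k]] <- d[k]
  do.call(`[<-`, c(list(x), idx, list(value = 0)))
}

shift_circ <- function(x, k, by) {
  d <- dim(x)
  i <- ((seq_len(d[k]) - 1 + by) %% d[k]) + 1
  idx <- rep(list(quote(expr = )), length(d))
  idx[[k]] <- i
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

shift_zero <- function(x, k, by) {
  d <- dim(x)
  i <- seq_len(d[k]) + by
  ok <- i >= 1 & i <= d[k]
  out <- array(0 * x[1], d)
  idx_to <- rep(list(quote(expr = )), length(d))
  idx_from <- idx_to
  idx_to[[k]] <- which(ok)
  idx_from[[k]] <- i[ok]
  do.call(`[<-`, c(list(out), idx_to,
                   list(value = do.call(`[`, c(list(x), idx_from,
                                               list(drop = FALSE))))))
}

#' Spatio-temporal finite differences
#'
#' First differences along each spatial axis (zero at the trailing boundary)
#' and along the phase axis (circular by default). The result gains one
#' trailing dimension indexing the difference axis.
#'
#' @param x Image stack (phase-last).
#' @param circular_phase Circular differences along phase.
#' @return Array `c(dim(x), n_axes)`.
#' @export
finite_diff <- function(x, circular_phase = TRUE) {
  d <- dim(x)
  nd <- length(d)
  out <- array(0 * x[1], c(d, nd))
  for (k in seq_len(nd)) {
    g <- if (k == nd && circular_phase) shift_circ(x, k, 1) - x
         else zero_last(shift_zero(x, k, 1) - x, k)
    out <- set_phase(out, k, g)
  }
  out
}

#' Adjoint of [finite_diff()]
#'
#' @param y Difference stack `c(dim(x), n_axes)`.
#' @param circular_phase Must match the forward call.
#' @return Image stack.
#' @export
finite_diff_adjoint <- function(y, circular_phase = TRUE) {
  d <- dim(y)
  nd <- length(d) - 1L
  out <- array(0 * y[1], d[seq_len(nd)])
  for (k in seq_len(nd)) {
    g <- get_phase(y, k)
    if (k == nd && circular_phase) {
      out <- out + shift_circ(g, k, -1) - g
    } else {
      g <- zero_last(g, k)
      out <- out + shift_zero(g, k, -1) - g
    }
  }
  out
}

#' Complex soft-thresholding (proximal operator of the l1 norm)
#'
#' `z * max(1 - tau/|z|, 0)` elementwise.
#'
#' @param z Complex (or real) array.
#' @param tau Threshold (>= 0).
#' @return Shrunk array.
#' @export
prox_l1 <- function(z, tau) {
  if (tau < 0) stop("tau must be >= 0")
  if (tau == 0) return(z)
  a <- abs(z)
  z * ifelse(a > tau, 1 - tau / pmax(a, .Machine$double.xmin), 0)
}

#' Singular-value soft-thresholding (proximal operator of the nuclear norm)
#'
#' Exact minimizer of `0.5*||X - Y||_F^2 + tau*||X||_*`: the SVD of Y with
#' singular values shrunk by tau.
#'
#' @param Y Complex matrix (phases x voxels Casorati reshape).
#' @param tau Threshold (>= 0).
#' @return Matrix of the same shape.
#' @export
prox_nuclear <- function(Y, tau) {
  if (tau < 0) stop("tau must be >= 0")
  if (tau == 0) return(Y)
  sv <- svd(Y)
  s <- pmax(sv$d - tau, 0)
  keep <- s > 0
  if (!any(keep)) return(Y * 0)
  sv$u[, keep, drop = FALSE] %*%
    (s[keep] * Conj(t(sv$v[, keep, drop = FALSE])))
}

#' Forward-only motion-compensated low-rank proximal update
#'
#' For each reference phase in turn: warp every phase onto the reference
#' with forward fields only, soft-threshold the singular values of the
#' aligned Casorati matrix, and keep only the reference row of the result.
#' No inverse deformation is ever applied, which keeps the update stable
#' when the fields are non-diffeomorphic. With identity motion this reduces
#' exactly to [prox_nuclear()] assembled row by row.
#'
#' @param x Complex image stack (phase-last).
#' @param tau Singular-value threshold.
#' @param fields Motion-field table as returned by [estimate_moco_fields()]
#'   (`fields[[ref]][[p]]` warps phase p onto ref); estimated from the
#'   magnitude of `x` when NULL.
#' @return Updated image stack.
#' @export
moco_lr_prox <- function(x, tau, fields = NULL) {
  R <- stack_phases(x)
  grid <- stack_grid(x)
  if (R == 1) {
    Y <- as_casorati(x)
    return(from_casorati(prox_nuclear(Y, tau), grid))
  }
  fields <- fields %||% estimate_moco_fields(x)
  out <- array(0 + 0i, dim(x))
  for (ref in seq_len(R)) {
    aligned <- array(0 + 0i, dim(x))
    for (p in seq_len(R)) {
      f <- fields[[ref]][[p]]
      if (any(!is.finite(f)))
        stop("non-finite motion field for phase pair (", p, ", ", ref, ")")
      aligned <- set_phase(aligned, p,
                           if (p == ref) get_phase(x, p)
                           else warp(get_phase(x, p), f))
    }
    Xs <- prox_nuclear(as_casorati(aligned), tau)
    out <- set_phase(out, ref, array(Xs[ref, ], grid))
  }
  out
}

#' Value of the regularization term
#'
#' `lambda*||Gx||_1`, `lambda*||x||_2^2`, `lambda*||x||_*`, or
#' `lambda*||Mx||_*` (aligned to phase 1, a fixed reporting reference).
#'
#' @param x Image stack.
#' @param spec A [regularizer_spec()].
#' @param fields Motion-field table (mocolr only).
#' @return Nonnegative scalar.
#' @export
regularizer_value <- function(x, spec, fields = NULL) {
  lam <- spec$lambda
  switch(spec$kind,
    none = 0,
    cgsense = lam * sum(abs(x)^2),
    tv = lam * sum(abs(finite_diff(x, spec$circular_phase))),
    lr = lam * sum(svd(as_casorati(x), nu = 0, nv = 0)$d),
    mocolr = {
      R <- stack_phases(x)
      if (R == 1) return(lam * sum(svd(as_casorati(x), nu = 0, nv = 0)$d))
      fields <- fields %||% estimate_moco_fields(x)
      aligned <- array(0 + 0i, dim(x))
      for (p in seq_len(R))
        aligned <- set_phase(aligned, p,
                             if (p == 1) get_phase(x, p)
                             else warp(get_phase(x, p), fields[[1]][[p]]))
      lam * sum(svd(as_casorati(aligned), nu = 0, nv = 0)$d)
    })
}

## Proximal operator dispatch: returns function(z, tau) for the regularizer,
## or NULL when the prox is not separable/closed-form (tv handled by its own
## dual machinery in the solvers).
prox_for <- function(spec, fields_env = NULL) {
  switch(spec$kind,
    none = function(z, tau) z,
    cgsense = function(z, tau) z / (1 + 2 * tau),
    lr = function(z, tau)
      from_casorati(prox_nuclear(as_casorati(z), tau), stack_grid(z)),
    mocolr = function(z, tau)
      moco_lr_prox(z, tau, fields = if (!is.null(fields_env)) fields_env$fields),
    tv = NULL)
}
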