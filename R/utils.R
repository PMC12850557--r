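#' @useDynLib coilsketch, .registration = TRUE
#' @importFrom stats fft rnorm runif approx optimize sd
#' @importFrom utils head tail modifyList write.csv
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators behave as pure
#' functions of their arguments and do not disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stream-specific 31-bit sub-seed from a master seed (double
## arithmetic stays exact well beyond the 31-bit range used here).
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %%
               2147480783)
}

## A block of independent sub-seeds drawn through the RNG itself: linearly
## related seeds leave Mersenne-Twister initialization artifacts in the
## first draws of each stream, which biases Monte-Carlo aggregates across
## many streams (fresh sketches, noise replicas).
sub_seeds <- function(seed, n, salt = 0L) {
  with_seed(derive_seed(seed, salt), sample.int(2147483646L, n))
}

## Circular shift of an array along every dimension.
circshift <- function(x, shift) {
  d <- dim(x) %||% length(x)
  idx <- lapply(seq_along(d), function(i) {
    s <- shift[i] %% d[i]
    if (s == 0) seq_len(d[i]) else c((d[i] - s + 1):d[i], seq_len(d[i] - s))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

## DC-centred <-> FFT-order conversions. Grids are even in all internal uses,
## where the two shifts coincide; both directions kept for clarity.
fftshift  <- function(x) circshift(x, floor((dim(x) %||% length(x)) / 2))
ifftshift <- function(x) circshift(x, ceiling((dim(x) %||% length(x)) / 2))

fftnd  <- function(x) stats::fft(x)
ifftnd <- function(x) stats::fft(x, inverse = TRUE) / length(x)

## Zero-pad an array into the centre of a larger grid (centre voxel
## floor(N/2) maps onto floor(M/2)).
pad_center <- function(x, newdim) {
  d <- dim(x)
  out <- array(0 + 0i, newdim)
  off <- floor(newdim / 2) - floor(d / 2)
  idx <- lapply(seq_along(d), function(i) off[i] + seq_len(d[i]))
  out <- do.call(`[<-`, c(list(out), idx, list(value = x)))
  out
}

crop_center <- function(x, newdim) {
  d <- dim(x)
  off <- floor(d / 2) - floor(newdim / 2)
  idx <- lapply(seq_along(newdim), function(i) off[i] + seq_len(newdim[i]))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

## Multilinear interpolation of a (real or complex) d-dimensional array at
## arbitrary points (n x d matrix, 1-based voxel coordinates). Out-of-domain
## points take edge values.
interp_linear <- function(vol, pts) {
  d <- dim(vol)
  nd <- length(d)
  pts <- pmin(pmax(pts, 1), matrix(d, nrow(pts), nd, byrow = TRUE))
  lo <- floor(pts)
  lo <- pmin(lo, matrix(d - 1L, nrow(pts), nd, byrow = TRUE))
  lo <- pmax(lo, 1)
  fr <- pts - lo
  out <- if (is.complex(vol)) complex(nrow(pts)) else numeric(nrow(pts))
  strides <- cumprod(c(1, d[-nd]))
  for (corner in 0:(2^nd - 1)) {
    bits <- as.integer(intToBits(corner))[seq_len(nd)]
    w <- rep(1, nrow(pts))
    idx <- rep(1, nrow(pts))
    for (k in seq_len(nd)) {
      w <- w * if (bits[k] == 1L) fr[, k] else 1 - fr[, k]
      idx <- idx + (lo[, k] - 1 + bits[k]) * strides[k]
    }
    out <- out + w * vol[idx]
  }
  out
}

#' Image-stack helpers
#'
#' Image stacks (and coil-map sets) are plain arrays whose LAST dimension
#' indexes the respiratory phase (or coil). `stack_grid`/`stack_phases`
#' read off the spatial grid and phase count; `get_phase`/`set_phase`
#' extract or replace one slice; `as_casorati` reshapes a stack into the
#' phases-x-voxels Casorati matrix that rank penalties act on, and
#' `from_casorati` inverts it.
#'
#' @param x Array with the phase/coil on the last dimension.
#' @param r Slice index.
#' @param value Replacement slice.
#' @param m Casorati matrix (phases x voxels).
#' @param grid Spatial dimensions.
#' @name stack-helpers
NULL

#' @rdname stack-helpers
#' @export
stack_grid <- function(x) {
  d <- dim(x); d[-length(d)]
}

#' @rdname stack-helpers
#' @export
stack_phases <- function(x) {
  d <- dim(x); d[length(d)]
}

#' @rdname stack-helpers
#' @export
get_phase <- function(x, r) {
  d <- dim(x)
  idx <- c(rep(list(quote(expr = )), length(d) - 1), list(r))
  arr <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  array(arr, d[-length(d)])
}
#' @rdname stack-helpers
#' @export
set_phase <- function(x, r, value) {
  d <- dim(x)
  idx <- c(rep(list(quote(expr = )), length(d) - 1), list(r))
  do.call(`[<-`, c(list(x), idx, list(value = value)))
}

#' @rdname stack-helpers
#' @export
as_casorati <- function(x) {
  d <- dim(x)
  t(matrix(x, prod(d[-length(d)]), d[length(d)]))
}
#' @rdname stack-helpers
#' @export
from_casorati <- function(m, grid) {
  array(t(m), c(grid, nrow(m)))
}

l2norm <- function(x) sqrt(sum(abs(x)^2))

inner_prod <- function(a, b) sum(Conj(a) * b)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
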