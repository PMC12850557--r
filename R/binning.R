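## Respiratory self-navigation: instantaneous phase of the navigator by the
## analytic signal, followed by retrospective sorting of whole readouts into
## R equal-width phase bins on [-pi, pi).

#' Instantaneous phase of a navigator series (Hilbert transform)
#'
#' Mean-removes the series, forms the analytic signal by one-sided spectral
#' weighting, and returns its argument.
#'
#' @param navigator Real series, length >= 8.
#' @return Phase series in `[-pi, pi)`.
#' @export
hilbert_phase <- function(navigator) {
  n <- length(navigator)
  if (n < 8) stop("navigator series must have at least 8 samples")
  x <- navigator - mean(navigator)
  if (max(abs(x)) == 0)
    stop("navigator series is constant; instantaneous phase is undefined")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  analytic <- stats::fft(X * h, inverse = TRUE) / n
  Arg(analytic)
}

## Unwrap a phase series (cumulative removal of 2*pi jumps).
unwrap_phase <- function(phi) {
  dp <- diff(phi)
  jumps <- -2 * pi * cumsum(round(dp / (2 * pi)))
  c(phi[1], phi[-1] + jumps)
}

#' Assign readouts to respiratory bins
#'
#' The navigator phase is unwrapped, linearly interpolated to each readout's
#' start time, re-wrapped, and assigned to one of R equal-width bins on
#' `[-pi, pi)`. Readout times outside the navigator span take the nearest
#' navigator phase (with a warning).
#'
#' @param phases Navigator phase series from [hilbert_phase()].
#' @param R Number of respiratory bins.
#' @param navigator_time Timestamps (ms) of the phase series.
#' @param readout_times Start time (ms) of each readout.
#' @param flip If TRUE negate the phase (swaps the inhale/exhale sign
#'   convention).
#' @return Integer bin per readout (1..R).
#' @export
assign_bins <- function(phases, R, navigator_time, readout_times,
                        flip = FALSE) {
  if (R < 1) stop("R must be >= 1")
  if (R == 1) return(rep(1L, length(readout_times)))
  if (any(readout_times < min(navigator_time) |
          readout_times > max(navigator_time)))
    warning("readout times outside the navigator span; ",
            "using nearest-neighbor extrapolation")
  up <- unwrap_phase(phases)
  phi <- stats::approx(navigator_time, up, xout = readout_times,
                       rule = 2)$y
  phi <- wrap_phase(phi)
  if (flip) phi <- wrap_phase(-phi)
  phase_to_bin(phi, R)
}

#' Sort raw k-space into respiratory phases
#'
#' Partitions samples and coordinates by the bin of their readout. Counts are
#' conserved; an empty bin is an error (a phase with no data cannot be
#' reconstructed).
#'
#' @param raw A `raw_dataset`.
#' @param bin_of_readout Integer bin (1..R) per readout.
#' @param R Number of bins.
#' @return A list of class `binned_kspace`: `kspace` (list of R C x K_r
#'   matrices), `coords` (list of R K_r x d matrices), `bin_of_readout`, `R`,
#'   and `grid_shape`.
#' @export
bin_dataset <- function(raw, bin_of_readout, R) {
  n_readouts <- length(unique(raw$readout_id))
  if (length(bin_of_readout) != n_readouts)
    stop("bin assignment covers ", length(bin_of_readout),
         " readouts but the dataset has ", n_readouts)
  bin_of_sample <- bin_of_readout[raw$readout_id]
  kspace <- vector("list", R)
  coords <- vector("list", R)
  for (r in seq_len(R)) {
    sel <- which(bin_of_sample == r)
    if (length(sel) == 0)
      stop("respiratory bin ", r, " is empty; reconstruction is undefined")
    kspace[[r]] <- raw$kspace[, sel, drop = FALSE]
    coords[[r]] <- raw$coords[sel, , drop = FALSE]
  }
  structure(list(kspace = kspace, coords = coords,
                 bin_of_readout = as.integer(bin_of_readout), R = as.integer(R),
                 grid_shape = raw$meta$grid_shape),
            class = "binned_kspace")
}

#' Bin occupancy table
#'
#' @param binned A `binned_kspace`.
#' @return Integer vector of per-bin sample counts.
#' @export
bin_occupancy <- function(binned) {
  vapply(binned$kspace, ncol, integer(1))
}
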