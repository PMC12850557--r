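## Free-breathing stack-of-spirals acquisition simulator.
##
## The respiratory cycle is the sinusoid d(t) = A*sin(2*pi*t/T). Its analytic
## -signal (Hilbert) phase is phi(t) = wrap(2*pi*t/T - pi/2), and the
## generator assigns every readout to the bin of phi at the readout start
## time -- the same equal-width [-pi, pi) bins used by the retrospective
## binning stage, so navigator-driven binning can be checked against the
## generating schedule.

golden_angle_rad <- 2 * pi * 2 / (1 + sqrt(5))  # ~222.4922 degrees

wrap_phase <- function(phi) (phi + pi) %% (2 * pi) - pi

resp_phase_at <- function(t_ms, period_ms) {
  wrap_phase(2 * pi * t_ms / period_ms - pi / 2)
}

#' Map respiratory phases to equal-width bins
#'
#' Bin b (1-based) covers `[-pi + (b-1)*2*pi/R, -pi + b*2*pi/R)`.
#'
#' @param phi Phases in `[-pi, pi)`.
#' @param R Number of bins.
#' @return Integer bin indices in 1..R.
#' @export
phase_to_bin <- function(phi, R) {
  pmin(pmax(floor((phi + pi) / (2 * pi / R)), 0), R - 1) + 1L
}

#' Stack-of-spirals (or 2-D spiral) trajectory
#'
#' Archimedean spiral interleaves rotated by the golden angle
#' (~222.4922 degrees) between successive readouts, replicated across kz
#' partitions for 3-D grids. Coordinates are in grid units and reach the
#' Nyquist box edge.
#'
#' @param n_interleaves In-plane interleaves per kz partition (the acquisition
#'   this emulates uses 397).
#' @param n_kz Number of kz partitions (1 for a 2-D grid).
#' @param grid_shape 2 or 3 image dimensions.
#' @param golden_angle If TRUE rotate successive interleaves by the golden
#'   angle; if FALSE use uniform rotations `2*pi*i/n_interleaves`.
#' @param samples_per_interleaf Readout length; default scales with grid size.
#' @param TR_ms Repetition time between readouts (default 8.3 ms).
#' @param readout_ms Duration of one readout (default 5.4 ms).
#' @return A list of class `trajectory`: `coords` (K x d), `readout_id`,
#'   `time` (ms, nondecreasing within a readout), and the generation
#'   parameters.
#' @export
make_stack_of_spirals <- function(n_interleaves = 397, n_kz = 1,
                                  grid_shape = c(64, 64),
                                  golden_angle = TRUE,
                                  samples_per_interleaf = NULL,
                                  TR_ms = 8.3, readout_ms = 5.4) {
  if (n_interleaves < 1) stop("n_interleaves must be >= 1")
  N <- as.integer(grid_shape)
  d <- length(N)
  if (d == 2 && n_kz != 1) stop("a 2-D grid requires n_kz = 1")
  nxy <- min(N[1:2])
  n_turns <- max(1, ceiling(nxy / 2 / n_interleaves))
  K_per <- samples_per_interleaf %||% max(64L, as.integer(4 * nxy * n_turns))
  rmax <- nxy / 2 - 0.5
  tau <- seq(0, 1, length.out = K_per)
  n_shots <- n_interleaves * n_kz
  coords <- matrix(0, n_shots * K_per, d)
  readout_id <- rep(seq_len(n_shots), each = K_per)
  time <- rep((seq_len(n_shots) - 1) * TR_ms, each = K_per) +
    rep(seq(0, readout_ms, length.out = K_per), n_shots)
  for (s in seq_len(n_shots)) {
    i_rot <- if (golden_angle) s - 1 else (s - 1) %% n_interleaves
    rot <- if (golden_angle) i_rot * golden_angle_rad
           else 2 * pi * i_rot / n_interleaves
    th <- 2 * pi * n_turns * tau + rot
    rows <- (s - 1) * K_per + seq_len(K_per)
    coords[rows, 1] <- rmax * tau * cos(th)
    coords[rows, 2] <- rmax * tau * sin(th)
    if (d == 3) {
      kz_idx <- (s - 1) %/% n_interleaves
      coords[rows, 3] <- (kz_idx - floor(n_kz / 2)) * (N[3] / n_kz)
    }
  }
  structure(list(coords = coords, readout_id = readout_id, time = time,
                 n_interleaves = n_interleaves, n_kz = n_kz,
                 grid_shape = N, samples_per_interleaf = K_per,
                 TR_ms = TR_ms, readout_ms = readout_ms,
                 golden_angle = golden_angle),
            class = "trajectory")
}

#' Simulate a superior-inferior navigator series
#'
#' Quasi-periodic diaphragm-position trace `A*sin(2*pi*t/T)` sampled every
#' `interval_ms` (default 120 ms), plus Gaussian noise.
#'
#' @param amplitude Peak SI excursion (same units as the phantom's
#'   diaphragm_amplitude, voxels).
#' @param period_ms Breathing period (default 4000 ms).
#' @param duration_ms Total acquisition duration.
#' @param interval_ms Navigator cadence (default 120 ms).
#' @param noise_sd Gaussian noise SD added to the trace.
#' @param seed Integer seed.
#' @return List with `value` and `time` (ms).
#' @export
simulate_navigator <- function(amplitude, period_ms = 4000, duration_ms,
                               interval_ms = 120, noise_sd = 0, seed = 1) {
  if (interval_ms <= 0) stop("interval_ms must be positive")
  t <- seq(0, duration_ms, by = interval_ms)
  v <- amplitude * sin(2 * pi * t / period_ms)
  if (noise_sd > 0) v <- v + with_seed(seed, rnorm(length(t), sd = noise_sd))
  list(value = v, time = t)
}

#' Simulate a multicoil non-Cartesian acquisition of a dynamic phantom
#'
#' Each readout is assigned a respiratory phase from its start time and the
#' sinusoidal motion schedule; its samples are the forward NUFFT of that
#' phase's coil-weighted image plus independent complex Gaussian noise.
#'
#' @param phantom A [make_dynamic_phantom()] result.
#' @param maps Sensitivity array `c(grid, C)`.
#' @param traj A [make_stack_of_spirals()] trajectory.
#' @param noise_sd SD of the complex noise per sample (real and imaginary
#'   parts each have SD `noise_sd/sqrt(2)`).
#' @param seed Integer seed for the noise.
#' @param period_ms Breathing period of the motion schedule (default 4000).
#' @param nav_noise_sd Noise SD of the simulated navigator trace.
#' @param image_override Optional complex stack replacing the phantom images
#'   (e.g., a delta image for point-spread tests).
#' @return A list of class `raw_dataset`: `kspace` (C x K_total), `coords`,
#'   `readout_id`, `time`, `navigator`, `navigator_time`, `noise_sigma`,
#'   `true_bins` (the generating schedule, per readout), and `meta`.
#' @export
simulate_acquisition <- function(phantom, maps, traj, noise_sd = 0, seed = 1,
                                 period_ms = 4000, nav_noise_sd = 0,
                                 image_override = NULL) {
  images <- image_override %||% phantom$images
  N <- stack_grid(images)
  R <- stack_phases(images)
  if (ncol(traj$coords) != length(N))
    stop("trajectory dimensionality (", ncol(traj$coords),
         ") does not match the phantom (", length(N), ")")
  C <- map_count(maps)
  start_t <- tapply(traj$time, traj$readout_id, min)
  true_bins <- phase_to_bin(resp_phase_at(as.numeric(start_t), period_ms), R)
  bin_of_sample <- true_bins[traj$readout_id]

  K_total <- nrow(traj$coords)
  kspace <- matrix(0 + 0i, C, K_total)
  for (p in sort(unique(bin_of_sample))) {
    sel <- which(bin_of_sample == p)
    plan <- nufft_plan(traj$coords[sel, , drop = FALSE], N)
    xp <- get_phase(images, p)
    for (c in seq_len(C))
      kspace[c, sel] <- nufft_forward(get_coil(maps, c) * xp, plan)
  }
  if (noise_sd > 0) {
    noise <- with_seed(derive_seed(seed, 11L),
      matrix(complex(real = rnorm(C * K_total, sd = noise_sd / sqrt(2)),
                     imaginary = rnorm(C * K_total, sd = noise_sd / sqrt(2))),
             C, K_total))
    kspace <- kspace + noise
  }
  amp <- phantom$spec$diaphragm_amplitude %||% 1
  nav <- simulate_navigator(amplitude = if (amp > 0) amp else 1,
                            period_ms = period_ms,
                            duration_ms = max(traj$time),
                            noise_sd = nav_noise_sd,
                            seed = derive_seed(seed, 12L))
  structure(list(kspace = kspace, coords = traj$coords,
                 readout_id = traj$readout_id, time = traj$time,
                 navigator = nav$value, navigator_time = nav$time,
                 noise_sigma = noise_sd, true_bins = as.integer(true_bins),
                 meta = list(grid_shape = N, n_coils = C, n_phases = R,
                             seed = as.integer(seed), period_ms = period_ms)),
            class = "raw_dataset")
}
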