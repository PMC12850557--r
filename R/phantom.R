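## Seeded analytic lung phantom.
##
## Geometry is rasterized from ellipses/spheres so that the ground-truth
## motion fields are known in closed form. Axis convention: the LAST spatial
## axis is superior-inferior (SI), with increasing index running toward the
## diaphragm (inferior). Respiratory motion is an SI translation plus uniform
## SI scaling of each lung about its (fixed) apex: at phase p the diaphragm
## is displaced by `diaphragm_amplitude * sin(2*pi*(p-1)/R)` voxels and lung
## intensity is scaled by the inverse of the SI stretch, so total lung signal
## ("mass") is conserved across phases.

#' Specify a dynamic lung phantom
#'
#' @param grid_shape 2 or 3 spatial dimensions (voxels), each >= 16.
#' @param n_phases Number of respiratory phases R (>= 1).
#' @param diaphragm_amplitude Peak SI diaphragm displacement in voxels.
#' @param lung_intensity Baseline parenchyma level relative to torso = 1.
#' @param n_cysts Number of zero-intensity spherical inclusions.
#' @param vessel_density Fraction of lung voxels carrying bright vessel
#'   texture.
#' @param seed Integer RNG seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64), n_phases = 6,
                         diaphragm_amplitude = 4, lung_intensity = 0.35,
                         n_cysts = 3, vessel_density = 0.03, seed = 1) {
  grid_shape <- as.integer(grid_shape)
  if (!length(grid_shape) %in% c(2, 3))
    stop("grid_shape must have 2 or 3 dimensions")
  for (k in seq_along(grid_shape))
    if (grid_shape[k] < 16)
      stop("grid dimension ", k, " is ", grid_shape[k],
           "; at least 16 voxels are needed to contain the anatomy")
  if (n_phases < 1) stop("n_phases must be >= 1")
  if (lung_intensity <= 0 || lung_intensity >= 1)
    stop("lung_intensity must lie strictly between 0 and 1")
  structure(list(grid_shape = grid_shape, n_phases = as.integer(n_phases),
                 diaphragm_amplitude = diaphragm_amplitude,
                 lung_intensity = lung_intensity, n_cysts = as.integer(n_cysts),
                 vessel_density = vessel_density, seed = as.integer(seed)),
            class = "phantom_spec")
}

## Smoothed ellipse membership: ~1 inside, ~0 outside, smooth over ~1.5 vox.
ellipse_weight <- function(coords, center, semi, edge = 1.5) {
  q <- 0
  for (k in seq_along(center)) q <- q + ((coords[[k]] - center[k]) / semi[k])^2
  t <- (1 - sqrt(q)) * min(semi) / edge
  w <- pmin(pmax(t + 0.5, 0), 1)
  w * w * (3 - 2 * w)
}

## Internal geometry shared by the generator and its ground-truth fields.
phantom_geometry <- function(spec) {
  N <- spec$grid_shape
  d <- length(N)
  nsi <- N[d]
  nx <- N[1]
  ctr <- N / 2 + 0.5
  lung_dx <- 0.17 * nx
  semi_x <- 0.13 * nx
  b0 <- 0.26 * nsi
  c0 <- ctr[d] + 0.04 * nsi
  torso_semi <- 0.42 * N
  torso_semi[d] <- 0.44 * nsi
  list(N = N, d = d, ctr = ctr,
       torso_center = ctr, torso_semi = torso_semi,
       lung_centers = list(c(ctr[1] - lung_dx, if (d == 3) ctr[2], c0),
                           c(ctr[1] + lung_dx, if (d == 3) ctr[2], c0)),
       lung_semi = c(semi_x, if (d == 3) 0.13 * N[2], b0),
       b0 = b0, c0 = c0, top = c0 - b0)
}

## Diaphragm displacement (voxels) for phase p of R.
diaphragm_shift <- function(p, R, amplitude) {
  amplitude * sin(2 * pi * (p - 1) / R)
}

#' Generate a dynamic lung phantom with analytic ground truth
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `dynamic_phantom` with elements `images` (complex
#'   stack, phase-last), `true_fields` (list of per-phase displacement arrays
#'   `c(grid, d)` mapping each phase onto phase 1; `warp(images[,,1],
#'   true_fields[[p]])` times the density factor `si_scale[p]` reproduces
#'   phase p inside the lung), `lung_mask` (logical interior lung mask,
#'   phase-last), `si_scale` (per-phase SI density factor), and `spec`.
#' @export
make_dynamic_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_geometry(spec)
  N <- g$N; d <- g$d; R <- spec$n_phases
  J <- prod(N)
  idx <- arrayInd(seq_len(J), N)
  coords <- lapply(seq_len(d), function(k) idx[, k])

  rng <- with_seed(spec$seed, {
    lung_pick <- sample(1:2, spec$n_cysts + 200, replace = TRUE)
    un <- matrix(runif((spec$n_cysts + 200) * d, -0.65, 0.65), ncol = d)
    phase_coef <- rnorm(6 + 4 * (d == 3), sd = 0.18)
    list(lung_pick = lung_pick, un = un, phase_coef = phase_coef)
  })

  ## features fixed in phase-1 (material) coordinates
  feat_center <- function(i) {
    cen <- g$lung_centers[[rng$lung_pick[i]]]
    cen + rng$un[i, ] * g$lung_semi
  }
  n_vessels <- round(spec$vessel_density * prod(g$lung_semi) * 2 * pi / 4)
  n_vessels <- min(n_vessels, 200 - spec$n_cysts)
  cyst_r <- max(2, 0.03 * min(N))
  vessel_r <- 1.4

  poly_phase <- function(pts) {
    u <- lapply(seq_len(d), function(k) 2 * (pts[[k]] - g$ctr[k]) / N[k])
    cf <- rng$phase_coef
    ph <- cf[1] + cf[2] * u[[1]] + cf[3] * u[[d]] + cf[4] * u[[1]] * u[[d]] +
      cf[5] * u[[1]]^2 + cf[6] * u[[d]]^2
    if (d == 3) ph <- ph + cf[7] * u[[2]] + cf[8] * u[[2]]^2 +
      cf[9] * u[[1]] * u[[2]] + cf[10] * u[[2]] * u[[d]]
    ph
  }

  ## lung interior content in material coordinates (before density scaling)
  lung_content <- function(pts, lung) {
    val <- rep(spec$lung_intensity, length(pts[[1]]))
    for (i in seq_len(spec$n_cysts + n_vessels)) {
      if (rng$lung_pick[i] != lung) next
      cen <- feat_center(i)
      q2 <- 0
      for (k in seq_len(d)) q2 <- q2 + (pts[[k]] - cen[k])^2
      if (i <= spec$n_cysts) {
        w <- ellipse_weight(pts, cen, rep(cyst_r, d), edge = 1)
        val <- val * (1 - w)
      } else {
        val <- val + 0.55 * exp(-q2 / (2 * vessel_r^2))
      }
    }
    val
  }

  torso_w <- ellipse_weight(coords, g$torso_center, g$torso_semi)
  images <- array(0 + 0i, c(N, R))
  lung_mask <- array(FALSE, c(N, R))
  true_fields <- vector("list", R)

  for (p in seq_len(R)) {
    dp <- diaphragm_shift(p, R, spec$diaphragm_amplitude)
    bp <- g$b0 + dp / 2
    scale_si <- g$b0 / bp            # SI pull-back slope and density factor
    val <- torso_w * (1 + 0i) * exp(1i * poly_phase(coords))
    mask_p <- rep(FALSE, J)
    field_si <- rep(0, J)
    for (lung in 1:2) {
      cen <- g$lung_centers[[lung]]
      cen_p <- cen; cen_p[d] <- cen[d] + dp / 2
      semi_p <- g$lung_semi; semi_p[d] <- bp
      wl <- ellipse_weight(coords, cen_p, semi_p)
      inside <- wl > 0
      if (!any(inside)) next
      pts0 <- lapply(coords, function(v) v[inside])
      y0 <- g$top + (pts0[[d]] - g$top) * scale_si
      pts0[[d]] <- y0
      content <- lung_content(pts0, lung) * scale_si *
        exp(1i * poly_phase(pts0))
      val[inside] <- val[inside] * (1 - wl[inside]) + wl[inside] * content
      mask_p <- mask_p | (wl > 0.995)
      field_si[inside] <- field_si[inside] +
        (y0 - coords[[d]][inside]) * (wl[inside] > 0.5)
    }
    images <- set_phase(images, p, array(val, N))
    lung_mask <- set_phase(lung_mask, p, array(mask_p, N))
    fld <- array(0, c(N, d))
    fld <- set_phase(fld, d, array(field_si, N))
    true_fields[[p]] <- fld
  }

  si_scale <- vapply(seq_len(R), function(p) {
    dp <- diaphragm_shift(p, R, spec$diaphragm_amplitude)
    g$b0 / (g$b0 + dp / 2)
  }, numeric(1))
  structure(list(images = images, true_fields = true_fields,
                 lung_mask = lung_mask, si_scale = si_scale, spec = spec),
            class = "dynamic_phantom")
}

#' Total lung signal ("mass") per phase
#'
#' The generator's density rule makes this constant across phases up to
#' rasterization error.
#'
#' @param phantom A [make_dynamic_phantom()] result.
#' @return Numeric vector of per-phase sums of `|image|` over the lung mask.
#' @export
lung_mass <- function(phantom) {
  R <- stack_phases(phantom$images)
  vapply(seq_len(R), function(p) {
    m <- get_phase(phantom$lung_mask, p)
    sum(abs(get_phase(phantom$images, p))[m])
  }, numeric(1))
}

#' Synthetic surface-coil sensitivity maps
#'
#' Smooth complex Gaussian-profile coils placed around the torso perimeter
#' (in the plane of the first and last spatial axes), with seeded jitter in
#' position and phase. Maps are globally scaled so the per-voxel
#' root-sum-of-squares is at most 1, and are strictly positive everywhere.
#'
#' @param n_coils Number of coil elements (>= 1).
#' @param grid_shape Spatial dimensions.
#' @param seed Integer seed.
#' @param uniform If TRUE, return all-ones maps (identity sensitivity).
#' @return Complex array `c(grid_shape, n_coils)`.
#' @export
make_coil_maps <- function(n_coils, grid_shape, seed = 1, uniform = FALSE) {
  if (n_coils < 1) stop("n_coils must be >= 1")
  N <- as.integer(grid_shape)
  d <- length(N)
  if (uniform) return(array(1 + 0i, c(N, n_coils)))
  J <- prod(N)
  idx <- arrayInd(seq_len(J), N)
  ctr <- N / 2 + 0.5
  jit <- with_seed(seed, list(ang = runif(n_coils, -0.15, 0.15),
                              ph0 = runif(n_coils, -pi, pi),
                              ramp = matrix(rnorm(n_coils * d, sd = 0.6),
                                            n_coils, d)))
  maps <- array(0 + 0i, c(N, n_coils))
  sigma <- 0.42 * mean(N)
  for (c in seq_len(n_coils)) {
    th <- 2 * pi * (c - 1) / n_coils + jit$ang[c]
    cen <- ctr
    cen[1] <- ctr[1] + 0.62 * N[1] / 2 * cos(th)
    cen[d] <- ctr[d] + 0.62 * N[d] / 2 * sin(th)
    q2 <- 0
    for (k in seq_len(d)) q2 <- q2 + (idx[, k] - cen[k])^2
    mag <- exp(-q2 / (2 * sigma^2))
    ph <- jit$ph0[c]
    for (k in seq_len(d)) ph <- ph + jit$ramp[c, k] * (idx[, k] - ctr[k]) / N[k]
    maps <- set_phase(maps, c, array(mag * exp(1i * ph), N))
  }
  rss <- sqrt(apply(abs(maps)^2, seq_len(d), sum))
  maps / max(rss)
}
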