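## Virtual-coil machinery: SVD energy reordering, coil compression,
## eigenvector (ESPIRiT-style) sensitivity-map estimation on a 2x downscaled
## grid, and randomized Rademacher sketch plans.

#' SVD coil-energy reordering
#'
#' Eigen-decomposition of the C x C coil covariance of the data; virtual
#' coils are ordered by nonincreasing energy and the data are rotated into
#' that basis.
#'
#' @param kspace C x K complex matrix (concatenate phases for a global
#'   basis).
#' @param max_samples Subsample cap for the covariance estimate.
#' @return List of class `coil_basis`: `mixing` (C x C unitary; column c is
#'   virtual coil c), `energies` (nonincreasing), `kspace` (rotated data
#'   `mixing^H %*% kspace`).
#' @export
svd_reorder <- function(kspace, max_samples = 20000) {
  C <- nrow(kspace)
  if (all(abs(kspace) == 0)) stop("cannot reorder all-zero k-space data")
  sub <- kspace
  if (ncol(kspace) > max_samples) {
    step <- ceiling(ncol(kspace) / max_samples)
    sub <- kspace[, seq(1, ncol(kspace), by = step), drop = FALSE]
  }
  cov <- sub %*% Conj(t(sub)) / ncol(sub)
  eg <- eigen(cov, symmetric = TRUE)
  mixing <- eg$vectors
  structure(list(mixing = mixing, energies = pmax(Re(eg$values), 0),
                 kspace = Conj(t(mixing)) %*% kspace),
            class = "coil_basis")
}

## Rotate sensitivity maps into a virtual-coil basis.
mix_maps <- function(maps, mixing) {
  d <- dim(maps)
  C <- d[length(d)]
  m <- matrix(maps, prod(d[-length(d)]), C)
  array(m %*% Conj(mixing), d)
}

#' Coil compression to the top virtual coils
#'
#' Keeps the `C_prime` highest-energy virtual coils of already-reordered
#' data and the correspondingly mixed maps.
#'
#' @param kspace Reordered C x K data (or a per-phase list of such).
#' @param maps Sensitivity array already rotated into the virtual basis.
#' @param C_prime Number of virtual coils to keep.
#' @return List `kspace`, `maps` with the leading `C_prime` coils.
#' @export
compress_coils <- function(kspace, maps, C_prime) {
  C <- map_count(maps)
  if (C_prime < 1 || C_prime > C) stop("C_prime must be in 1..C")
  keep <- seq_len(C_prime)
  ks <- if (is.list(kspace)) lapply(kspace, function(m) m[keep, , drop = FALSE])
        else kspace[keep, , drop = FALSE]
  d <- dim(maps)
  idx <- c(rep(list(quote(expr = )), length(d) - 1), list(keep))
  list(kspace = ks, maps = do.call(`[`, c(list(maps), idx, list(drop = FALSE))))
}

#' Retained energy fraction after compression
#'
#' @param basis A `coil_basis`.
#' @param C_prime Number of kept virtual coils.
#' @return Fraction in (0, 1].
#' @export
energy_fraction <- function(basis, C_prime) {
  sum(basis$energies[seq_len(C_prime)]) / sum(basis$energies)
}

#' Eigenvector sensitivity maps from central k-space
#'
#' ESPIRiT-style estimation: grid the phase-combined data onto a 2-fold
#' downscaled Cartesian grid, harvest calibration kernels from the central
#' k-space by SVD of the block-Hankel calibration matrix, form the per-voxel
#' coil covariance from the kernel images, and take the top eigenvector per
#' voxel, masked by its eigenvalue. Maps are upscaled to the full grid,
#' phase-referenced to coil 1, and normalized so the per-voxel
#' root-sum-of-squares is at most 1.
#'
#' @param binned A `binned_kspace` (all phases are pooled for one shared map
#'   set).
#' @param grid_shape Full image grid.
#' @param calib Calibration region width on the downscaled grid (default 12,
#'   clipped to the grid).
#' @param kernel Calibration kernel width (default 4).
#' @param null_thresh Relative singular-value threshold for the kernel
#'   subspace (default 0.02).
#' @param eig_thresh Relative eigenvalue threshold masking the support
#'   (default 0.95).
#' @param upscale "fourier" (zero-padded Fourier interpolation, default) or
#'   "linear" upscaling of the low-resolution maps.
#' @return Complex array `c(grid_shape, C)`.
#' @export
estimate_maps <- function(binned, grid_shape, calib = 16, kernel = 4,
                          null_thresh = 0.02, eig_thresh = 0.95,
                          upscale = c("fourier", "linear")) {
  upscale <- match.arg(upscale)
  N <- as.integer(grid_shape)
  d <- length(N)
  coords <- do.call(rbind, binned$coords)
  y <- do.call(cbind, binned$kspace)
  C <- nrow(y)
  Nlow <- pmax(8L, (N %/% 2L) %/% 2L * 2L)
  inbox <- rep(TRUE, nrow(coords))
  for (k in seq_len(d))
    inbox <- inbox & abs(coords[, k]) < Nlow[k] / 2 - 0.5
  if (sum(inbox) < 10 * C)
    stop("not enough calibration signal near the k-space centre")
  co <- coords[inbox, , drop = FALSE]
  dcf <- pipe_menon_dcf(co, Nlow)
  plan <- nufft_plan(co, Nlow)
  lowres <- array(0 + 0i, c(Nlow, C))
  for (c in seq_len(C))
    lowres <- set_phase(lowres, c, nufft_adjoint(dcf * y[c, inbox], plan))

  ## centred Cartesian calibration k-space
  calK <- array(0 + 0i, c(Nlow, C))
  for (c in seq_len(C))
    calK <- set_phase(calK, c,
                      fftshift(fftnd(ifftshift(get_phase(lowres, c)))))
  csize <- pmin(Nlow, as.integer(calib))
  calK <- crop_center_coils(calK, csize)

  ## block-Hankel calibration matrix
  kw <- rep(as.integer(kernel), d)
  nwin <- csize - kw + 1L
  if (any(nwin < 1)) stop("calibration region smaller than the kernel")
  win_idx <- arrayInd(seq_len(prod(nwin)), nwin)
  ker_idx <- arrayInd(seq_len(prod(kw)), kw)
  A <- matrix(0 + 0i, prod(nwin), prod(kw) * C)
  strides <- cumprod(c(1, csize[-d]))
  for (c in seq_len(C)) {
    kc <- get_phase(calK, c)
    for (j in seq_len(prod(kw))) {
      lin <- rep(1, prod(nwin))
      for (k in seq_len(d))
        lin <- lin + (win_idx[, k] + ker_idx[j, k] - 2) * strides[k]
      A[, (c - 1) * prod(kw) + j] <- kc[lin]
    }
  }
  sv <- svd(A)
  keep <- which(sv$d >= null_thresh * sv$d[1])
  V <- sv$v[, keep, drop = FALSE]           # kernels, prod(kw)*C x Nk

  ## kernel k-space -> image domain, per coil
  Nk <- ncol(V)
  kimg <- array(0 + 0i, c(Nlow, C, Nk))
  for (n in seq_len(Nk)) {
    for (c in seq_len(C)) {
      ## the Hankel windows correlate with the data, so the kernel acts
      ## conjugated in k-space
      kk <- Conj(array(V[(c - 1) * prod(kw) + seq_len(prod(kw)), n], kw))
      padded <- pad_center(kk, Nlow)
      img <- fftshift(stats::fft(ifftshift(padded), inverse = TRUE))
      idx <- c(rep(list(quote(expr = )), d), list(c), list(n))
      kimg <- do.call(`[<-`, c(list(kimg), idx, list(value = img)))
    }
  }
  ## per-voxel eigen-decomposition of the kernel covariance
  J <- prod(Nlow)
  W <- matrix(kimg, J, C * Nk)
  maps_low <- matrix(0 + 0i, J, C)
  ev <- numeric(J)
  for (q in seq_len(J)) {
    Wq <- matrix(W[q, ], C, Nk)
    M <- Wq %*% Conj(t(Wq))
    eg <- eigen(M, symmetric = TRUE)
    ev[q] <- Re(eg$values[1])
    v <- eg$vectors[, 1]
    v <- v * exp(-1i * Arg(v[1]))
    maps_low[q, ] <- v
  }
  mask <- ev >= eig_thresh * max(ev)
  maps_low[!mask, ] <- 0

  ## upscale to the full grid
  maps <- array(0 + 0i, c(N, C))
  if (upscale == "fourier") {
    for (c in seq_len(C)) {
      K <- fftshift(fftnd(ifftshift(array(maps_low[, c], Nlow))))
      up <- fftshift(stats::fft(ifftshift(pad_center(K, N)), inverse = TRUE)) /
        prod(Nlow)
      maps <- set_phase(maps, c, up)
    }
  } else {
    pts <- arrayInd(seq_len(prod(N)), N)
    for (k in seq_len(d))
      pts[, k] <- (pts[, k] - (N[k] / 2 + 0.5)) * Nlow[k] / N[k] +
        Nlow[k] / 2 + 0.5
    for (c in seq_len(C))
      maps <- set_phase(maps, c,
                        array(interp_linear(array(maps_low[, c], Nlow), pts),
                              N))
  }
  rss <- sqrt(apply(abs(maps)^2, seq_len(d), sum))
  scale <- ifelse(rss > 1, rss, 1)
  maps / array(rep(scale, C), c(N, C))
}

## Crop the spatial part of a coil array to a centred region.
crop_center_coils <- function(x, newdim) {
  d <- dim(x)
  C <- d[length(d)]
  out <- array(0 + 0i, c(newdim, C))
  for (c in seq_len(C))
    out <- set_phase(out, c, crop_center(get_phase(x, c), newdim))
  out
}

#' Build a coil-sketch plan
#'
#' One sketch matrix per outer iteration. Each sketch keeps virtual coil 1
#' verbatim (its row is the first unit vector); the remaining `C_S - 1` rows
#' carry independent Rademacher (+/-1) weights over coils 2..C, scaled by
#' `1/sqrt(C_S - 1)` so that `E[sketch^H sketch]` is the identity on coils
#' 2..C. A pure coil-selection variant is available via `mode = "select"`.
#'
#' @param C Total (virtual) coil count.
#' @param C_S Sketched coil count (2..C).
#' @param n_outer Number of outer iterations (one fresh sketch each).
#' @param seed Master seed; sketch t uses a sub-seed derived from it.
#' @param mode "rademacher" (random +/-1 combinations, default) or "select"
#'   (random subset selection).
#' @param identity If TRUE (requires `C_S == C`), every sketch is the
#'   identity; the sketched operator then equals the full operator.
#' @return List of class `sketch_plan` with `sketches` (list of C_S x C
#'   matrices), `kept_coils = 1L`, `seed`.
#' @export
build_sketch_plan <- function(C, C_S, n_outer, seed = 1,
                              mode = c("rademacher", "select"),
                              identity = FALSE) {
  mode <- match.arg(mode)
  if (identity) {
    if (C_S != C) stop("identity sketch requires C_S == C")
    sketches <- replicate(n_outer, diag(C) + 0i, simplify = FALSE)
    return(structure(list(sketches = sketches, kept_coils = 1L,
                          seed = as.integer(seed)), class = "sketch_plan"))
  }
  if (C_S < 2 || C_S > C) stop("C_S must be in 2..C")
  seeds_t <- sub_seeds(seed, n_outer, salt = 100L)
  sketches <- lapply(seq_len(n_outer), function(t) {
    with_seed(seeds_t[t], {
      S <- matrix(0 + 0i, C_S, C)
      S[1, 1] <- 1
      if (mode == "rademacher") {
        s <- 1 / sqrt(C_S - 1)
        S[-1, -1] <- matrix(sample(c(-s, s), (C_S - 1) * (C - 1),
                                   replace = TRUE), C_S - 1, C - 1)
      } else {
        picks <- sample(2:C, C_S - 1)
        for (r in seq_len(C_S - 1)) S[r + 1, picks[r]] <- 1
      }
      S
    })
  })
  structure(list(sketches = sketches, kept_coils = 1L,
                 seed = as.integer(seed)), class = "sketch_plan")
}

#' Apply a sketch matrix to maps or k-space data
#'
#' Forms `S_St = sketch %*% S` (maps) or `y_St = sketch %*% y` (per-phase
#' data).
#'
#' @param sketch A C_S x C matrix from a `sketch_plan`.
#' @param maps Sensitivity array (coil-last), or NULL.
#' @param kspace C x K matrix or per-phase list of such, or NULL.
#' @return List with the sketched `maps` and/or `kspace`.
#' @export
apply_sketch <- function(sketch, maps = NULL, kspace = NULL) {
  out <- list()
  if (!is.null(maps)) {
    d <- dim(maps)
    C <- d[length(d)]
    m <- matrix(maps, prod(d[-length(d)]), C)
    out$maps <- array(m %*% t(sketch), c(d[-length(d)], nrow(sketch)))
  }
  if (!is.null(kspace)) {
    out$kspace <- if (is.list(kspace)) lapply(kspace, function(m) sketch %*% m)
                  else sketch %*% kspace
  }
  out
}
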