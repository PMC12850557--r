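## Metrics and the desk-scale experiment harness.

#' Masked normalized root-mean-square error
#'
#' `||(|test| - |reference|) * mask|| / ||  |reference| * mask ||` on
#' magnitude images.
#'
#' @param test,reference Arrays of identical shape.
#' @param mask Logical (or 0/1) array of the same shape; NULL = all voxels.
#' @return Nonnegative scalar.
#' @export
nrmse_masked <- function(test, reference, mask = NULL) {
  if (!identical(dim(test), dim(reference)))
    stop("test and reference must share a shape")
  mask <- mask %||% array(TRUE, dim(reference))
  if (!any(mask)) stop("mask is empty")
  ref <- abs(reference)[mask]
  den <- sqrt(sum(ref^2))
  if (den == 0) stop("reference has zero energy inside the mask")
  sqrt(sum((abs(test)[mask] - ref)^2)) / den
}

#' Convergence curve relative to a reference objective
#'
#' @param trace Data frame with an `objective` column (a solver trace).
#' @param reference_objective Objective value of the converged reference
#'   run (> 0).
#' @return Numeric vector `objective / reference_objective` per iteration.
#' @export
convergence_curve <- function(trace, reference_objective) {
  if (!is_scalar_number(reference_objective) || reference_objective <= 0)
    stop("reference_objective must be a positive scalar")
  trace$objective / reference_objective
}

#' Pre-whiten raw multicoil data
#'
#' Transforms the coil dimension so that thermal noise is unit-variance and
#' uncorrelated across channels: `y <- L^{-1} y` with `L L^H` the Cholesky
#' factorization of the noise covariance (or a plain scale for scalar
#' sigma).
#'
#' @param raw A `raw_dataset`.
#' @param noise_cov C x C noise covariance matrix, or NULL.
#' @param sigma Scalar per-channel noise SD (used when `noise_cov` is NULL;
#'   defaults to the dataset's recorded `noise_sigma`).
#' @return The whitened `raw_dataset` (noise_sigma set to 1).
#' @export
prewhiten <- function(raw, noise_cov = NULL, sigma = NULL) {
  if (is.null(noise_cov)) {
    sigma <- sigma %||% raw$noise_sigma
    if (!is_scalar_number(sigma) || sigma <= 0)
      stop("a positive scalar sigma (or a covariance matrix) is required")
    raw$kspace <- raw$kspace / sigma
  } else {
    ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(Re(ev)) <= 1e-12 * max(Re(ev)))
      stop("noise covariance is singular or not positive definite")
    L <- t(chol(noise_cov))         # lower triangular, L L^H = cov
    raw$kspace <- solve(L, raw$kspace)
  }
  raw$noise_sigma <- 1
  raw
}

#' Pseudo-replica SNR map
#'
#' Adds unit-SD complex Gaussian noise to (pre-whitened) raw data,
#' reconstructs, and repeats; the SNR map is the voxelwise mean divided by
#' the voxelwise SD of the replica magnitudes.
#'
#' @param raw A pre-whitened `raw_dataset` (noise SD 1).
#' @param recon_closure Function mapping a `raw_dataset` to an image stack.
#' @param n_replicas Number of pseudo-replicas (default 30).
#' @param seed Integer seed; replica i uses a sub-seed derived from it.
#' @return List with `snr` (real array), `mean`, `sd`, `n_replicas`.
#' @export
pseudo_replica_snr <- function(raw, recon_closure, n_replicas = 30,
                               seed = 1) {
  if (n_replicas < 2) stop("n_replicas must be >= 2")
  acc <- NULL; acc2 <- NULL
  CK <- length(raw$kspace)
  seeds_i <- sub_seeds(seed, n_replicas, salt = 300L)
  for (i in seq_len(n_replicas)) {
    noisy <- raw
    noise <- with_seed(seeds_i[i],
      complex(real = rnorm(CK, sd = 1 / sqrt(2)),
              imaginary = rnorm(CK, sd = 1 / sqrt(2))))
    noisy$kspace <- raw$kspace + matrix(noise, nrow(raw$kspace))
    img <- abs(recon_closure(noisy))
    if (is.null(acc)) { acc <- img * 0; acc2 <- img * 0 }
    acc <- acc + img
    acc2 <- acc2 + img^2
  }
  mu <- acc / n_replicas
  va <- pmax(acc2 / n_replicas - mu^2, 0) * n_replicas / (n_replicas - 1)
  sdv <- sqrt(va)
  list(snr = mu / pmax(sdv, .Machine$double.eps), mean = mu, sd = sdv,
       n_replicas = n_replicas)
}

#' Seeded desk-scale synthetic fixture
#'
#' One self-contained instance of the full pipeline input: dynamic phantom,
#' coil maps, golden-angle stack-of-spirals trajectory spanning several
#' breathing cycles, simulated noisy acquisition, navigator-driven binning.
#'
#' @param grid_shape Image grid (default 32 x 32).
#' @param n_coils Coils (default 6).
#' @param n_phases Respiratory bins R (default 3).
#' @param n_interleaves Total readouts (default 1440, ~12 s of acquisition
#'   at TR 8.3 ms, three 4-s breathing cycles).
#' @param samples_per_interleaf Readout length (default 64).
#' @param noise_sd Complex k-space noise SD (default 0.05).
#' @param diaphragm_amplitude Peak SI motion in voxels (default 3).
#' @param seed Master seed.
#' @return List with `phantom`, `maps`, `traj`, `raw`, `binned`,
#'   `bin_agreement` (fraction of readouts whose navigator bin matches the
#'   generating schedule).
#' @export
synthetic_fixture <- function(grid_shape = c(32, 32), n_coils = 6,
                              n_phases = 3, n_interleaves = 1440,
                              samples_per_interleaf = 64, noise_sd = 0.05,
                              diaphragm_amplitude = 3, seed = 1) {
  spec <- phantom_spec(grid_shape = grid_shape, n_phases = n_phases,
                       diaphragm_amplitude = diaphragm_amplitude,
                       seed = derive_seed(seed, 1L))
  phantom <- make_dynamic_phantom(spec)
  maps <- make_coil_maps(n_coils, grid_shape, seed = derive_seed(seed, 2L))
  traj <- make_stack_of_spirals(
    n_interleaves = n_interleaves, n_kz = 1, grid_shape = grid_shape,
    samples_per_interleaf = samples_per_interleaf)
  raw <- simulate_acquisition(phantom, maps, traj, noise_sd = noise_sd,
                              seed = derive_seed(seed, 3L))
  phi <- hilbert_phase(raw$navigator)
  rt <- as.numeric(tapply(raw$time, raw$readout_id, min))
  bins <- suppressWarnings(
    assign_bins(phi, n_phases, raw$navigator_time, rt))
  binned <- bin_dataset(raw, bins, n_phases)
  list(phantom = phantom, maps = maps, traj = traj, raw = raw,
       binned = binned, bin_agreement = mean(bins == raw$true_bins),
       seed = seed)
}

#' Run a named desk-scale experiment
#'
#' Scenario arms run on the seeded synthetic fixture; metric tables (and,
#' when `outdir` is given, NIfTI volumes, trace CSVs) are produced.
#' Available scenarios: `regularizer_gallery`, `compression_vs_sketching`,
#' `convergence`, `toeplitz_accuracy`, `snr`.
#'
#' @param name Scenario name.
#' @param config Base [recon_config()] (scenario arms override fields).
#' @param fixture A [synthetic_fixture()]; built from `config$seed` if NULL.
#' @param outdir Output directory, or NULL for no files.
#' @param n_replicas Pseudo-replicas for the `snr` scenario.
#' @return A list report with a `metrics` data frame.
#' @export
run_experiment <- function(name, config = recon_config(), fixture = NULL,
                           outdir = NULL, n_replicas = 10) {
  scenarios <- c("regularizer_gallery", "compression_vs_sketching",
                 "convergence", "toeplitz_accuracy", "snr")
  if (!name %in% scenarios)
    stop("unknown experiment scenario '", name, "'")
  fixture <- fixture %||% synthetic_fixture(n_phases = config$n_bins,
                                            seed = config$seed)
  C <- map_count(fixture$maps)
  lung <- fixture$phantom$lung_mask
  save_arm <- function(res, arm) {
    if (is.null(outdir)) return(invisible(NULL))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    export_images(res$images, file.path(outdir, paste0(arm, ".nii")))
    write_trace_csv(res$trace, file.path(outdir, paste0(arm, "_trace.csv")))
  }
  arm_cfg <- function(...) {
    modifyList(config, list(...))
  }
  report <- switch(name,
    regularizer_gallery = {
      arms <- list(
        cgsense = arm_cfg(regularizer = "cgsense", solver = "cg"),
        tv = arm_cfg(regularizer = "tv", solver = "pdhg"),
        lr = arm_cfg(regularizer = "lr", solver = "pdhg"),
        mocolr = arm_cfg(regularizer = "mocolr", solver = "pdhg"))
      rows <- lapply(names(arms), function(a) {
        res <- sketched_reconstruct(fixture$binned, fixture$maps, arms[[a]])
        save_arm(res, a)
        data.frame(arm = a,
                   nrmse_lung = nrmse_masked(res$images,
                                             fixture$phantom$images, lung),
                   final_objective = tail(res$trace$objective, 1))
      })
      list(metrics = do.call(rbind, rows))
    },
    compression_vs_sketching = {
      ref <- sketched_reconstruct(fixture$binned, fixture$maps,
                                  arm_cfg(sketch_coils = 0L,
                                          compress_coils = 0L))
      save_arm(ref, "conventional")
      rows <- list()
      for (n in seq(3, C)) {
        cmp <- sketched_reconstruct(fixture$binned, fixture$maps,
                                    arm_cfg(sketch_coils = 0L,
                                            compress_coils = as.integer(n)))
        skt <- sketched_reconstruct(fixture$binned, fixture$maps,
                                    arm_cfg(sketch_coils = as.integer(n),
                                            compress_coils = 0L))
        save_arm(cmp, paste0("compressed_", n))
        save_arm(skt, paste0("sketched_", n))
        rows[[length(rows) + 1]] <- data.frame(
          coils = n,
          nrmse_compressed = nrmse_masked(cmp$images, ref$images, lung),
          nrmse_sketched = nrmse_masked(skt$images, ref$images, lung))
      }
      list(metrics = do.call(rbind, rows), reference = "conventional")
    },
    convergence = {
      total <- config$n_initial + config$n_inner * config$n_outer
      long <- arm_cfg(sketch_coils = 0L,
                      n_outer = as.integer(
                        ceiling((200 - config$n_initial) / config$n_inner)))
      ref <- sketched_reconstruct(fixture$binned, fixture$maps, long)
      ref_obj <- min(ref$trace$objective)
      arms <- list(
        conventional = arm_cfg(sketch_coils = 0L),
        compressed = arm_cfg(sketch_coils = 0L, compress_coils = 3L),
        sketched = arm_cfg(sketch_coils = 3L))
      curves <- lapply(names(arms), function(a) {
        res <- sketched_reconstruct(fixture$binned, fixture$maps, arms[[a]])
        save_arm(res, a)
        data.frame(arm = a, iteration = res$trace$iteration,
                   ratio = convergence_curve(res$trace, ref_obj))
      })
      metrics <- do.call(rbind, lapply(curves, function(cv)
        data.frame(arm = cv$arm[1], final_ratio = tail(cv$ratio, 1))))
      list(metrics = metrics, curves = do.call(rbind, curves),
           reference_objective = ref_obj, reference_iterations = 200)
    },
    toeplitz_accuracy = {
      rows <- list()
      for (arm in c("conventional", "sketched")) {
        sc <- if (arm == "sketched") 3L else 0L
        std <- sketched_reconstruct(fixture$binned, fixture$maps,
                                    arm_cfg(sketch_coils = sc,
                                            toeplitz = FALSE))
        toe <- sketched_reconstruct(fixture$binned, fixture$maps,
                                    arm_cfg(sketch_coils = sc,
                                            toeplitz = TRUE))
        save_arm(std, paste0(arm, "_standard"))
        save_arm(toe, paste0(arm, "_toeplitz"))
        rows[[arm]] <- data.frame(
          arm = arm,
          nrmse_toeplitz = nrmse_masked(toe$images, std$images))
      }
      list(metrics = do.call(rbind, rows))
    },
    snr = {
      white <- prewhiten(fixture$raw)
      ## the trajectory (hence plans/preconditioner/normalization) is shared
      ## across replicas; reuse the system and skip per-iteration tracing
      rec_for <- function(cfg) {
        cfg$svd_reorder <- FALSE
        cache <- new.env()
        function(rw) {
          phi <- hilbert_phase(rw$navigator)
          rt <- as.numeric(tapply(rw$time, rw$readout_id, min))
          bins <- suppressWarnings(
            assign_bins(phi, cfg$n_bins, rw$navigator_time, rt))
          bd <- bin_dataset(rw, bins, cfg$n_bins)
          res <- sketched_reconstruct(bd, fixture$maps, cfg,
                                      system = cache$sys, trace = FALSE)
          cache$sys <- res$system
          res$images
        }
      }
      arms <- list(conventional = arm_cfg(sketch_coils = 0L),
                   compressed = arm_cfg(sketch_coils = 0L,
                                        compress_coils = 3L),
                   sketched = arm_cfg(sketch_coils = 3L))
      maps_list <- lapply(names(arms), function(a) {
        s <- pseudo_replica_snr(white, rec_for(arms[[a]]),
                                n_replicas = n_replicas,
                                seed = config$seed)
        if (!is.null(outdir))
          export_images(s$snr + 0i, file.path(outdir, paste0("snr_", a, ".nii")))
        s
      })
      names(maps_list) <- names(arms)
      mean_lung <- vapply(maps_list, function(s)
        mean(s$snr[lung]), numeric(1))
      list(metrics = data.frame(arm = names(arms), mean_lung_snr = mean_lung),
           snr_maps = maps_list)
    })
  if (!is.null(outdir))
    utils::write.csv(report$metrics,
                     file.path(outdir, paste0(name, "_metrics.csv")),
                     row.names = FALSE)
  report
}
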