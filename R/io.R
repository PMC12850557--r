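## Raw-data container (HDF5), image export (NIfTI-1), and configuration.
##
## Container layout (dataset names; array dims are stored in C order, i.e.
## reversed relative to the R dim attribute):
##   /kspace          complex, C x K_total (compound type {r, i})
##   /coords          double,  K_total x d (grid units)
##   /navigator       double vector
##   /navigator_time  double vector (ms)
##   /readout_id      integer per sample
##   /time            double per sample (ms)
##   /true_bins       integer per readout (synthetic ground truth; optional)
##   /meta/*          grid_shape, n_coils, n_phases, seed, period_ms,
##                    noise_sigma

h5_write_all <- function(path, objects) {
  .Call(C_h5_write, path.expand(path), names(objects), unname(objects))
}

h5_read <- function(path, name) .Call(C_h5_read, path.expand(path), name)

h5_exists <- function(path, name) .Call(C_h5_exists, path.expand(path), name)

#' Write a raw dataset to an HDF5 container
#'
#' @param dataset A `raw_dataset` (see [simulate_acquisition()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raw <- function(dataset, path) {
  stopifnot(inherits(dataset, "raw_dataset"))
  objs <- list(
    "/kspace" = dataset$kspace,
    "/coords" = dataset$coords,
    "/navigator" = as.numeric(dataset$navigator),
    "/navigator_time" = as.numeric(dataset$navigator_time),
    "/readout_id" = as.integer(dataset$readout_id),
    "/time" = as.numeric(dataset$time),
    "/meta/grid_shape" = as.integer(dataset$meta$grid_shape),
    "/meta/n_coils" = as.integer(dataset$meta$n_coils),
    "/meta/n_phases" = as.integer(dataset$meta$n_phases),
    "/meta/seed" = as.integer(dataset$meta$seed),
    "/meta/period_ms" = as.numeric(dataset$meta$period_ms),
    "/meta/noise_sigma" = as.numeric(dataset$noise_sigma))
  if (!is.null(dataset$true_bins))
    objs[["/true_bins"]] <- as.integer(dataset$true_bins)
  h5_write_all(path, objs)
  invisible(path)
}

#' Read a raw dataset from an HDF5 container
#'
#' Errors name any missing dataset; the k-space and coordinate sample
#' counts must agree.
#'
#' @param path Container path.
#' @return A `raw_dataset`.
#' @export
read_raw <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  required <- c("/kspace", "/coords", "/navigator", "/navigator_time",
                "/readout_id", "/time", "/meta/grid_shape", "/meta/n_coils",
                "/meta/n_phases")
  for (nm in required)
    if (!h5_exists(path, nm))
      stop("HDF5 container is missing dataset '", nm, "'")
  kspace <- h5_read(path, "/kspace")
  coords <- h5_read(path, "/coords")
  if (ncol(kspace) != nrow(coords))
    stop("shape mismatch: /kspace has ", ncol(kspace),
         " samples but /coords has ", nrow(coords))
  structure(list(
    kspace = kspace, coords = coords,
    readout_id = h5_read(path, "/readout_id"),
    time = h5_read(path, "/time"),
    navigator = h5_read(path, "/navigator"),
    navigator_time = h5_read(path, "/navigator_time"),
    noise_sigma = if (h5_exists(path, "/meta/noise_sigma"))
      h5_read(path, "/meta/noise_sigma") else NA_real_,
    true_bins = if (h5_exists(path, "/true_bins"))
      h5_read(path, "/true_bins"),
    meta = list(grid_shape = h5_read(path, "/meta/grid_shape"),
                n_coils = h5_read(path, "/meta/n_coils"),
                n_phases = h5_read(path, "/meta/n_phases"),
                seed = if (h5_exists(path, "/meta/seed"))
                  h5_read(path, "/meta/seed") else NA_integer_,
                period_ms = if (h5_exists(path, "/meta/period_ms"))
                  h5_read(path, "/meta/period_ms") else NA_real_)),
    class = "raw_dataset")
}

#' Export an image stack as a 4-D NIfTI volume
#'
#' Writes the magnitude as (x, y, z, phase); a 2-D stack exports as
#' (x, y, 1, phase). Uncompressed `.nii` output is byte-reproducible.
#'
#' @param images Complex or real image stack (phase-last).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_mm Voxel size metadata (recycled to 3 values).
#' @return `path`, invisibly.
#' @export
export_images <- function(images, path, voxel_mm = c(1, 1, 1)) {
  if (any(!is.finite(images)))
    stop("refusing to export non-finite voxel values")
  d <- dim(images)
  R <- d[length(d)]
  grid <- d[-length(d)]
  if (length(grid) == 2) grid <- c(grid, 1L)
  arr <- array(abs(images), c(grid, R))
  img <- RNifti::asNifti(arr, pixdim = rep_len(voxel_mm, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct a reconstruction configuration
#'
#' Defaults follow the reference pipeline settings: `lambda = 0.1`,
#' 5 initial iterations, 5 inner iterations per sketched subproblem,
#' 6 outer iterations, 4 PDHG primal inner iterations, and a 1.33-fold
#' padded reconstruction matrix.
#'
#' @param regularizer One of "cgsense", "tv", "lr", "mocolr", "none".
#' @param solver One of "cg", "fista", "pdhg". CG requires a quadratic
#'   regularizer ("cgsense" or "none").
#' @param lambda Regularization strength (>= 0).
#' @param n_bins Respiratory phase count R used when binning.
#' @param sketch_coils C_S; 0 disables sketching (conventional
#'   reconstruction).
#' @param compress_coils C'; 0 disables; > 0 runs the conventional schedule
#'   on the C'-coil SVD-compressed system.
#' @param n_initial Initial (SVD-compressed) iterations.
#' @param n_inner Inner iterations per sketched subproblem.
#' @param n_outer Outer iterations (fresh sketch each).
#' @param pdhg_inner Gradient steps in the PDHG primal update.
#' @param toeplitz Use Toeplitz embedding for all normal-operator
#'   evaluations.
#' @param pad_factor Reconstruction-matrix enlargement (>= 1).
#' @param precond "frobenius" (trajectory-PSF diagonal preconditioner),
#'   "dcf" (Pipe-Menon density compensation), or "none".
#' @param svd_reorder Rotate data and maps into the SVD virtual-coil basis
#'   first (default TRUE).
#' @param identity_sketch Use identity sketches (requires
#'   `sketch_coils == C`; for equivalence testing).
#' @param moco_refresh Outer iterations between motion-field re-estimations
#'   (0 = estimate once after the initial phase).
#' @param seed Integer seed driving sketch draws and the power method.
#' @return A list of class `recon_config`.
#' @export
recon_config <- function(regularizer = "mocolr", solver = "pdhg",
                         lambda = 0.1, n_bins = 6L, sketch_coils = 3L,
                         compress_coils = 0L, n_initial = 5L, n_inner = 5L,
                         n_outer = 6L, pdhg_inner = 4L, toeplitz = FALSE,
                         pad_factor = 1.33, precond = "frobenius",
                         svd_reorder = TRUE, identity_sketch = FALSE,
                         moco_refresh = 0L, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "recon_config")
  validate_config(cfg)
}

#' Validate (and normalize) a reconstruction configuration
#'
#' @param config A `recon_config` or plain named list.
#' @param C Available coil count, if known (checks `sketch_coils <= C`).
#' @return The validated configuration.
#' @export
validate_config <- function(config, C = NULL) {
  num_ge <- function(key, lo) {
    v <- config[[key]]
    if (!is_scalar_number(v) || v < lo)
      stop("config key '", key, "' must be a number >= ", lo)
    v
  }
  if (!config$regularizer %in% c("none", "cgsense", "tv", "lr", "mocolr"))
    stop("config key 'regularizer' must be one of none/cgsense/tv/lr/mocolr")
  if (!config$solver %in% c("cg", "fista", "pdhg"))
    stop("config key 'solver' must be one of cg/fista/pdhg")
  if (config$solver == "cg" && !config$regularizer %in% c("none", "cgsense"))
    stop("the CG solver requires a quadratic regularizer (none or cgsense)")
  num_ge("lambda", 0)
  if (num_ge("pad_factor", 0) < 1) stop("config key 'pad_factor' must be >= 1")
  for (k in c("n_bins", "n_initial", "n_inner", "n_outer", "pdhg_inner",
              "sketch_coils", "compress_coils"))
    config[[k]] <- as.integer(num_ge(k, 0))
  if (config$n_bins < 1) stop("config key 'n_bins' must be >= 1")
  if (config$sketch_coils == 1)
    stop("sketch_coils must be 0 (off) or >= 2")
  if (!is.null(C) && config$sketch_coils > C)
    stop("sketch_coils (", config$sketch_coils,
         ") exceeds the available coil count (", C, ")")
  if (!config$precond %in% c("frobenius", "dcf", "none"))
    stop("config key 'precond' must be one of frobenius/dcf/none")
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

#' Load a reconstruction configuration from a YAML file
#'
#' Flat key-value YAML; absent keys take the documented defaults, unknown
#' keys are an error.
#'
#' @param path Config file path.
#' @return A validated `recon_config`.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(recon_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(recon_config, vals)
}

#' Write a solver trace as CSV
#'
#' One line per iteration: iteration index, objective value, elapsed
#' seconds.
#'
#' @param trace Data frame from a `recon_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
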