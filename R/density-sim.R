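#' Parameters for simulating density from atomic coordinates
#'
#' The resolution is interpreted as the full width at half maximum (FWHM) of
#' an isotropic Gaussian point spread, so `sigma = resolution / (2 sqrt(2
#' ln 2))`. Gaussians are truncated at `trunc` standard deviations (default
#' 4, < 0.01\% mass loss).
#'
#' @param resolution nominal resolution in Angstrom (> 0).
#' @param voxel_size grid spacing in Angstrom (> 0); a warning is issued when
#'   it exceeds `resolution / 2` (under-sampling).
#' @param padding margin beyond the atomic bounding box in Angstrom (default
#'   3x the resolution, the common simulate-map convention); values below
#'   `2 * resolution` trigger a warning.
#' @param weighting `"electron-count"` (atomic number, default) or
#'   `"uniform"`.
#' @param trunc Gaussian truncation radius in sigmas.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(resolution = 5, voxel_size = 1.043,
                              padding = 3 * resolution,
                              weighting = c("electron-count", "uniform"),
                              trunc = 4) {
  weighting <- match.arg(weighting)
  stopifnot(resolution > 0, voxel_size > 0, padding >= 0, trunc > 0)
  if (voxel_size > resolution / 2)
    warning("voxel_size > resolution/2: simulated map will be under-sampled")
  if (padding < 2 * resolution)
    warning("padding below 2 * resolution may truncate the density envelope")
  structure(list(resolution = resolution, voxel_size = voxel_size,
                 padding = padding, weighting = weighting, trunc = trunc),
            class = "simulation_params")
}

#' Gaussian sigma corresponding to a FWHM resolution
#' @param resolution FWHM in Angstrom.
#' @return sigma in Angstrom.
#' @export
resolution_sigma <- function(resolution) resolution / (2 * sqrt(2 * log(2)))

.sim_weights <- function(atoms_df, weighting) {
  if (weighting == "uniform") rep(1, nrow(atoms_df))
  else as.numeric(atomic_number(atoms_df$element))
}

# Accumulate the Gaussian kernel sum for `atoms_df` (data frame with x, y, z,
# element) on an explicit grid. Shared by simulate_map and the fit scorer.
.simulate_on_grid <- function(atoms_df, dims, origin, voxel_size, params) {
  sigma <- resolution_sigma(params$resolution)
  # mass-normalized kernels: each atom integrates to its weight, so the map
  # integral is the total weight and coarser blurring lowers (never raises)
  # the peak
  w <- .sim_weights(atoms_df, params$weighting) / ((2 * pi)^1.5 * sigma^3)
  vals <- .cpp_accumulate_gaussians(
    as.integer(dims), as.numeric(origin), as.numeric(voxel_size),
    as.matrix(atoms_df[, c("x", "y", "z")]), w, sigma, params$trunc)
  array(vals, dim = dims)
}

#' Simulate a density map from atomic coordinates
#'
#' Each atom contributes a mass-normalized isotropic Gaussian of FWHM equal
#' to the nominal resolution, weighted by its atomic number (electron count)
#' or uniformly, so the map integral equals the summed weights. The grid
#' covers the atomic bounding box plus the requested padding.
#'
#' @param atoms a `ligand_atoms`, `model_structure`, or atoms data frame with
#'   columns `x, y, z, element`.
#' @param params a [simulation_params].
#' @param name label for the returned map.
#' @return A [density_map]; the parameters used are attached as the
#'   `sim_params` attribute.
#' @export
simulate_map <- function(atoms, params = simulation_params(), name = "simulated") {
  df <- if (is.data.frame(atoms)) atoms else atoms$atoms
  if (is.null(df) || nrow(df) == 0) stop("cannot simulate a map from zero atoms")
  lo <- apply(df[, c("x", "y", "z")], 2, min) - params$padding
  hi <- apply(df[, c("x", "y", "z")], 2, max) + params$padding
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / params$voxel_size)) + 1L)
  m <- density_map(
    .simulate_on_grid(df, dims, lo, rep(params$voxel_size, 3), params),
    voxel_size = params$voxel_size, origin = lo, name = name)
  attr(m, "sim_params") <- params
  m
}

#' Write the simulation parameters used for a map as a JSON sidecar
#' @param map a map produced by [simulate_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_sidecar <- function(map, path) {
  p <- attr(map, "sim_params")
  if (is.null(p)) stop("map carries no sim_params attribute")
  jsonlite::write_json(
    list(resolution_A = p$resolution, resolution_convention = "FWHM",
         voxel_size_A = p$voxel_size, padding_A = p$padding,
         weighting = p$weighting, truncation_sigmas = p$trunc),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
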