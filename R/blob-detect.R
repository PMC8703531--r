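#' Zero out density already accounted for by an atomic model
#'
#' Voxels whose center lies within `mask_radius` of any model heavy atom are
#' set to the map minimum, leaving only unmodeled density above any display
#' level. Waters are part of the model and masked too.
#'
#' @param map a [density_map].
#' @param model a `model_structure`.
#' @param mask_radius radius in Angstrom (default 3.0).
#' @return The masked [density_map]; the number of voxels masked is attached
#'   as the `masked_voxels` attribute.
#' @export
mask_modeled_density <- function(map, model, mask_radius = 3.0) {
  stopifnot(mask_radius > 0)
  xyz <- atom_coords(model, heavy_only = TRUE)
  if (nrow(xyz) == 0) stop("empty model: nothing to mask")
  idx <- .cpp_voxels_near_atoms(map$dims, map$origin, map$voxel_size,
                                xyz, mask_radius)
  out <- map
  if (length(idx) > 0) out$values[idx] <- min(map$values)
  attr(out, "masked_voxels") <- length(idx)
  out
}

# Metrics for one connected component: centroid and principal extents from
# density-weighted PCA of voxel-center coordinates; extents are 2*sqrt(lambda).
.blob_metrics <- function(map, idx) {
  d <- map$dims
  i0 <- idx - 1L
  ix <- i0 %% d[1]
  iy <- (i0 %/% d[1]) %% d[2]
  iz <- i0 %/% (d[1] * d[2])
  xyz <- cbind(map$origin[1] + ix * map$voxel_size[1],
               map$origin[2] + iy * map$voxel_size[2],
               map$origin[3] + iz * map$voxel_size[3])
  dens <- as.numeric(map$values[idx])
  w <- dens - min(0, min(dens))          # guard against negative weights
  if (sum(w) <= 0) w <- rep(1, length(idx))
  w <- w / sum(w)
  ctr <- colSums(xyz * w)
  cc <- sweep(xyz, 2, ctr)
  cov <- crossprod(cc * sqrt(w))
  ev <- eigen(cov, symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  ext <- 2 * sqrt(ev)                    # descending by eigen() convention
  # degenerate thin blobs: floor the minor extents at one voxel edge
  ext_f <- pmax(ext, min(map$voxel_size))
  list(voxel_idx = idx,
       voxel_count = length(idx),
       volume = length(idx) * voxel_volume(map),
       centroid = ctr,
       principal_extents = ext,
       elongation = ext_f[1] / ext_f[2],
       max_density = max(dens),
       mean_density = mean(dens))
}

#' Connected components of above-level density
#'
#' Components of `{value >= level}` under 6-, 18- or 26-connectivity, each
#' summarized by volume, density-weighted centroid, principal extents
#' (2 sqrt of the PCA eigenvalues of voxel-center coordinates) and
#' elongation (first / second extent). Sorted by volume, largest first.
#'
#' @param map a [density_map] (typically after [mask_modeled_density()]).
#' @param level density level.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param min_voxels drop components smaller than this (default 10).
#' @return List of blobs (class `blob_list`), possibly empty.
#' @export
find_blobs <- function(map, level, connectivity = 26, min_voxels = 10) {
  stopifnot(is.finite(level), min_voxels >= 1,
            connectivity %in% c(6L, 18L, 26L))
  mask <- as.integer(map$values >= level)
  lab <- .cpp_label_components(mask, map$dims, as.integer(connectivity))
  if (all(lab == 0L)) return(structure(list(), class = "blob_list", level = level))
  tab <- tabulate(lab)
  keep <- which(tab >= min_voxels)
  idx_by <- split(which(lab > 0L), lab[lab > 0L])
  blobs <- lapply(keep, function(k) .blob_metrics(map, idx_by[[as.character(k)]]))
  ord <- order(vapply(blobs, `[[`, numeric(1), "volume"), decreasing = TRUE)
  structure(blobs[ord], class = "blob_list", level = level)
}

#' Reference envelope volume expected for a ligand
#'
#' Simulates the ligand at the stated resolution, takes the simulated map's
#' own `mean + k * sd` level, and returns the volume enclosed — the size
#' yardstick for the volume criterion.
#'
#' @param ligand a `ligand_atoms`.
#' @param params a [simulation_params].
#' @param k SD multiplier applied to the simulated map (default 7).
#' @return Expected envelope volume in cubic Angstrom.
#' @export
expected_ligand_volume <- function(ligand, params = simulation_params(), k = 7) {
  sim <- simulate_map(ligand, params, name = "ligand-reference")
  enclosed_volume(sim, sd_threshold(sim, k))$enclosed_volume
}

#' Screen a candidate blob against the four ligand-density criteria
#'
#' The four criteria for accepting an unmodeled density feature as a bound
#' ligand: (1) the feature is visible at the protein display level (any blob
#' passed in was found at that level, so this records its existence and
#' level); (2) it is roughly rod-shaped, operationalized as elongation >=
#' `rod_min_elongation`; (3) its continuous volume is within `volume_band`
#' times the expected ligand envelope volume; (4) once fitted, the ligand
#' pose has no serious clashes with the model. Criterion 4 is
#' `NA` (not evaluated) until a pose and model are supplied.
#'
#' @param blob one element of a [find_blobs()] result.
#' @param protein_level the display level the blob was found at.
#' @param ligand a `ligand_atoms` (the candidate molecule).
#' @param params a [simulation_params] used for the reference envelope.
#' @param k SD multiplier for the reference envelope (default 7).
#' @param rod_min_elongation minimum elongation for criterion 2 (default 2).
#' @param volume_band multiplicative band for criterion 3
#'   (default `c(0.5, 2)`).
#' @param pose optional `ligand_pose` for criterion 4.
#' @param model optional `model_structure` for criterion 4.
#' @param clash_cutoff serious-clash distance in Angstrom (default 2.0).
#' @return A `criteria_report` list: logical `c1_visible_at_protein_level`,
#'   `c2_rod_shaped`, `c3_volume_match`, `c4_no_serious_clashes` (NA when not
#'   evaluated), `all_pass` over the evaluated criteria, and the backing
#'   ratios.
#' @export
evaluate_criteria <- function(blob, protein_level, ligand,
                              params = simulation_params(), k = 7,
                              rod_min_elongation = 2.0,
                              volume_band = c(0.5, 2.0),
                              pose = NULL, model = NULL,
                              clash_cutoff = 2.0) {
  stopifnot(length(volume_band) == 2, volume_band[1] <= volume_band[2])
  ref_vol <- expected_ligand_volume(ligand, params, k)
  vol_ratio <- blob$volume / ref_vol
  c1 <- blob$voxel_count >= 1
  c2 <- blob$elongation >= rod_min_elongation
  c3 <- vol_ratio >= volume_band[1] && vol_ratio <= volume_band[2]
  c4 <- NA
  n_serious <- NA_integer_
  if (!is.null(pose) && !is.null(model)) {
    cl <- clash_check(pose, ligand, model, serious_cutoff = clash_cutoff)
    n_serious <- cl$n_serious
    c4 <- cl$n_serious == 0
  }
  evaluated <- c(c1, c2, c3, if (!is.na(c4)) c4)
  structure(list(
    c1_visible_at_protein_level = c1,
    c2_rod_shaped = c2,
    c3_volume_match = c3,
    c4_no_serious_clashes = c4,
    all_pass = all(evaluated),
    protein_level = protein_level,
    elongation = blob$elongation,
    rod_min_elongation = rod_min_elongation,
    blob_volume = blob$volume,
    expected_volume = ref_vol,
    volume_ratio = vol_ratio,
    volume_band = volume_band,
    n_serious_clashes = n_serious),
    class = "criteria_report")
}

#' Export a blob list as a data frame / TSV
#' @param blobs a `blob_list` from [find_blobs()].
#' @param path optional TSV output path.
#' @return Data frame of per-blob metrics (one row per blob).
#' @export
blob_table <- function(blobs, path = NULL) {
  if (length(blobs) == 0) {
    df <- data.frame(blob = integer(0), voxel_count = integer(0),
                     volume_A3 = numeric(0), x = numeric(0), y = numeric(0),
                     z = numeric(0), elongation = numeric(0),
                     max_density = numeric(0), mean_density = numeric(0))
  } else {
    df <- do.call(rbind, lapply(seq_along(blobs), function(i) {
      b <- blobs[[i]]
      data.frame(blob = i, voxel_count = b$voxel_count, volume_A3 = b$volume,
                 x = b$centroid[1], y = b$centroid[2], z = b$centroid[3],
                 elongation = b$elongation, max_density = b$max_density,
                 mean_density = b$mean_density)
    }))
  }
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  df
}
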