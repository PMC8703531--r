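#' Pipeline configuration
#'
#' Bundles every tunable of the detection and geometry pipelines with the
#' study defaults; all values are validated here and the effective config is
#' echoed verbatim into every report.
#'
#' @param display_target_volume protein display volume in cubic Angstrom
#'   (default 153000, the deposited-map display convention).
#' @param resolution simulated-map resolution in Angstrom (default 5).
#' @param voxel_size simulation voxel size in Angstrom (default 1.043).
#' @param k SD multiplier for the simulated-ligand envelope (default 7).
#' @param mask_radius model-density mask radius in Angstrom (default 3).
#' @param connectivity blob connectivity, 6/18/26 (default 26).
#' @param min_voxels minimum blob size in voxels (default 10).
#' @param rod_min_elongation rod-shape criterion threshold (default 2).
#' @param volume_band multiplicative volume band (default `c(0.5, 2)`).
#' @param n_rotations rotation-grid size for fitting (default 576).
#' @param clash_cutoff serious-clash distance in Angstrom (default 2).
#' @param contact_cutoff contact distance in Angstrom (default 4.5).
#' @param pocket_radius pocket shell radius in Angstrom (default 5).
#' @param prune_cutoff RMSD pruning cutoff in Angstrom (default 2).
#' @param cc_method correlation variant (default "about-mean").
#' @param seed integer seed echoed into reports.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(display_target_volume = 153000,
                            resolution = 5.0, voxel_size = 1.043, k = 7,
                            mask_radius = 3.0, connectivity = 26,
                            min_voxels = 10, rod_min_elongation = 2.0,
                            volume_band = c(0.5, 2.0), n_rotations = 576,
                            clash_cutoff = 2.0, contact_cutoff = 4.5,
                            pocket_radius = 5.0, prune_cutoff = 2.0,
                            cc_method = "about-mean", seed = 1) {
  stopifnot(display_target_volume > 0, resolution > 0, voxel_size > 0,
            is.finite(k), mask_radius > 0, connectivity %in% c(6, 18, 26),
            min_voxels >= 1, rod_min_elongation >= 1,
            length(volume_band) == 2, volume_band[1] > 0,
            volume_band[1] <= volume_band[2], n_rotations >= 1,
            clash_cutoff > 0, contact_cutoff > 0, pocket_radius > 0,
            prune_cutoff > 0, cc_method %in% c("about-mean", "raw"))
  structure(list(display_target_volume = display_target_volume,
                 resolution = resolution, voxel_size = voxel_size, k = k,
                 mask_radius = mask_radius,
                 connectivity = as.integer(connectivity),
                 min_voxels = as.integer(min_voxels),
                 rod_min_elongation = rod_min_elongation,
                 volume_band = volume_band,
                 n_rotations = as.integer(n_rotations),
                 clash_cutoff = clash_cutoff, contact_cutoff = contact_cutoff,
                 pocket_radius = pocket_radius, prune_cutoff = prune_cutoff,
                 cc_method = cc_method, seed = as.integer(seed)),
            class = "pipeline_config")
}

.cfg_sim_params <- function(config) {
  simulation_params(resolution = config$resolution,
                    voxel_size = config$voxel_size)
}

.as_map <- function(x) if (inherits(x, "density_map")) x else read_density_map(x)
.as_model <- function(x) if (inherits(x, "model_structure")) x else read_model(x)
.as_ligand <- function(x) if (inherits(x, "ligand_atoms")) x else read_ligand(x)

#' Run the ligand-density detection pipeline on one map
#'
#' Stages, in order: equal-volume display threshold
#' ([threshold_for_volume()]); masking of model-accounted density
#' ([mask_modeled_density()]); blob search ([find_blobs()]); the
#' four-criterion screen per blob ([evaluate_criteria()]); and, for the
#' largest blob passing the first three criteria, rigid fitting
#' ([rigid_fit()]), flip disambiguation ([flip_compare()]), clash check and
#' contact listing. The map is flagged ligand-bearing when a blob passes all
#' evaluated criteria.
#'
#' @param map a [density_map] or path to an MRC file.
#' @param model a `model_structure` or path to a PDB/mmCIF file.
#' @param ligand a `ligand_atoms` or path to a PDB/SDF file.
#' @param config a [pipeline_config]; its `display_target_volume` must suit
#'   the map (for synthetic scenes use the scene truth's `display_volume`).
#' @param fit run the fitting stage for the best candidate (default TRUE).
#' @return A `detection_report` list (see fields in the implementation);
#'   serializable with [write_report_json()].
#' @export
run_detection <- function(map, model, ligand, config = pipeline_config(),
                          fit = TRUE) {
  map <- .as_map(map); model <- .as_model(model); ligand <- .as_ligand(ligand)
  params <- .cfg_sim_params(config)
  thr <- threshold_for_volume(map, config$display_target_volume)
  masked <- mask_modeled_density(map, model, config$mask_radius)
  blobs <- find_blobs(masked, thr$level, config$connectivity, config$min_voxels)
  reports <- lapply(blobs, evaluate_criteria,
                    protein_level = thr$level, ligand = ligand,
                    params = params, k = config$k,
                    rod_min_elongation = config$rod_min_elongation,
                    volume_band = config$volume_band)
  pass13 <- vapply(reports, function(r)
    r$c1_visible_at_protein_level && r$c2_rod_shaped && r$c3_volume_match,
    logical(1))
  best <- if (any(pass13)) which(pass13)[1] else NA_integer_
  pose <- NULL; flip <- NULL; clashes <- NULL; contacts <- NULL
  if (fit && !is.na(best)) {
    pose <- rigid_fit(ligand, map, blobs[[best]],
                      n_rotations = config$n_rotations, params = params,
                      k = config$k, method = config$cc_method)
    flip <- flip_compare(ligand, map, pose, params, config$k,
                         config$cc_method)
    clashes <- clash_check(pose, ligand, model, config$clash_cutoff)
    contacts <- contact_residues(pose, ligand, model, config$contact_cutoff)
    reports[[best]] <- evaluate_criteria(
      blobs[[best]], thr$level, ligand, params, config$k,
      config$rod_min_elongation, config$volume_band,
      pose = pose, model = model, clash_cutoff = config$clash_cutoff)
  }
  all_pass <- vapply(reports, `[[`, logical(1), "all_pass")
  structure(list(
    map_name = map$name,
    protein_level = thr$level,
    display_volume = thr$enclosed_volume,
    n_blobs = length(blobs),
    blob_table = blob_table(blobs),
    criteria = reports,
    best_candidate = best,
    ligand_bearing = !is.na(best) && all_pass[best],
    pose = pose,
    cc = if (!is.null(pose)) pose$cc else NA_real_,
    cc_flipped = if (!is.null(flip)) flip$cc_flipped else NA_real_,
    n_serious_clashes = if (!is.null(clashes)) clashes$n_serious else NA_integer_,
    contacts = contacts,
    config = unclass(config)), class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("detection_report '%s': level %.4g (%.0f A^3), %d blob(s), %s\n",
              x$map_name, x$protein_level, x$display_volume, x$n_blobs,
              if (x$ligand_bearing) "ligand-bearing" else "no qualifying feature"))
  if (!is.na(x$cc))
    cat(sprintf("  best fit cc %.3f vs flipped %.3f, %d serious clash(es)\n",
                x$cc, x$cc_flipped, x$n_serious_clashes))
  invisible(x)
}

#' Run the conformational-geometry pipeline
#'
#' Per model: the separation between the two named domains. Per model pair:
#' the matched, pruned RMSD. Per map (optional): the pocket volume around
#' the supplied reference atoms.
#'
#' @param models named list of `model_structure`s (or file paths).
#' @param selections list with [domain_selection]s `selA` and `selB`;
#'   defaults to the `nbd1`/`nbd2` attributes carried by toy transporter
#'   models.
#' @param maps optional named list of [density_map]s (or paths) for pocket
#'   volumes.
#' @param pocket_ref optional reference atoms for [pocket_volume()].
#' @param config a [pipeline_config].
#' @return A `geometry_report` list with `separations` (data frame),
#'   `rmsd` (data frame over model pairs), `pockets` (data frame or NULL)
#'   and the config echo.
#' @export
run_geometry <- function(models, selections = NULL, maps = NULL,
                         pocket_ref = NULL, config = pipeline_config()) {
  models <- lapply(models, .as_model)
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- paste0("model", seq_along(models))
  seps <- vapply(models, function(m) {
    sa <- if (!is.null(selections)) selections$selA else attr(m, "nbd1")
    sb <- if (!is.null(selections)) selections$selB else attr(m, "nbd2")
    if (is.null(sa) || is.null(sb)) return(NA_real_)
    domain_separation(m, sa, sb)
  }, numeric(1))
  separations <- data.frame(model = names(models), separation_A = seps,
                            stringsAsFactors = FALSE)
  pairs <- if (length(models) >= 2) utils::combn(names(models), 2) else NULL
  rmsd <- NULL
  if (!is.null(pairs)) {
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
      r <- matched_rmsd(models[[pairs[1, j]]], models[[pairs[2, j]]],
                        prune_cutoff = config$prune_cutoff)
      data.frame(modelA = pairs[1, j], modelB = pairs[2, j],
                 n_matched = r$n_matched, rmsd_all = r$rmsd_all,
                 n_retained = r$n_retained, rmsd_retained = r$rmsd_retained,
                 stringsAsFactors = FALSE)
    })
    rmsd <- do.call(rbind, rows)
  }
  pockets <- NULL
  if (!is.null(maps) && !is.null(pocket_ref)) {
    maps <- lapply(maps, .as_map)
    if (is.null(names(maps)) || any(names(maps) == ""))
      names(maps) <- paste0("map", seq_along(maps))
    rows <- lapply(names(maps), function(nm) {
      p <- pocket_volume(maps[[nm]], pocket_ref, config$pocket_radius)
      data.frame(map = nm, pocket_volume_A3 = p$volume,
                 voxel_count = p$voxel_count, radius_A = p$radius,
                 stringsAsFactors = FALSE)
    })
    pockets <- do.call(rbind, rows)
  }
  structure(list(separations = separations, rmsd = rmsd, pockets = pockets,
                 config = unclass(config)), class = "geometry_report")
}

#' Serialize a pipeline report as JSON
#'
#' Poses are flattened to numeric vectors; blob voxel index lists are
#' dropped. Deterministic: no timestamps.
#'
#' @param report a `detection_report` or `geometry_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  x <- unclass(report)
  if (!is.null(x$pose))
    x$pose <- list(rotation = as.numeric(x$pose$rotation),
                   translation = x$pose$translation, cc = x$pose$cc,
                   n_scored_voxels = x$pose$n_scored_voxels)
  if (!is.null(x$criteria))
    x$criteria <- lapply(x$criteria, unclass)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", dataframe = "columns")
  invisible(path)
}
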