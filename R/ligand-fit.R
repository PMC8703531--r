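#' Rigid-body pose of a ligand
#'
#' A pose rotates the ligand about its own heavy-atom geometric center and
#' places that center at `translation`: posed coordinates are
#' `R (x - center) + translation`.
#'
#' @param rotation 3 x 3 proper orthonormal matrix.
#' @param translation length-3 position (Angstrom) of the ligand center
#'   after posing.
#' @param cc optional correlation score attached to the pose.
#' @param n_scored_voxels optional size of the scoring region.
#' @return A `ligand_pose` object.
#' @export
ligand_pose <- function(rotation, translation, cc = NA_real_,
                        n_scored_voxels = NA_integer_) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be a proper orthonormal matrix")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 cc = cc, n_scored_voxels = n_scored_voxels),
            class = "ligand_pose")
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat(sprintf("ligand_pose: center (%.2f, %.2f, %.2f) A, rotation %.1f deg, cc %s\n",
              x$translation[1], x$translation[2], x$translation[3],
              rotation_angle_deg(x$rotation),
              ifelse(is.na(x$cc), "NA", sprintf("%.4f", x$cc))))
  invisible(x)
}

.ligand_center <- function(ligand) colMeans(atom_coords(ligand, heavy_only = TRUE))

#' Apply a pose to ligand atoms
#' @param ligand a `ligand_atoms`.
#' @param pose a [ligand_pose].
#' @return A `ligand_atoms` with transformed coordinates.
#' @export
apply_pose <- function(ligand, pose) {
  ctr <- .ligand_center(ligand)
  xyz <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  new <- sweep(xyz, 2, ctr) %*% t(pose$rotation)
  new <- sweep(new, 2, pose$translation, "+")
  out <- ligand
  out$atoms$x <- new[, 1]; out$atoms$y <- new[, 2]; out$atoms$z <- new[, 3]
  out
}

# Sub-box of the experimental grid covering the posed ligand bounding box
# plus padding, clipped to the map. Returns index ranges or errors when the
# envelope leaves the map.
.scoring_box <- function(map, posed_xyz, padding) {
  lo_a <- apply(posed_xyz, 2, min)
  hi_a <- apply(posed_xyz, 2, max)
  map_hi <- map$origin + (map$dims - 1) * map$voxel_size
  if (any(lo_a < map$origin - 1e-9) || any(hi_a > map_hi + 1e-9))
    stop("posed ligand envelope lies outside the map bounds")
  i0 <- pmax(0L, as.integer(floor((lo_a - padding - map$origin) / map$voxel_size)))
  i1 <- pmin(map$dims - 1L,
             as.integer(ceiling((hi_a + padding - map$origin) / map$voxel_size)))
  list(i0 = i0, i1 = i1)
}

#' Correlation between a posed ligand's simulated density and a map
#'
#' Simulates the posed ligand on the experimental grid (restricted to the
#' ligand bounding box plus the simulation padding), takes the simulated
#' sub-map's own `mean + k * sd` level, and computes the correlation between
#' simulated and experimental values over the voxels at or above that level.
#'
#' @param ligand a `ligand_atoms`.
#' @param pose a [ligand_pose].
#' @param map the experimental [density_map].
#' @param params a [simulation_params]; its resolution and weighting define
#'   the simulated ligand density.
#' @param k SD multiplier defining the scoring envelope (default 7).
#' @param method `"about-mean"` for Pearson correlation (default) or
#'   `"raw"` for the overlap without mean subtraction.
#' @return List with `cc` and `n_scored_voxels`.
#' @export
correlation_score <- function(ligand, pose, map, params = simulation_params(),
                              k = 7, method = c("about-mean", "raw")) {
  method <- match.arg(method)
  posed <- apply_pose(ligand, pose)
  xyz <- atom_coords(posed, heavy_only = TRUE)
  box <- .scoring_box(map, xyz, params$padding)
  dims <- box$i1 - box$i0 + 1L
  org <- map$origin + box$i0 * map$voxel_size
  sim <- .simulate_on_grid(posed$atoms[posed$atoms$element != "H", ],
                           dims, org, map$voxel_size, params)
  sv <- as.numeric(sim)
  level <- mean(sv) + k * sqrt(mean((sv - mean(sv))^2))
  sel <- sv >= level
  n <- sum(sel)
  if (n < 2) stop("degenerate scoring region: fewer than 2 voxels above level")
  exp_vals <- map$values[(box$i0[1] + 1):(box$i1[1] + 1),
                         (box$i0[2] + 1):(box$i1[2] + 1),
                         (box$i0[3] + 1):(box$i1[3] + 1)]
  e <- as.numeric(exp_vals)[sel]
  s <- sv[sel]
  cc <- if (method == "about-mean") {
    if (stats::sd(s) == 0 || stats::sd(e) == 0) 0
    else stats::cor(s, e)
  } else {
    d <- sqrt(sum(s^2) * sum(e^2))
    if (d == 0) 0 else sum(s * e) / d
  }
  list(cc = cc, n_scored_voxels = as.integer(n))
}

# Objective wrapper: cc of a (rotation, translation) pair, -Inf out of bounds.
.pose_cc <- function(ligand, R, t, map, params, k, method) {
  tryCatch(correlation_score(ligand, ligand_pose(R, t), map, params, k,
                             method)$cc,
           error = function(e) -Inf)
}

#' Rigid-body fit of a ligand into a density blob
#'
#' Exhaustive search over a deterministic quasi-uniform rotation grid with
#' the ligand center fixed at the blob centroid, followed by optional local
#' refinement: repeated coordinate-wise golden-section search over
#' translation (within +/- 2 A per axis) and rotation (within +/- 15 degrees
#' about each axis), re-centered on the current best pose each sweep. The
#' whole procedure is deterministic for fixed inputs.
#'
#' @param ligand a `ligand_atoms`.
#' @param map the experimental [density_map].
#' @param blob a blob from [find_blobs()] (its centroid seeds the search).
#' @param n_rotations rotation-grid size (default 576).
#' @param local_refine run the local refinement stage (default TRUE).
#' @param params a [simulation_params].
#' @param k SD multiplier for the scoring envelope (default 7).
#' @param method correlation variant, see [correlation_score()].
#' @param refine_sweeps number of refinement sweeps (default 3).
#' @return A [ligand_pose] with `cc` and `n_scored_voxels` filled in.
#' @export
rigid_fit <- function(ligand, map, blob, n_rotations = 576,
                      local_refine = TRUE, params = simulation_params(),
                      k = 7, method = "about-mean", refine_sweeps = 3) {
  stopifnot(n_rotations >= 1)
  ctr <- as.numeric(blob$centroid)
  grid <- rotation_grid(n_rotations)
  best_cc <- -Inf
  best_R <- NULL
  for (R in grid) {
    cc <- .pose_cc(ligand, R, ctr, map, params, k, method)
    if (cc > best_cc) { best_cc <- cc; best_R <- R }
  }
  if (!is.finite(best_cc))
    stop("fit failure: every candidate pose fell outside the map bounds")
  best_t <- ctr
  if (local_refine) {
    lig_axes <- .ligand_principal_axes(ligand)
    for (sweep in seq_len(refine_sweeps)) {
      for (d in 1:3) {                   # translation along axis d
        f <- function(dt) {
          t2 <- best_t; t2[d] <- t2[d] + dt
          .pose_cc(ligand, best_R, t2, map, params, k, method)
        }
        op <- stats::optimize(f, c(-2, 2), maximum = TRUE, tol = 0.02)
        if (op$objective > best_cc) {
          best_cc <- op$objective
          best_t[d] <- best_t[d] + op$maximum
        }
      }
      # rotations about the posed ligand's own principal axes; the long axis
      # gets a wide scan (spin about an elongated ligand's shaft is the
      # weakly determined degree of freedom), the others a narrow one
      for (d in 1:3) {
        axis_w <- as.numeric(best_R %*% lig_axes[, d])
        f <- function(da) {
          R2 <- rotation_about_axis(axis_w, da * pi / 180) %*% best_R
          .pose_cc(ligand, R2, best_t, map, params, k, method)
        }
        half <- if (d == 1) 90 else 15
        if (d == 1) {                    # coarse scan, then local search
          grid_a <- seq(-half, half, by = 7.5)
          vals <- vapply(grid_a, f, numeric(1))
          a0 <- grid_a[which.max(vals)]
          op <- stats::optimize(f, c(a0 - 7.5, a0 + 7.5), maximum = TRUE,
                                tol = 0.2)
        } else {
          op <- stats::optimize(f, c(-half, half), maximum = TRUE, tol = 0.2)
        }
        if (op$objective > best_cc) {
          best_cc <- op$objective
          best_R <- rotation_about_axis(axis_w, op$maximum * pi / 180) %*% best_R
        }
      }
    }
  }
  sc <- correlation_score(ligand, ligand_pose(best_R, best_t), map, params,
                          k, method)
  ligand_pose(best_R, best_t, cc = sc$cc, n_scored_voxels = sc$n_scored_voxels)
}

# Principal axes of the ligand heavy atoms (columns = descending variance).
.ligand_principal_axes <- function(ligand) {
  xyz <- atom_coords(ligand, heavy_only = TRUE)
  cc <- sweep(xyz, 2, colMeans(xyz))
  eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors
}

#' Compare a pose with its end-over-end flip
#'
#' The flipped pose composes the given pose with a 180-degree rotation about
#' the ligand's second principal axis through its center, which swaps the
#' two ends of an elongated molecule. Both correlation scores are returned;
#' the larger identifies the preferred orientation.
#'
#' @param ligand a `ligand_atoms`.
#' @param map the experimental [density_map].
#' @param pose a [ligand_pose].
#' @param params a [simulation_params].
#' @param k SD multiplier for the scoring envelope (default 7).
#' @param method correlation variant, see [correlation_score()].
#' @return List with `cc_pose`, `cc_flipped`, `preferred`
#'   (`"pose"`/`"flipped"`), and the flipped [ligand_pose].
#' @export
flip_compare <- function(ligand, map, pose, params = simulation_params(),
                         k = 7, method = "about-mean") {
  ax <- .ligand_principal_axes(ligand)[, 2]
  R_flip <- pose$rotation %*% rotation_about_axis(ax, pi)
  flipped <- ligand_pose(R_flip, pose$translation)
  s0 <- correlation_score(ligand, pose, map, params, k, method)
  s1 <- correlation_score(ligand, flipped, map, params, k, method)
  flipped$cc <- s1$cc
  flipped$n_scored_voxels <- s1$n_scored_voxels
  list(cc_pose = s0$cc, cc_flipped = s1$cc,
       preferred = if (s0$cc >= s1$cc) "pose" else "flipped",
       flipped_pose = flipped)
}

#' Steric clashes between a posed ligand and a model
#'
#' All ligand-heavy / protein-heavy atom pairs closer than `serious_cutoff`
#' are listed. A cell-list spatial index is used; it returns exactly the
#' all-pairs result.
#'
#' @param pose a [ligand_pose].
#' @param ligand a `ligand_atoms`.
#' @param model a `model_structure`.
#' @param serious_cutoff clash distance in Angstrom (default 2.0).
#' @return A `clash_report`: data frame `pairs` (ligand_atom, protein index,
#'   chain, resno, resid, distance), `n_serious`, `cutoff`.
#' @export
clash_check <- function(pose, ligand, model, serious_cutoff = 2.0) {
  stopifnot(serious_cutoff > 0)
  posed <- apply_pose(ligand, pose)
  la <- posed$atoms[posed$atoms$element != "H", , drop = FALSE]
  pa <- model$atoms[model$atoms$element != "H", , drop = FALSE]
  hits <- .cpp_close_pairs(as.matrix(la[, c("x", "y", "z")]),
                           as.matrix(pa[, c("x", "y", "z")]), serious_cutoff)
  pairs <- data.frame(
    ligand_atom = la$atom_name[hits[, 1]],
    chain = pa$chain[hits[, 2]],
    resno = pa$resno[hits[, 2]],
    resid = pa$resid[hits[, 2]],
    protein_atom = pa$atom_name[hits[, 2]],
    distance = hits[, 3],
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$distance), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, n_serious = nrow(pairs),
                 cutoff = serious_cutoff), class = "clash_report")
}

#' Residues in contact with a posed ligand
#'
#' Residues with any heavy atom within `contact_cutoff` of any posed ligand
#' heavy atom, sorted by minimum distance.
#'
#' @param pose a [ligand_pose].
#' @param ligand a `ligand_atoms`.
#' @param model a `model_structure`.
#' @param contact_cutoff contact distance in Angstrom (default 4.5).
#' @return Data frame with columns `chain, resno, resid, min_distance`.
#' @export
contact_residues <- function(pose, ligand, model, contact_cutoff = 4.5) {
  stopifnot(contact_cutoff > 0)
  posed <- apply_pose(ligand, pose)
  la <- posed$atoms[posed$atoms$element != "H", , drop = FALSE]
  pa <- model$atoms[model$atoms$element != "H", , drop = FALSE]
  hits <- .cpp_close_pairs(as.matrix(la[, c("x", "y", "z")]),
                           as.matrix(pa[, c("x", "y", "z")]), contact_cutoff)
  if (nrow(hits) == 0)
    return(data.frame(chain = character(0), resno = integer(0),
                      resid = character(0), min_distance = numeric(0),
                      stringsAsFactors = FALSE))
  key <- paste(pa$chain[hits[, 2]], pa$resno[hits[, 2]], pa$resid[hits[, 2]],
               sep = "\r")
  mind <- tapply(hits[, 3], key, min)
  parts <- do.call(rbind, strsplit(names(mind), "\r", fixed = TRUE))
  out <- data.frame(chain = parts[, 1], resno = as.integer(parts[, 2]),
                    resid = parts[, 3], min_distance = as.numeric(mind),
                    stringsAsFactors = FALSE)
  out <- out[order(out$min_distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
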