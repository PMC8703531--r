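# All randomness in the generator flows from one master seed through this
# documented splitting scheme: stream k of master seed s uses
# (s * 1009 + k * 101) mod (2^31 - 1).
.split_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1009 + as.double(stream) * 101) %% 2147483647)
}

#' Uniform random rotation matrix
#' @param seed integer seed (splitting stream 7 of the master seed).
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function(seed) {
  set.seed(.split_seed(seed, 7))
  q <- stats::rnorm(4)
  .quat_to_matrix(q / sqrt(sum(q^2)))
}

#' Toy elongated "rocket" ligand
#'
#' A linear shaft of pseudo-atoms spaced 1.5 A with optional fin atoms
#' branching at one end, mimicking an elongated drug whose two bulky groups
#' mark one end. With fins the molecule is end-to-end asymmetric; without
#' them it is (up to jitter) symmetric. Deterministic per seed.
#'
#' @param n_shaft_atoms shaft length in atoms (>= 3, default 10).
#' @param n_fin_atoms 0 or 2 fin atoms (default 2).
#' @param seed integer seed for the small coordinate jitter.
#' @param jitter_sd per-coordinate jitter SD in Angstrom (default 0.05).
#' @return A `ligand_atoms` centered at the origin, shaft along x, fins at
#'   the +x end.
#' @export
make_toy_ligand <- function(n_shaft_atoms = 10, n_fin_atoms = 2, seed = 1,
                            jitter_sd = 0.05) {
  stopifnot(n_shaft_atoms >= 3, n_fin_atoms %in% c(0L, 2L))
  xs <- (seq_len(n_shaft_atoms) - 1) * 1.5
  xyz <- cbind(xs, 0, 0)
  if (n_fin_atoms == 2) {
    tip <- max(xs)
    xyz <- rbind(xyz,
                 c(tip - 0.7, 2.0, 0),
                 c(tip - 0.7, -2.0, 0))
  }
  set.seed(.split_seed(seed, 1))
  xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, jitter_sd), ncol = 3)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  ligand_from_coords(xyz, element = "C",
                     label = sprintf("toy-rocket-%d+%d", n_shaft_atoms,
                                     n_fin_atoms))
}

# One pseudo-helical Calpha trace: `n_res` residues, 1.5 A rise, 100 deg turn,
# 2.3 A radius, axis along `axis` starting at `base`.
.helix_trace <- function(base, axis, n_res, radius = 2.3, rise = 1.5,
                         turn_deg = 100) {
  u <- axis / sqrt(sum(axis^2))
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  i <- seq_len(n_res) - 1
  ang <- i * turn_deg * pi / 180
  t(vapply(seq_along(i), function(j)
    base + i[j] * rise * u + radius * (cos(ang[j]) * e1 + sin(ang[j]) * e2),
    numeric(3)))
}

#' Toy two-domain transporter model
#'
#' A Calpha-trace pseudo-structure emulating an inward-facing V-shaped
#' transporter: two helix-bundle "NBD" domains (chains A and B) whose mass
#' centers sit exactly `separation` apart on the x axis, and two crossing
#' "TM" arms (chains C and D) rising from the domains to an apex, leaving a
#' central aqueous cavity between the arms. Deterministic per seed.
#'
#' @param separation NBD center-of-mass separation in Angstrom (> 0).
#' @param n_helices_per_domain helices per NBD bundle (default 3).
#' @param seed integer seed for coordinate jitter.
#' @param jitter_sd per-coordinate jitter SD in Angstrom (default 0.15).
#' @return A `model_structure` with attributes `nbd1`, `nbd2`
#'   ([domain_selection]s), `ligand_site` (cavity center, length-3),
#'   and `separation`.
#' @export
make_toy_transporter <- function(separation, n_helices_per_domain = 3,
                                 seed = 1, jitter_sd = 0.15) {
  stopifnot(separation > 0)
  set.seed(.split_seed(seed, 2))
  half <- separation / 2
  n_res <- 12
  bundle <- function(cx) {
    ang <- 2 * pi * (seq_len(n_helices_per_domain) - 1) / n_helices_per_domain
    do.call(rbind, lapply(ang, function(a)
      .helix_trace(c(cx + 5 * cos(a), 5 * sin(a), -16), c(0, 0, 1), n_res)))
  }
  nbd1 <- bundle(-half)
  nbd2 <- bundle(half)
  arm <- function(x0, x1) {
    d <- c(x1 - x0, 0, 44)
    n <- 16
    rbind(
      t(vapply(0:(n - 1), function(i) c(x0, -3, 4) + (i / (n - 1)) * d, numeric(3))),
      t(vapply(0:(n - 1), function(i) c(x0, 3, 4) + (i / (n - 1)) * d, numeric(3))))
  }
  armC <- arm(-half, 12)
  armD <- arm(half, -12)
  jit <- function(m) m + matrix(stats::rnorm(length(m), 0, jitter_sd), ncol = 3)
  nbd1 <- jit(nbd1); nbd2 <- jit(nbd2); armC <- jit(armC); armD <- jit(armD)
  # recenter each NBD so the COM separation is exact (all atoms carbon)
  nbd1 <- sweep(nbd1, 2, colMeans(nbd1) - c(-half, 0, -8))
  nbd2 <- sweep(nbd2, 2, colMeans(nbd2) - c(half, 0, -8))
  mk <- function(m, chain) data.frame(
    chain = chain, resno = seq_len(nrow(m)), insert = "", resid = "ALA",
    atom_name = "CA", element = "C",
    x = m[, 1], y = m[, 2], z = m[, 3], occupancy = 1, is_water = FALSE,
    stringsAsFactors = FALSE)
  atoms <- rbind(mk(nbd1, "A"), mk(nbd2, "B"), mk(armC, "C"), mk(armD, "D"))
  model <- .new_model_structure(atoms,
                                name = sprintf("toy-transporter-%g", separation))
  attr(model, "nbd1") <- domain_selection("NBD1", "A", 1, nrow(nbd1))
  attr(model, "nbd2") <- domain_selection("NBD2", "B", 1, nrow(nbd2))
  attr(model, "ligand_site") <- c(0, 0, 16)
  attr(model, "separation") <- separation
  model
}

# Low-amplitude Gaussian-tube torus emulating a detergent micelle annulus
# around the TM midsection.
.add_micelle <- function(map, center = c(0, 0, 26), major_radius = 28,
                         tube_sd = 5, amplitude) {
  cx <- axis_coords(map, 1) - center[1]
  cy <- axis_coords(map, 2) - center[2]
  cz <- axis_coords(map, 3) - center[3]
  rxy <- sqrt(outer(cx^2, cy^2, "+"))
  for (k in seq_along(cz)) {
    d2 <- (rxy - major_radius)^2 + cz[k]^2
    map$values[, , k] <- map$values[, , k] + amplitude * exp(-d2 / (2 * tube_sd^2))
  }
  map
}

#' Build a ground-truthed synthetic scene
#'
#' Simulates the model density, optionally adds an occupancy-weighted posed
#' ligand and a micelle annulus, then white Gaussian voxel noise with SD
#' equal to `noise_sd` times the noiseless signal peak. Also records the
#' scene's protein display volume: the volume enclosed by the noiseless
#' protein-only map at its own `mean + 5 sd` level — the generator's fixed
#' display rule, emulating the tight (molecular-volume) display convention
#' used for experimental maps.
#'
#' @param model a `model_structure` from [make_toy_transporter()].
#' @param ligand optional `ligand_atoms`.
#' @param pose optional [ligand_pose]; default places the ligand at the
#'   model's cavity site under a seeded uniform random rotation.
#' @param params a [simulation_params].
#' @param noise_sd noise SD as a fraction of the signal peak (default 0.05).
#' @param occupancy ligand occupancy in [0, 1] (default 1).
#' @param micelle add the micelle annulus (default FALSE).
#' @param seed integer seed; drives pose and noise through the documented
#'   splitting scheme.
#' @return List with `map` (a [density_map]) and `truth` (a `scene_truth`
#'   list recording seed, separation, ligand presence, pose, occupancy,
#'   noise, resolution, voxel size, micelle flag and display volume).
#' @export
build_scene <- function(model, ligand = NULL, pose = NULL,
                        params = simulation_params(), noise_sd = 0.05,
                        occupancy = 1, micelle = FALSE, seed = 1) {
  stopifnot(occupancy >= 0, occupancy <= 1, noise_sd >= 0)
  protein <- simulate_map(model, params, name = "scene")
  disp <- enclosed_volume(protein, sd_threshold(protein, 5))$enclosed_volume
  map <- protein
  if (!is.null(ligand)) {
    if (is.null(pose)) {
      site <- attr(model, "ligand_site")
      if (is.null(site)) stop("model carries no ligand_site; supply a pose")
      pose <- ligand_pose(random_rotation(seed), site)
    }
    posed <- apply_pose(ligand, pose)
    xyz <- atom_coords(posed, heavy_only = TRUE)
    box <- tryCatch(.scoring_box(map, xyz, 0),
                    error = function(e) stop("ligand pose outside the map box"))
    lig_vals <- .simulate_on_grid(posed$atoms[posed$atoms$element != "H", ],
                                  map$dims, map$origin, map$voxel_size, params)
    map$values <- map$values + occupancy * lig_vals
  }
  if (micelle) {
    site <- attr(model, "ligand_site")
    ctr <- if (is.null(site)) colMeans(atom_coords(model)) else site
    map <- .add_micelle(map, center = ctr, amplitude = 0.15 * max(map$values))
  }
  peak <- max(map$values)
  if (noise_sd > 0) {
    set.seed(.split_seed(seed, 3))
    map$values <- map$values +
      array(stats::rnorm(prod(map$dims), 0, noise_sd * peak), dim = map$dims)
  }
  truth <- structure(list(
    seed = seed,
    domain_separation = attr(model, "separation"),
    ligand_present = !is.null(ligand),
    ligand_pose = if (!is.null(ligand))
      list(rotation = pose$rotation, translation = pose$translation),
    occupancy = if (!is.null(ligand)) occupancy else 0,
    noise_sd = noise_sd,
    resolution = params$resolution,
    voxel_size = params$voxel_size,
    micelle = micelle,
    display_volume = disp), class = "scene_truth")
  list(map = map, truth = truth)
}

#' Generate the default five-class ensemble of synthetic scenes
#'
#' One scene per class, emulating an ensemble of inward-facing conformations
#' at NBD separations `separations` with the ligand present only where
#' `ligand_in` is TRUE (default: only the first, widest class). When `dir`
#' is given, each class's map (MRC2014), model (PDB) and truth (JSON) are
#' written there along with a `manifest.tsv`.
#'
#' @param separations NBD separations in Angstrom
#'   (default `c(60, 56, 60, 55, 53)`).
#' @param ligand_in logical vector, same length (default ligand only in
#'   class 1).
#' @param params a [simulation_params].
#' @param noise_sd noise level as in [build_scene()] (default 0.05).
#' @param micelle per-class micelle flags (default all FALSE).
#' @param seed master seed; class k uses splitting stream 10 + k.
#' @param dir optional output directory for fixture files.
#' @return List with `scenes` (list of `list(map, model, ligand, truth)`)
#'   and `manifest` (data frame).
#' @export
make_ensemble <- function(separations = c(60, 56, 60, 55, 53),
                          ligand_in = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                          params = simulation_params(), noise_sd = 0.05,
                          micelle = rep(FALSE, length(separations)),
                          seed = 1, dir = NULL) {
  stopifnot(length(ligand_in) == length(separations),
            length(micelle) == length(separations))
  ligand <- make_toy_ligand(seed = .split_seed(seed, 5))
  scenes <- vector("list", length(separations))
  rows <- vector("list", length(separations))
  for (k in seq_along(separations)) {
    class_seed <- .split_seed(seed, 10 + k)
    model <- make_toy_transporter(separations[k], seed = class_seed)
    sc <- build_scene(model, ligand = if (ligand_in[k]) ligand,
                      params = params, noise_sd = noise_sd,
                      micelle = micelle[k], seed = class_seed)
    scenes[[k]] <- list(map = sc$map, model = model,
                        ligand = if (ligand_in[k]) ligand, truth = sc$truth)
    rows[[k]] <- data.frame(
      class = letters[k], separation_A = separations[k],
      ligand = ligand_in[k], micelle = micelle[k], seed = class_seed,
      map = sprintf("class_%s.mrc", letters[k]),
      model = sprintf("class_%s.pdb", letters[k]),
      truth = sprintf("class_%s_truth.json", letters[k]),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(scenes)) {
      write_density_map(scenes[[k]]$map, file.path(dir, manifest$map[k]))
      write_pdb_atoms(scenes[[k]]$model, file.path(dir, manifest$model[k]))
      tr <- scenes[[k]]$truth
      tr$ligand_pose$rotation <- if (!is.null(tr$ligand_pose))
        as.numeric(tr$ligand_pose$rotation)
      jsonlite::write_json(unclass(tr), file.path(dir, manifest$truth[k]),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  list(scenes = scenes, manifest = manifest)
}
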