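#' Domain selection by chain and residue ranges
#'
#' @param label free-text domain label (e.g. "NBD1").
#' @param chain character vector of chain ids, one per range.
#' @param start,end inclusive residue-number bounds, recycled with `chain`.
#' @return A `domain_selection` object.
#' @export
domain_selection <- function(label, chain, start, end) {
  n <- max(length(chain), length(start), length(end))
  chain <- rep_len(chain, n); start <- rep_len(start, n); end <- rep_len(end, n)
  if (any(start > end)) stop("selection range with start > end")
  structure(list(label = label,
                 ranges = data.frame(chain = chain, start = as.integer(start),
                                     end = as.integer(end),
                                     stringsAsFactors = FALSE)),
            class = "domain_selection")
}

#' Read named domain selections from a YAML file
#'
#' Expected layout: `label: [{chain: A, start: 1, end: 100}, ...]`.
#'
#' @param path YAML file path.
#' @return Named list of [domain_selection] objects.
#' @export
read_selections_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(stats::setNames(names(y), names(y)), function(lab) {
    r <- y[[lab]]
    domain_selection(lab,
                     chain = vapply(r, `[[`, "", "chain"),
                     start = vapply(r, function(e) as.integer(e$start), 0L),
                     end = vapply(r, function(e) as.integer(e$end), 0L))
  })
}

.select_atoms <- function(model, selection) {
  a <- model$atoms
  keep <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(selection$ranges))) {
    r <- selection$ranges[i, ]
    keep <- keep | (a$chain == r$chain & a$resno >= r$start & a$resno <= r$end)
  }
  a[keep & !a$is_water, , drop = FALSE]
}

#' Center of mass of a domain selection
#'
#' @param model a `model_structure`.
#' @param selection a [domain_selection].
#' @param weighting `"mass"` (standard atomic masses, default) or
#'   `"geometric"` (unweighted mean).
#' @return Length-3 position in Angstrom.
#' @export
center_of_mass <- function(model, selection, weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  a <- .select_atoms(model, selection)
  if (nrow(a) == 0)
    stop("selection '", selection$label, "' matches no atoms")
  w <- if (weighting == "mass") atomic_mass(a$element) else rep(1, nrow(a))
  as.numeric(colSums(as.matrix(a[, c("x", "y", "z")]) * w) / sum(w))
}

#' Distance between two domain centers of mass
#'
#' @param model a `model_structure`.
#' @param selA,selB two [domain_selection]s.
#' @param weighting passed to [center_of_mass()].
#' @return Euclidean separation in Angstrom.
#' @export
domain_separation <- function(model, selA, selB, weighting = "mass") {
  ca <- center_of_mass(model, selA, weighting)
  cb <- center_of_mass(model, selB, weighting)
  sqrt(sum((ca - cb)^2))
}

#' Voxel-rule binding-pocket volume
#'
#' Counts voxels whose center lies within `radius` of any reference atom and
#' whose value is strictly below the whole-map mean, and reports the
#' corresponding physical volume — the openness proxy for a nucleotide site.
#'
#' @param map a [density_map].
#' @param ref_atoms a `ligand_atoms`, `model_structure`, selection result, or
#'   n x 3 coordinate matrix giving the reference (e.g. positioned
#'   nucleotide) atoms.
#' @param radius shell radius in Angstrom (default 5.0).
#' @return List with `volume` (A^3), `voxel_count`, `radius`, `rule`.
#' @export
pocket_volume <- function(map, ref_atoms, radius = 5.0) {
  stopifnot(radius > 0)
  xyz <- if (is.matrix(ref_atoms)) ref_atoms
         else as.matrix(ref_atoms$atoms[, c("x", "y", "z")])
  if (nrow(xyz) == 0) stop("empty reference selection")
  idx <- .cpp_voxels_near_atoms(map$dims, map$origin, map$voxel_size, xyz,
                                radius)
  mu <- mean(map$values)
  n <- sum(map$values[idx] < mu)
  list(volume = n * voxel_volume(map), voxel_count = as.integer(n),
       radius = radius, rule = "value < whole-map mean (strict)")
}

# Kabsch: optimal rotation/translation superposing B onto A (n x 3 each).
.kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(B, 2, cb), sweep(A, 2, ca))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = ca - as.numeric(R %*% cb))
}

.transform_xyz <- function(xyz, R, t) sweep(xyz %*% t(R), 2, t, "+")

#' Matched-atom RMSD with iterative distance pruning
#'
#' Matches atoms between two models by (chain, residue number, insertion
#' code, atom name) restricted to `atom_name` (default Calpha), then
#' iterates: least-squares superposition of B onto A over the retained
#' pairs, prune pairs deviating by more than `prune_cutoff`, repeat until the
#' retained set is stable or `max_iter` is reached. Reports the RMSD over
#' the retained pairs and over all matched pairs in the final frame, in the
#' convention "X over n pairs within cutoff, Y overall m pairs".
#'
#' @param modelA,modelB two `model_structure`s.
#' @param atom_name atom used for matching (default `"CA"`).
#' @param prune_cutoff pruning distance in Angstrom (default 2.0);
#'   `max_iter = 1` gives a single superposition with no pruning applied to
#'   the report beyond the first pass.
#' @param max_iter maximum superpose-prune iterations (default 20).
#' @return An `rmsd_report` list: `n_matched`, `rmsd_all`, `n_retained`,
#'   `rmsd_retained`, `prune_cutoff`, `iterations`, `pruning_failed`,
#'   `retained_key` (match keys of the retained pairs).
#' @export
matched_rmsd <- function(modelA, modelB, atom_name = "CA", prune_cutoff = 2.0,
                         max_iter = 20) {
  a <- modelA$atoms[modelA$atoms$atom_name == atom_name & !modelA$atoms$is_water, ]
  b <- modelB$atoms[modelB$atoms$atom_name == atom_name & !modelB$atoms$is_water, ]
  keyA <- paste(a$chain, a$resno, a$insert, a$atom_name)
  keyB <- paste(b$chain, b$resno, b$insert, b$atom_name)
  common <- intersect(keyA, keyB)
  if (length(common) < 3)
    stop("fewer than 3 matched atom pairs between the models")
  A <- as.matrix(a[match(common, keyA), c("x", "y", "z")])
  B <- as.matrix(b[match(common, keyB), c("x", "y", "z")])
  n <- length(common)
  retained <- rep(TRUE, n)
  fit <- NULL
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    fit <- .kabsch(A[retained, , drop = FALSE], B[retained, , drop = FALSE])
    Bt <- .transform_xyz(B, fit$R, fit$t)
    dev <- sqrt(rowSums((A - Bt)^2))
    new_retained <- dev <= prune_cutoff
    if (sum(new_retained) < 3) break     # refuse to prune below a rigid fit
    if (identical(new_retained, retained)) break
    retained <- new_retained
  }
  Bt <- .transform_xyz(B, fit$R, fit$t)
  dev <- sqrt(rowSums((A - Bt)^2))
  pruning_failed <- sum(dev <= prune_cutoff) < 3
  if (pruning_failed) retained <- rep(TRUE, n)
  rmsd_all <- sqrt(mean(dev^2))
  rmsd_ret <- sqrt(mean(dev[retained]^2))
  structure(list(n_matched = n, rmsd_all = rmsd_all,
                 n_retained = sum(retained), rmsd_retained = rmsd_ret,
                 prune_cutoff = prune_cutoff, iterations = iters,
                 pruning_failed = pruning_failed,
                 retained_key = common[retained]),
            class = "rmsd_report")
}

#' @export
print.rmsd_report <- function(x, ...) {
  cat(sprintf("rmsd %.2f A for %d atom pairs within %g A, %.2f A overall %d atom pairs\n",
              x$rmsd_retained, x$n_retained, x$prune_cutoff, x$rmsd_all,
              x$n_matched))
  invisible(x)
}
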