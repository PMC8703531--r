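# Shared fixture builders; everything is generated in code.

random_map <- function(dims = c(16, 16, 16), voxel = 1, origin = c(0, 0, 0),
                       seed = 1) {
  set.seed(seed)
  density_map(array(rnorm(prod(dims)), dim = dims), voxel, origin,
              name = paste0("rand", seed))
}

# apply a rigid motion to every atom of a model
transform_model <- function(model, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

# model_structure from a bare coordinate matrix (CA trace, chain A)
trace_model <- function(xyz, chain = "A", name = "trace") {
  df <- data.frame(chain = chain, resno = seq_len(nrow(xyz)), insert = "",
                   resid = "ALA", atom_name = "CA", element = "C",
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   occupancy = 1, is_water = FALSE, stringsAsFactors = FALSE)
  cryomap:::.new_model_structure(df, name = name)
}

# minimal 3-atom PDB text
minimal_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       3.200   3.300   3.000  1.00  0.00           C",
    "END"), path)
  path
}

# same 3 atoms as mmCIF
minimal_cif <- function(path) {
  writeLines(c(
    "data_test",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 1.000 2.000 3.000 1.00 0.00 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.500 2.000 3.000 1.00 0.00 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 3.200 3.300 3.000 1.00 0.00 1 ALA A C 1"), path)
  path
}

# 5-heavy-atom SDF (V2000) with 2 explicit hydrogens
small_sdf <- function(path) {
  writeLines(c(
    "small",
    "  test",
    "",
    "  7  6  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    3.0000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
    "    4.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    6.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6000    0.9000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6000   -0.9000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0",
    "  2  3  1  0",
    "  3  4  1  0",
    "  4  5  2  0",
    "  1  6  1  0",
    "  1  7  1  0",
    "M  END",
    "$$$$"), path)
  path
}

ivacaftor_path <- function() {
  system.file("extdata", "ivacaftor_synthetic.sdf", package = "cryomap")
}

# pose rotation error modulo the toy ligand's exact two-fold symmetry about
# its shaft (fins at +y/-y are equivalent atoms)
pose_rotation_error <- function(ligand, R_fit, R_true) {
  ax <- cryomap:::.ligand_principal_axes(ligand)
  g <- rotation_about_axis(ax[, 1], pi)
  min(rotation_angle_deg(R_fit, R_true),
      rotation_angle_deg(R_fit %*% g, R_true))
}
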