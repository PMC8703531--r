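# Periodic-table data for the elements that occur in biomolecular models.
.element_data <- local({
  sym <- c("H", "B", "C", "N", "O", "F", "NA", "MG", "P", "S", "CL", "K",
           "CA", "MN", "FE", "CO", "NI", "CU", "ZN", "SE", "BR", "MO", "I")
  z <- c(1, 5, 6, 7, 8, 9, 11, 12, 15, 16, 17, 19,
         20, 25, 26, 27, 28, 29, 30, 34, 35, 42, 53)
  mass <- c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998, 22.990, 24.305,
            30.974, 32.06, 35.45, 39.098, 40.078, 54.938, 55.845, 58.933,
            58.693, 63.546, 65.38, 78.971, 79.904, 95.95, 126.904)
  data.frame(sym = sym, z = z, mass = mass, stringsAsFactors = FALSE)
})

#' Standard atomic mass of an element symbol
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of atomic masses (u).
#' @export
atomic_mass <- function(element) {
  i <- match(toupper(element), .element_data$sym)
  if (anyNA(i)) stop("unknown element symbol: ",
                     paste(unique(element[is.na(i)]), collapse = ", "))
  .element_data$mass[i]
}

#' Atomic number of an element symbol
#' @param element character vector of element symbols (case-insensitive).
#' @return integer vector of atomic numbers.
#' @export
atomic_number <- function(element) {
  i <- match(toupper(element), .element_data$sym)
  if (anyNA(i)) stop("unknown element symbol: ",
                     paste(unique(element[is.na(i)]), collapse = ", "))
  .element_data$z[i]
}

# Infer an element symbol from a PDB atom name (e.g. " CA " -> C for calcium
# only when the residue says so; here we use the simple organic-set rule).
.infer_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  ifelse(two %in% .element_data$sym & !one %in% c("C", "N", "O", "H", "P", "S"),
         two, one)
}

.new_model_structure <- function(atoms, name = "model") {
  need <- c("chain", "resno", "insert", "resid", "atom_name", "element",
            "x", "y", "z", "occupancy", "is_water")
  stopifnot(all(need %in% names(atoms)))
  if (nrow(atoms) == 0) stop("empty model: no atoms parsed")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("model contains non-finite coordinates")
  bad <- !toupper(atoms$element) %in% .element_data$sym
  if (any(bad)) {
    warning("unrecognized element(s) ",
            paste(unique(atoms$element[bad]), collapse = ", "),
            "; inferring from atom names")
    atoms$element[bad] <- .infer_element(atoms$atom_name[bad])
  }
  atoms$element <- toupper(atoms$element)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, insertion, atom name) records in model")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, name = name), class = "model_structure")
}

#' @export
print.model_structure <- function(x, ...) {
  cat(sprintf("model_structure '%s': %d atoms, chains %s\n", x$name,
              nrow(x$atoms), paste(unique(x$atoms$chain), collapse = "")))
  invisible(x)
}

# Resolve altlocs: keep, per (chain,resno,insert,atom_name), the record with
# the highest occupancy, ties broken by alphabetical altloc id.
.resolve_altloc <- function(df, alt) {
  alt[is.na(alt) | alt == ""] <- ""
  key <- paste(df$chain, df$resno, df$insert, df$atom_name)
  ord <- order(key, -df$occupancy, alt)
  keep <- sort(ord[!duplicated(key[ord])])   # winners, in original file order
  df[keep, , drop = FALSE]
}

#' Read an atomic model from PDB or mmCIF
#'
#' Parsing is delegated to \pkg{bio3d}. Alternate locations are resolved by
#' highest occupancy then alphabetical altloc id; waters are retained and
#' flagged in the `is_water` column. Only the first model of a multi-model
#' file is used.
#'
#' @param path path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param name label for the model; defaults to the file name.
#' @return A `model_structure` whose `atoms` data frame has columns
#'   `chain, resno, insert, resid, atom_name, element, x, y, z, occupancy,
#'   is_water`.
#' @export
read_model <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("model file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  } else {
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  }
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("empty model: no atoms parsed from ", path)
  occ <- suppressWarnings(as.numeric(a$o))
  occ[!is.finite(occ)] <- 1
  occ <- pmin(pmax(occ, 0), 1)
  elem <- a$elesy
  if (is.null(elem)) elem <- rep("", nrow(a))
  elem[is.na(elem)] <- ""
  elem <- toupper(trimws(elem))
  miss <- elem == "" | !elem %in% .element_data$sym
  if (any(miss)) {
    if (any(elem[miss] != ""))
      warning("unknown element symbol(s) in ", basename(path),
              "; inferred from atom names")
    elem[miss] <- .infer_element(a$elety[miss])
  }
  chain <- a$chain
  chain[is.na(chain)] <- ""
  ins <- a$insert
  if (is.null(ins)) ins <- rep("", nrow(a))
  ins[is.na(ins)] <- ""
  df <- data.frame(
    chain = chain, resno = as.integer(a$resno), insert = ins,
    resid = a$resid, atom_name = trimws(a$elety), element = elem,
    x = a$x, y = a$y, z = a$z, occupancy = occ,
    is_water = a$resid %in% c("HOH", "WAT", "DOD"),
    stringsAsFactors = FALSE)
  alt <- if (!is.null(a$alt)) a$alt else rep("", nrow(a))
  df <- .resolve_altloc(df, alt)
  .new_model_structure(df, name = name)
}

#' Extract an n x 3 coordinate matrix
#' @param x a `model_structure` or `ligand_atoms`.
#' @param heavy_only drop hydrogens first.
#' @return numeric matrix with columns x, y, z.
#' @export
atom_coords <- function(x, heavy_only = FALSE) {
  a <- x$atoms
  if (heavy_only) a <- a[a$element != "H", , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

.new_ligand_atoms <- function(atoms, label) {
  if (nrow(atoms) < 2) stop("degenerate ligand: fewer than 2 atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (anyDuplicated(round(xyz, 6)) > 0)
    stop("degenerate ligand: duplicate atom coordinates")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = label), class = "ligand_atoms")
}

#' @export
print.ligand_atoms <- function(x, ...) {
  cat(sprintf("ligand_atoms '%s': %d atoms (%s)\n", x$label, nrow(x$atoms),
              paste(names(table(x$atoms$element)), table(x$atoms$element),
                    sep = ":", collapse = " ")))
  invisible(x)
}

#' Read ligand atoms from a PDB or SDF (V2000) file
#'
#' Heavy atoms only by default; set `include_hydrogens = TRUE` to keep
#' hydrogens. SDF parsing is delegated to \pkg{ChemmineR} when available,
#' with a minimal V2000 atom-block fallback otherwise.
#'
#' @param path path to a `.pdb` or `.sdf`/`.mol` file.
#' @param include_hydrogens keep hydrogen atoms (default `FALSE`).
#' @param label free-text label; defaults to the file name.
#' @return A `ligand_atoms` object (>= 2 atoms, unique coordinates).
#' @export
read_ligand <- function(path, include_hydrogens = FALSE, label = basename(path)) {
  if (!file.exists(path)) stop("ligand file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sdf", "mol")) {
    ab <- .read_sdf_atoms(path)
    df <- data.frame(chain = "L", resno = 1L, insert = "", resid = "LIG",
                     atom_name = paste0(ab$element, seq_len(nrow(ab))),
                     element = toupper(ab$element),
                     x = ab$x, y = ab$y, z = ab$z, occupancy = 1,
                     is_water = FALSE, stringsAsFactors = FALSE)
  } else {
    m <- read_model(path, name = label)
    df <- m$atoms
  }
  if (!include_hydrogens) df <- df[toupper(df$element) != "H", , drop = FALSE]
  if (nrow(df) < 2) stop("degenerate ligand: fewer than 2 heavy atoms in ", path)
  .new_ligand_atoms(df, label = label)
}

# First molecule of an SDF/MOL V2000 file -> data.frame(element, x, y, z).
.read_sdf_atoms <- function(path) {
  if (requireNamespace("ChemmineR", quietly = TRUE)) {
    sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
    ab <- ChemmineR::atomblock(sdf[[1]])
    el <- gsub("_.*$", "", rownames(ab))
    return(data.frame(element = el, x = ab[, 1], y = ab[, 2], z = ab[, 3],
                      stringsAsFactors = FALSE))
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) stop("malformed SDF: fewer than 4 lines")
  natoms <- as.integer(substr(lines[4], 1, 3))
  if (!is.finite(natoms) || natoms < 1) stop("malformed SDF counts line")
  at <- lines[5:(4 + natoms)]
  data.frame(
    element = trimws(substr(at, 32, 34)),
    x = as.numeric(substr(at, 1, 10)),
    y = as.numeric(substr(at, 11, 20)),
    z = as.numeric(substr(at, 21, 30)),
    stringsAsFactors = FALSE)
}

#' Build ligand atoms directly from coordinates
#'
#' @param xyz n x 3 numeric matrix of positions (Angstrom).
#' @param element element symbols, recycled to `nrow(xyz)`.
#' @param label free-text label.
#' @return A `ligand_atoms` object.
#' @export
ligand_from_coords <- function(xyz, element = "C", label = "ligand") {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3)
  element <- rep_len(toupper(element), nrow(xyz))
  df <- data.frame(chain = "L", resno = 1L, insert = "", resid = "LIG",
                   atom_name = paste0(element, seq_len(nrow(xyz))),
                   element = element,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   occupancy = 1, is_water = FALSE, stringsAsFactors = FALSE)
  .new_ligand_atoms(df, label = label)
}

#' Write posed ligand (or any atom table) as a minimal PDB file
#'
#' @param x a `ligand_atoms` or `model_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_atoms <- function(x, path) {
  a <- x$atoms
  rec <- sprintf(
    "HETATM%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), substr(a$atom_name, 1, 4), substr(a$resid, 1, 3),
    ifelse(a$chain == "", "L", substr(a$chain, 1, 1)),
    a$resno, a$x, a$y, a$z, a$occupancy, 0, a$element)
  writeLines(c(rec, "END"), path)
  invisible(path)
}
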