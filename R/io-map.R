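#' Density map container
#'
#' A `density_map` is a 3-D scalar field on a regular orthogonal grid with a
#' physical voxel size and origin. The physical position of voxel
#' `(i, j, k)` (0-based) is `origin + c(i, j, k) * voxel_size`; every module
#' in the package shares this convention.
#'
#' @param values numeric 3-D array (X fastest, as stored) or a vector with a
#'   `dim` attribute of length 3; all values must be finite.
#' @param voxel_size voxel edge lengths in Angstrom, length 1 (isotropic) or 3.
#' @param origin physical position of voxel (0,0,0) in Angstrom, length 3.
#' @param name free-text label carried through reports.
#' @return An object of class `density_map` with fields `dims`, `voxel_size`,
#'   `origin`, `values`, `name`.
#' @export
density_map <- function(values, voxel_size, origin = c(0, 0, 0), name = "map") {
  if (is.null(dim(values)) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L, length(origin) == 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size components must be positive and finite")
  if (any(!is.finite(values))) stop("map values must all be finite")
  m <- structure(
    list(dims = as.integer(dim(values)),
         voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin),
         values = values,
         name = as.character(name)[1]),
    class = "density_map")
  m
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map '%s': %d x %d x %d voxels, %.4g x %.4g x %.4g A/voxel\n",
              x$name, x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  origin (%.3f, %.3f, %.3f) A; range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Physical volume of one voxel
#'
#' @param map a `density_map`.
#' @return Voxel volume in cubic Angstrom.
#' @export
voxel_volume <- function(map) prod(map$voxel_size)

#' Total physical volume of the map box
#' @param map a `density_map`.
#' @return Box volume in cubic Angstrom.
#' @export
total_volume <- function(map) voxel_volume(map) * prod(map$dims)

#' Physical centers of all voxels along one axis
#' @keywords internal
axis_coords <- function(map, axis) {
  map$origin[axis] + (seq_len(map$dims[axis]) - 1) * map$voxel_size[axis]
}

# ---- MRC2014 ----------------------------------------------------------------

.mrc_read_header <- function(con, endian) {
  seek(con, 0)
  h <- list()
  ints1 <- readBin(con, "integer", n = 10, size = 4, endian = endian)
  h$nc <- ints1[1]; h$nr <- ints1[2]; h$ns <- ints1[3]
  h$mode <- ints1[4]
  h$nstart <- ints1[5:7]
  h$m <- ints1[8:10]
  h$cella <- readBin(con, "numeric", n = 3, size = 4, endian = endian)
  h$cellb <- readBin(con, "numeric", n = 3, size = 4, endian = endian)
  h$mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = endian)
  h$dstats <- readBin(con, "numeric", n = 3, size = 4, endian = endian)
  ispg_nsym <- readBin(con, "integer", n = 2, size = 4, endian = endian)
  h$nsymbt <- ispg_nsym[2]
  seek(con, 4 * 49)                      # words 50-52: origin
  h$origin <- readBin(con, "numeric", n = 3, size = 4, endian = endian)
  h$maptag <- rawToChar(readBin(con, "raw", n = 4))
  h
}

.mrc_header_plausible <- function(h) {
  all(is.finite(c(h$nc, h$nr, h$ns))) &&
    all(c(h$nc, h$nr, h$ns) >= 1) && all(c(h$nc, h$nr, h$ns) <= 100000L) &&
    h$mode %in% c(0L, 1L, 2L)
}

#' Read a density map from an MRC/CCP4 file
#'
#' Supports MRC2014 modes 0 (int8), 1 (int16) and 2 (float32), both byte
#' orders, and arbitrary axis storage order (`mapc/mapr/maps`); the returned
#' array is always normalized to X-fastest. Voxel size is cell length divided
#' by grid sampling per axis. The origin is taken from the MRC2014 origin
#' header words when any is nonzero, otherwise from `nstart * voxel_size`.
#'
#' @param path path to an MRC/CCP4 map file.
#' @param name label for the returned map; defaults to the file name.
#' @return A [density_map].
#' @export
read_density_map <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("map file not found: ", path)
  if (file.size(path) < 1024) stop("malformed MRC header: file shorter than 1024 bytes")
  con <- file(path, "rb")
  on.exit(close(con))
  h <- .mrc_read_header(con, "little")
  endian <- "little"
  if (!.mrc_header_plausible(h)) {
    h <- .mrc_read_header(con, "big")
    endian <- "big"
  }
  if (!.mrc_header_plausible(h)) {
    if (!h$mode %in% c(0L, 1L, 2L))
      stop("malformed MRC header: unsupported mode field (", h$mode, ")")
    stop("malformed MRC header: implausible nx/ny/nz fields")
  }
  if (any(abs(h$cellb - 90) > 1e-3))
    stop("unsupported feature: non-orthogonal cell (angles ",
         paste(signif(h$cellb, 6), collapse = ", "), ")")
  if (any(sort(h$mapcrs) != 1:3))
    stop("malformed MRC header: mapc/mapr/maps fields are not a permutation of 1:3")
  if (any(h$m <= 0))
    stop("malformed MRC header: non-positive mx/my/mz sampling fields")
  n <- as.double(h$nc) * h$nr * h$ns
  seek(con, 1024 + max(0, h$nsymbt))
  vals <- switch(as.character(h$mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE,
                             endian = endian)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                             endian = endian)),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = endian))
  if (length(vals) != n) stop("malformed MRC file: truncated data block")
  arr <- array(vals, dim = c(h$nc, h$nr, h$ns))
  # normalize storage order (cols/rows/sections) to X-fastest
  pos <- match(1:3, h$mapcrs)            # pos[d]: which of (c,r,s) is axis d
  if (!identical(pos, 1:3)) arr <- aperm(arr, pos)
  vox <- h$cella / h$m
  nstart_xyz <- numeric(3)
  nstart_xyz[h$mapcrs] <- h$nstart
  org <- if (any(h$origin != 0)) h$origin else nstart_xyz * vox
  density_map(arr, voxel_size = vox, origin = org, name = name)
}

#' Write a density map as MRC2014 (mode 2)
#'
#' Writes X-fastest, `mapc/mapr/maps = 1/2/3`, little-endian float32, with
#' header min/max/mean/rms recomputed from the data and the physical origin
#' stored in the MRC2014 origin words.
#'
#' @param map a [density_map].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  v <- as.numeric(map$values)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(map$dims)                           # nx ny nz
  wi(2L)                                 # mode 2 = float32
  wi(c(0L, 0L, 0L))                      # nstart
  wi(map$dims)                           # mx my mz
  wf(map$dims * map$voxel_size)          # cella
  wf(c(90, 90, 90))                      # cellb
  wi(1:3)                                # mapc mapr maps
  wf(c(min(v), max(v), mean(v)))         # dmin dmax dmean
  wi(c(1L, 0L))                          # ispg, nsymbt
  wi(rep(0L, 25))                        # extra (words 25-49)
  wf(map$origin)                         # origin (words 50-52)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little-endian
  wf(stats::sd(v) * sqrt(max(1, length(v) - 1) / length(v)))  # rms (population)
  wi(1L)                                 # nlabl
  lab <- sprintf("%-80s", paste("cryomap", map$name))
  writeBin(charToRaw(substr(lab, 1, 80)), con)
  writeBin(raw(800 - 80), con)
  wf(v)
  invisible(path)
}
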