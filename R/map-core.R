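#' Mean and population standard deviation of a density map
#'
#' @param map a [density_map].
#' @return Named list with `mean` and `sd` (population, divisor n).
#' @export
map_stats <- function(map) {
  v <- as.numeric(map$values)
  mu <- mean(v)
  list(mean = mu, sd = sqrt(mean((v - mu)^2)))
}

#' Density level at a multiple of the map standard deviation
#'
#' `level = mean + k * sd`, the rule used to display a resolution-matched
#' simulated ligand map (k = 7 in the study this package reproduces).
#'
#' @param map a [density_map].
#' @param k SD multiplier (finite; may be 0 or negative).
#' @return Density level (same units as the map values).
#' @export
sd_threshold <- function(map, k) {
  stopifnot(is.finite(k))
  s <- map_stats(map)
  s$mean + k * s$sd
}

#' Volume enclosed at a density level
#'
#' Thresholding is closed: voxels with `value >= level` count.
#'
#' @param map a [density_map].
#' @param level density level (finite).
#' @return List with `level`, `voxel_count` and `enclosed_volume` (A^3).
#' @export
enclosed_volume <- function(map, level) {
  stopifnot(is.finite(level))
  n <- sum(map$values >= level)
  list(level = level, voxel_count = as.integer(n),
       enclosed_volume = n * voxel_volume(map))
}

#' Density level enclosing a target physical volume
#'
#' Returns the m-th largest voxel value where `m = round(target / voxel
#' volume)`, i.e. the level at which displaying the map encloses (as nearly
#' as the grid allows) the requested volume. Ties at the level are all
#' included, so the recomputed volume may exceed the target by up to one
#' voxel volume per tied voxel.
#'
#' @param map a [density_map].
#' @param target_volume desired enclosed volume in cubic Angstrom,
#'   in `(0, total_volume(map)]`.
#' @return List with `level`, `voxel_count`, `enclosed_volume` and
#'   `target_volume`.
#' @export
threshold_for_volume <- function(map, target_volume) {
  tv <- total_volume(map)
  if (!is.finite(target_volume) || target_volume <= 0 || target_volume > tv)
    stop("target_volume must be in (0, ", format(tv), "] A^3")
  m <- max(1L, min(prod(map$dims), as.integer(round(target_volume / voxel_volume(map)))))
  v <- as.numeric(map$values)
  p <- length(v) - m + 1L                # m-th largest = p-th smallest
  level <- sort(v, partial = p)[p]
  out <- enclosed_volume(map, level)
  out$target_volume <- target_volume
  out
}

#' Fourier shell correlation between two half-maps
#'
#' FSC per radial shell `s` of discrete Fourier space:
#' `FSC(s) = Re(sum F1 conj(F2)) / sqrt(sum |F1|^2 * sum |F2|^2)`.
#' Shells are one reciprocal voxel wide; each Fourier component is assigned
#' to the shell given by its rounded integer radius (in reciprocal-voxel
#' units), and shells run from 0 up to Nyquist along the shortest axis.
#' No masking or sharpening is applied.
#'
#' @param half1,half2 two [density_map]s with identical dims and voxel size.
#' @param n_shells number of shells; default one per integer radius up to
#'   Nyquist.
#' @return Data frame with columns `shell_radius` (reciprocal-voxel integer
#'   radius), `frequency` (1/A at the shell center), `fsc`, `n_voxels`.
#'   Empty shells are omitted and recorded in the `dropped_shells` attribute.
#' @export
fsc_curve <- function(half1, half2, n_shells = NULL) {
  if (!identical(half1$dims, half2$dims))
    stop("half-map dimension mismatch: ",
         paste(half1$dims, collapse = "x"), " vs ",
         paste(half2$dims, collapse = "x"))
  if (max(abs(half1$voxel_size - half2$voxel_size)) > 1e-6)
    stop("half-map voxel size mismatch")
  d <- half1$dims
  F1 <- stats::fft(half1$values)
  F2 <- stats::fft(half2$values)
  # fractional frequency along each axis, in cycles/sample, range (-0.5, 0.5]
  ff <- function(n) {
    k <- 0:(n - 1)
    k[k > n / 2] <- k[k > n / 2] - n
    k / n
  }
  fx <- ff(d[1]); fy <- ff(d[2]); fz <- ff(d[3])
  # radius in units of the smallest nonzero frequency step of the shortest axis
  nmin <- min(d)
  r <- sqrt(outer(outer(fx^2, fy^2, "+"), fz^2, "+")) * nmin
  shell <- as.integer(round(r))
  max_shell <- floor(nmin / 2)
  if (!is.null(n_shells)) max_shell <- min(max_shell, n_shells - 1L)
  keep <- shell <= max_shell
  num <- Re(F1 * Conj(F2))
  p1 <- Mod(F1)^2
  p2 <- Mod(F2)^2
  sh <- factor(shell[keep], levels = 0:max_shell)
  s_num <- tapply(num[keep], sh, sum)
  s_p1 <- tapply(p1[keep], sh, sum)
  s_p2 <- tapply(p2[keep], sh, sum)
  s_n <- tapply(rep(1, sum(keep)), sh, sum)
  s_n[is.na(s_n)] <- 0
  denom <- sqrt(s_p1 * s_p2)
  fsc <- ifelse(is.na(denom) | denom == 0, NA_real_, s_num / denom)
  # frequency at shell center: radius / (nmin * voxel)
  freq <- (0:max_shell) / (nmin * half1$voxel_size[1])
  out <- data.frame(shell_radius = 0:max_shell, frequency = freq,
                    fsc = as.numeric(fsc), n_voxels = as.integer(s_n))
  dropped <- out$shell_radius[out$n_voxels == 0 | is.na(out$fsc)]
  out <- out[out$n_voxels > 0 & !is.na(out$fsc), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_shells") <- dropped
  attr(out, "binning") <- "rounded integer radius, one reciprocal voxel per shell"
  out
}

#' Resolution at an FSC criterion
#'
#' Reciprocal of the frequency at the first downward crossing of the
#' criterion (default 0.143), linearly interpolated between the bracketing
#' shells. If the curve never falls below the criterion the Nyquist
#' resolution is returned with `nyquist_limited = TRUE`.
#'
#' @param curve data frame from [fsc_curve()].
#' @param criterion FSC criterion in (0, 1); default 0.143.
#' @return List with `resolution` (Angstrom), `frequency` (1/A) and
#'   `nyquist_limited` flag.
#' @export
resolution_at <- function(curve, criterion = 0.143) {
  if (nrow(curve) == 0) stop("empty FSC curve")
  if (!is.finite(criterion) || criterion <= 0 || criterion >= 1)
    stop("criterion must be in (0, 1)")
  below <- which(curve$fsc < criterion)
  below <- below[below > 1]              # need a bracketing shell above
  if (length(below) == 0) {
    fmax <- max(curve$frequency)
    return(list(resolution = 1 / fmax, frequency = fmax,
                nyquist_limited = TRUE))
  }
  i <- below[1]
  f0 <- curve$frequency[i - 1]; f1 <- curve$frequency[i]
  y0 <- curve$fsc[i - 1]; y1 <- curve$fsc[i]
  fc <- if (y0 == y1) f1 else f0 + (criterion - y0) * (f1 - f0) / (y1 - y0)
  list(resolution = 1 / fc, frequency = fc, nyquist_limited = FALSE)
}

#' Export an FSC curve as TSV
#' @param curve data frame from [fsc_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fsc_tsv <- function(curve, path) {
  df <- data.frame(shell_center_invA = curve$frequency, fsc = curve$fsc,
                   n_voxels = curve$n_voxels)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
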