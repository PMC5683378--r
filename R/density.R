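#' Cryo-EM density map container
#'
#' A 3-D scalar grid with isotropic voxel size, a world-space origin (the
#' center of voxel `[1,1,1]`) and an optional nominal resolution. The array
#' is indexed `values[ix, iy, iz]` with x fastest, matching R's column-major
#' layout.
#'
#' @param values numeric 3-D array.
#' @param voxel_size isotropic voxel edge length (Angstrom).
#' @param origin world position of the first voxel center (Angstrom).
#' @param resolution nominal resolution (Angstrom) or `NA`.
#' @return A `density_map`.
#' @export
density_map <- function(values, voxel_size, origin = c(0, 0, 0), resolution = NA_real_) {
  if (length(dim(values)) != 3L) stopf("values must be a 3-D array")
  if (!is_scalar_number(voxel_size) || voxel_size <= 0) stopf("voxel_size must be > 0")
  if (!all(is.finite(values))) stopf("map values must be finite")
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), resolution = as.numeric(resolution)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map: %s voxels @ %.3f A, origin (%.1f, %.1f, %.1f), res %s A\n",
              paste(dim(x$values), collapse = "x"), x$voxel_size,
              x$origin[1], x$origin[2], x$origin[3],
              ifelse(is.na(x$resolution), "?", format(x$resolution))))
  invisible(x)
}

map_upper_bound <- function(map) map$origin + (dim(map$values) - 1L) * map$voxel_size

point_in_map <- function(map, p) {
  all(p >= map$origin - 1e-9) && all(p <= map_upper_bound(map) + 1e-9)
}

#' Read an MRC/CCP4 2014 density map
#'
#' Parses the 1024-byte header and mode-2 (32-bit float) data. Axis order is
#' normalized so x is fastest regardless of the file's MAPC/MAPR/MAPS
#' permutation; the origin is taken from the ORIGIN fields, falling back to
#' the start indices. Anisotropic voxels are rejected.
#'
#' @param path MRC file path.
#' @param resolution optional nominal resolution to attach (Angstrom).
#' @return A [density_map()].
#' @export
read_map <- function(path, resolution = NA_real_) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  sz <- file.size(path)
  if (sz < 1024) stopf("format error: %s is too small to be an MRC file", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ints1 <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  cellb <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  stats3 <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  ispg_nsym <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  invisible(readBin(con, "raw", n = 100L))           # words 25-49 (extra)
  orig <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  map_tag <- rawToChar(readBin(con, "raw", n = 4L))
  invisible(readBin(con, "raw", n = 4L))             # MACHST
  invisible(readBin(con, "numeric", n = 1L, size = 4L, endian = "little"))  # RMS
  invisible(readBin(con, "raw", n = 4L + 800L))      # NLABL + labels
  if (!identical(substr(map_tag, 1, 3), "MAP")) {
    stopf("format error: %s lacks the MAP signature (not MRC 2014)", path)
  }
  nxyz <- ints1[1:3]; mode <- ints1[4]; starts <- ints1[5:7]; mxyz <- ints1[8:10]
  if (mode != 2L) stopf("unsupported MRC mode %d (only mode 2, float32)", mode)
  if (any(nxyz <= 0L)) stopf("format error: non-positive dimensions")
  n_total <- prod(as.double(nxyz))
  if (sz < 1024 + ispg_nsym[2] + 4 * n_total) stopf("format error: %s is truncated", path)
  if (ispg_nsym[2] > 0L) invisible(readBin(con, "raw", n = ispg_nsym[2]))
  vals <- readBin(con, "numeric", n = n_total, size = 4L, endian = "little")
  if (length(vals) < n_total) stopf("format error: %s is truncated", path)
  arr <- array(vals, dim = nxyz)
  perm <- mapcrs
  if (!setequal(perm, 1:3)) stopf("format error: invalid MAPC/MAPR/MAPS")
  inv <- match(1:3, perm)
  arr <- aperm(arr, inv)
  starts_xyz <- starts[inv]
  mx <- ifelse(mxyz > 0L, mxyz, dim(arr))
  voxels <- cella / mx
  if (any(cella <= 0)) voxels <- rep(1, 3)
  if (diff(range(voxels)) > 1e-4 * max(voxels)) {
    stopf("anisotropic voxels (%s A) are not supported; resample the map first",
          paste(signif(voxels, 6), collapse = ", "))
  }
  voxel <- mean(voxels)
  origin <- if (any(abs(orig) > 1e-6)) orig else starts_xyz * voxel
  density_map(arr, voxel, origin, resolution)
}

#' Write a density map as MRC/CCP4 2014 (mode 2)
#'
#' @param map a [density_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  dm <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(dm, 2L, 0L, 0L, 0L, dm)), con, size = 4L, endian = "little")
  writeBin(as.numeric(c(dm * map$voxel_size, 90, 90, 90)), con, size = 4L, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4L, endian = "little")
  v <- map$values
  writeBin(as.numeric(c(min(v), max(v), mean(v))), con, size = 4L, endian = "little")
  writeBin(as.integer(c(1L, 0L)), con, size = 4L, endian = "little")   # ISPG, NSYMBT
  extra <- integer(25L)
  extra[3L] <- 20140L                                                   # NVERSION
  writeBin(extra, con, size = 4L, endian = "little")
  writeBin(as.numeric(map$origin), con, size = 4L, endian = "little")
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)                      # MACHST little-endian
  writeBin(as.numeric(stats::sd(v)), con, size = 4L, endian = "little")
  writeBin(0L, con, size = 4L, endian = "little")                       # NLABL
  writeBin(raw(800L), con)
  writeBin(as.numeric(v), con, size = 4L, endian = "little")
  invisible(path)
}

# Radial spatial-frequency grid magnitudes for an FFT of the given dims.
fft_freq <- function(n, voxel) {
  k <- seq_len(n) - 1L
  ifelse(k < ceiling(n / 2), k, k - n) / (n * voxel)
}

# Butterworth transfer function H(f) = 1/sqrt(1 + (f/fc)^(2*order)) on the
# FFT grid of the given dimensions.
bw_transfer <- function(dm, voxel, cutoff_resolution, order) {
  fc <- 1 / cutoff_resolution
  fx <- fft_freq(dm[1], voxel); fy <- fft_freq(dm[2], voxel); fz <- fft_freq(dm[3], voxel)
  f2 <- outer(outer(fx^2, fy^2, `+`), fz^2, `+`)
  1 / sqrt(1 + (f2 / fc^2)^order)
}

bw_apply <- function(values, H) {
  Re(stats::fft(stats::fft(values) * H, inverse = TRUE)) / length(values)
}

#' Butterworth low-pass filter a density map
#'
#' Multiplies the map's Fourier transform by
#' `H(f) = 1 / sqrt(1 + (f/fc)^(2*order))` with `fc = 1/cutoff_resolution`,
#' the maximally-flat low-pass used to impose a nominal resolution limit.
#' `H(0) = 1`, so total mass (the DC term) is preserved, and the gain at the
#' cutoff frequency is exactly `2^(-1/2)` for every order.
#'
#' @param map a [density_map()].
#' @param cutoff_resolution cutoff as a resolution (Angstrom); must be at
#'   least twice the voxel size (Nyquist).
#' @param order filter order (>= 1, default 8).
#' @return the filtered [density_map()].
#' @export
butterworth_lowpass <- function(map, cutoff_resolution, order = 8L) {
  if (!is_scalar_number(cutoff_resolution) || cutoff_resolution <= 0) {
    stopf("cutoff_resolution must be a positive number")
  }
  if (order < 1) stopf("filter order must be >= 1")
  if (cutoff_resolution < 2 * map$voxel_size) {
    stopf("cutoff resolution %.3f A is beyond Nyquist (%.3f A) for voxel %.3f A",
          cutoff_resolution, 2 * map$voxel_size, map$voxel_size)
  }
  H <- bw_transfer(dim(map$values), map$voxel_size, cutoff_resolution, order)
  out <- map
  out$values <- bw_apply(map$values, H)
  out
}

# Next FFT-friendly length (2/3/5-smooth).
next_fast_len <- function(n) {
  n <- max(1L, as.integer(n))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Simulate a density map from atomic coordinates
#'
#' Deposits unit weight per heavy atom by trilinear splatting onto the grid,
#' then low-pass filters to the requested nominal resolution. Mimics the
#' map-from-model step of the scoring pipeline: candidate fragments are
#' simulated on the experimental minimal-box grid and compared by
#' cross-correlation.
#'
#' @param coords a [coord_set()] (or n x 3 matrix) of heavy-atom positions.
#' @param voxel_size grid spacing (Angstrom).
#' @param resolution nominal resolution (Angstrom, >= 2 * voxel_size), or
#'   `NA` to skip filtering (raw deposition).
#' @param box grid specification: `NULL` to fit the atoms with a margin of
#'   one resolution, a `density_map` whose grid is reused, or a list with
#'   `origin` and `dim`.
#' @param out_of_box `"error"` (default) or `"clip"` for atoms outside the grid.
#' @param order Butterworth order.
#' @return A [density_map()].
#' @export
simulate_map <- function(coords, voxel_size, resolution, box = NULL,
                         out_of_box = c("error", "clip"), order = 8L) {
  out_of_box <- match.arg(out_of_box)
  P <- if (is.data.frame(coords)) cs_xyz(coords) else as.matrix(coords)
  if (nrow(P) == 0L) stopf("no atoms to deposit")
  if (!is.na(resolution) && resolution < 2 * voxel_size) {
    stopf("resolution %.3f A below Nyquist for voxel %.3f A", resolution, voxel_size)
  }
  if (is.null(box)) {
    margin <- if (is.na(resolution)) 3 * voxel_size else resolution
    lo <- floor((apply(P, 2, min) - margin) / voxel_size) * voxel_size
    hi <- apply(P, 2, max) + margin
    dm <- vapply(ceiling((hi - lo) / voxel_size) + 1, next_fast_len, integer(1))
    origin <- lo
  } else if (inherits(box, "density_map")) {
    origin <- box$origin; dm <- dim(box$values)
    if (abs(box$voxel_size - voxel_size) > 1e-9) {
      stopf("voxel size %.4f does not match the template grid (%.4f)", voxel_size, box$voxel_size)
    }
  } else {
    origin <- box$origin; dm <- as.integer(box$dim)
  }
  vals <- array(0, dim = dm)
  g <- sweep(P, 2L, origin) / voxel_size   # 0-based continuous voxel coords
  inside <- g[, 1] >= 0 & g[, 1] <= dm[1] - 1L &
    g[, 2] >= 0 & g[, 2] <= dm[2] - 1L &
    g[, 3] >= 0 & g[, 3] <= dm[3] - 1L
  if (!all(inside)) {
    if (out_of_box == "error") {
      stopf("%d atom(s) fall outside the simulation box", sum(!inside))
    }
    g <- g[inside, , drop = FALSE]
  }
  if (nrow(g)) {
    i0 <- floor(g)
    fr <- g - i0
    for (a in seq_len(nrow(g))) {
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        ix <- i0[a, 1] + dx; iy <- i0[a, 2] + dy; iz <- i0[a, 3] + dz
        if (ix < 0 || ix >= dm[1] || iy < 0 || iy >= dm[2] || iz < 0 || iz >= dm[3]) next
        w <- (if (dx) fr[a, 1] else 1 - fr[a, 1]) *
          (if (dy) fr[a, 2] else 1 - fr[a, 2]) *
          (if (dz) fr[a, 3] else 1 - fr[a, 3])
        vals[ix + 1L, iy + 1L, iz + 1L] <- vals[ix + 1L, iy + 1L, iz + 1L] + w
      }
    }
  }
  out <- density_map(vals, voxel_size, origin, resolution)
  if (!is.na(resolution)) out <- butterworth_lowpass(out, resolution, order)
  out$resolution <- resolution
  out
}

#' Extract the minimal sub-volume that can contain a gap's segment
#'
#' The segment's stereochemically reachable region is bounded by the prolate
#' spheroid of points whose summed distance to the two stem CA atoms is at
#' most 3.8 * (L + 1) Angstrom (the contour-length reach of an L-residue
#' chain anchored at both stems). The box is the spheroid's axis-aligned
#' bounding box expanded by `pad`, clipped to the map; the origin is updated
#' so world coordinates are preserved.
#'
#' @param gap a `gap_spec`.
#' @param map a [density_map()].
#' @param pad padding (Angstrom); defaults to the map's nominal resolution
#'   (or 3 voxels when no resolution is recorded).
#' @return the sub-volume as a [density_map()].
#' @export
minimal_box <- function(gap, map, pad = NULL) {
  pad <- pad %||% (if (is.na(map$resolution)) 3 * map$voxel_size else map$resolution)
  ca <- function(cs) { i <- match("CA", cs$elety); c(cs$x[i], cs$y[i], cs$z[i]) }
  p_n <- ca(gap$nstem_atoms); p_c <- ca(gap$cstem_atoms)
  if (!point_in_map(map, p_n) || !point_in_map(map, p_c)) {
    stopf("stem residues lie outside the density map")
  }
  reach <- 3.8 * (gap$L + 1)
  d <- vnorm(p_c - p_n)
  a <- max(reach, d + 1e-6) / 2
  cf <- d / 2
  b <- sqrt(max(a^2 - cf^2, 1e-12))
  u <- if (d > 1e-9) (p_c - p_n) / d else c(1, 0, 0)
  center <- (p_n + p_c) / 2
  half <- sqrt(a^2 * u^2 + b^2 * (1 - u^2))
  lo <- center - half - pad
  hi <- center + half + pad
  dmv <- dim(map$values)
  i_lo <- pmax(0L, pmin(dmv - 1L, as.integer(floor((lo - map$origin) / map$voxel_size))))
  i_hi <- pmax(0L, pmin(dmv - 1L, as.integer(ceiling((hi - map$origin) / map$voxel_size))))
  sub <- map$values[(i_lo[1] + 1L):(i_hi[1] + 1L),
                    (i_lo[2] + 1L):(i_hi[2] + 1L),
                    (i_lo[3] + 1L):(i_hi[3] + 1L), drop = FALSE]
  density_map(sub, map$voxel_size, map$origin + i_lo * map$voxel_size, map$resolution)
}

#' Normalize a density map to mean 0, standard deviation 1
#'
#' @param map a [density_map()].
#' @return the normalized [density_map()].
#' @export
normalize_map <- function(map) {
  s <- stats::sd(map$values)
  if (!is.finite(s) || s == 0) stopf("cannot normalize a constant map")
  out <- map
  out$values <- (map$values - mean(map$values)) / s
  out
}

#' Subtract the context's simulated density from an experimental box
#'
#' Simulates the structural context that falls inside the box on the box's
#' own grid, normalizes both volumes to mean 0 / sd 1 (the intensity-level
#' adjustment), and subtracts, leaving a residual dominated by the density
#' of the missing segment. This suppresses false positives: candidates are
#' not rewarded for landing in already-occupied density.
#'
#' @param exp_box experimental sub-volume (a [density_map()]).
#' @param context_coords [coord_set()] of context atoms; atoms outside the
#'   box are dropped.
#' @param resolution nominal resolution for the simulated context map.
#' @param order Butterworth order.
#' @return the residual [density_map()].
#' @export
subtract_context <- function(exp_box, context_coords, resolution, order = 8L) {
  if (is.null(context_coords) || nrow(context_coords) == 0L) {
    message("subtract_context: no context atoms in box; returning input unchanged")
    return(exp_box)
  }
  P <- cs_xyz(context_coords)
  ub <- map_upper_bound(exp_box)
  inside <- P[, 1] >= exp_box$origin[1] & P[, 1] <= ub[1] &
    P[, 2] >= exp_box$origin[2] & P[, 2] <= ub[2] &
    P[, 3] >= exp_box$origin[3] & P[, 3] <= ub[3]
  if (!any(inside)) {
    message("subtract_context: no context atoms in box; returning input unchanged")
    return(exp_box)
  }
  sim <- simulate_map(P[inside, , drop = FALSE], exp_box$voxel_size, resolution,
                      box = exp_box, out_of_box = "clip", order = order)
  out <- normalize_map(exp_box)
  out$values <- out$values - normalize_map(sim)$values
  out
}

#' Pearson cross-correlation between two density maps
#'
#' The density-fit score: voxel-wise Pearson correlation over the full grid.
#' Symmetric and invariant to positive affine rescaling of either map.
#'
#' @param a,b [density_map()]s on identical grids.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_ccc <- function(a, b) {
  if (!all(dim(a$values) == dim(b$values))) stopf("grid shape mismatch")
  if (abs(a$voxel_size - b$voxel_size) > 1e-6 || any(abs(a$origin - b$origin) > 1e-4)) {
    stopf("grid geometry mismatch")
  }
  va <- as.vector(a$values); vb <- as.vector(b$values)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) stopf("zero-variance map in correlation")
  stats::cor(va, vb)
}
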