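#' Construct a CT volume object
#'
#' A CT volume is a 3D array of Hounsfield-unit intensities (rescale slope
#' and intercept already applied) with its voxel spacing and the physical
#' position of voxel `(1,1,1)`. Axis order is `(z, y, x)` throughout:
#' array index 1 runs along z, and all physical coordinates are `(z, y, x)`
#' millimetre triples in the scanner frame.
#'
#' @param voxels 3D numeric array of HU intensities.
#' @param spacing Length-3 positive numeric, mm per voxel along `(z, y, x)`.
#' @param origin Length-3 numeric, physical mm position of voxel `(1,1,1)`.
#' @param scan_id Optional identifier carried through to extracted cubes.
#' @return A `ct_volume` object.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0), scan_id = NA_character_) {
  if (!(is.array(voxels) && length(dim(voxels)) == 3)) {
    stopf("voxels must be a 3D array")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("spacing must be 3 strictly positive numbers (z, y, x)")
  }
  structure(
    list(voxels = voxels, spacing = spacing, origin = as.numeric(origin),
         scan_id = scan_id),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(dim(x$voxels), collapse = " x "),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

# Trilinear sample of a 3D array at fractional voxel positions given as
# per-axis coordinate vectors (0-based); the full output grid is the outer
# product of the three vectors. Positions are clamped to the valid support,
# so querying exactly the input grid reproduces it bit-for-bit.
trilinear_grid <- function(vox, pos_z, pos_y, pos_x) {
  n <- dim(vox)
  axis_parts <- function(pos, n_axis) {
    if (n_axis < 2) stopf("axis with fewer than 2 voxels cannot be interpolated")
    i0 <- clamp(floor(pos), 0, n_axis - 2)
    f <- clamp(pos - i0, 0, 1)
    list(i0 = as.integer(i0) + 1L, f = f)  # 1-based lower index
  }
  z <- axis_parts(pos_z, n[1]); y <- axis_parts(pos_y, n[2]); x <- axis_parts(pos_x, n[3])
  out <- array(0, dim = c(length(pos_z), length(pos_y), length(pos_x)))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wz <- if (dz == 0) 1 - z$f else z$f
    wy <- if (dy == 0) 1 - y$f else y$f
    wx <- if (dx == 0) 1 - x$f else x$f
    w <- outer(outer(wz, wy), wx)
    out <- out + w * vox[z$i0 + dz, y$i0 + dy, x$i0 + dx, drop = FALSE]
  }
  out
}

#' Resample a CT volume to isotropic 1 mm voxels
#'
#' Trilinear interpolation onto a grid with the requested spacing (default
#' 1 x 1 x 1 mm). The output shape is `round(shape * spacing / new)` per
#' axis and the origin is unchanged. A volume already at the target spacing
#' passes through unchanged; constant volumes stay constant under
#' interpolation.
#'
#' @param vol A [ct_volume()].
#' @param new_spacing Target spacing in mm (scalar or length 3).
#' @return A resampled `ct_volume` with spacing `new_spacing`.
#' @export
resample_isotropic <- function(vol, new_spacing = 1) {
  stopifnot(inherits(vol, "ct_volume"))
  new_spacing <- rep(as.numeric(new_spacing), length.out = 3)
  n_in <- dim(vol$voxels)
  if (any(n_in < 2)) {
    stopf("cannot resample a degenerate volume (axis with a single slice)")
  }
  if (isTRUE(all.equal(vol$spacing, new_spacing))) return(vol)
  n_out <- pmax(as.integer(round(n_in * vol$spacing / new_spacing)), 1L)
  pos <- lapply(1:3, function(a) {
    (seq_len(n_out[a]) - 1) * new_spacing[a] / vol$spacing[a]
  })
  ct_volume(
    trilinear_grid(vol$voxels, pos[[1]], pos[[2]], pos[[3]]),
    spacing = new_spacing, origin = vol$origin, scan_id = vol$scan_id
  )
}

#' Extract a 32^3 cube centred on a nodule
#'
#' Crops a `size`^3 voxel window centred on the voxel nearest to the
#' physical centre (nearest-voxel rounding of `(centre - origin)/spacing`).
#' The volume must already be isotropically resampled. Voxels falling
#' outside the volume are padded with air (-1000 HU) and the `padded` flag
#' is set. A centre outside the volume is an error naming the nodule.
#'
#' @param vol An isotropic [ct_volume()].
#' @param centre_mm Physical `(z, y, x)` centre in mm.
#' @param size Cube edge length in voxels (default 32).
#' @param pad_hu Fill value for out-of-volume voxels.
#' @param nodule_id Identifier used in provenance and errors.
#' @return A `nodule_cube`: list with `voxels` (`size`^3 array), `scan_id`,
#'   `centre_mm`, `centre_voxel`, `padded`, `normalized`.
#' @export
extract_cube <- function(vol, centre_mm, size = 32L, pad_hu = -1000,
                         nodule_id = NA_character_) {
  stopifnot(inherits(vol, "ct_volume"))
  n <- dim(vol$voxels)
  centre_vox <- round_half_up((as.numeric(centre_mm) - vol$origin) /
                                vol$spacing) + 1  # 1-based
  if (any(centre_vox < 1) || any(centre_vox > n)) {
    stopf("nodule '%s': centre (%s mm) falls outside the volume",
          nodule_id, paste(format(centre_mm), collapse = ", "))
  }
  half <- size %/% 2L
  lo <- as.integer(centre_vox) - half          # window is [lo, lo+size-1]
  hi <- lo + size - 1L
  cube <- array(pad_hu, dim = rep(size, 3))
  src_lo <- pmax(lo, 1L); src_hi <- pmin(hi, n)
  dst_lo <- src_lo - lo + 1L; dst_hi <- src_hi - lo + 1L
  cube[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    vol$voxels[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  structure(
    list(voxels = cube, scan_id = vol$scan_id,
         nodule_id = nodule_id, centre_mm = as.numeric(centre_mm),
         centre_voxel = as.integer(centre_vox),
         padded = any(lo < 1L) || any(hi > n),
         normalized = FALSE),
    class = "nodule_cube"
  )
}

#' @export
print.nodule_cube <- function(x, ...) {
  cat(sprintf("<nodule_cube> %s, scan %s, %s%s\n",
              paste(dim(x$voxels), collapse = " x "), x$scan_id,
              if (x$normalized) "normalized [0,1]" else "HU",
              if (x$padded) ", padded" else ""))
  invisible(x)
}

#' Window and normalize cube intensities
#'
#' Clips Hounsfield intensities to the lung window `[-1000, 400]` HU and
#' maps them affinely onto `[0, 1]`. The map is monotone and clipping
#' absorbs outliers, so the output range is always a subset of `[0, 1]`.
#'
#' @param cube A `nodule_cube` in HU.
#' @param window Length-2 HU window, default `c(-1000, 400)`.
#' @return The cube with voxels in `[0, 1]` and `normalized = TRUE`.
#' @export
normalize_hu <- function(cube, window = c(-1000, 400)) {
  stopifnot(inherits(cube, "nodule_cube"))
  cube$voxels <- (clamp(cube$voxels, window[1], window[2]) - window[1]) /
    (window[2] - window[1])
  cube$normalized <- TRUE
  cube
}

#' Preprocess one scan/nodule pair into a normalized cube
#'
#' Convenience composition: isotropic resampling, cube extraction at the
#' nodule centre, then intensity normalization.
#'
#' @inheritParams extract_cube
#' @return A normalized `nodule_cube`.
#' @export
prepare_cube <- function(vol, centre_mm, size = 32L, nodule_id = NA_character_) {
  vol |>
    resample_isotropic() |>
    extract_cube(centre_mm, size = size, nodule_id = nodule_id) |>
    normalize_hu()
}
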