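#' Reconstruct an isotropic Hounsfield-unit volume
#'
#' Stacks sorted slices into a 3D HU grid with axis order `[z, y, x]`
#' (z = stacking axis, y = image rows, x = image columns) and resamples along
#' z to the in-plane pixel spacing, giving isotropic voxels. Only z is
#' resampled; in-plane data are never touched. New z samples run from the
#' first to the last slice location at the pixel-spacing step; each output
#' plane is linearly interpolated in HU between the two bracketing slices by
#' their slice-location distance, and copied exactly when a sample coincides
#' with an original location. Non-uniform original slice spacing is
#' supported.
#'
#' When sorted slice locations are not strictly increasing (tied locations,
#' e.g. a duplicated slice), location-based interpolation is ill-posed; the
#' slices are then assigned uniform positions by stack index between the
#' first and last location. Under that fallback every received plane
#' contributes to the reconstruction, so a duplicated plane shifts the
#' projection content and remains detectable downstream.
#'
#' @param sorted_slices list of [slice_image] in stacking order, length >= 2,
#'   identical rows/cols/pixel spacing, square in-plane spacing.
#' @return object of class `hu_volume`: list with `hu` (3D array
#'   `[z, y, x]`), `spacing` (mm), `n_slices_original`, `provenance`
#'   (source SOP Instance UIDs in input order).
#' @export
build_volume <- function(sorted_slices) {
  n <- length(sorted_slices)
  if (n < 2) stop("at least 2 slices are required to build a volume")

  rows <- vapply(sorted_slices, function(s) s$rows, integer(1))
  cols <- vapply(sorted_slices, function(s) s$cols, integer(1))
  sp <- t(vapply(sorted_slices, function(s) s$pixel_spacing, numeric(2)))
  if (length(unique(rows)) != 1L || length(unique(cols)) != 1L) {
    stop("geometry mismatch: slices differ in Rows/Columns")
  }
  if (max(sp) - min(sp) > 1e-6) {
    stop("geometry mismatch: slices differ in pixel spacing")
  }
  if (abs(sp[1, 1] - sp[1, 2]) > 1e-6) {
    stop("geometry mismatch: in-plane pixel spacing is not square")
  }
  spacing <- sp[1, 1]
  if (spacing <= 0) stop("pixel spacing must be positive")

  locs <- vapply(sorted_slices, function(s) s$slice_location, numeric(1))
  if (any(is.na(locs))) {
    stop("cannot build volume: slices lack Slice Location")
  }
  z0 <- locs[1]; z1 <- locs[n]
  if (abs(z1 - z0) < 1e-9) {
    stop("degenerate series: all slice locations are equal")
  }
  pos <- if (all(diff(locs) > 0)) locs else seq(z0, z1, length.out = n)

  hu_planes <- lapply(sorted_slices, to_hu)
  ny <- rows[1]; nx <- cols[1]

  n_out <- floor((z1 - z0) / spacing + 1e-9) + 1L
  zs <- z0 + (seq_len(n_out) - 1L) * spacing
  vol <- array(0, dim = c(n_out, ny, nx))
  for (j in seq_len(n_out)) {
    z <- zs[j]
    i <- findInterval(z, pos)
    i <- min(max(i, 1L), n - 1L)
    if (abs(z - pos[i]) < 1e-9) {
      vol[j, , ] <- hu_planes[[i]]
    } else if (abs(z - pos[i + 1L]) < 1e-9) {
      vol[j, , ] <- hu_planes[[i + 1L]]
    } else {
      w <- (z - pos[i]) / (pos[i + 1L] - pos[i])
      vol[j, , ] <- (1 - w) * hu_planes[[i]] + w * hu_planes[[i + 1L]]
    }
  }

  structure(
    list(
      hu = vol, spacing = spacing, n_slices_original = n,
      provenance = vapply(sorted_slices, function(s) s$sop_instance_uid, character(1))
    ),
    class = "hu_volume"
  )
}

#' @export
print.hu_volume <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf(
    "<hu_volume> %d x %d x %d voxels (z,y,x) at %.4g mm isotropic\n  from %d slices, HU range [%.1f, %.1f]\n",
    d[1], d[2], d[3], x$spacing, x$n_slices_original, min(x$hu), max(x$hu)
  ))
  invisible(x)
}
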