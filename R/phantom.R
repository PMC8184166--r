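# Deterministic synthetic DICOM series: ellipsoids of distinct HU on an air
# background. Stands in for patient CT data so the full
# seal -> tamper -> verify cycle runs in seconds with no external accession.

#' Default phantom shapes
#'
#' Three ellipsoids on air: a soft-tissue body (40 HU), a bone-like inclusion
#' (700 HU), and a near-air cavity (-950 HU), scaled to the grid. Centers and
#' radii are in (z, y, x) voxel units, 1-based.
#'
#' @param rows,cols,n_slices grid extents.
#' @return list of shape descriptors (`center`, `radii`, `hu`).
#' @export
phantom_shapes_default <- function(rows = 64, cols = 64, n_slices = 40) {
  cz <- (n_slices + 1) / 2; cy <- (rows + 1) / 2; cx <- (cols + 1) / 2
  list(
    list(center = c(cz, cy, cx), radii = c(n_slices * 0.35, rows * 0.32, cols * 0.32), hu = 40L),
    list(center = c(cz - n_slices * 0.05, cy, cx - cols * 0.15),
         radii = c(n_slices * 0.18, rows * 0.10, cols * 0.10), hu = 700L),
    list(center = c(cz + n_slices * 0.08, cy + rows * 0.08, cx + cols * 0.15),
         radii = c(n_slices * 0.10, rows * 0.08, cols * 0.08), hu = -950L)
  )
}

#' Describe a synthetic phantom series
#'
#' Defaults define the desk-scale study condition: a 64 x 64 x 40 grid at
#' 1 mm isotropic spacing (so volume reconstruction is an exact identity
#' resample), three ellipsoids, no noise. Stored pixels are unsigned 16-bit
#' with rescale slope 1 and intercept -1024 (the common CT encoding), so HU
#' conversion is exercised nontrivially.
#'
#' @param rows,cols in-plane extents (divisible by 4 by default).
#' @param n_slices number of slices, >= 2.
#' @param slice_spacing,pixel_spacing in mm.
#' @param background_hu air background, default -1024.
#' @param shapes list of ellipsoids (`center`, `radii` in (z, y, x) voxels,
#'   `hu` within -1024..3072); later shapes overwrite earlier ones.
#' @param noise_sigma Gaussian HU noise standard deviation (0 = none).
#' @param seed integer; drives noise and the deterministic UID stem.
#' @param defects list of `list(slice =, tag =, action = "drop"|"empty")`
#'   attribute defects for validation tests.
#' @param dataset_id label carried into reports.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(rows = 64L, cols = 64L, n_slices = 40L,
                         slice_spacing = 1.0, pixel_spacing = 1.0,
                         background_hu = -1024L,
                         shapes = phantom_shapes_default(rows, cols, n_slices),
                         noise_sigma = 0, seed = 1L, defects = list(),
                         dataset_id = "phantom") {
  stopifnot(rows >= 1, cols >= 1, n_slices >= 2,
            slice_spacing > 0, pixel_spacing > 0, noise_sigma >= 0)
  for (sh in shapes) {
    if (sh$hu < -1024 || sh$hu > 3072) stop("shape HU out of the -1024..3072 scale")
    if (any(sh$radii <= 0)) stop("shape radii must be positive")
  }
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         n_slices = as.integer(n_slices),
         slice_spacing = slice_spacing, pixel_spacing = pixel_spacing,
         background_hu = as.integer(background_hu), shapes = shapes,
         noise_sigma = noise_sigma, seed = as.integer(seed),
         defects = defects, dataset_id = dataset_id),
    class = "phantom_spec"
  )
}

#' Read a phantom spec from JSON
#'
#' @param path JSON file mirroring the [phantom_spec()] arguments.
#' @return a `phantom_spec`.
#' @export
read_phantom_spec <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!is.null(obj$shapes)) {
    obj$shapes <- lapply(obj$shapes, function(sh) {
      list(center = as.numeric(sh$center), radii = as.numeric(sh$radii),
           hu = as.integer(sh$hu))
    })
  }
  do.call(phantom_spec, obj)
}

# stored-pixel planes (integer matrices, uint16 with intercept -1024); the
# single source of truth shared by the DICOM writer and the analytic volume,
# so the round trip is exact by construction
phantom_stored_planes <- function(spec) {
  ny <- spec$rows; nx <- spec$cols
  y <- matrix(seq_len(ny), ny, nx)
  x <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  noise <- NULL
  if (spec$noise_sigma > 0) {
    noise <- withr::with_seed(spec$seed, lapply(seq_len(spec$n_slices), function(i) {
      matrix(rnorm(ny * nx, 0, spec$noise_sigma), ny, nx)
    }))
  }
  lapply(seq_len(spec$n_slices), function(z) {
    hu <- matrix(as.numeric(spec$background_hu), ny, nx)
    for (sh in spec$shapes) {
      d2 <- ((z - sh$center[1]) / sh$radii[1])^2 +
            ((y - sh$center[2]) / sh$radii[2])^2 +
            ((x - sh$center[3]) / sh$radii[3])^2
      hu[d2 <= 1] <- sh$hu
    }
    if (!is.null(noise)) hu <- hu + noise[[z]]
    stored <- round_half_away(hu) + 1024
    stored[stored < 0] <- 0
    stored[stored > 65535] <- 65535
    storage.mode(stored) <- "integer"
    stored
  })
}

phantom_uid <- function(spec, i) {
  sprintf("1.2.826.0.1.3680043.9590.%d.%d", spec$seed, i)
}

phantom_slices <- function(spec) {
  planes <- phantom_stored_planes(spec)
  study_uid <- sprintf("1.2.826.0.1.3680043.9590.%d.0.1", spec$seed)
  series_uid <- sprintf("1.2.826.0.1.3680043.9590.%d.0.2", spec$seed)
  lapply(seq_len(spec$n_slices), function(i) {
    defects <- Filter(function(d) d$slice == i, spec$defects)
    defects <- lapply(defects, function(d) list(tag = d$tag, action = d$action))
    slice_image(
      sop_instance_uid = phantom_uid(spec, i),
      stored_pixels = planes[[i]],
      rows = spec$rows, cols = spec$cols,
      slice_location = (i - 1) * spec$slice_spacing,
      instance_number = i,
      rescale_slope = 1, rescale_intercept = -1024,
      pixel_spacing = c(spec$pixel_spacing, spec$pixel_spacing),
      attributes = list("0020,000D" = study_uid, "0020,000E" = series_uid),
      defects = defects
    )
  })
}

#' Generate a synthetic DICOM series on disk
#'
#' Writes `n_slices` single-frame files with consistent Study/Series UIDs,
#' unique SOP Instance UIDs, ascending Slice Location starting at 0, and any
#' requested attribute defects. Regeneration from the same spec is
#' byte-identical.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
generate_phantom <- function(spec, out_dir) {
  stopifnot(inherits(spec, "phantom_spec"))
  write_series(phantom_slices(spec), out_dir)
}

#' Analytic HU volume of a phantom
#'
#' The ground-truth volume the generated series encodes (after stored-value
#' quantization), axis order `[z, y, x]`. When `slice_spacing ==
#' pixel_spacing` it equals `build_volume(sort_slices(read_series(...)))$hu`
#' exactly.
#'
#' @param spec a [phantom_spec()].
#' @return 3D numeric array of HU values.
#' @export
phantom_volume <- function(spec) {
  planes <- phantom_stored_planes(spec)
  vol <- array(0, dim = c(spec$n_slices, spec$rows, spec$cols))
  for (z in seq_len(spec$n_slices)) vol[z, , ] <- planes[[z]] - 1024
  vol
}
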