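# shared fixture builders; everything is generated in code at test time

tiny_spec <- function(seed = 1L, n_slices = 12L, ...) {
  phantom_spec(rows = 32L, cols = 32L, n_slices = n_slices, seed = seed,
               shapes = phantom_shapes_default(32, 32, n_slices), ...)
}

make_phantom_dir <- function(spec, dir = tempfile("series-")) {
  generate_phantom(spec, dir)
  dir
}

# in-memory slices from a list of stored-pixel integer matrices
make_slices <- function(planes, slice_spacing = 1, pixel_spacing = 1,
                        slope = 1, intercept = -1024, locs = NULL,
                        uid_stem = "1.2.3.4") {
  n <- length(planes)
  if (is.null(locs)) locs <- (seq_len(n) - 1) * slice_spacing
  lapply(seq_len(n), function(i) {
    slice_image(
      sop_instance_uid = paste0(uid_stem, ".", i),
      stored_pixels = planes[[i]],
      rows = nrow(planes[[i]]), cols = ncol(planes[[i]]),
      slice_location = locs[i], instance_number = i,
      rescale_slope = slope, rescale_intercept = intercept,
      pixel_spacing = c(pixel_spacing, pixel_spacing)
    )
  })
}

# volume of random integer HU built through the slice pipeline (identity
# resample: unit spacing both in-plane and between slices)
random_volume <- function(nz, ny, nx, seed = 1) {
  planes <- withr::with_seed(seed, lapply(seq_len(nz), function(i) {
    matrix(sample.int(4097L, ny * nx, replace = TRUE) - 1L, ny, nx)
  }))
  build_volume(make_slices(planes))
}

random_drr <- function(nr = 16, nc = 16, seed = 1, direction = "coronal") {
  px <- withr::with_seed(seed, matrix(rnorm(nr * nc, -500, 400), nr, nc))
  structure(list(pixels = px, direction = direction,
                 source_extents = c(nz = nr, ny = 1L, nx = nc)),
            class = "drr_image")
}

# independent per-pixel projection oracle: plain triple loop
drr_oracle <- function(vol, direction) {
  v <- vol$hu; d <- dim(v)
  if (direction == "axial") {
    out <- matrix(0, d[2], d[3])
    for (y in seq_len(d[2])) for (x in seq_len(d[3])) out[y, x] <- mean(v[, y, x])
  } else if (direction == "coronal") {
    out <- matrix(0, d[1], d[3])
    for (z in seq_len(d[1])) for (x in seq_len(d[3])) out[z, x] <- mean(v[z, , x])
  } else {
    out <- matrix(0, d[1], d[2])
    for (z in seq_len(d[1])) for (y in seq_len(d[2])) out[z, y] <- mean(v[z, y, ])
  }
  out
}

# independent zig-zag oracle: coordinate walk with explicit bounce rules
zigzag_walk_oracle <- function(gr, gc) {
  out <- integer(gr * gc)
  r <- 0L; c <- 0L
  for (k in seq_len(gr * gc)) {
    out[k] <- r * gc + c + 1L
    if ((r + c) %% 2L == 0L) {        # moving up-right
      if (c == gc - 1L) r <- r + 1L
      else if (r == 0L) c <- c + 1L
      else { r <- r - 1L; c <- c + 1L }
    } else {                          # moving down-left
      if (r == gr - 1L) c <- c + 1L
      else if (c == 0L) r <- r + 1L
      else { r <- r + 1L; c <- c - 1L }
    }
  }
  out
}
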