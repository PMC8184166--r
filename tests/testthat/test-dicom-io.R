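test_that("a written slice reads back with identical pixels and metadata", {
  planes <- withr::with_seed(42, lapply(1:3, function(i) {
    matrix(sample.int(4097L, 16 * 16, replace = TRUE) - 1L, 16, 16)
  }))
  slices <- make_slices(planes, slice_spacing = 2.5)
  dir <- tempfile("rt-")
  write_series(slices, dir)
  back <- read_series(dir)
  expect_length(back, 3)
  back <- sort_slices(back)
  for (i in 1:3) {
    expect_identical(back[[i]]$stored_pixels, slices[[i]]$stored_pixels)
    expect_equal(back[[i]]$slice_location, slices[[i]]$slice_location)
    expect_identical(back[[i]]$sop_instance_uid, slices[[i]]$sop_instance_uid)
    expect_equal(back[[i]]$rescale_intercept, -1024)
    expect_equal(back[[i]]$rescale_slope, 1)
    expect_equal(back[[i]]$pixel_spacing, c(1, 1))
  }
})

test_that("read_series counts files, skips non-DICOM with a warning, errors on empty", {
  dir <- make_phantom_dir(phantom_spec(rows = 16, cols = 16, n_slices = 3,
                                       shapes = list()))
  expect_length(read_series(dir), 3)

  writeLines("not an image", file.path(dir, "notes.txt"))
  expect_warning(back <- read_series(dir), "non-DICOM")
  expect_length(back, 3)

  empty <- tempfile("empty-"); dir.create(empty)
  expect_error(read_series(empty), "no DICOM files")
  expect_error(read_series(tempfile("missing-")), "no such directory")
})

test_that("to_hu applies the rescale transform without clamping", {
  mk <- function(stored, slope, intercept) {
    slice_image("u", matrix(as.integer(stored), 1, 1), 1, 1,
                rescale_slope = slope, rescale_intercept = intercept)
  }
  expect_equal(to_hu(mk(0, 1, -1024))[1, 1], -1024)
  expect_equal(to_hu(mk(2048, 1, -1024))[1, 1], 1024)
  expect_equal(to_hu(mk(100, 2, 0))[1, 1], 200)

  # affine property against a scalar loop oracle on random 8x8 slices
  for (seed in 1:5) {
    px <- withr::with_seed(seed, matrix(sample.int(4000L, 64), 8, 8))
    slope <- seed / 2; intercept <- -100 * seed
    s <- slice_image("u", px, 8, 8, rescale_slope = slope,
                     rescale_intercept = intercept)
    hu <- to_hu(s)
    oracle <- matrix(0, 8, 8)
    for (i in 1:8) for (j in 1:8) oracle[i, j] <- px[i, j] * slope + intercept
    expect_equal(hu, oracle)
  }
})

test_that("sort_slices orders by location with instance-number tie-break and fallback", {
  planes <- lapply(1:3, function(i) matrix(0L, 2, 2))
  s <- make_slices(planes, locs = c(10, -5, 2.5))
  expect_equal(vapply(sort_slices(s), function(x) x$slice_location, numeric(1)),
               c(-5, 2.5, 10))

  tied <- make_slices(lapply(1:2, function(i) matrix(0L, 2, 2)), locs = c(0, 0))
  tied[[1]]$instance_number <- 2L; tied[[2]]$instance_number <- 1L
  expect_equal(vapply(sort_slices(tied), function(x) x$instance_number, integer(1)),
               c(1L, 2L))

  noloc <- make_slices(lapply(1:3, function(i) matrix(0L, 2, 2)))
  for (i in 1:3) noloc[[i]]$slice_location <- NA_real_
  noloc_order <- c(3L, 1L, 2L)
  for (i in 1:3) noloc[[i]]$instance_number <- noloc_order[i]
  expect_equal(vapply(sort_slices(noloc), function(x) x$instance_number, integer(1)),
               1:3)

  for (i in 1:3) noloc[[i]]$instance_number <- NA_integer_
  expect_error(sort_slices(noloc), "unsortable")
})

test_that("sort_slices is a permutation: SOP UID multiset preserved", {
  for (seed in 1:5) {
    n <- 8
    locs <- withr::with_seed(seed, sample(c(-5, -2, 0, 0, 1, 3, 3, 9)))
    s <- make_slices(lapply(seq_len(n), function(i) matrix(0L, 2, 2)), locs = locs)
    expect_setequal(
      vapply(sort_slices(s), function(x) x$sop_instance_uid, character(1)),
      vapply(s, function(x) x$sop_instance_uid, character(1))
    )
  }
})

test_that("series validation flags type1/type2/type1c per the requirement classes", {
  spec <- phantom_spec(rows = 16, cols = 16, n_slices = 3, shapes = list(),
    defects = list(
      list(slice = 1, tag = "PixelData", action = "drop"),
      list(slice = 2, tag = "PatientName", action = "empty"),
      list(slice = 3, tag = "SliceLocation", action = "drop")
    ))
  dir <- make_phantom_dir(spec)
  val <- validate_series(read_series(dir))
  f <- tidy(val)

  expect_false(val$is_valid)
  # type1: missing Pixel Data is a finding
  expect_true(any(f$tag == "7FE0,0010" & f$failure_kind == "missing_tag"))
  # type2: present-but-empty Patient Name is NOT a finding
  expect_false(any(f$tag == "0010,0010"))
  # type1c: Slice Location dropped while Image Position present -> condition_unmet
  expect_true(any(f$tag == "0020,1041" & f$failure_kind == "condition_unmet"))
})

test_that("a clean phantom series validates and duplicates are findings not errors", {
  dir <- make_phantom_dir(tiny_spec())
  slices <- read_series(dir)
  val <- validate_series(slices)
  expect_true(val$is_valid)
  expect_equal(nrow(tidy(val)), 0)

  dup <- c(slices, slices[3])
  val2 <- validate_series(dup)
  expect_false(val2$is_valid)
  expect_equal(val2$duplicate_uids, slices[[3]]$sop_instance_uid)
  expect_equal(nrow(val2$per_slice_findings), 0)
})

test_that("validation rules load from JSON and reject malformed configs", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(
      list(tag = "0008,0018", name = "SOPInstanceUID", type_class = "type1"),
      list(tag = "0010,0020", name = "PatientID", type_class = "type2")
    ),
    path, auto_unbox = TRUE
  )
  rules <- read_validation_rules(path)
  expect_equal(nrow(rules), 2)
  expect_equal(rules$type_class, c("type1", "type2"))

  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(list(tag = "0020,1041", name = "SliceLocation", type_class = "type1c")),
    bad, auto_unbox = TRUE
  )
  expect_error(read_validation_rules(bad), "condition_tag")
})
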