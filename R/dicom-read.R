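# Minimal DICOM Part-10 parser: Explicit and Implicit VR Little Endian,
# uncompressed single-frame images, defined element lengths only.

# VR lookup for Implicit VR files, restricted to the attributes this package
# interprets; anything else is treated as opaque bytes.
implicit_vr_for <- function(tag) {
  vrs <- c(
    "0008,0016" = "UI", "0008,0018" = "UI", "0008,0060" = "CS",
    "0010,0010" = "PN", "0010,0020" = "LO",
    "0020,000D" = "UI", "0020,000E" = "UI", "0020,0013" = "IS",
    "0020,0032" = "DS", "0020,0037" = "DS", "0020,1041" = "DS",
    "0028,0002" = "US", "0028,0004" = "CS", "0028,0010" = "US",
    "0028,0011" = "US", "0028,0030" = "DS", "0028,0100" = "US",
    "0028,0101" = "US", "0028,0102" = "US", "0028,0103" = "US",
    "0028,1050" = "DS", "0028,1051" = "DS", "0028,1052" = "DS",
    "0028,1053" = "DS", "7FE0,0010" = "OW"
  )
  unname(vrs[tag]) %||% "UN"
}

read_u16 <- function(bytes, at) {
  readBin(bytes[at:(at + 1L)], "integer", n = 1, size = 2, signed = FALSE, endian = "little")
}
read_u32 <- function(bytes, at) {
  # element lengths in this package are far below 2^31; signed read is safe
  readBin(bytes[at:(at + 3L)], "integer", n = 1, size = 4, endian = "little")
}

# parse a stream of data elements starting at `at` (1-based); returns a list
# of list(tag, vr, bytes) and stops at end of input or when `stop_group`
# is left (used to delimit the file meta group)
parse_elements <- function(bytes, at, explicit, only_group = NULL) {
  out <- list()
  n <- length(bytes)
  while (at + 7L <= n) {
    group <- read_u16(bytes, at)
    if (!is.null(only_group) && group != only_group) break
    element <- read_u16(bytes, at + 2L)
    tag <- sprintf("%04X,%04X", group, element)
    if (explicit) {
      vr <- rawToChar(bytes[(at + 4L):(at + 5L)])
      if (vr %in% LONG_FORM_VRS) {
        len <- read_u32(bytes, at + 8L)
        val_at <- at + 12L
      } else {
        len <- read_u16(bytes, at + 6L)
        val_at <- at + 8L
      }
    } else {
      vr <- implicit_vr_for(tag)
      len <- read_u32(bytes, at + 4L)
      val_at <- at + 8L
    }
    if (len == -1L) {
      stop("unsupported DICOM element with undefined length at tag ", tag)
    }
    if (val_at + len - 1L > n) {
      stop("truncated DICOM element at tag ", tag)
    }
    value <- if (len > 0L) bytes[val_at:(val_at + len - 1L)] else raw(0)
    out[[length(out) + 1L]] <- list(tag = tag, vr = vr, bytes = value)
    at <- val_at + len
  }
  out
}

element_string <- function(el) {
  if (length(el$bytes) == 0L) return("")
  s <- rawToChar(el$bytes[el$bytes != as.raw(0L)])
  sub("[ ]+$", "", sub("^[ ]+", "", s))
}

element_numeric <- function(el) {
  if (el$vr == "US") {
    readBin(el$bytes, "integer", n = length(el$bytes) / 2L, size = 2,
            signed = FALSE, endian = "little")
  } else if (el$vr == "UL") {
    readBin(el$bytes, "integer", n = length(el$bytes) / 4L, size = 4,
            endian = "little")
  } else {
    as.numeric(strsplit(element_string(el), "\\\\")[[1]])
  }
}

#' Construct a slice image object
#'
#' In-memory representation of one validated 2D DICOM slice: stored pixel
#' matrix plus the rescale and geometry metadata needed to derive Hounsfield
#' units and stack the slice into a volume.
#'
#' @param sop_instance_uid unique instance identifier.
#' @param stored_pixels integer matrix (rows x cols) of stored values, or
#'   `NULL` when the source element is absent.
#' @param rows,cols image dimensions.
#' @param slice_location position along the stacking axis in mm (`NA` if absent).
#' @param instance_number acquisition counter (`NA` if absent).
#' @param rescale_slope,rescale_intercept affine map from stored values to HU.
#' @param pixel_spacing length-2 numeric, (row, column) spacing in mm.
#' @param attributes named list, tag `"GGGG,EEEE"` -> string value, used by
#'   [validate_series()]; presence of a name means the tag was present.
#' @param defects write-time attribute defects (see [write_dicom()]).
#' @param source_file originating path, if read from disk.
#' @return an object of class `slice_image`.
#' @export
slice_image <- function(sop_instance_uid, stored_pixels, rows, cols,
                        slice_location = NA_real_, instance_number = NA_integer_,
                        rescale_slope = 1, rescale_intercept = 0,
                        pixel_spacing = c(1, 1), attributes = list(),
                        defects = list(), source_file = NA_character_) {
  if (!is.null(stored_pixels)) {
    stored_pixels <- as.matrix(stored_pixels)
    if (!identical(dim(stored_pixels), c(as.integer(rows), as.integer(cols)))) {
      stop("stored_pixels must be a ", rows, " x ", cols, " matrix")
    }
  }
  if (!is.finite(rescale_slope) || rescale_slope == 0) {
    stop("rescale_slope must be finite and nonzero")
  }
  if (!is.finite(rescale_intercept)) stop("rescale_intercept must be finite")
  structure(
    list(
      sop_instance_uid = as.character(sop_instance_uid),
      slice_location = as.numeric(slice_location),
      instance_number = as.integer(instance_number),
      rows = as.integer(rows), cols = as.integer(cols),
      stored_pixels = stored_pixels,
      rescale_slope = as.numeric(rescale_slope),
      rescale_intercept = as.numeric(rescale_intercept),
      pixel_spacing = as.numeric(pixel_spacing),
      attributes = attributes,
      defects = defects,
      source_file = source_file
    ),
    class = "slice_image"
  )
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf(
    "<slice_image> %s\n  %d x %d stored pixels, spacing %.4g x %.4g mm\n  slice_location %s, instance %s, HU = stored * %g + %g\n",
    x$sop_instance_uid, x$rows, x$cols, x$pixel_spacing[1], x$pixel_spacing[2],
    format(x$slice_location), format(x$instance_number),
    x$rescale_slope, x$rescale_intercept
  ))
  invisible(x)
}

#' Read one DICOM file
#'
#' Parses a single-frame Part-10 file (Explicit or Implicit VR Little
#' Endian). Rescale slope and intercept default to 1 and 0 when the elements
#' are absent, so non-CT modalities read as raw stored intensities.
#'
#' @param path file path.
#' @return a [slice_image].
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 132L || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM Part-10 file: ", path)
  }
  meta <- parse_elements(bytes, 133L, explicit = TRUE, only_group = 0x0002L)
  meta_len <- sum(vapply(meta, function(e) length(e$bytes), numeric(1))) +
    sum(vapply(meta, function(e) if (e$vr %in% LONG_FORM_VRS) 12L else 8L, numeric(1)))
  ts <- TRANSFER_SYNTAX_EXPLICIT_LE
  for (e in meta) if (e$tag == "0002,0010") ts <- element_string(e)
  explicit <- switch(ts,
    "1.2.840.10008.1.2.1" = TRUE,
    "1.2.840.10008.1.2" = FALSE,
    stop("unsupported transfer syntax ", ts, " in ", path)
  )
  els <- parse_elements(bytes, 133L + meta_len, explicit = explicit)
  names(els) <- vapply(els, function(e) e$tag, character(1))

  get_el <- function(tag) els[[tag]]
  str_or_na <- function(tag) {
    el <- get_el(tag)
    if (is.null(el)) NA_character_ else element_string(el)
  }
  num_or_na <- function(tag) {
    el <- get_el(tag)
    if (is.null(el) || length(el$bytes) == 0L) NA_real_ else element_numeric(el)[1]
  }

  rows <- num_or_na("0028,0010")
  cols <- num_or_na("0028,0011")
  bits <- num_or_na("0028,0100")
  signed_px <- isTRUE(num_or_na("0028,0103") == 1)

  stored <- NULL
  px <- get_el("7FE0,0010")
  if (!is.null(px) && length(px$bytes) > 0L && !is.na(rows) && !is.na(cols)) {
    if (!is.na(bits) && bits != 16) stop("only 16-bit pixel data is supported: ", path)
    v <- readBin(px$bytes, "integer", n = rows * cols, size = 2,
                 signed = signed_px, endian = "little")
    if (length(v) < rows * cols) stop("pixel data shorter than Rows x Columns in ", path)
    stored <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  }

  spacing <- {
    el <- get_el("0028,0030")
    if (is.null(el) || length(el$bytes) == 0L) c(1, 1) else element_numeric(el)[1:2]
  }
  inum <- num_or_na("0020,0013")

  # attribute map for validation: tag -> string rendering ("" = empty value)
  att <- lapply(els, function(e) {
    if (e$vr %in% c("OW", "OB", "UN")) {
      if (length(e$bytes) > 0L) sprintf("<%d bytes>", length(e$bytes)) else ""
    } else if (e$vr %in% c("US", "UL")) {
      paste(element_numeric(e), collapse = "\\")
    } else {
      element_string(e)
    }
  })

  slice_image(
    sop_instance_uid = str_or_na("0008,0018") %||% NA_character_,
    stored_pixels = stored,
    rows = if (is.na(rows)) 0L else rows,
    cols = if (is.na(cols)) 0L else cols,
    slice_location = num_or_na("0020,1041"),
    instance_number = if (is.na(inum)) NA_integer_ else as.integer(inum),
    rescale_slope = num_or_na("0028,1053") %0na% 1,
    rescale_intercept = num_or_na("0028,1052") %0na% 0,
    pixel_spacing = spacing,
    attributes = att,
    source_file = path
  )
}

`%0na%` <- function(x, y) if (is.na(x)) y else x

#' Read a DICOM series from a directory
#'
#' Reads every parseable DICOM file in `directory` (any order); non-DICOM
#' files are skipped with a warning.
#'
#' @param directory path containing the series.
#' @return list of [slice_image] objects.
#' @export
read_series <- function(directory) {
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  files <- sort(list.files(directory, full.names = TRUE))
  files <- files[!dir.exists(files)]
  slices <- list()
  for (f in files) {
    bytes_ok <- file.size(f) >= 132 &&
      identical(readBin(f, "raw", n = 132)[129:132], charToRaw("DICM"))
    if (!bytes_ok) {
      warning("skipping non-DICOM file: ", f, call. = FALSE)
      next
    }
    slices[[length(slices) + 1L]] <- read_dicom(f)
  }
  if (length(slices) == 0L) {
    stop("no DICOM files found in ", directory)
  }
  slices
}
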