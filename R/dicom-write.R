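# Minimal single-frame DICOM Part-10 writer (Explicit VR Little Endian,
# uncompressed MONOCHROME2). Covers exactly the attribute set this package
# reads back and validates; not a general DICOM implementation.

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TRANSFER_SYNTAX_IMPLICIT_LE <- "1.2.840.10008.1.2"
SOP_CLASS_CT_IMAGE <- "1.2.840.10008.5.1.4.1.1.2"
IMPLEMENTATION_CLASS_UID <- "1.2.826.0.1.3680043.10.9590.1"

# VRs whose explicit form carries a 2-byte reserved field + 4-byte length
LONG_FORM_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

# DS values must be <= 16 bytes; plain decimal, no scientific notation
format_ds <- function(x) {
  s <- format(x, trim = TRUE, scientific = FALSE, digits = 10)
  if (any(nchar(s) > 16)) s <- format(signif(x, 8), trim = TRUE, scientific = FALSE)
  paste(s, collapse = "\\")
}

encode_value <- function(vr, value) {
  if (vr %in% c("UI", "LO", "PN", "CS", "DS", "IS", "SH", "DA", "TM")) {
    v <- charToRaw(paste(as.character(value), collapse = "\\"))
    if (length(v) %% 2L == 1L) {
      pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
      v <- c(v, pad)
    }
    v
  } else if (vr == "US") {
    dcm_uint16(value)
  } else if (vr == "UL") {
    dcm_uint32(value)
  } else if (vr %in% c("OW", "OB")) {
    stopifnot(is.raw(value))
    value
  } else {
    stop("unsupported VR for writing: ", vr)
  }
}

encode_element <- function(group, element, vr, value_raw) {
  len <- length(value_raw)
  header <- c(
    dcm_uint16(group), dcm_uint16(element), charToRaw(vr),
    if (vr %in% LONG_FORM_VRS) c(as.raw(c(0L, 0L)), dcm_uint32(len)) else dcm_uint16(len)
  )
  c(header, value_raw)
}

# one dataset element spec: list(tag = "GGGG,EEEE", vr, value)
encode_dataset <- function(elements) {
  tags <- vapply(elements, function(e) e$tag, character(1))
  elements <- elements[order(tags)]
  out <- lapply(elements, function(e) {
    ge <- strtoi(strsplit(e$tag, ",")[[1]], base = 16L)
    encode_element(ge[1], ge[2], e$vr, encode_value(e$vr, e$value))
  })
  do.call(c, out)
}

#' Write one slice as a DICOM Part-10 file
#'
#' Serializes a [slice_image] to an uncompressed Explicit VR Little Endian
#' single-frame file. Attribute defects requested on the slice (used by the
#' phantom generator to exercise validation) are applied here: a `"drop"`
#' defect omits the element entirely, an `"empty"` defect writes it with a
#' zero-length value.
#'
#' @param slice a [slice_image].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(slice, path) {
  stopifnot(inherits(slice, "slice_image"))
  tab <- dicom_tag_table()
  att <- slice$attributes

  els <- list()
  add <- function(name, vr, value) {
    els[[length(els) + 1L]] <<- list(tag = unname(tab[[name]]), vr = vr, value = value)
  }

  add("SOPClassUID", "UI", att[["0008,0016"]] %||% SOP_CLASS_CT_IMAGE)
  add("SOPInstanceUID", "UI", slice$sop_instance_uid)
  add("Modality", "CS", att[["0008,0060"]] %||% "CT")
  add("PatientName", "PN", att[["0010,0010"]] %||% "PHANTOM^SUBJECT")
  add("PatientID", "LO", att[["0010,0020"]] %||% "PH-001")
  add("StudyInstanceUID", "UI", att[["0020,000D"]] %||% paste0(IMPLEMENTATION_CLASS_UID, ".1"))
  add("SeriesInstanceUID", "UI", att[["0020,000E"]] %||% paste0(IMPLEMENTATION_CLASS_UID, ".2"))
  if (!is.na(slice$instance_number)) add("InstanceNumber", "IS", as.character(slice$instance_number))
  if (!is.na(slice$slice_location)) {
    add("ImagePositionPatient", "DS",
        att[["0020,0032"]] %||% paste(c("0", "0", format_ds(slice$slice_location)), collapse = "\\"))
    add("ImageOrientationPatient", "DS", "1\\0\\0\\0\\1\\0")
    add("SliceLocation", "DS", format_ds(slice$slice_location))
  }
  add("SamplesPerPixel", "US", 1L)
  add("PhotometricInterpretation", "CS", "MONOCHROME2")
  add("Rows", "US", slice$rows)
  add("Columns", "US", slice$cols)
  add("PixelSpacing", "DS", paste(format_ds(slice$pixel_spacing[1]), format_ds(slice$pixel_spacing[2]), sep = "\\"))
  add("BitsAllocated", "US", 16L)
  add("BitsStored", "US", 16L)
  add("HighBit", "US", 15L)
  add("PixelRepresentation", "US", 0L)
  add("RescaleIntercept", "DS", format_ds(slice$rescale_intercept))
  add("RescaleSlope", "DS", format_ds(slice$rescale_slope))
  if (!is.null(slice$stored_pixels)) {
    px <- as.integer(t(slice$stored_pixels))  # row-major per the standard
    if (any(px < 0L | px > 65535L)) stop("stored pixel values out of uint16 range")
    add("PixelData", "OW", writeBin(px, raw(), size = 2, endian = "little"))
  }

  # apply write-time defects
  for (d in slice$defects %||% list()) {
    tag <- resolve_tag(d$tag)
    hit <- vapply(els, function(e) e$tag == tag, logical(1))
    if (d$action == "drop") {
      els <- els[!hit]
    } else if (d$action == "empty") {
      for (i in which(hit)) {
        els[[i]]$value <- if (els[[i]]$vr %in% c("OW", "OB")) raw(0) else ""
      }
    } else {
      stop("unknown defect action: ", d$action)
    }
  }

  body <- encode_dataset(els)

  meta <- encode_dataset(list(
    list(tag = "0002,0001", vr = "OB", value = as.raw(c(0L, 1L))),
    list(tag = "0002,0002", vr = "UI", value = SOP_CLASS_CT_IMAGE),
    list(tag = "0002,0003", vr = "UI", value = slice$sop_instance_uid),
    list(tag = "0002,0010", vr = "UI", value = TRANSFER_SYNTAX_EXPLICIT_LE),
    list(tag = "0002,0012", vr = "UI", value = IMPLEMENTATION_CLASS_UID)
  ))
  group_len <- encode_element(0x0002L, 0x0000L, "UL", dcm_uint32(length(meta)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta, body), con)
  invisible(path)
}

#' Write a series of slices to a directory
#'
#' Writes each slice as `slice_NNNN.dcm` in list order. Used both by the
#' phantom generator and to materialize tampered series for transmission
#' experiments; duplicated SOP Instance UIDs are allowed (files are named by
#' position, not UID).
#'
#' @param slices list of [slice_image] objects.
#' @param dir output directory, created if needed.
#' @return character vector of file paths, invisibly.
#' @export
write_series <- function(slices, dir) {
  stopifnot(length(slices) >= 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(seq_along(slices), function(i) {
    p <- file.path(dir, sprintf("slice_%04d.dcm", i))
    write_dicom(slices[[i]], p)
    p
  }, character(1))
  invisible(paths)
}
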