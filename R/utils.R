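`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Deterministic rounding used before histogram binning: 0.5 -> 1,
#' -0.5 -> -1 (base `round()` rounds half to even and would bin such
#' boundary pixels differently depending on parity).
#'
#' @param x numeric vector or matrix.
#' @return object of the same shape with integral values (still numeric).
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# canonical "GGGG,EEEE" form, uppercase, no parentheses/whitespace
normalize_tag <- function(tag) {
  t <- toupper(gsub("[^0-9A-Fa-f,]", "", tag))
  if (!grepl("^[0-9A-F]{4},[0-9A-F]{4}$", t)) {
    stop("not a DICOM tag identifier: '", tag, "'", call. = FALSE)
  }
  t
}

# named vector: attribute keyword -> tag, for the attributes this package
# reads, writes and validates
dicom_tag_table <- function() {
  c(
    SOPClassUID              = "0008,0016",
    SOPInstanceUID           = "0008,0018",
    Modality                 = "0008,0060",
    PatientName              = "0010,0010",
    PatientID                = "0010,0020",
    StudyInstanceUID         = "0020,000D",
    SeriesInstanceUID        = "0020,000E",
    InstanceNumber           = "0020,0013",
    ImagePositionPatient     = "0020,0032",
    ImageOrientationPatient  = "0020,0037",
    SliceLocation            = "0020,1041",
    SamplesPerPixel          = "0028,0002",
    PhotometricInterpretation= "0028,0004",
    Rows                     = "0028,0010",
    Columns                  = "0028,0011",
    PixelSpacing             = "0028,0030",
    BitsAllocated            = "0028,0100",
    BitsStored               = "0028,0101",
    HighBit                  = "0028,0102",
    PixelRepresentation      = "0028,0103",
    WindowCenter             = "0028,1050",
    WindowWidth              = "0028,1051",
    RescaleIntercept         = "0028,1052",
    RescaleSlope             = "0028,1053",
    PixelData                = "7FE0,0010"
  )
}

# accept either a keyword ("PixelData") or a tag ("7FE0,0010")
resolve_tag <- function(x) {
  tab <- dicom_tag_table()
  if (x %in% names(tab)) unname(tab[[x]]) else normalize_tag(x)
}
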