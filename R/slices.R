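#' Convert stored pixel values to Hounsfield units
#'
#' Applies the modality rescale transform `stored * slope + intercept`
#' element-wise. No clamping is performed here: the CT convention of a
#' -1024..+3072 HU scale is applied only when histograms are built
#' ([quantize_drr()], [block_histogram()]).
#'
#' @param slice a [slice_image] with stored pixels present.
#' @return numeric matrix (rows x cols) of HU values.
#' @export
to_hu <- function(slice) {
  stopifnot(inherits(slice, "slice_image"))
  if (is.null(slice$stored_pixels)) {
    stop("slice ", slice$sop_instance_uid, " has no pixel data")
  }
  slice$stored_pixels * slice$rescale_slope + slice$rescale_intercept
}

#' Sort a series into stacking order
#'
#' Ascending Slice Location (tag 0020,1041), ties broken by Instance Number
#' and then lexicographic SOP Instance UID. When no slice carries a location
#' but all carry an instance number, the instance number is the sort key.
#'
#' @param slices list of [slice_image] objects.
#' @return a new list in stacking order (input untouched).
#' @export
sort_slices <- function(slices) {
  locs <- vapply(slices, function(s) s$slice_location, numeric(1))
  inums <- vapply(slices, function(s) as.numeric(s$instance_number), numeric(1))
  uids <- vapply(slices, function(s) s$sop_instance_uid, character(1))
  if (all(!is.na(locs))) {
    ord <- order(locs, inums, uids, na.last = TRUE)
  } else if (all(!is.na(inums))) {
    ord <- order(inums, uids)
  } else {
    stop("series is unsortable: slices lack both Slice Location and Instance Number")
  }
  slices[ord]
}

#' Default DICOM attribute validation rules
#'
#' Requirement classes follow the standard's attribute types: type 1 needs
#' tag and non-empty value, type 2 needs the tag only, type 1c needs the tag
#' whenever its condition tag is present with a value. The default set covers
#' the identity, geometry, and pixel attributes the pipeline depends on; it
#' is a tibble and can be extended by row-binding or replaced via
#' [read_validation_rules()].
#'
#' @return tibble with columns `tag`, `name`, `type_class`, `condition_tag`.
#' @export
default_validation_rules <- function() {
  tibble::tibble(
    tag = c("0008,0016", "0008,0018", "0028,0010", "0028,0011", "0028,0100",
            "7FE0,0010", "0010,0010", "0010,0020", "0020,1041"),
    name = c("SOPClassUID", "SOPInstanceUID", "Rows", "Columns",
             "BitsAllocated", "PixelData", "PatientName", "PatientID",
             "SliceLocation"),
    type_class = c(rep("type1", 6), "type2", "type2", "type1c"),
    condition_tag = c(rep(NA_character_, 8), "0020,0032")
  )
}

#' Load validation rules from a JSON config
#'
#' The file holds an array of objects with fields `tag`, `name`,
#' `type_class` (one of `type1`, `type2`, `type1c`) and, for type 1c only,
#' `condition_tag`.
#'
#' @param path JSON file path.
#' @return tibble in the shape of [default_validation_rules()].
#' @export
read_validation_rules <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  rules <- tibble::as_tibble(raw)
  if (!all(c("tag", "name", "type_class") %in% names(rules))) {
    stop("validation rule config must provide tag, name and type_class")
  }
  if (!"condition_tag" %in% names(rules)) rules$condition_tag <- NA_character_
  bad <- xor(rules$type_class == "type1c", !is.na(rules$condition_tag))
  if (any(bad)) {
    stop("condition_tag must be present exactly for type1c rules: ",
         paste(rules$name[bad], collapse = ", "))
  }
  rules$tag <- vapply(rules$tag, normalize_tag, character(1))
  rules
}

#' Validate a DICOM series against attribute rules
#'
#' Emits one finding per slice and violated rule: `missing_tag` (type 1 or 2
#' tag absent), `empty_value` (type 1 tag present with empty value), or
#' `condition_unmet` (type 1c condition tag present with a value but the
#' conditioned tag absent). SOP Instance UIDs occurring more than once are
#' reported separately; findings are data, not errors.
#'
#' @param slices list of [slice_image] objects.
#' @param rules rules tibble, see [default_validation_rules()].
#' @return object of class `series_validation`: list with `per_slice_findings`
#'   (tibble: sop_instance_uid, tag, type_class, failure_kind),
#'   `duplicate_uids`, and `is_valid` (true iff both are empty).
#' @export
validate_series <- function(slices, rules = default_validation_rules()) {
  stopifnot(nrow(rules) >= 1)
  findings <- list()
  for (s in slices) {
    att <- s$attributes
    for (i in seq_len(nrow(rules))) {
      tag <- rules$tag[i]; tc <- rules$type_class[i]
      present <- tag %in% names(att)
      empty <- present && !nzchar(att[[tag]])
      kind <- NA_character_
      if (tc == "type1") {
        if (!present) kind <- "missing_tag" else if (empty) kind <- "empty_value"
      } else if (tc == "type2") {
        if (!present) kind <- "missing_tag"
      } else if (tc == "type1c") {
        cond <- rules$condition_tag[i]
        cond_active <- cond %in% names(att) && nzchar(att[[cond]])
        if (cond_active && !present) kind <- "condition_unmet"
      } else {
        stop("unknown type_class: ", tc)
      }
      if (!is.na(kind)) {
        findings[[length(findings) + 1L]] <- tibble::tibble(
          sop_instance_uid = s$sop_instance_uid, tag = tag,
          type_class = tc, failure_kind = kind
        )
      }
    }
  }
  per_slice <- if (length(findings)) dplyr::bind_rows(findings) else
    tibble::tibble(sop_instance_uid = character(), tag = character(),
                   type_class = character(), failure_kind = character())
  uids <- vapply(slices, function(s) s$sop_instance_uid, character(1))
  dup <- unique(uids[duplicated(uids)])
  structure(
    list(per_slice_findings = per_slice, duplicate_uids = dup,
         is_valid = nrow(per_slice) == 0L && length(dup) == 0L),
    class = "series_validation"
  )
}

#' @export
print.series_validation <- function(x, ...) {
  cat("<series_validation>", if (x$is_valid) "VALID" else "INVALID", "\n")
  if (nrow(x$per_slice_findings)) print(x$per_slice_findings)
  if (length(x$duplicate_uids)) {
    cat("duplicate SOP Instance UIDs:", paste(x$duplicate_uids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname validate_series
#' @param x a `series_validation`.
#' @param ... unused.
#' @method tidy series_validation
#' @export
tidy.series_validation <- function(x, ...) x$per_slice_findings
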