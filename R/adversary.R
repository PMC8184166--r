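# Simulated in-transit attacks on a series: the three image-injection cases
# (insert, delete, modify) exercised end-to-end without a network. All
# operations are pure (the input list is untouched) and deterministic given
# the op's seed.

#' Describe a tamper operation
#'
#' @param kind `"insert"`, `"delete"`, or `"modify"`.
#' @param target_index 1-based position in sorted order: the insertion
#'   position for insert, the victim slice for delete/modify.
#' @param source for insert: `"duplicate"` (re-insert the slice currently at
#'   `target_index`, keeping its SOP Instance UID) or a foreign
#'   [slice_image] from another dataset.
#' @param amplitude signed HU shift magnitude for modify (nonzero; default 10,
#'   the canonical barely-visible perturbation).
#' @param n_pixels number of pixels to modify, or `"all"`.
#' @param seed integer driving pixel selection and per-pixel sign choice.
#' @param all_positive if `TRUE`, every modified pixel shifts by `+amplitude`
#'   (guarantees no cancellation in the projection mean); otherwise signs are
#'   i.i.d. per pixel.
#' @return object of class `tamper_op`.
#' @export
tamper_op <- function(kind = c("insert", "delete", "modify"), target_index,
                      source = "duplicate", amplitude = 10L, n_pixels = "all",
                      seed = 1L, all_positive = FALSE) {
  kind <- match.arg(kind)
  if (kind == "modify" && amplitude == 0) stop("modify requires a nonzero amplitude")
  if (!identical(n_pixels, "all") && (!is.numeric(n_pixels) || n_pixels < 1)) {
    stop("n_pixels must be a positive count or \"all\"")
  }
  structure(
    list(kind = kind, target_index = as.integer(target_index), source = source,
         amplitude = as.integer(amplitude), n_pixels = n_pixels,
         seed = as.integer(seed), all_positive = isTRUE(all_positive)),
    class = "tamper_op"
  )
}

check_bounds <- function(series, op) {
  if (op$target_index < 1 || op$target_index > length(series)) {
    stop(op$kind, " target_index ", op$target_index,
         " out of bounds for a series of ", length(series), " slices")
  }
}

#' Insert a slice into a series
#'
#' Places either a duplicated slice (same SOP Instance UID, creating the
#' duplicate-UID condition the validator reports) or a foreign slice from
#' another dataset at `target_index`. The list grows by one; the input is
#' untouched.
#'
#' @param series list of [slice_image] in sorted order.
#' @param op a [tamper_op()] with `kind = "insert"`.
#' @return new list of slices.
#' @export
insert_image <- function(series, op) {
  stopifnot(inherits(op, "tamper_op"), op$kind == "insert")
  check_bounds(series, op)
  new_slice <- if (identical(op$source, "duplicate")) {
    series[[op$target_index]]
  } else if (inherits(op$source, "slice_image")) {
    op$source
  } else {
    stop("insert source must be \"duplicate\" or a slice_image")
  }
  append(series, list(new_slice), after = op$target_index - 1L)
}

#' Delete a slice from a series
#'
#' @param series list of [slice_image], length >= 3 (so a volume can still be
#'   built from the result).
#' @param op a [tamper_op()] with `kind = "delete"`.
#' @return new list without the slice at `target_index`.
#' @export
delete_image <- function(series, op) {
  stopifnot(inherits(op, "tamper_op"), op$kind == "delete")
  if (length(series) < 3) stop("refusing to delete from a series of fewer than 3 slices")
  check_bounds(series, op)
  series[-op$target_index]
}

#' Modify pixels of one slice
#'
#' Picks `n_pixels` positions of the slice at `target_index` uniformly with
#' the op's seed and shifts each by `+amplitude` or `-amplitude` HU (sign per
#' pixel from the same seeded generator, or all positive). Stored values are
#' updated consistently with the slice's rescale slope so the HU shift is
#' exact; where a shift would leave the unsigned 16-bit stored range (e.g.
#' a negative shift on an air pixel stored as 0) its sign is flipped, keeping
#' the perturbation at exactly `+-amplitude`.
#'
#' @param series list of [slice_image].
#' @param op a [tamper_op()] with `kind = "modify"`.
#' @return new list with the modified slice.
#' @export
modify_pixels <- function(series, op) {
  stopifnot(inherits(op, "tamper_op"), op$kind == "modify")
  check_bounds(series, op)
  s <- series[[op$target_index]]
  if (is.null(s$stored_pixels)) stop("target slice has no pixel data to modify")
  npx <- length(s$stored_pixels)
  k <- if (identical(op$n_pixels, "all")) npx else min(as.integer(op$n_pixels), npx)

  delta_stored <- op$amplitude / s$rescale_slope
  if (abs(delta_stored - round(delta_stored)) > 1e-9) {
    stop("amplitude ", op$amplitude, " HU is not an integer number of stored units",
         " at slope ", s$rescale_slope)
  }
  delta_stored <- as.integer(round(delta_stored))

  withr::with_seed(op$seed, {
    idx <- sample.int(npx, k)
    signs <- if (op$all_positive) rep(1L, k) else sample(c(-1L, 1L), k, replace = TRUE)
  })
  px <- s$stored_pixels
  # stored values are unsigned: where a shift would leave the uint16 range,
  # flip its sign so the HU perturbation is still exactly +-amplitude
  cand <- px[idx] + signs * delta_stored
  flip <- cand < 0L | cand > 65535L
  signs[flip] <- -signs[flip]
  px[idx] <- px[idx] + signs * delta_stored
  if (any(px[idx] < 0L | px[idx] > 65535L)) {
    stop("modification drives stored values out of the uint16 range")
  }
  s$stored_pixels <- px
  series[[op$target_index]] <- s
  series
}

#' Apply a tamper operation
#'
#' Dispatches to [insert_image()], [delete_image()], or [modify_pixels()].
#'
#' @param series list of [slice_image] in sorted order.
#' @param op a [tamper_op()].
#' @return new list of slices.
#' @export
apply_tamper <- function(series, op) {
  stopifnot(inherits(op, "tamper_op"))
  switch(op$kind,
    insert = insert_image(series, op),
    delete = delete_image(series, op),
    modify = modify_pixels(series, op)
  )
}
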