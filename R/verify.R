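#' Integer HU histogram of a block
#'
#' Pixels are quantized (round half away from zero, clamp to `[lo, hi]`) and
#' counted per integer bin over the full inclusive range, the CT HU scale
#' -1024..+3072 by default. The counts always sum to the block's pixel count.
#'
#' @param block numeric matrix.
#' @param lo,hi inclusive integer bin range.
#' @param label block label carried through for reporting.
#' @return object of class `block_histogram`: list with `counts` (integer
#'   vector of `hi - lo + 1` bins), `lo`, `hi`, `block_label`, `shape`.
#' @export
block_histogram <- function(block, lo = -1024L, hi = 3072L, label = NA_integer_) {
  stopifnot(lo < hi)
  q <- quantize_drr(block, lo = lo, hi = hi)
  structure(
    list(counts = tabulate(as.vector(q) - lo + 1L, nbins = hi - lo + 1L),
         lo = as.integer(lo), hi = as.integer(hi),
         block_label = as.integer(label), shape = dim(as.matrix(block))),
    class = "block_histogram"
  )
}

#' L1 distance between two block histograms
#'
#' Sum over bins of the absolute count difference; zero iff the histograms
#' are identical. The histograms must share bin range and block shape.
#'
#' @param a,b `block_histogram` objects.
#' @return non-negative integer.
#' @export
hist_l1_diff <- function(a, b) {
  stopifnot(inherits(a, "block_histogram"), inherits(b, "block_histogram"))
  if (a$lo != b$lo || a$hi != b$hi) {
    stop("histogram bin ranges differ: [", a$lo, ",", a$hi, "] vs [", b$lo, ",", b$hi, "]")
  }
  if (!identical(a$shape, b$shape)) {
    stop("block shapes differ: ", paste(a$shape, collapse = "x"),
         " vs ", paste(b$shape, collapse = "x"))
  }
  sum(abs(a$counts - b$counts))
}

#' Root-mean-square error between two DRR images
#'
#' `sqrt(mean((a - b)^2))` at full double precision with a fixed summation
#' order; exactly zero iff the images are bitwise identical at the evaluated
#' precision.
#'
#' @param a,b `drr_image` objects or numeric matrices of identical shape
#'   (and, for `drr_image`s, identical direction).
#' @return non-negative numeric scalar.
#' @export
drr_rmse <- function(a, b) {
  if (inherits(a, "drr_image") && inherits(b, "drr_image") &&
      !identical(a$direction, b$direction)) {
    stop("cannot compare DRRs of different directions: ", a$direction, " vs ", b$direction)
  }
  pa <- if (inherits(a, "drr_image")) a$pixels else a
  pb <- if (inherits(b, "drr_image")) b$pixels else b
  if (!identical(dim(pa), dim(pb))) {
    stop("shape mismatch: ", paste(dim(pa), collapse = "x"),
         " vs ", paste(dim(pb), collapse = "x"))
  }
  sqrt(mean((pa - pb)^2))
}

new_verification_report <- function(per_block, rmse, verdict, direction, grid,
                                    reason = NA_character_, validation = NULL) {
  structure(
    list(per_block = per_block, rmse = rmse, verdict = verdict,
         direction = direction, grid = grid, reason = reason,
         validation = validation),
    class = "verification_report"
  )
}

empty_per_block <- function() {
  tibble::tibble(label = integer(), hist_l1_diff = integer(), passed = logical())
}

fail_report <- function(reason, direction = NA_character_, grid = c(NA_integer_, NA_integer_),
                        validation = NULL) {
  new_verification_report(empty_per_block(), NA_real_, "FAIL", direction, grid,
                          reason = reason, validation = validation)
}

#' Verify a received DICOM series against a sealed manifest
#'
#' Receiver-side pipeline: decrypt the manifest blocks, read and validate the
#' received series, sort it, rebuild the isotropic volume, regenerate the DRR
#' in the manifest's direction, partition it with the manifest's grid and
#' padding, then compare (a) each regenerated block against the matching
#' decrypted block by integer-histogram L1 difference and (b) the regenerated
#' DRR against the reassembled decrypted DRR by RMSE. The verdict is PASS iff
#' every block difference is zero, the RMSE is exactly zero, and the series
#' validates cleanly; any structural failure (unreadable series, malformed
#' manifest, wrong passphrase, geometry mismatch) yields a FAIL report with a
#' reason rather than an error.
#'
#' @param directory received series directory.
#' @param manifest a `seal_manifest` or path to a manifest JSON.
#' @param passphrase secret text used at sealing.
#' @param rules validation rules applied to the received series.
#' @param hist_range inclusive integer bin range for the block histograms.
#' @return object of class `verification_report`: `per_block` tibble
#'   (`label`, `hist_l1_diff`, `passed`), `rmse`, `verdict` (`"PASS"` or
#'   `"FAIL"`), `direction`, `grid`, `reason`, `validation`.
#' @export
verify_series <- function(directory, manifest, passphrase,
                          rules = default_validation_rules(),
                          hist_range = c(-1024L, 3072L)) {
  if (is.character(manifest)) {
    manifest <- tryCatch(read_seal_manifest(manifest), error = function(e) e)
    if (inherits(manifest, "error")) {
      return(fail_report(paste("manifest unreadable:", conditionMessage(manifest))))
    }
  }
  direction <- manifest$direction %||% NA_character_
  grid <- manifest$grid %||% c(NA_integer_, NA_integer_)

  sealed <- tryCatch(unseal(manifest, passphrase), error = function(e) e)
  if (inherits(sealed, "error")) {
    return(fail_report(conditionMessage(sealed), direction, grid))
  }

  pipeline <- tryCatch({
    slices <- read_series(directory)
    val <- validate_series(slices, rules)
    vol <- build_volume(sort_slices(slices))
    drr <- compute_drr(vol, direction)
    list(val = val, drr = drr)
  }, error = function(e) e)
  if (inherits(pipeline, "error")) {
    return(fail_report(paste("series pipeline failed:", conditionMessage(pipeline)),
                       direction, grid))
  }
  val <- pipeline$val
  drr <- pipeline$drr

  pad <- manifest$pad %||% "none"
  shape <- dim(drr$pixels)
  if (pad == "air") shape <- as.integer(ceiling(shape / grid) * grid)
  if (!identical(as.integer(shape), as.integer(manifest$drr_shape))) {
    return(fail_report(
      sprintf("regenerated DRR shape %s does not match sealed shape %s",
              paste(shape, collapse = "x"),
              paste(manifest$drr_shape, collapse = "x")),
      direction, grid, validation = val
    ))
  }
  regen <- partition_blocks(drr, grid = grid, pad = pad)

  lo <- as.integer(hist_range[1]); hi <- as.integer(hist_range[2])
  diffs <- vapply(seq_along(regen$blocks), function(k) {
    hist_l1_diff(
      block_histogram(regen$blocks[[k]], lo, hi, label = regen$labels[k]),
      block_histogram(sealed$blocks[[k]], lo, hi, label = sealed$labels[k])
    )
  }, numeric(1))
  per_block <- tibble::tibble(
    label = regen$labels,
    hist_l1_diff = as.integer(diffs),
    passed = diffs == 0
  )

  rmse <- drr_rmse(reassemble_blocks(regen), reassemble_blocks(sealed))

  reason <- NA_character_
  if (!val$is_valid) {
    reason <- sprintf("series validation failed (%d finding(s), %d duplicate UID(s))",
                      nrow(val$per_slice_findings), length(val$duplicate_uids))
  } else if (any(!per_block$passed) || rmse > 0) {
    reason <- "regenerated DRR differs from sealed DRR"
  }

  verdict <- if (all(per_block$passed) && rmse == 0 && val$is_valid) "PASS" else "FAIL"
  new_verification_report(per_block, rmse, verdict, direction, grid,
                          reason = reason, validation = val)
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("<verification_report> %s (%s DRR, %s grid)\n",
              x$verdict, x$direction,
              paste(x$grid, collapse = "x")))
  cat(sprintf("  RMSE: %s | blocks with nonzero histogram diff: %d of %d\n",
              format(x$rmse), sum(!x$per_block$passed), nrow(x$per_block)))
  if (!is.na(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Tidy per-block verification results
#'
#' @param x a `verification_report`.
#' @param ... unused.
#' @return tibble with one row per block: `label`, `hist_l1_diff`, `passed`.
#' @method tidy verification_report
#' @export
tidy.verification_report <- function(x, ...) x$per_block

#' One-row verification summary
#'
#' @param x a `verification_report`.
#' @param ... unused.
#' @return tibble with `verdict`, `rmse`, `hist_diff_total`, `n_blocks`,
#'   `n_blocks_failed`, `direction`, `reason`.
#' @method glance verification_report
#' @export
glance.verification_report <- function(x, ...) {
  tibble::tibble(
    verdict = x$verdict,
    rmse = x$rmse,
    hist_diff_total = sum(x$per_block$hist_l1_diff),
    n_blocks = nrow(x$per_block),
    n_blocks_failed = sum(!x$per_block$passed),
    direction = x$direction,
    reason = x$reason
  )
}

#' Plot per-block histogram differences
#'
#' @param object a `verification_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot verification_report
#' @export
autoplot.verification_report <- function(object, ...) {
  df <- object$per_block
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$label), y = .data$hist_l1_diff,
                                   fill = .data$passed)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2b8cbe", `FALSE` = "#d7301f"),
                               labels = c(`TRUE` = "unchanged", `FALSE` = "modified")) +
    ggplot2::labs(x = "block (row-major label)", y = "histogram L1 difference",
                  fill = NULL,
                  title = sprintf("Verification %s (RMSE = %s)",
                                  object$verdict, format(object$rmse))) +
    ggplot2::theme_minimal()
}
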