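DRR_DIRECTIONS <- c("coronal", "sagittal", "axial")

#' Compute a digitally reconstructed radiograph
#'
#' Projects the HU volume along one patient axis by averaging: coronal
#' averages over y (`pixels[z, x] = mean_y hu[z, y, x]`), sagittal over x,
#' axial over z. Pixels stay at full double precision — a +-10 HU change in
#' one of N projected voxels moves a DRR pixel by only 10/N, which integer
#' rounding could erase. Accumulation is sequential in ascending index order,
#' so identical input volumes give bit-identical DRRs on both ends of a
#' transmission.
#'
#' @param volume a [build_volume()] result.
#' @param direction `"coronal"` (default, the view the sealing stage
#'   encrypts), `"sagittal"`, or `"axial"`.
#' @return object of class `drr_image`: list with `pixels` (matrix),
#'   `direction`, `source_extents` (nz, ny, nx).
#' @export
compute_drr <- function(volume, direction = DRR_DIRECTIONS) {
  stopifnot(inherits(volume, "hu_volume"))
  direction <- match.arg(direction)
  v <- volume$hu
  d <- dim(v)
  pixels <- switch(direction,
    axial    = colMeans(v, dims = 1),                   # mean over z -> (ny, nx)
    coronal  = colMeans(aperm(v, c(2, 1, 3)), dims = 1), # mean over y -> (nz, nx)
    sagittal = rowMeans(v, dims = 2)                     # mean over x -> (nz, ny)
  )
  structure(
    list(pixels = pixels, direction = direction,
         source_extents = c(nz = d[1], ny = d[2], nx = d[3])),
    class = "drr_image"
  )
}

#' @export
print.drr_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<drr_image> %s, %d x %d pixels, mean %.2f HU\n",
              x$direction, d[1], d[2], mean(x$pixels)))
  invisible(x)
}

#' Quantize DRR pixels to integer HU bins
#'
#' Rounds half away from zero, then clamps to `[lo, hi]`. Used only for
#' histogram construction; sealing and RMSE operate on the float pixels.
#'
#' @param drr a `drr_image` or numeric matrix.
#' @param lo,hi inclusive integer HU range (defaults -1024 and +3072, the CT
#'   HU scale; configurable for non-CT intensities).
#' @return integer matrix of the same shape.
#' @export
quantize_drr <- function(drr, lo = -1024L, hi = 3072L) {
  stopifnot(lo < hi)
  px <- if (inherits(drr, "drr_image")) drr$pixels else drr
  q <- round_half_away(px)
  q[q < lo] <- lo
  q[q > hi] <- hi
  storage.mode(q) <- "integer"
  q
}

#' Plot a DRR image
#'
#' @param object a `drr_image`.
#' @param center,width display window in HU.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot drr_image
#' @export
autoplot.drr_image <- function(object, center = 0, width = 2000, ...) {
  px <- object$pixels
  df <- expand.grid(row = seq_len(nrow(px)), col = seq_len(ncol(px)))
  df$value <- pmin(pmax((as.vector(px) - (center - width / 2)) / width, 0), 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste(object$direction, "DRR"), fill = "grey") +
    ggplot2::theme_minimal()
}

#' Export a window/levelled DRR as PNG
#'
#' Visual inspection aid only; verification never consumes this output.
#'
#' @param drr a `drr_image`.
#' @param path output file.
#' @param center,width display window in HU.
#' @return `path`, invisibly.
#' @export
export_drr_png <- function(drr, path, center = 0, width = 2000) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export")
  }
  g <- pmin(pmax((drr$pixels - (center - width / 2)) / width, 0), 1)
  png::writePNG(g, path)
  invisible(path)
}
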