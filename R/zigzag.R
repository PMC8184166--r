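#' Zig-zag traversal order of a block grid
#'
#' JPEG-style anti-diagonal scan of a `g_rows x g_cols` grid of blocks
#' labelled 1..`g_rows * g_cols` in row-major order: start at the top-left
#' block, first step to the right, then alternate diagonal directions. The
#' scrambled transmission order makes it hard for an adversary to reassemble
#' intercepted blocks; for the default 4 x 4 grid the third block visited is
#' row-major label 5.
#'
#' @param g_rows,g_cols grid dimensions, both >= 1.
#' @return integer vector: a permutation of `1:(g_rows * g_cols)` giving the
#'   1-based row-major labels in visiting order.
#' @export
zigzag_order <- function(g_rows, g_cols) {
  g_rows <- as.integer(g_rows); g_cols <- as.integer(g_cols)
  stopifnot(g_rows >= 1, g_cols >= 1)
  out <- integer(g_rows * g_cols)
  k <- 0L
  for (s in 0:(g_rows + g_cols - 2L)) {
    r_range <- max(0L, s - g_cols + 1L):min(g_rows - 1L, s)
    if (s %% 2L == 0L) r_range <- rev(r_range)  # even anti-diagonals run up-right
    for (r in r_range) {
      k <- k + 1L
      out[k] <- r * g_cols + (s - r) + 1L
    }
  }
  out
}
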