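#' Partition a DRR into an equal block grid in zig-zag order
#'
#' Splits the image into `g_rows x g_cols` equal blocks (row-major labels),
#' then orders them by [zigzag_order()]. A 512 x 512 DRR under the default
#' 4 x 4 grid gives 16 blocks of 128 x 128; 256 x 256 gives 64 x 64 blocks.
#' Dimensions must divide the grid exactly unless `pad = "air"`, which pads
#' the bottom/right edges with -1024 HU before splitting (the receiver pads
#' identically, as recorded in the sealed manifest).
#'
#' @param drr a `drr_image` or numeric matrix.
#' @param grid integer pair `(g_rows, g_cols)`, default `c(4, 4)`.
#' @param pad `"none"` (error on non-divisible dimensions) or `"air"`.
#' @return object of class `block_set`: list with `blocks` (in traversal
#'   order), `labels` (matching row-major labels), `grid`, `block_shape`,
#'   `drr_shape` (possibly padded), `orig_shape`, `pad`.
#' @export
partition_blocks <- function(drr, grid = c(4, 4), pad = c("none", "air")) {
  pad <- match.arg(pad)
  px <- if (inherits(drr, "drr_image")) drr$pixels else drr
  grid <- as.integer(grid)
  stopifnot(length(grid) == 2, all(grid >= 1))
  orig_shape <- dim(px)

  if (nrow(px) %% grid[1] != 0 || ncol(px) %% grid[2] != 0) {
    if (pad == "none") {
      off <- c(if (nrow(px) %% grid[1] != 0) sprintf("rows (%d %% %d != 0)", nrow(px), grid[1]),
               if (ncol(px) %% grid[2] != 0) sprintf("cols (%d %% %d != 0)", ncol(px), grid[2]))
      stop("DRR dimensions not divisible by grid: ", paste(off, collapse = ", "),
           "; use pad = \"air\"")
    }
    nr <- ceiling(nrow(px) / grid[1]) * grid[1]
    nc <- ceiling(ncol(px) / grid[2]) * grid[2]
    padded <- matrix(-1024, nr, nc)
    padded[seq_len(nrow(px)), seq_len(ncol(px))] <- px
    px <- padded
  }

  br <- nrow(px) %/% grid[1]
  bc <- ncol(px) %/% grid[2]
  labels <- zigzag_order(grid[1], grid[2])
  blocks <- lapply(labels, function(lab) {
    r <- (lab - 1L) %/% grid[2]
    c0 <- (lab - 1L) %% grid[2]
    px[(r * br + 1L):((r + 1L) * br), (c0 * bc + 1L):((c0 + 1L) * bc), drop = FALSE]
  })

  structure(
    list(blocks = blocks, labels = labels, grid = grid,
         block_shape = c(br, bc), drr_shape = dim(px),
         orig_shape = orig_shape, pad = pad),
    class = "block_set"
  )
}

#' Reassemble a block set into the full image
#'
#' Inverse of [partition_blocks()] (up to padding): places each block back at
#' its row-major label position.
#'
#' @param block_set a `block_set`.
#' @return numeric matrix of shape `drr_shape`.
#' @export
reassemble_blocks <- function(block_set) {
  stopifnot(inherits(block_set, "block_set"))
  g <- block_set$grid; bs <- block_set$block_shape
  out <- matrix(NA_real_, g[1] * bs[1], g[2] * bs[2])
  for (k in seq_along(block_set$blocks)) {
    lab <- block_set$labels[k]
    r <- (lab - 1L) %/% g[2]
    c0 <- (lab - 1L) %% g[2]
    out[(r * bs[1] + 1L):((r + 1L) * bs[1]), (c0 * bs[2] + 1L):((c0 + 1L) * bs[2])] <-
      block_set$blocks[[k]]
  }
  out
}

#' Serialize a block to bytes
#'
#' Fixed, documented dialect so sender and receiver agree bit-for-bit: two
#' 32-bit little-endian unsigned dimensions (rows, cols) followed by the
#' pixels as 64-bit little-endian IEEE doubles in row-major order.
#'
#' @param block numeric matrix with finite values.
#' @return raw vector of `8 + 8 * length(block)` bytes.
#' @export
serialize_block <- function(block) {
  block <- as.matrix(block)
  if (!all(is.finite(block))) stop("block contains non-finite values")
  c(
    writeBin(as.integer(dim(block)), raw(), size = 4, endian = "little"),
    writeBin(as.vector(t(block)), raw(), size = 8, endian = "little")
  )
}

#' Deserialize a block from bytes
#'
#' @param bytes raw vector produced by [serialize_block()].
#' @return numeric matrix.
#' @export
deserialize_block <- function(bytes) {
  if (length(bytes) < 8) stop("malformed block payload: too short")
  dims <- readBin(bytes[1:8], "integer", n = 2, size = 4, endian = "little")
  if (any(dims < 1) || length(bytes) != 8 + 8 * prod(dims)) {
    stop("malformed block payload: length does not match dimensions")
  }
  vals <- readBin(bytes[-(1:8)], "double", n = prod(dims), size = 8, endian = "little")
  matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
}
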