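MANIFEST_FORMAT_VERSION <- "1"
ZIGZAG_ID <- "jpeg-antidiagonal-right-start-v1"
SERIALIZATION_ID <- "u32le-dims+f64le-rowmajor-v1"
DEFAULT_KDF_ITERATIONS <- 200000L

#' Derive an AES-256 key from a passphrase
#'
#' PBKDF2-HMAC-SHA256 with a random 16-byte salt and 200,000 iterations by
#' default; the salt and iteration count travel in the sealed manifest so the
#' receiver derives the identical key.
#'
#' @param passphrase secret text (non-empty).
#' @param salt raw vector.
#' @param iterations positive integer.
#' @return raw vector of 32 key bytes.
#' @export
derive_key <- function(passphrase, salt, iterations = DEFAULT_KDF_ITERATIONS) {
  if (!is.character(passphrase) || length(passphrase) != 1 || !nzchar(passphrase)) {
    stop("passphrase must be a non-empty string")
  }
  stopifnot(is.raw(salt), length(salt) >= 8)
  .Call("C_pbkdf2_sha256", charToRaw(passphrase), salt, as.integer(iterations), 32L,
        PACKAGE = "drrseal")
}

#' Seal a DRR into an encrypted block manifest
#'
#' Partitions the DRR with [partition_blocks()], serializes each block
#' ([serialize_block()]), and encrypts each independently with AES-256 in CBC
#' mode with PKCS#7 padding and a fresh random IV per block. No MAC is added:
#' integrity is established by the receiver regenerating the DRR from the
#' transmitted series and comparing content, not by authenticating the
#' ciphertext. Entries are stored in zig-zag order with their row-major
#' labels.
#'
#' @param drr a `drr_image`.
#' @param passphrase secret text shared with the receiver.
#' @param grid block grid, default `c(4, 4)` (8 x 8 also supported).
#' @param pad see [partition_blocks()].
#' @param kdf_iterations PBKDF2 iteration count.
#' @param source_image_count number of slices the DRR was built from (kept in
#'   the manifest for reporting).
#' @return object of class `seal_manifest`.
#' @export
seal_drr <- function(drr, passphrase, grid = c(4, 4), pad = c("none", "air"),
                     kdf_iterations = DEFAULT_KDF_ITERATIONS,
                     source_image_count = NA_integer_) {
  stopifnot(inherits(drr, "drr_image"))
  pad <- match.arg(pad)
  bs <- partition_blocks(drr, grid = grid, pad = pad)

  salt <- openssl::rand_bytes(16)
  key <- derive_key(passphrase, salt, kdf_iterations)

  entries <- lapply(seq_along(bs$blocks), function(k) {
    iv <- openssl::rand_bytes(16)
    ct <- openssl::aes_cbc_encrypt(serialize_block(bs$blocks[[k]]), key = key, iv = iv)
    attributes(ct) <- NULL
    list(label = bs$labels[k], iv = iv, ciphertext = ct)
  })

  structure(
    list(
      format_version = MANIFEST_FORMAT_VERSION,
      direction = drr$direction,
      drr_shape = bs$drr_shape,
      orig_shape = bs$orig_shape,
      grid = bs$grid,
      pad = bs$pad,
      zigzag_id = ZIGZAG_ID,
      serialization = SERIALIZATION_ID,
      kdf = list(salt = salt, iterations = as.integer(kdf_iterations)),
      entries = entries,
      source_image_count = as.integer(source_image_count)
    ),
    class = "seal_manifest"
  )
}

#' Seal a DICOM series end to end
#'
#' Sender-side pipeline: read the series, validate it (refusing to seal an
#' invalid series), sort, build the isotropic volume, project the DRR in the
#' requested direction, and seal it. The manifest is the sidecar to transmit
#' alongside the dataset.
#'
#' @param directory series directory.
#' @param passphrase secret text.
#' @param direction projection direction, default `"coronal"`.
#' @inheritParams seal_drr
#' @param rules validation rules; set `NULL` to skip sender-side validation.
#' @return a `seal_manifest`.
#' @export
seal_series <- function(directory, passphrase, direction = "coronal",
                        grid = c(4, 4), pad = c("none", "air"),
                        kdf_iterations = DEFAULT_KDF_ITERATIONS,
                        rules = default_validation_rules()) {
  slices <- read_series(directory)
  if (!is.null(rules)) {
    val <- validate_series(slices, rules)
    if (!val$is_valid) {
      stop("refusing to seal an invalid series: ",
           nrow(val$per_slice_findings), " finding(s), ",
           length(val$duplicate_uids), " duplicate UID(s)")
    }
  }
  vol <- build_volume(sort_slices(slices))
  drr <- compute_drr(vol, direction)
  seal_drr(drr, passphrase, grid = grid, pad = pad,
           kdf_iterations = kdf_iterations,
           source_image_count = vol$n_slices_original)
}

check_manifest <- function(manifest) {
  if (!inherits(manifest, "seal_manifest")) stop("malformed manifest: wrong class")
  m <- manifest
  need <- c("format_version", "direction", "drr_shape", "grid", "zigzag_id",
            "serialization", "kdf", "entries")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("malformed manifest: missing fields ", paste(miss, collapse = ", "))
  if (!identical(m$format_version, MANIFEST_FORMAT_VERSION)) {
    stop("malformed manifest: unsupported format_version ", m$format_version)
  }
  expected <- zigzag_order(m$grid[1], m$grid[2])
  labels <- vapply(m$entries, function(e) as.integer(e$label), integer(1))
  if (length(m$entries) != prod(m$grid)) {
    stop("malformed manifest: ", length(m$entries), " entries for a ",
         m$grid[1], "x", m$grid[2], " grid")
  }
  if (!identical(labels, expected)) {
    stop("malformed manifest: entry labels do not follow the zig-zag traversal")
  }
  ivs <- vapply(m$entries, function(e) paste(as.character(e$iv), collapse = ""), character(1))
  if (anyDuplicated(ivs)) stop("malformed manifest: repeated IVs")
  invisible(TRUE)
}

#' Decrypt a sealed manifest back into blocks
#'
#' Derives the key from the passphrase with the manifest's KDF parameters and
#' decrypts every entry. A PKCS#7 padding failure is reported as a wrong-key
#' or corrupted-ciphertext error; structural violations (entry count, label
#' order, repeated IVs) are malformed-manifest errors.
#'
#' @param manifest a `seal_manifest` (or path to one, see
#'   [read_seal_manifest()]).
#' @param passphrase secret text used at sealing.
#' @return a `block_set` with the decrypted blocks in zig-zag order.
#' @export
unseal <- function(manifest, passphrase) {
  if (is.character(manifest)) manifest <- read_seal_manifest(manifest)
  check_manifest(manifest)
  key <- derive_key(passphrase, manifest$kdf$salt, manifest$kdf$iterations)
  blocks <- lapply(manifest$entries, function(e) {
    pt <- tryCatch(
      openssl::aes_cbc_decrypt(e$ciphertext, key = key, iv = e$iv),
      error = function(err) {
        stop("wrong passphrase or corrupted ciphertext for block ", e$label,
             call. = FALSE)
      }
    )
    deserialize_block(pt)
  })
  shapes <- unique(lapply(blocks, dim))
  if (length(shapes) != 1) stop("malformed manifest: decrypted blocks differ in shape")
  structure(
    list(blocks = blocks,
         labels = vapply(manifest$entries, function(e) as.integer(e$label), integer(1)),
         grid = manifest$grid, block_shape = shapes[[1]],
         drr_shape = manifest$drr_shape,
         orig_shape = manifest$orig_shape %||% manifest$drr_shape,
         pad = manifest$pad %||% "none"),
    class = "block_set"
  )
}

#' Write a sealed manifest as a JSON sidecar
#'
#' Binary fields are base64-encoded; conventionally written next to the
#' dataset as `<series>.seal.json`.
#'
#' @param manifest a `seal_manifest`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_seal_manifest <- function(manifest, path) {
  check_manifest(manifest)
  m <- manifest
  obj <- list(
    format_version = m$format_version,
    direction = m$direction,
    drr_shape = as.integer(m$drr_shape),
    orig_shape = as.integer(m$orig_shape),
    grid = as.integer(m$grid),
    pad = m$pad,
    zigzag_id = m$zigzag_id,
    serialization = m$serialization,
    kdf = list(salt = jsonlite::base64_enc(m$kdf$salt),
               iterations = m$kdf$iterations),
    source_image_count = m$source_image_count,
    entries = lapply(m$entries, function(e) list(
      label = as.integer(e$label),
      iv = jsonlite::base64_enc(e$iv),
      ciphertext = jsonlite::base64_enc(e$ciphertext)
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a sealed manifest from JSON
#'
#' @param path manifest file.
#' @return a `seal_manifest`.
#' @export
read_seal_manifest <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- c("format_version", "direction", "drr_shape", "grid", "kdf", "entries")
  miss <- setdiff(need, names(obj))
  if (length(miss)) stop("malformed manifest: missing fields ", paste(miss, collapse = ", "))
  structure(
    list(
      format_version = obj$format_version,
      direction = obj$direction,
      drr_shape = vapply(obj$drr_shape, as.integer, integer(1)),
      orig_shape = if (!is.null(obj$orig_shape))
        vapply(obj$orig_shape, as.integer, integer(1)) else NULL,
      grid = vapply(obj$grid, as.integer, integer(1)),
      pad = obj$pad %||% "none",
      zigzag_id = obj$zigzag_id,
      serialization = obj$serialization,
      kdf = list(salt = jsonlite::base64_dec(obj$kdf$salt),
                 iterations = as.integer(obj$kdf$iterations)),
      entries = lapply(obj$entries, function(e) list(
        label = as.integer(e$label),
        iv = jsonlite::base64_dec(e$iv),
        ciphertext = jsonlite::base64_dec(e$ciphertext)
      )),
      source_image_count = as.integer(obj$source_image_count %||% NA_integer_)
    ),
    class = "seal_manifest"
  )
}

#' @export
print.seal_manifest <- function(x, ...) {
  cat(sprintf(
    "<seal_manifest v%s> %s DRR %d x %d, grid %d x %d (%d AES-256-CBC blocks)\n  KDF: PBKDF2-HMAC-SHA256, %d iterations; sealed from %s slices\n",
    x$format_version, x$direction, x$drr_shape[1], x$drr_shape[2],
    x$grid[1], x$grid[2], length(x$entries), x$kdf$iterations,
    format(x$source_image_count)
  ))
  invisible(x)
}
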