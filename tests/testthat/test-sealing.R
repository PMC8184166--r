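test_that("partition geometry matches the equal-grid contract", {
  big <- matrix(rnorm(512 * 512), 512, 512)
  bs <- partition_blocks(big, grid = c(4, 4))
  expect_length(bs$blocks, 16)
  expect_true(all(vapply(bs$blocks, function(b) identical(dim(b), c(128L, 128L)), logical(1))))

  mid <- matrix(rnorm(256 * 256), 256, 256)
  expect_equal(partition_blocks(mid, grid = c(4, 4))$block_shape, c(64, 64))

  expect_error(partition_blocks(matrix(0, 30, 32), grid = c(4, 4)), "rows \\(30")
  expect_error(partition_blocks(matrix(0, 32, 30), grid = c(4, 4)), "cols \\(30")
})

test_that("reassembling blocks restores the image bitwise; padding is air", {
  px <- withr::with_seed(5, matrix(rnorm(40 * 64, -500, 300), 40, 64))
  bs <- partition_blocks(px, grid = c(4, 4))
  expect_identical(reassemble_blocks(bs), px)
  expect_setequal(bs$labels, 1:16)

  odd <- matrix(100, 30, 32)
  padded <- partition_blocks(odd, grid = c(4, 4), pad = "air")
  expect_equal(padded$drr_shape, c(32, 32))
  re <- reassemble_blocks(padded)
  expect_identical(re[1:30, ], odd)
  expect_true(all(re[31:32, ] == -1024))
})

test_that("block serialization is a deterministic bitwise round trip", {
  one <- matrix(0.0, 1, 1)
  expect_length(serialize_block(one), 16)  # 8 header + 8 payload bytes

  b23 <- matrix(rnorm(6), 2, 3)
  expect_length(serialize_block(b23), 8 + 48)

  for (seed in 1:5) {
    b <- withr::with_seed(seed, matrix(rnorm(35, 0, 1000), 5, 7))
    expect_identical(deserialize_block(serialize_block(b)), b)
    expect_identical(serialize_block(b), serialize_block(b))
  }
  expect_error(deserialize_block(as.raw(1:4)), "malformed")
  expect_error(serialize_block(matrix(c(1, NaN), 1, 2)), "non-finite")
})

test_that("seal/unseal is the identity on blocks for random DRRs and passphrases", {
  for (seed in 1:5) {
    drr <- random_drr(16, 16, seed = seed)
    pw <- paste0("pw-", withr::with_seed(seed, paste(sample(letters, 12), collapse = "")))
    m <- seal_drr(drr, pw, kdf_iterations = 500L)
    got <- unseal(m, pw)
    want <- partition_blocks(drr, c(4, 4))
    expect_equal(got$labels, want$labels)
    for (k in seq_along(want$blocks)) {
      expect_identical(got$blocks[[k]], want$blocks[[k]])
    }
  }
})

test_that("fresh IVs give different ciphertexts but identical plaintext blocks", {
  drr <- random_drr(8, 8, seed = 2)
  m1 <- seal_drr(drr, "same-pass", kdf_iterations = 500L)
  m2 <- seal_drr(drr, "same-pass", kdf_iterations = 500L)
  expect_false(identical(m1$entries[[1]]$ciphertext, m2$entries[[1]]$ciphertext))
  expect_identical(unseal(m1, "same-pass")$blocks, unseal(m2, "same-pass")$blocks)
  ivs <- vapply(m1$entries, function(e) paste(as.character(e$iv), collapse = ""), character(1))
  expect_equal(anyDuplicated(ivs), 0L)
})

test_that("ciphertext length is the PKCS#7-padded plaintext length", {
  drr <- random_drr(8, 12, seed = 3)
  m <- seal_drr(drr, "pw", grid = c(2, 2), kdf_iterations = 500L)
  pt_len <- 8 + 8 * (4 * 6)  # header + doubles per 4x6 block
  expect_true(all(vapply(m$entries, function(e) length(e$ciphertext), numeric(1)) ==
                    (pt_len %/% 16 + 1) * 16))
})

test_that("plaintext bytes do not survive into the ciphertext", {
  for (seed in 1:3) {
    b <- withr::with_seed(seed, matrix(rnorm(16), 4, 4))
    drr <- structure(list(pixels = b, direction = "coronal",
                          source_extents = c(nz = 4L, ny = 1L, nx = 4L)),
                     class = "drr_image")
    m <- seal_drr(drr, "pw", grid = c(1, 1), kdf_iterations = 500L)
    pt <- serialize_block(b)
    expect_length(grepRaw(pt, m$entries[[1]]$ciphertext, fixed = TRUE), 0)
  }
})

test_that("wrong passphrases and malformed manifests are rejected", {
  drr <- random_drr(8, 8, seed = 4)
  m <- seal_drr(drr, "right", kdf_iterations = 500L)
  res <- tryCatch(unseal(m, "wrong"), error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "wrong passphrase|corrupted")
  } else {
    expect_false(identical(res$blocks, partition_blocks(drr, c(4, 4))$blocks))
  }

  m15 <- m
  m15$entries <- m15$entries[-1]
  expect_error(unseal(m15, "right"), "malformed manifest")

  mbad <- m
  mbad$entries <- rev(mbad$entries)
  expect_error(unseal(mbad, "right"), "zig-zag")
})

test_that("manifest JSON sidecar round trips and unseals identically", {
  drr <- random_drr(12, 16, seed = 6)
  m <- seal_drr(drr, "sidecar-pw", kdf_iterations = 500L,
                source_image_count = 12L)
  path <- tempfile(fileext = ".seal.json")
  write_seal_manifest(m, path)
  m2 <- read_seal_manifest(path)
  expect_equal(m2$format_version, m$format_version)
  expect_equal(m2$grid, m$grid)
  expect_equal(m2$drr_shape, m$drr_shape)
  expect_equal(m2$kdf$iterations, m$kdf$iterations)
  expect_identical(m2$kdf$salt, m$kdf$salt)
  expect_equal(m2$source_image_count, 12L)
  expect_identical(unseal(m2, "sidecar-pw")$blocks, unseal(m, "sidecar-pw")$blocks)
})
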