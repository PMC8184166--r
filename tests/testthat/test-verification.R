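test_that("block histograms count quantized pixels over the HU range", {
  const <- matrix(0.0, 128, 128)
  h <- block_histogram(const)
  expect_equal(sum(h$counts), 128 * 128)
  expect_equal(h$counts[0 - h$lo + 1], 128 * 128)
  expect_equal(sum(h$counts != 0), 1)

  edges <- matrix(c(-1024, 3072), 1, 2)
  he <- block_histogram(edges)
  expect_equal(he$counts[1], 1)
  expect_equal(he$counts[length(he$counts)], 1)

  for (seed in 1:3) {
    b <- withr::with_seed(seed, matrix(rnorm(64, 0, 2000), 8, 8))
    expect_equal(sum(block_histogram(b)$counts), 64)
  }
})

test_that("histogram L1 difference matches the bin-by-bin loop oracle", {
  a <- matrix(0, 4, 4)
  expect_equal(hist_l1_diff(block_histogram(a), block_histogram(a)), 0)

  b <- a; b[1, 1] <- 10  # one pixel moved from bin 0 to bin 10
  expect_equal(hist_l1_diff(block_histogram(a), block_histogram(b)), 2)

  for (seed in 1:4) {
    p <- withr::with_seed(seed, matrix(sample(-1024:3072, 64, TRUE), 8, 8))
    q <- withr::with_seed(seed + 9, matrix(sample(-1024:3072, 64, TRUE), 8, 8))
    ha <- block_histogram(p); hb <- block_histogram(q)
    oracle <- 0
    for (i in seq_along(ha$counts)) oracle <- oracle + abs(ha$counts[i] - hb$counts[i])
    expect_equal(hist_l1_diff(ha, hb), oracle)
  }

  expect_error(hist_l1_diff(block_histogram(a), block_histogram(matrix(0, 2, 2))),
               "shapes differ")
  expect_error(hist_l1_diff(block_histogram(a), block_histogram(a, lo = 0, hi = 10)),
               "ranges differ")
})

test_that("RMSE matches its closed form and the scalar loop oracle", {
  a <- withr::with_seed(1, matrix(rnorm(24), 4, 6))
  expect_identical(drr_rmse(a, a), 0)

  b <- a; b[2, 3] <- b[2, 3] + 7
  expect_equal(drr_rmse(a, b), 7 / sqrt(24))

  for (seed in 1:4) {
    p <- withr::with_seed(seed, matrix(rnorm(35, 0, 100), 5, 7))
    q <- withr::with_seed(seed + 50, matrix(rnorm(35, 0, 100), 5, 7))
    acc <- 0
    for (i in 1:5) for (j in 1:7) acc <- acc + (p[i, j] - q[i, j])^2
    expect_equal(drr_rmse(p, q), sqrt(acc / 35))
  }

  expect_error(drr_rmse(a, matrix(0, 2, 2)), "shape mismatch")
  d1 <- random_drr(4, 4, seed = 1, direction = "coronal")
  d2 <- random_drr(4, 4, seed = 1, direction = "axial")
  expect_error(drr_rmse(d1, d2), "different directions")
})

test_that("an untampered series verifies with exact zeros", {
  dir <- make_phantom_dir(tiny_spec(seed = 11))
  m <- seal_series(dir, "pw", kdf_iterations = 500L)

  # verify a fresh copy of the transmitted files, not the originals
  copy <- tempfile("received-")
  dir.create(copy)
  file.copy(list.files(dir, full.names = TRUE), copy)

  rep <- verify_series(copy, m, "pw")
  expect_equal(rep$verdict, "PASS")
  expect_identical(rep$rmse, 0)
  expect_true(all(rep$per_block$hist_l1_diff == 0L))
  expect_equal(nrow(tidy(rep)), 16)
  g <- glance(rep)
  expect_equal(g$hist_diff_total, 0L)
  expect_equal(g$n_blocks_failed, 0L)
})

test_that("hist diffs are zero for all blocks whenever RMSE is zero", {
  dir <- make_phantom_dir(tiny_spec(seed = 12, noise_sigma = 20))
  m <- seal_series(dir, "pw", kdf_iterations = 500L)
  rep <- verify_series(dir, m, "pw")
  expect_identical(rep$rmse, 0)
  expect_true(all(rep$per_block$passed))
})

test_that("verification failures are FAIL reports with reasons, never errors", {
  dir <- make_phantom_dir(tiny_spec(seed = 13))
  m <- seal_series(dir, "pw", kdf_iterations = 500L)

  r1 <- verify_series(dir, m, "not-the-passphrase")
  expect_equal(r1$verdict, "FAIL")
  expect_match(r1$reason, "wrong passphrase|corrupted")

  r2 <- verify_series(tempfile("nowhere-"), m, "pw")
  expect_equal(r2$verdict, "FAIL")
  expect_match(r2$reason, "no such directory")

  mbad <- m
  mbad$entries <- mbad$entries[-1]
  r3 <- verify_series(dir, mbad, "pw")
  expect_equal(r3$verdict, "FAIL")
  expect_match(r3$reason, "malformed manifest")

  badpath <- tempfile(fileext = ".json")
  writeLines("{}", badpath)
  r4 <- verify_series(dir, badpath, "pw")
  expect_equal(r4$verdict, "FAIL")
  expect_match(r4$reason, "manifest")

  # a shorter series than sealed: DRR shape mismatch is reported, not thrown
  spec2 <- tiny_spec(seed = 13, n_slices = 10L)
  dir2 <- make_phantom_dir(spec2)
  r5 <- verify_series(dir2, m, "pw")
  expect_equal(r5$verdict, "FAIL")
  expect_match(r5$reason, "shape")
})

test_that("single-slice tampers along the projection axis are always caught", {
  spec <- tiny_spec(seed = 14)
  dir <- make_phantom_dir(spec)
  m <- seal_series(dir, "pw", kdf_iterations = 500L)
  sorted <- sort_slices(read_series(dir))

  for (seed in 1:4) {
    idx <- withr::with_seed(seed, sample(3:9, 1))
    amp <- withr::with_seed(seed + 5, sample(c(10L, 25L, 40L), 1))
    ops <- list(
      tamper_op("insert", idx, source = "duplicate"),
      tamper_op("delete", idx),
      tamper_op("modify", idx, amplitude = amp, n_pixels = "all",
                seed = seed, all_positive = TRUE)
    )
    for (op in ops) {
      tampered <- apply_tamper(sorted, op)
      tdir <- tempfile("tampered-")
      write_series(tampered, tdir)
      rep <- verify_series(tdir, m, "pw")
      expect_equal(rep$verdict, "FAIL")
      expect_gt(rep$rmse, 0)
    }
  }
})
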