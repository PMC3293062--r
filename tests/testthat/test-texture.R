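# Co-occurrence ---------------------------------------------------------------

test_that("co-occurrence counts match hand enumeration on a 2x2 image", {
  img <- gray_image(matrix(c(0L, 0L, 1L, 1L), 2, 2), levels = 16)
  M <- compute_com(img, c(0, 1))
  expected <- matrix(0L, 16, 16)
  expected[1, 2] <- 2L; expected[2, 1] <- 2L   # two horizontal (0,1) pairs
  expect_equal(M$counts, expected)
  expect_equal(sum(M$normalized), 1, tolerance = 1e-12)
})

test_that("a constant image yields a single diagonal co-occurrence entry", {
  img <- gray_image(matrix(5L, 8, 8), levels = 16)
  M <- compute_com(img, c(1, 1))
  expect_equal(sum(M$counts > 0), 1)
  expect_gt(M$counts[6, 6], 0)
  f <- com_features(M)
  expect_equal(unname(f["asm"]), 1)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["correlation"]), 0)     # zero-variance convention
})

test_that("co-occurrence matrices are symmetric for random images", {
  for (seed in 1:4) {
    img <- rand_gray(16, 16, 8, seed)
    for (off in list(c(0, 1), c(-1, 1), c(1, 0), c(2, -3))) {
      M <- compute_com(img, off)
      expect_identical(M$counts, t(M$counts))
    }
  }
})

test_that("checkerboard contrast equals (L-1)^2", {
  for (L in c(16, 64)) {
    f <- com_features(compute_com(checkerboard(8, L), c(0, 1)))
    expect_equal(unname(f["contrast"]), (L - 1)^2)
  }
})

test_that("invalid co-occurrence offsets are rejected", {
  img <- rand_gray(16, 16, 8, 1)
  expect_error(compute_com(img, c(0, 0)), "not a valid displacement")
  expect_error(compute_com(img, c(0, 16)), "larger than the image")
  expect_error(com_features(structure(list(counts = matrix(0, 4, 4),
                                           normalized = matrix(0, 4, 4),
                                           levels = 4L),
                                      class = "cooccurrence_matrix")),
               "no counted pairs")
})

test_that("co-occurrence features match the brute-force oracle", {
  for (seed in 1:10) {
    img <- rand_gray(16, 16, 8, seed)
    for (off in list(c(0, 1), c(-1, 1), c(1, 0), c(1, 1), c(0, 3))) {
      M <- compute_com(img, off)
      expect_equal(com_features(M),
                   oracle_com_features(oracle_com_counts(img$pixels, 8,
                                                         off[1], off[2])),
                   tolerance = 1e-10)
    }
  }
})

test_that("co-occurrence features respect their analytic bounds", {
  for (seed in 1:8) {
    img <- rand_gray(12, 12, 8, seed + 100)
    f <- com_features(compute_com(img, c(0, 1)))
    expect_gt(f[["asm"]], 0); expect_lte(f[["asm"]], 1)
    expect_gte(f[["entropy"]], 0)
    expect_lte(f[["entropy"]], 2 * log2(8))
    expect_gte(f[["contrast"]], 0)
    expect_gte(f[["correlation"]], -1); expect_lte(f[["correlation"]], 1)
    expect_gt(f[["idm"]], 0); expect_lte(f[["idm"]], 1)
  }
})

# Run length ------------------------------------------------------------------

test_that("run-length counts match a hand-scanned row", {
  img <- gray_image(matrix(c(1L, 1L, 2L, 2L, 2L, 3L), nrow = 1), levels = 16)
  R <- compute_rlm(img, 0)
  expect_equal(R$counts[2, 2], 1)   # level 1, run of 2
  expect_equal(R$counts[3, 3], 1)   # level 2, run of 3
  expect_equal(R$counts[4, 1], 1)   # level 3, single pixel
  expect_equal(sum(R$counts), 3)
})

test_that("a constant NxN image has one maximal run of length N per row", {
  n <- 7
  img <- gray_image(matrix(3L, n, n), levels = 16)
  R <- compute_rlm(img, 0)
  expect_equal(R$counts[4, n], n)
  expect_equal(sum(R$counts), n)
  f <- rlm_features(R)
  expect_equal(unname(f["lre"]), n^2)
})

test_that("every pixel belongs to exactly one maximal run in each direction", {
  for (seed in 1:5) {
    img <- rand_gray(11, 14, 4, seed + 30)     # few levels => long runs
    for (dir in c(0, 45, 90, 135)) {
      R <- compute_rlm(img, dir)
      r <- seq_len(ncol(R$counts))
      expect_equal(sum(colSums(R$counts) * r), 11 * 14)
    }
  }
})

test_that("short-run emphasis attains 1 when all runs have length one", {
  f <- rlm_features(compute_rlm(checkerboard(8, 16), 0))
  expect_equal(unname(f["sre"]), 1)
  expect_equal(unname(f["rp"]), 1)             # one run per pixel
})

test_that("run-length features match the brute-force oracle", {
  for (seed in 1:6) {
    img <- rand_gray(13, 9, 4, seed + 50)
    for (dir in c(0, 45, 90, 135)) {
      R <- compute_rlm(img, dir)
      oc <- oracle_rlm_counts(img$pixels, 4, dir)
      expect_equal(unname(R$counts[, seq_len(ncol(oc))]), unname(oc))
      expect_equal(rlm_features(R), oracle_rlm_features(oc, 13 * 9),
                   tolerance = 1e-10)
    }
  }
})

test_that("run fraction lies in (0, 1] for random images", {
  for (seed in 1:5) {
    f <- rlm_features(compute_rlm(rand_gray(10, 10, 8, seed + 70), 90))
    expect_gt(f[["rp"]], 0); expect_lte(f[["rp"]], 1)
  }
})

# Gradient --------------------------------------------------------------------

test_that("gradient map of a constant image is zero everywhere", {
  img <- gray_image(matrix(9L, 10, 10), levels = 256)
  G <- compute_grm(img)
  expect_true(all(G$magnitudes == 0))
  f <- grm_features(G)
  expect_equal(unname(f["mean"]), 0)
  expect_equal(unname(f["nonzero_pct"]), 0)
  expect_equal(unname(f["skewness"]), 0)       # zero-variance convention
  expect_equal(unname(f["kurtosis"]), 0)
})

test_that("a horizontal ramp has uniform central-difference magnitude 2", {
  img <- gray_image(matrix(rep(0:19, each = 10), nrow = 10), levels = 256)
  G <- compute_grm(img)
  expect_true(all(G$magnitudes == 2))
  f <- grm_features(G)
  expect_equal(unname(f["variance"]), 0)
  expect_equal(unname(f["skewness"]), 0)
})

test_that("transposing the image transposes the gradient map", {
  img <- rand_gray(9, 12, 256, 77)
  timg <- gray_image(t(img$pixels), levels = 256)
  expect_equal(t(compute_grm(img)$magnitudes), compute_grm(timg)$magnitudes)
})

test_that("gradient summary features match hand arithmetic on a mixed map", {
  G <- structure(list(magnitudes = matrix(c(0, 0, 2, 2), 2)),
                 class = "gradient_map")
  f <- grm_features(G)
  expect_equal(unname(f["mean"]), 1)
  expect_equal(unname(f["nonzero_pct"]), 50)
})

test_that("gradient features match the brute-force oracle", {
  for (seed in 1:5) {
    img <- rand_gray(10, 10, 256, seed + 90)
    expect_equal(grm_features(compute_grm(img)),
                 oracle_grm_features(img$pixels), tolerance = 1e-10)
  }
})

test_that("images below 3x3 are rejected for gradients", {
  expect_error(compute_grm(gray_image(matrix(0L, 2, 5), levels = 16)),
               "3 x 3")
})

# Batch extraction ------------------------------------------------------------

test_that("default extraction yields 65 named features per image", {
  img <- rand_gray(32, 32, 256, 1)
  tab <- extract_features(list(img))
  fn <- feature_names(tab)
  expect_length(fn, 65)
  expect_length(grep("^com_d[1-5]_", fn), 55)
  expect_length(grep("^rlm_", fn), 5)
  expect_length(grep("^grm_", fn), 5)
  expect_true(all(is.finite(as.numeric(tab[1, fn]))))
})

test_that("identical images give identical feature rows", {
  img <- rand_gray(32, 32, 256, 2)
  tab <- extract_features(list(img, img))
  expect_equal(unname(as.numeric(tab[1, feature_names(tab)])),
               unname(as.numeric(tab[2, feature_names(tab)])))
})

test_that("features are invariant to a constant intensity shift", {
  img <- rand_gray(24, 24, 64, 3)               # values 0..63
  shifted <- gray_image(img$pixels + 100L, levels = 256)
  img256 <- gray_image(img$pixels, levels = 256)
  t1 <- extract_features(list(img256), distances = 1:2)
  t2 <- extract_features(list(shifted), distances = 1:2)
  expect_equal(as.numeric(t1[1, feature_names(t1)]),
               as.numeric(t2[1, feature_names(t2)]), tolerance = 1e-12)
})

test_that("an empty image list is rejected", {
  expect_error(extract_features(list()), "non-empty")
})
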