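test_that("quantization bins per-image min-max range uniformly", {
  expect_true(all(quantize(matrix(42L, 5, 5), 64) == 0L))
  q <- quantize(matrix(c(0L, 255L), 1), 64)
  expect_equal(as.vector(q), c(0L, 63L))
  # linear ramp 0..255 over 256 pixels: exactly 4 pixels per level
  ramp <- matrix(0:255, 1)
  expect_true(all(tabulate(quantize(ramp, 64) + 1, 64) == 4))
})

test_that("the GLCM matches hand-enumerated pair counts", {
  q <- rbind(c(0L, 0L, 1L), c(0L, 1L, 1L), c(0L, 1L, 1L))
  g <- glcm(q, levels = 2, angle = 0)
  expect_equal(unclass(g) * 12,
               matrix(c(2, 3, 3, 4), 2, 2), ignore_attr = TRUE)
  expect_equal(sum(g), 1)

  # constant image concentrates all mass at (0, 0)
  g0 <- glcm(matrix(0L, 4, 4), levels = 3, angle = 45)
  expect_equal(g0[1, 1], 1)
  expect_equal(sum(g0), 1)

  # symmetrization is exact for every angle
  qr <- withr::with_seed(4, matrix(sample(0:5, 60, TRUE), 6))
  for (a in c(0, 45, 90, 135)) {
    g <- glcm(qr, levels = 6, angle = a)
    expect_identical(unclass(g), t(unclass(g)))
  }

  # no pairs available -> error
  expect_error(glcm(matrix(0L, 1, 1), levels = 2, angle = 0), "no pixel pairs")
  expect_error(glcm(matrix(0L, 1, 3), levels = 2, angle = 90), "no pixel pairs")
})

test_that("descriptors match hand computations and degenerate conventions", {
  # single-mass matrix (constant image)
  d0 <- glcm_descriptors(glcm(matrix(0L, 4, 4), levels = 3, angle = 0))
  expect_equal(unname(d0), c(0, 1, 1, 1, 0))

  q <- rbind(c(0L, 0L, 1L), c(0L, 1L, 1L), c(0L, 1L, 1L))
  d <- glcm_descriptors(glcm(q, levels = 2, angle = 0))
  expect_equal(d[["contrast"]], 6 / 12)
  expect_equal(d[["homogeneity"]], 0.75)
  expect_equal(d[["asm"]], (4 + 9 + 9 + 16) / 144)
  p <- c(2, 3, 3, 4) / 12
  expect_equal(d[["entropy"]], -sum(p * log2(p)))
  expect_equal(d[["correlation"]],
               oracle_descriptors(oracle_glcm(q, 2, 0))[["correlation"]])

  # entropy never exceeds log2 of the occupied cells
  qr <- withr::with_seed(8, matrix(sample(0:7, 100, TRUE), 10))
  g <- glcm(qr, levels = 8, angle = 135)
  expect_lte(glcm_descriptors(g)[["entropy"]], log2(sum(g > 0)))
})

test_that("feature vectors follow the canonical layout and symmetries", {
  nm <- feature_names()
  expect_length(nm, 25)
  expect_equal(nm[1:5], c("Contrast0", "Contrast45", "Contrast90",
                          "Contrast135", "Contrast"))

  # radially symmetric image is invariant under 90 degree rotation
  n <- 31
  d <- round(sqrt(outer((seq_len(n) - 16)^2, (seq_len(n) - 16)^2, `+`)))
  img <- new_image2d((d * 17) %% 256, 8)
  f <- extract_features(img, glcm_config(levels = 16))
  expect_equal(f$Contrast0, f$Contrast90, tolerance = 1e-9)
  expect_equal(f$Contrast45, f$Contrast135, tolerance = 1e-9)

  # the average slot is exactly the mean of its four angle slots
  rimg <- withr::with_seed(2, new_image2d(matrix(sample(0:255, 144, TRUE), 12), 8))
  fv <- extract_features(rimg)
  for (dsc in c("Contrast", "Correlation", "ASM", "Homogeneity", "Entropy")) {
    expect_equal(fv[[dsc]],
                 mean(unlist(fv[paste0(dsc, c("0", "45", "90", "135"))])))
  }
})

test_that("features equal the brute-force oracle on random small images", {
  for (s in 1:30) {
    img <- withr::with_seed(100 + s, {
      h <- sample(4:16, 1); w <- sample(4:16, 1)
      matrix(sample(0:255, h * w, TRUE), h)
    })
    lv <- withr::with_seed(200 + s, sample(2:8, 1))
    got <- unlist(extract_features(new_image2d(img, 8), glcm_config(levels = lv)))
    want <- oracle_features(img, lv)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("features are shift-invariant when the min-max range is preserved", {
  img <- withr::with_seed(6, matrix(sample(0:200, 100, TRUE), 10))
  f1 <- extract_features(new_image2d(img, 8), glcm_config(levels = 8))
  f2 <- extract_features(new_image2d(img + 50L, 8), glcm_config(levels = 8))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("z-score standardization is leakage-safe and handles degenerate columns", {
  tbl <- planted_feature_table(3, n_per = 6)
  std <- zscore_fit(tbl)
  out <- zscore_apply(std, tbl)
  x <- as.matrix(out[feature_names()])
  expect_true(all(abs(colMeans(x)) < 1e-9))
  expect_true(all(abs(apply(x, 2, sd) - 1) < 1e-9))

  # constant column maps to zero without a division error
  tbl2 <- tbl
  tbl2$ASM <- 5
  out2 <- zscore_apply(zscore_fit(tbl2), tbl2)
  expect_true(all(out2$ASM == 0))

  # a test row equal to the training means maps to the origin
  mean_row <- tbl[1, ]
  mean_row[feature_names()] <- as.list(colMeans(as.matrix(tbl[feature_names()])))
  out3 <- zscore_apply(std, mean_row)
  expect_true(all(abs(unlist(out3[feature_names()])) < 1e-9))

  # column mismatch is a schema error
  expect_error(zscore_apply(std, tbl[setdiff(names(tbl), "Entropy45")]),
               "Entropy45")
})
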