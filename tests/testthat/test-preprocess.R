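test_that("centered crop uses floor((src - target)/2) offsets", {
  # panoramic-sized frame: offsets must be (537, 312)
  W <- 2775L; H <- 1504L
  img <- new_image2d(outer(seq_len(H), seq_len(W), function(r, cc) (r * 7 + cc * 13) %% 256))
  out <- crop_center(img, c(1700, 880))
  expect_equal(dim(out), c(880, 1700))
  expect_equal(out[1, 1], img[312 + 1, 537 + 1])
  expect_equal(out[880, 1700], img[312 + 880, 537 + 1700])

  small <- new_image2d(matrix(0:24, 5), 8)
  expect_identical(crop_center(small, c(5, 5)), small)     # identity
  expect_equal(dim(crop_center(small, c(1, 1))), c(1, 1))  # minimal crop
  expect_error(crop_center(small, c(6, 5)), "exceeds")
})

test_that("histogram equalization follows the textbook CDF map", {
  # constant image passes through
  cst <- new_image2d(matrix(77L, 10, 10), 8)
  expect_identical(hist_equalize(cst), cst)

  # two-valued image {10: 25%, 200: 75%} maps onto the full 8-bit range
  img <- new_image2d(matrix(c(rep(10L, 25), rep(200L, 75)), 10), 8)
  he <- hist_equalize(img)
  expect_setequal(unique(as.vector(he)), c(0L, 255L))
  expect_true(all((he == 255) == (img == 200)))   # order preserved
  expect_equal(max(he), 255L)
})

test_that("equalization flattens the CDF and is idempotent up to one gray level", {
  sk <- withr::with_seed(9, new_image2d(
    matrix(pmin(255, round(255 * rbeta(96 * 96, 2, 8))), 96), 8))
  ks <- function(m) {
    e <- ecdf(as.vector(m))
    max(abs(e(0:255) - (0:255 + 1) / 256))
  }
  he <- hist_equalize(sk)
  expect_lte(ks(he), ks(sk))
  expect_lte(max(abs(hist_equalize(he) - he)), 1)
  # monotone mapping preserves pixel rank order
  v0 <- as.vector(unclass(sk)); v1 <- as.vector(unclass(he))
  ord <- order(v0)
  expect_true(all(diff(v1[ord]) >= 0))
})

test_that("CLAHE reduces to global HE for one tile with unbounded clip", {
  img <- withr::with_seed(1, new_image2d(matrix(sample(0:255, 40 * 50, TRUE), 40), 8))
  expect_lte(max(abs(clahe(img, Inf, c(1, 1)) - hist_equalize(img))), 1)
  # constant image stays constant
  cst <- new_image2d(matrix(9L, 16, 16), 8)
  expect_equal(length(unique(as.vector(clahe(cst, 2, c(2, 2))))), 1)
  expect_error(clahe(new_image2d(matrix(0L, 4, 4), 8), 2, c(8, 8)), "smaller")
})

test_that("CLAHE raises local contrast on a low-contrast phantom", {
  img <- withr::with_seed(42, {
    f <- matrix(rnorm(96 * 96), 96)
    f <- (f - min(f)) / diff(range(f))
    new_image2d(round(100 + 40 * f), 8)
  })
  out <- clahe(img, 2, c(8, 8))
  patch_sd <- function(m) {
    mean(sapply(seq(1, 81, 16), function(r)
      sapply(seq(1, 81, 16), function(cc) sd(m[r:(r + 15), cc:(cc + 15)]))))
  }
  expect_gt(patch_sd(unclass(out)), patch_sd(unclass(img)))
})

test_that("the enhancement chain composes crop, HE and CLAHE in order", {
  img <- withr::with_seed(3, new_image2d(matrix(sample(0:255, 100 * 120, TRUE), 100), 8))
  cfg <- enhance_config(crop_to = c(96, 80), clahe_clip = 2, clahe_grid = c(4, 4))
  expect_identical(enhance(img, cfg),
                   clahe(hist_equalize(crop_center(img, c(96, 80))), 2, c(4, 4)))
  # flags off -> crop only
  cfg0 <- enhance_config(crop_to = c(96, 80), apply_he = FALSE, apply_clahe = FALSE)
  expect_identical(enhance(img, cfg0), crop_center(img, c(96, 80)))
  # deterministic
  expect_identical(enhance(img, cfg), enhance(img, cfg))
  # small sources skip the crop stage
  smallimg <- new_image2d(matrix(0:63, 8), 8)
  expect_equal(dim(enhance(smallimg, enhance_config(apply_clahe = FALSE))), c(8, 8))
})

test_that("enhancement preserves shape, depth and intensity range", {
  for (s in 1:3) {
    img <- withr::with_seed(s, new_image2d(matrix(sample(0:255, 64 * 72, TRUE), 64), 8))
    for (f in list(hist_equalize, function(x) clahe(x, 2, c(4, 4)))) {
      out <- f(img)
      expect_equal(dim(out), dim(img))
      expect_equal(attr(out, "depth"), 8L)
      expect_true(all(out >= 0 & out <= 255))
    }
  }
})
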