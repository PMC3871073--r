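test_that("finger extent reads the first and last foreground rows", {
  mask <- matrix(0, 120, 160)
  mask[20:100, ] <- 1
  ext <- finger_extent_at_column(mask, 150)
  expect_equal(c(ext$y1, ext$y2), c(20, 100))
  full <- matrix(1, 10, 12)
  extf <- finger_extent_at_column(full, 5)
  expect_equal(c(extf$y1, extf$y2), c(1, 10))
  expect_error(finger_extent_at_column(matrix(0, 5, 5), 3), "all-background")
})

test_that("empty anchor column falls back to the nearest nonempty one", {
  mask <- matrix(0, 60, 160)
  mask[10:40, 1:148] <- 1
  expect_warning(ext <- finger_extent_at_column(mask, 150), "nearest")
  expect_equal(ext$col_used, 148)
  expect_equal(c(ext$y1, ext$y2), c(10, 40))
})

test_that("block projection is the column sum of the block", {
  img <- matrix(1, 10, 100)
  p <- block_projection(img, 3, 4, c(21, 23))
  expect_equal(p$values, c(2, 2, 2))
  img2 <- img; img2[, 22] <- 2
  p2 <- block_projection(img2, 3, 4, c(21, 23))
  expect_equal(p2$values, c(2, 4, 2))
  expect_equal(sum(p2$values), sum(img2[3:4, 21:23]))
  expect_error(block_projection(img, 5, 5, c(21, 23)), "y1 < y2")
})

test_that("block projection matches the double-loop oracle", {
  set.seed(17)
  for (rep in 1:20) {
    img <- as_gray_image(matrix(runif(120 * 160, 0, 255), 120, 160))
    y1 <- sample(1:50, 1); y2 <- y1 + sample(10:60, 1)
    p <- block_projection(img, y1, y2, c(21, 80))
    expect_equal(p$values, unname(brute_projection(img, y1, y2, 21, 80)))
  }
})

test_that("reference column maps the block argmax into frame coordinates", {
  v <- rep(1, 60); v[7] <- 9
  p <- structure(list(values = v, origin = c(row = 10, col = 21),
                      m1 = 5, n1 = 60), class = "projection_profile")
  rc <- reference_column(p)
  expect_equal(rc$c, 7)
  expect_equal(rc$ref, 27)  # c + 20 for the default block start
  p$values <- rep(3, 60)    # tie -> smallest index
  expect_equal(reference_column(p)$ref, 21)
})

test_that("ROI crop applies the printed corner formulas and is 95 wide", {
  img <- as_gray_image(matrix(runif(120 * 160, 0, 255), 120, 160))
  roi <- crop_roi(img, ref = 60, y1 = 20, y2 = 100)
  expect_equal(dim(roi), c(77L, 95L))
  expect_equal(roi, as_gray_image(img[22:98, 45:139]))
  expect_error(crop_roi(img, 60, 50, 53), "degenerate")
})

test_that("out-of-frame rectangles are clamped with a warning", {
  img <- as_gray_image(matrix(0, 120, 160))
  expect_warning(roi <- crop_roi(img, ref = 10, y1 = 20, y2 = 100), "clamped")
  expect_equal(ncol(roi), 10 + 80 - 1)  # columns 1..89
})

test_that("normalization always yields the fixed ROI geometry", {
  roi <- as_gray_image(matrix(runif(77 * 95, 0, 255), 77, 95))
  out <- normalize_roi(roi)
  expect_equal(dim(out), c(60L, 128L))
  same <- as_gray_image(matrix(runif(60 * 128, 0, 255), 60, 128))
  expect_identical(normalize_roi(same), same)
  const <- normalize_roi(as_gray_image(matrix(80, 30, 40)))
  expect_true(all(abs(const - 80) < 1e-9))
})

test_that("knuckle column is recovered within one column on synthetics", {
  for (sd in 1:5) {
    s <- generate_finger_image(synthetic_params(seed = 60 + sd,
                                                knuckle_col = 35 + 5 * sd))
    r <- run_pipeline(s$image)
    expect_lte(abs(r$meta$ref - s$truth_knuckle_col), 1)
  }
})

test_that("translating the finger shifts the reference column equally", {
  base <- generate_finger_image(synthetic_params(seed = 77))
  r0 <- run_pipeline(base$image)
  for (dc in c(-5, 5)) {
    s <- generate_finger_image(synthetic_params(seed = 77,
                                                translation = c(0, dc)))
    r <- run_pipeline(s$image)
    expect_equal(r$meta$ref - r0$meta$ref, dc)
  }
})
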