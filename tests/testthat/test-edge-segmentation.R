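test_that("the 3x3 operator is the Prewitt horizontal kernel and pairs mirror", {
  k <- build_edge_kernels(3, 3)
  expect_equal(k$upper, matrix(rep(c(-1, 0, 1), 3), 3, 3))
  expect_equal(k$lower, k$upper[3:1, ])
  for (dims in list(c(3, 11), c(5, 7))) {
    kk <- build_edge_kernels(dims[1], dims[2])
    expect_equal(sum(kk$upper), 0)
    expect_equal(sum(kk$lower), 0)
    expect_equal(kk$lower, kk$upper[dims[1]:1, ])
  }
  expect_error(build_edge_kernels(4, 3), "odd")
  expect_error(build_edge_kernels(1, 3), "odd")
})

test_that("upper-kernel response peaks at a dark-to-bright transition row", {
  k <- build_edge_kernels(3, 11)
  img <- rbind(matrix(0, 19, 40), matrix(200, 21, 40))  # transition at row 19/20
  resp <- veinroi:::correlate2d(img, k$upper)
  peaks <- apply(resp, 2, which.max)
  expect_true(all(peaks %in% c(19, 20)))
})

test_that("filter_halves normalizes each half to [0,255] and is scale invariant", {
  s <- clean_sample(seed = 11)
  f <- filter_halves(s$image, build_edge_kernels())
  m <- nrow(f)
  expect_equal(range(f[1:(m / 2), ]), c(0, 255))
  expect_equal(range(f[(m / 2 + 1):m, ]), c(0, 255))
  half_bright <- as_gray_image(pmin(s$image * 2, 255) / 2)  # exact doubling-safe copy
  expect_equal(filter_halves(as_gray_image(half_bright * 2), build_edge_kernels()),
               filter_halves(half_bright, build_edge_kernels()))
  expect_error(filter_halves(matrix(9, 20, 20), build_edge_kernels()),
               "constant")
})

test_that("filtered synthetic band shows contour ridges near the true edges", {
  s <- clean_sample(seed = 2)
  cb <- coarse_binarize(s$image)
  expect_lt(max(abs(cb$trace$up - round(s$truth_up))), 2)
  expect_lt(max(abs(cb$trace$low - round(s$truth_low))), 2)
})

test_that("trace_edges matches the brute-force argmax oracle on random inputs", {
  set.seed(42)
  for (rep in 1:25) {
    f <- matrix(runif(40 * 30, 0, 255), 40, 30)
    f[cbind(sample(40, 5, TRUE), sample(30, 5, TRUE))] <- 255  # force some ties
    f <- as_gray_image(f)
    tr <- trace_edges(f)
    or <- brute_trace(f)
    expect_identical(tr$up, or$up)
    expect_identical(tr$low, or$low)
  }
})

test_that("argmax ties break toward the horizontal center line", {
  f <- as_gray_image(matrix(100, 12, 4))
  tr <- trace_edges(f)
  expect_true(all(tr$up == 6))   # m/2
  expect_true(all(tr$low == 7))  # first row of the lower half
})

test_that("edges_to_mask fills one contiguous run per column", {
  tr <- structure(list(up = 2L, low = 4L, n = 1L, m = 6L), class = "edge_trace")
  expect_equal(edges_to_mask(tr, 6, 1)[, 1], c(0, 1, 1, 1, 0, 0))
  tr2 <- structure(list(up = rep(1L, 5), low = rep(8L, 5), n = 5L, m = 8L),
                   class = "edge_trace")
  expect_true(all(edges_to_mask(tr2, 8, 5) == 1))
  tr3 <- structure(list(up = 5L, low = 3L, n = 1L, m = 6L), class = "edge_trace")
  expect_error(edges_to_mask(tr3, 6, 1), "inconsistent")
})

test_that("per-column foreground count equals low - up + 1", {
  s <- clean_sample(seed = 9, tilt = 3)
  cb <- coarse_binarize(s$image)
  expect_equal(colSums(cb$mask), as.numeric(cb$trace$low - cb$trace$up + 1))
  runs <- apply(cb$mask, 2, function(col) sum(diff(col) != 0))
  expect_true(all(runs <= 2))  # single contiguous run per column
})

test_that("complemented image with swapped kernels reproduces the segmentation", {
  s <- clean_sample(seed = 14, tilt = -2)
  k <- build_edge_kernels()
  swapped <- structure(list(upper = k$lower, lower = k$upper, h = k$h, w = k$w),
                       class = "edge_kernels")
  a <- coarse_binarize(s$image, k)
  b <- coarse_binarize(as_gray_image(255 - s$image), swapped)
  expect_identical(a$trace$up, b$trace$up)
  expect_identical(a$trace$low, b$trace$low)
  expect_equal(a$mask, b$mask)
})
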