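make_trace <- function(up, low, m = 120L) {
  structure(list(up = as.integer(up), low = as.integer(low),
                 n = length(up), m = m), class = "edge_trace")
}

test_that("edge variances use sample variance on equal split halves", {
  tr <- make_trace(rep(10, 8), c(rep(5, 4), 10, 20, 30, 40) + 60)
  v <- edge_variances(tr)
  expect_equal(v$var_up_I, 0)
  expect_equal(v$var_up_II, 0)
  expect_equal(v$var_low_I, 0)
  expect_equal(v$var_low_II, 500 / 3)  # var of {70, 80, 90, 100}
  expect_error(edge_variances(make_trace(1:3, 4:6)), "at least 4")
})

test_that("variances agree with a brute-force two-pass oracle, odd and even n", {
  set.seed(7)
  for (n in c(9, 10, 160)) {
    up <- sample(1:60, n, TRUE); low <- sample(61:120, n, TRUE)
    v <- edge_variances(make_trace(up, low))
    first <- seq_len(ceiling(n / 2)); second <- (ceiling(n / 2) + 1):n
    expect_equal(v$var_up_I, brute_var(up[first]))
    expect_equal(v$var_up_II, brute_var(up[second]))
    expect_equal(v$var_low_I, brute_var(low[first]))
    expect_equal(v$var_low_II, brute_var(low[second]))
  }
})

test_that("case classification follows the threshold rule with upper precedence", {
  rep0 <- function(a, b, c, d) structure(list(var_up_I = a, var_up_II = b,
    var_low_I = c, var_low_II = d), class = "variance_report")
  expect_equal(classify_case(rep0(0, 0, 0, 0), 38), "normal")
  expect_equal(classify_case(rep0(50, 0, 0, 0), 38), "broken_upper")
  expect_equal(classify_case(rep0(0, 39, 0, 0), 38), "broken_upper")
  expect_equal(classify_case(rep0(0, 0, 0, 120), 38), "broken_lower")
  expect_equal(classify_case(rep0(50, 0, 0, 120), 38), "broken_upper")
  expect_equal(classify_case(rep0(38, 38, 38, 38), 38), "normal")  # strict >
})

test_that("padding preserves dimensions and repairs a truncated top", {
  s <- generate_finger_image(synthetic_params(seed = 21, artifact = "truncated_top"))
  out <- pad_and_rebinarize(s$image, "broken_upper", t = 3)
  expect_equal(dim(out$mask), dim(s$image))
  expect_equal(out$trace$n, ncol(s$image))
  truncated_cols <- which(s$truth_up <= 1)
  expect_gt(length(truncated_cols), 5)
  expect_true(all(out$trace$up[truncated_cols] <= 2))
  expect_error(pad_and_rebinarize(s$image, "normal"), "broken_upper or broken_lower")
})

test_that("midpoints are the exact contour means, kept fractional", {
  tr <- make_trace(c(10, 10), c(30, 31), m = 40L)
  mids <- compute_midpoints(tr)
  expect_equal(mids$y, c(20, 20.5))
  expect_equal(mids$p, 0L)
  s <- clean_sample(seed = 3)
  cb <- coarse_binarize(s$image)
  mids <- compute_midpoints(cb$trace)
  expect_equal(mids$y, (cb$trace$up + cb$trace$low) / 2)
})

test_that("single-linkage pruning flags isolated outliers and keeps chains", {
  mids <- midpoint_set(1:4, rep(50, 4))
  expect_equal(cluster_midpoints(mids, 5)$p, 0L)
  mids <- midpoint_set(1:4, c(50, 50, 50, 10))
  out <- cluster_midpoints(mids, 5)
  expect_equal(out$p, 1L)
  expect_equal(which(out$wrong), 4L)
})

test_that("clustering matches the exhaustive-merge oracle on small point sets", {
  set.seed(99)
  for (rep in 1:30) {
    np <- sample(4:12, 1)
    pts <- cbind(runif(np, 0, 30), runif(np, 0, 30))
    cut <- runif(1, 2, 10)
    mids <- midpoint_set(pts[, 1], pts[, 2])
    ours <- cluster_midpoints(mids, cut)
    hc_labels <- integer(np)
    keep <- !ours$wrong
    oracle <- brute_single_linkage(pts, cut)
    # same partition up to relabeling
    hc <- stats::cutree(stats::hclust(dist(pts), method = "single"), h = cut)
    expect_equal(comembership(hc), comembership(oracle))
    # the kept set is exactly the largest oracle cluster (when unique)
    sizes <- tabulate(oracle)
    if (sum(sizes == max(sizes)) == 1)
      expect_equal(which(keep), which(oracle == which.max(sizes)))
  }
})

test_that("false-background removal reconstructs by midpoint symmetry", {
  # horizontal finger, midline y = 60; broken upper contour in column 3
  tr <- make_trace(c(30, 30, 75, 30), c(90, 90, 90, 90))
  mask <- edges_to_mask(tr, 120, 4)
  mids <- midpoint_set(1:4, (tr$up + tr$low) / 2, c(FALSE, FALSE, TRUE, FALSE))
  fit <- fit_midline(mids)
  out <- remove_false_background(mask, tr, mids, fit)
  expect_equal(out$trace$up[3], 30)  # 2*60 - 90
  expect_equal(out$trace$low[3], 90)
  # repaired midpoint sits on the line
  expect_lt(abs((out$trace$up[3] + out$trace$low[3]) / 2 - 60), 0.5)
})

test_that("false-background removal is a no-op when nothing is flagged", {
  s <- clean_sample(seed = 6)
  cb <- coarse_binarize(s$image)
  mids <- compute_midpoints(cb$trace)
  fit <- fit_midline(mids)
  out <- remove_false_background(cb$mask, cb$trace, mids, fit)
  expect_identical(out$mask, cb$mask)
  expect_identical(out$trace, cb$trace)
})

test_that("everything-flagged input is an unrecoverable error", {
  tr <- make_trace(c(10, 10), c(30, 30), m = 40L)
  mids <- midpoint_set(1:2, c(20, 20), c(TRUE, TRUE))
  fit <- structure(list(k = 0, b = 20), class = "midline_fit")
  expect_error(remove_false_background(edges_to_mask(tr, 40, 2), tr, mids, fit),
               "unrecoverable")
})

test_that("the elaborate path is idempotent on a clean image", {
  s <- clean_sample(seed = 8, tilt = 2)
  r1 <- run_pipeline(s$image)
  expect_equal(r1$meta$case, "normal")
  # feeding the pipeline its own correct segmentation frame changes nothing
  cb <- coarse_binarize(s$image)
  v <- edge_variances(cb$trace)
  expect_equal(classify_case(v, 38), "normal")
  mids <- cluster_midpoints(compute_midpoints(cb$trace), 5)
  expect_equal(mids$p, 0L)
})
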