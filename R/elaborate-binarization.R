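#' Variances of the split contour traces
#'
#' Each contour trace is split into a left and a right half (the left half
#' takes the extra column when `n` is odd) and the sample variance (divisor
#' `n - 1`) of the row values in each half is computed. A broken contour --
#' the argmax landing on noise where the true finger edge left the frame or
#' was washed out -- shows up as a large variance in at least one half.
#'
#' @param trace an `edge_trace` with `n >= 4` columns.
#' @return list of class `variance_report` with `var_up_I`, `var_up_II`,
#'   `var_low_I`, `var_low_II`.
#' @export
edge_variances <- function(trace) {
  n <- trace$n
  if (n < 4) stop("need at least 4 columns for the variance test", call. = FALSE)
  first <- seq_len(ceiling(n / 2))
  second <- (ceiling(n / 2) + 1):n
  structure(list(
    var_up_I   = stats::var(trace$up[first]),
    var_up_II  = stats::var(trace$up[second]),
    var_low_I  = stats::var(trace$low[first]),
    var_low_II = stats::var(trace$low[second])
  ), class = "variance_report")
}

#' Classify a capture as normal or broken-contour
#'
#' The disappeared edge is in the upper part if either upper-half variance
#' exceeds `Thr`; otherwise in the lower part if either lower-half variance
#' exceeds `Thr`; otherwise the capture is normal. The upper test takes
#' precedence. The default `Thr = 38` (squared pixels on the 120 x 160
#' working scale) separates contour jitter from genuine breaks.
#'
#' @param report a `variance_report` from [edge_variances()].
#' @param Thr variance threshold.
#' @return one of `"broken_upper"`, `"broken_lower"`, `"normal"`.
#' @export
classify_case <- function(report, Thr = 38) {
  if (report$var_up_I > Thr || report$var_up_II > Thr) return("broken_upper")
  if (report$var_low_I > Thr || report$var_low_II > Thr) return("broken_lower")
  "normal"
}

# shared worker: pad, rebinarize, discard padded rows; pad_top/pad_bottom in rows
pad_rebinarize_impl <- function(img, pad_top, pad_bottom, kernels) {
  m <- nrow(img); n <- ncol(img)
  padded <- rbind(matrix(0, pad_top, n), img, matrix(0, pad_bottom, n))
  cb <- coarse_binarize(as_gray_image(padded), kernels)
  up <- pmin(pmax(cb$trace$up - pad_top, 1L), m)
  low <- pmin(pmax(cb$trace$low - pad_top, 1L), m)
  low <- pmax(low, up)
  trace <- structure(list(up = up, low = low, n = n, m = m), class = "edge_trace")
  list(mask = edges_to_mask(trace, m, n), trace = trace)
}

#' Boundary padding and re-binarization
#'
#' Repairs a broken contour caused by the finger leaving the frame: `t` zero
#' (background) rows are prepended (`broken_upper`) or appended
#' (`broken_lower`) so that the image boundary produces a clean dark-to-bright
#' transition, the coarse binarization is re-run on the `(m + t) x n` padded
#' image, and the padded rows are then discarded so the returned mask and
#' trace match the original frame. On truly truncated columns the recovered
#' contour sits on the image boundary (row 1 or row `m`). Breaks caused by
#' scattering or illumination rather than truncation are not fixed here and
#' fall through to midpoint clustering. `t = 3` keeps the extra filtering
#' cost negligible.
#'
#' @param img gray image matrix (working frame).
#' @param case `"broken_upper"` or `"broken_lower"`.
#' @param t number of padding rows.
#' @param kernels an `edge_kernels` pair.
#' @return list with `mask` and `trace`, shapes matching `img`.
#' @export
pad_and_rebinarize <- function(img, case, t = 3L,
                               kernels = build_edge_kernels()) {
  img <- as_gray_image(img)
  if (!case %in% c("broken_upper", "broken_lower"))
    stop("case must be broken_upper or broken_lower", call. = FALSE)
  if (t < 1) stop("t must be >= 1", call. = FALSE)
  if (case == "broken_upper") pad_rebinarize_impl(img, t, 0L, kernels)
  else pad_rebinarize_impl(img, 0L, t, kernels)
}

#' Midline points of the segmented finger
#'
#' One midpoint per column: `y_i = (up_i + low_i) / 2`, kept fractional. The
#' midpoints define the finger midline used for orientation estimation and
#' false-background repair.
#'
#' @param trace a consistent `edge_trace` (`up <= low` everywhere).
#' @return list of class `midpoint_set` with vectors `x`, `y`, logical
#'   `wrong`, and scalar `p` (count of flagged points, 0 at creation).
#' @export
compute_midpoints <- function(trace) {
  if (any(trace$up > trace$low))
    stop("inconsistent trace: up > low", call. = FALSE)
  structure(list(x = seq_len(trace$n),
                 y = (trace$up + trace$low) / 2,
                 wrong = rep(FALSE, trace$n),
                 p = 0L),
            class = "midpoint_set")
}

#' Flag erroneous midpoints by single-linkage clustering
#'
#' Midpoints of a correctly segmented finger form one smooth chain; residual
#' segmentation errors (scattering haze, uneven illumination) displace a run
#' of midpoints far from that chain. Agglomerative single-linkage clustering
#' on the `(x, y)` coordinates (Euclidean distance) is cut where the smallest
#' inter-cluster link distance exceeds `link_dist`; the largest cluster is
#' kept as correct and every other point is flagged wrong. Size ties are
#' broken by keeping the cluster whose `y` values have the smaller variance
#' (the flatter chain is the finger midline).
#'
#' The default cut of 7 px balances two failure modes: erroneous plateaus
#' (scattering, parasitic light) displace midpoints by at least ~9 px in `y`
#' and must stay separate, while a short run of hijacked columns inside an
#' otherwise correct chain opens an `x` gap of run length + 1 that must still
#' be bridged, or the correct points behind it would be flagged and
#' needlessly reconstructed.
#'
#' @param mids a `midpoint_set` with at least 2 points.
#' @param link_dist single-link cut distance in pixels (working scale).
#' @return the `midpoint_set` with `wrong` and `p` updated.
#' @export
cluster_midpoints <- function(mids, link_dist = 7) {
  np <- length(mids$x)
  if (np < 2) stop("need at least 2 midpoints to cluster", call. = FALSE)
  pts <- cbind(mids$x, mids$y)
  hc <- stats::hclust(stats::dist(pts), method = "single")
  labels <- stats::cutree(hc, h = link_dist)
  sizes <- tabulate(labels)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    yvar <- vapply(best, function(g) {
      yy <- mids$y[labels == g]
      if (length(yy) < 2) Inf else stats::var(yy)
    }, numeric(1))
    best <- best[which.min(yvar)]
  }
  mids$wrong <- labels != best[1]
  mids$p <- sum(mids$wrong)
  mids
}

#' Line-guided removal of false background
#'
#' For every column whose midpoint was flagged wrong, the corrected midpoint
#' is taken on the fitted midline, `y_c = k x + b`, and the broken contour row
#' is reconstructed by midpoint symmetry from the trusted opposite contour:
#' `up = round(2 y_c - low)` when the upper contour is broken, and the
#' mirrored formula for the lower contour (the midline is by definition
#' equidistant from both contours). Which contour is broken is decided per
#' column (`side = "auto"`) by comparing each contour against its prediction
#' from the fitted line and the median half-width of the correct columns, or
#' forced with `side`. Reconstructed rows are clamped to the frame and the
#' mask is refilled from the updated trace.
#'
#' A flagged column is only reconstructed when its midpoint actually lies
#' further than `tol` from the fitted line: cluster fragmentation (e.g. an
#' error plateau splitting the chain into left and right halves) can flag
#' whole runs of perfectly good columns, and points already on the midline
#' are accurate whatever their cluster membership. Rewriting them from an
#' extrapolated line would trade exact contours for the fit's extrapolation
#' error, doubled by the symmetry formula.
#'
#' @param mask binary mask (will be refilled).
#' @param trace the `edge_trace` behind `mask`.
#' @param mids a clustered `midpoint_set`; columns with `wrong = TRUE` are
#'   repaired. If `p = 0` the inputs are returned unchanged.
#' @param fit a `midline_fit` computed from the correct midpoints only.
#' @param side `"auto"`, `"upper"` or `"lower"`.
#' @param tol midline deviation (pixels) below which a flagged column is left
#'   untouched; half the single-linkage cut distance by default.
#' @return list with repaired `mask` and `trace`.
#' @export
remove_false_background <- function(mask, trace, mids, fit, side = "auto",
                                    tol = 3.5) {
  if (mids$p == 0L) return(list(mask = mask, trace = trace))
  if (all(mids$wrong))
    stop("unrecoverable segmentation: every midpoint flagged wrong", call. = FALSE)
  m <- trace$m
  up <- trace$up; low <- trace$low
  ok <- !mids$wrong
  half_width <- stats::median((low[ok] - up[ok]) / 2)
  for (j in which(mids$wrong)) {
    y_c <- fit$k * mids$x[j] + fit$b
    if (abs(mids$y[j] - y_c) <= tol) next
    broken <- side
    if (side == "auto") {
      dev_up <- abs(up[j] - (y_c - half_width))
      dev_low <- abs(low[j] - (y_c + half_width))
      broken <- if (dev_up >= dev_low) "upper" else "lower"
    }
    if (broken == "upper") up[j] <- round(2 * y_c - low[j])
    else low[j] <- round(2 * y_c - up[j])
    up[j] <- min(max(up[j], 1), m)
    low[j] <- min(max(low[j], up[j]), m)
  }
  trace <- structure(list(up = up, low = low, n = trace$n, m = m),
                     class = "edge_trace")
  list(mask = edges_to_mask(trace, m, trace$n), trace = trace)
}
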