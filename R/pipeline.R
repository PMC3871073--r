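#' Pipeline configuration
#'
#' All tunable parameters of the ROI localization pipeline, on the 120 x 160
#' working scale unless noted. Defaults are the standard operating point:
#' `Thr = 38` squared pixels for the broken-contour variance gate, `t = 3`
#' padding rows, a 5-pixel single-linkage cut distance, the 1-degree rotation
#' gate, anchor column 150 for the finger extent, knuckle search block over
#' columns 21..80, ROI columns `[ref - 15, ref + 80)` with 2-row vertical
#' insets, and 60 x 128 output. Half-size captures need a larger variance
#' threshold (e.g. `Thr = 150`), which is what per-database profiles are for.
#'
#' @param Thr variance threshold (squared pixels).
#' @param t padding rows for re-binarization.
#' @param link_dist single-linkage cut distance (pixels).
#' @param min_angle_deg rotation gate (degrees).
#' @param ref_col anchor column for the finger extent.
#' @param block_cols inclusive column range of the knuckle search block.
#' @param roi_col_offsets ROI column offsets relative to `ref` (right offset
#'   exclusive).
#' @param roi_row_insets insets applied to the finger extent rows.
#' @param roi_out ROI output shape (rows, cols).
#' @param work_size working frame (rows, cols) every input is resized to.
#' @param kernel_rows,kernel_cols edge-operator dimensions.
#' @param bright_background complement intensities before processing
#'   (bright-background capture polarity).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(Thr = 38, t = 3L, link_dist = 7,
                            min_angle_deg = 1, ref_col = 150L,
                            block_cols = c(21L, 80L),
                            roi_col_offsets = c(-15L, 80L),
                            roi_row_insets = c(2L, -2L),
                            roi_out = c(60L, 128L),
                            work_size = c(120L, 160L),
                            kernel_rows = 3L, kernel_cols = 11L,
                            bright_background = FALSE) {
  if (Thr <= 0 || t < 1 || link_dist <= 0)
    stop("Thr and link_dist must be positive, t >= 1", call. = FALSE)
  if (ref_col < 1 || ref_col > work_size[2])
    stop("ref_col outside the working frame", call. = FALSE)
  structure(list(Thr = Thr, t = as.integer(t), link_dist = link_dist,
                 min_angle_deg = min_angle_deg, ref_col = as.integer(ref_col),
                 block_cols = as.integer(block_cols),
                 roi_col_offsets = as.integer(roi_col_offsets),
                 roi_row_insets = as.integer(roi_row_insets),
                 roi_out = as.integer(roi_out),
                 work_size = as.integer(work_size),
                 kernel_rows = as.integer(kernel_rows),
                 kernel_cols = as.integer(kernel_cols),
                 bright_background = isTRUE(bright_background)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML profile
#'
#' Keys mirror the [pipeline_config()] arguments; unknown keys are an error,
#' missing keys keep their defaults. `overrides` (e.g. parsed CLI flags) take
#' precedence over file values.
#'
#' @param path YAML file, or `NULL` for defaults only.
#' @param overrides named list applied after the file.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    bad <- setdiff(names(vals), names(formals(pipeline_config)))
    if (length(bad))
      stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

# run one side of the variance-gated repair; returns possibly-updated seg
elaborate_pass <- function(img, seg, cfg, kernels, log) {
  rep0 <- edge_variances(seg$trace)
  case <- classify_case(rep0, cfg$Thr)
  if (case == "normal") return(list(seg = seg, case = "normal", log = log))
  log <- c(log, sprintf("variance gate fired: %s", case))
  seg <- pad_and_rebinarize(img, case, cfg$t, kernels)
  # sides are treated sequentially: after an upper repair, re-test the lower
  if (case == "broken_upper") {
    rep1 <- edge_variances(seg$trace)
    if (rep1$var_low_I > cfg$Thr || rep1$var_low_II > cfg$Thr) {
      log <- c(log, "lower gate fired after upper repair")
      both <- pad_rebinarize_impl(img, cfg$t, cfg$t, kernels)
      seg <- both
    }
  }
  list(seg = seg, case = case, log = log)
}

#' Run the full ROI localization pipeline on one image
#'
#' Orchestrates every stage: resize to the working frame (and polarity
#' complement if configured), coarse binarization, the variance-gated repair
#' path (boundary padding and re-binarization; midpoint clustering;
#' line-guided false-background removal), least-squares orientation
#' estimation with gated rotation, knuckle reference-line detection by block
#' vertical projection, ROI crop and geometry normalization.
#'
#' @param img gray image matrix of any size (native captures are resized).
#' @param config a `pipeline_config`.
#' @param keep_intermediates keep masks, traces, midpoints, fit and
#'   projection profile in the result (for inspection/debug rendering).
#' @return object of class `finger_roi`: `roi` (the normalized ROI image) and
#'   `meta` (case label, signed angle, whether rotation was applied,
#'   reference column, finger extent, crop rectangle, warnings, stage log).
#'   With `keep_intermediates = TRUE` also `mask`, `trace`, `midpoints`,
#'   `fit`, `profile`, `work_img`.
#' @export
run_pipeline <- function(img, config = pipeline_config(),
                         keep_intermediates = FALSE) {
  img <- as_gray_image(img)
  warns <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  log <- character(0)
  if (config$bright_background) img <- as_gray_image(255 - img)
  work <- resize_image(img, config$work_size[1], config$work_size[2])
  kernels <- build_edge_kernels(config$kernel_rows, config$kernel_cols)

  seg <- coarse_binarize(work, kernels)
  el <- elaborate_pass(work, seg, config, kernels, log)
  seg <- el$seg; case <- el$case; log <- el$log
  mids <- compute_midpoints(seg$trace)

  if (case != "normal") {
    mids <- cluster_midpoints(mids, config$link_dist)
    if (mids$p > 0L) {
      log <- c(log, sprintf("%d wrong midpoint(s) flagged", mids$p))
      fit0 <- fit_midline(mids)
      seg <- remove_false_background(seg$mask, seg$trace, mids, fit0,
                                     tol = config$link_dist / 2)
      mids <- compute_midpoints(seg$trace)
    }
  }

  fit <- fit_midline(mids)
  rot <- collect(rotate_if_needed(work, seg$mask, fit$theta_deg,
                                  config$min_angle_deg))
  log <- c(log, sprintf("theta = %+.3f deg (|theta| = %.3f), rotation %s",
                        fit$theta_deg, fit$theta_mag,
                        if (rot$applied) "applied" else "skipped"))

  segmented <- rot$img * rot$mask          # finger on black background
  ext <- collect(finger_extent_at_column(rot$mask, config$ref_col))
  prof <- block_projection(segmented, ext$y1, ext$y2, config$block_cols)
  refc <- reference_column(prof)
  roi <- collect(crop_roi(segmented, refc$ref, ext$y1, ext$y2,
                          config$roi_col_offsets, config$roi_row_insets))
  roi <- normalize_roi(roi, config$roi_out[1], config$roi_out[2])

  meta <- list(case = case, theta_deg = fit$theta_deg,
               applied_rotation = rot$applied,
               ref = refc$ref, y1 = ext$y1, y2 = ext$y2,
               rect = c(row_top = ext$y1 + config$roi_row_insets[1],
                        row_bottom = ext$y2 + config$roi_row_insets[2],
                        col_left = refc$ref + config$roi_col_offsets[1],
                        col_right_excl = refc$ref + config$roi_col_offsets[2]),
               warnings = warns, log = log)
  out <- list(roi = roi, meta = meta,
              mask = seg$mask)   # segmentation in the unrotated frame
  if (keep_intermediates) {
    out$trace <- seg$trace; out$midpoints <- mids; out$fit <- fit
    out$profile <- prof; out$work_img <- work
    out$rotated_mask <- rot$mask; out$rotated_img <- rot$img
  }
  structure(out, class = "finger_roi")
}

#' @export
print.finger_roi <- function(x, ...) {
  cat(sprintf("finger ROI %dx%d | case: %s | theta %+0.2f deg (%s) | ref col %d | rows %d..%d\n",
              nrow(x$roi), ncol(x$roi), x$meta$case, x$meta$theta_deg,
              if (x$meta$applied_rotation) "rotated" else "not rotated",
              x$meta$ref, x$meta$y1, x$meta$y2))
  if (length(x$meta$warnings))
    cat("warnings:", paste(x$meta$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.finger_roi <- function(object, ...) {
  print(object)
  cat("stage log:\n")
  for (l in object$meta$log) cat("  -", l, "\n")
  invisible(object)
}

#' @export
plot.finger_roi <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show_gray(x$mask * 255, "segmentation")
  show_gray(x$roi, "normalized ROI")
  invisible(x)
}

# draw a gray image with row 1 on top
show_gray <- function(img, title = "") {
  graphics::image(t(img[nrow(img):1, , drop = FALSE]), col = grDevices::gray(0:255 / 255),
                  axes = FALSE, main = title, useRaster = TRUE, zlim = c(0, 255))
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b binary masks of the same shape.
#' @return IoU in `[0, 1]` (1 if both masks are empty).
#' @export
mask_iou <- function(a, b) {
  a <- as_binary_mask(a); b <- as_binary_mask(b)
  stopifnot_same_shape(a, b)
  un <- sum(a == 1 | b == 1)
  if (un == 0) return(1)
  sum(a == 1 & b == 1) / un
}

#' Verdict on one segmentation against ground truth
#'
#' A segmentation is "correct" when it contains no appreciable false
#' background or false foreground: mask IoU with the truth of at least
#' `iou_min`, and no connected mismatch component (8-connectivity) larger
#' than `max_comp_frac` of the true finger area.
#'
#' @param mask segmentation to judge.
#' @param truth_mask ground-truth mask.
#' @param iou_min IoU threshold.
#' @param max_comp_frac largest tolerated mismatch component, as a fraction
#'   of the finger area.
#' @return list with logical `correct`, `iou`, and `max_comp_frac_observed`.
#' @export
segmentation_verdict <- function(mask, truth_mask, iou_min = 0.98,
                                 max_comp_frac = 0.01) {
  iou <- mask_iou(mask, truth_mask)
  mism <- (mask != truth_mask) * 1
  max_frac <- 0
  if (any(mism == 1)) {
    lab <- EBImage::bwlabel(mism)
    sizes <- tabulate(lab[lab > 0])
    max_frac <- max(sizes) / sum(truth_mask)
  }
  list(correct = iou >= iou_min && max_frac <= max_comp_frac,
       iou = iou, max_comp_frac_observed = max_frac)
}

#' Segmentation accuracy over a set of verdicts
#'
#' Accuracy is the fraction of correctly segmented images:
#' `n_correct / n_total`.
#'
#' @param verdicts logical vector, one entry per image.
#' @return list of class `segmentation_report` with `n_total`, `n_correct`,
#'   `accuracy` and the verdicts.
#' @export
evaluate_segmentation <- function(verdicts) {
  if (length(verdicts) < 1) stop("no verdicts to evaluate", call. = FALSE)
  verdicts <- as.logical(verdicts)
  structure(list(n_total = length(verdicts),
                 n_correct = sum(verdicts),
                 accuracy = mean(verdicts),
                 verdicts = verdicts),
            class = "segmentation_report")
}

#' @export
print.segmentation_report <- function(x, ...) {
  cat(sprintf("segmentation accuracy: %d / %d = %.4f\n",
              x$n_correct, x$n_total, x$accuracy))
  invisible(x)
}
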