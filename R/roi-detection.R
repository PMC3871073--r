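#' Finger extent at an anchor column
#'
#' Returns the first and last foreground rows of the mask at the given
#' column. The anchor defaults to column 150 of the 160-column working frame
#' because the narrowest finger width usually sits near the right (fingertip)
#' end. If the anchor column holds no foreground, the nearest column that
#' does is used instead and a warning is issued.
#'
#' @param mask binary mask.
#' @param col anchor column index.
#' @return list with `y1`, `y2` (rows), and `col_used`.
#' @export
finger_extent_at_column <- function(mask, col = 150L) {
  mask <- as_binary_mask(mask)
  if (!any(mask == 1)) stop("all-background mask: no finger region", call. = FALSE)
  col <- min(max(as.integer(col), 1L), ncol(mask))
  nonempty <- which(colSums(mask) > 0)
  used <- col
  if (!col %in% nonempty) {
    used <- nonempty[which.min(abs(nonempty - col))]
    warning("anchor column ", col, " empty; using nearest nonempty column ",
            used, call. = FALSE)
  }
  rows <- which(mask[, used] == 1)
  list(y1 = rows[1], y2 = rows[length(rows)], col_used = used)
}

#' Vertical projection of the knuckle search block
#'
#' Cuts the block spanning rows `y1..y2` and columns `block_cols[1]..
#' block_cols[2]` from the (rotation-corrected) image and sums each column:
#' `V_j = sum_i w(i, j)`. The articular cartilage of the second knuckle
#' transmits NIR light, so the knuckle column accumulates the largest sum.
#' Restricting the projection to a block left of mid-frame (default columns
#' 21..80) avoids distraction from illumination gradients elsewhere.
#'
#' @param img gray image (segmented or rotation-corrected).
#' @param y1,y2 block row range, `y1 < y2`.
#' @param block_cols inclusive column range of the block.
#' @return list of class `projection_profile` with `values` (length `n1`),
#'   `origin` (row, col of the block corner), `m1`, `n1`.
#' @export
block_projection <- function(img, y1, y2, block_cols = c(21L, 80L)) {
  img <- as_gray_image(img)
  if (y1 >= y2) stop("need y1 < y2 for the projection block", call. = FALSE)
  c_lo <- max(1L, as.integer(block_cols[1]))
  c_hi <- min(ncol(img), as.integer(block_cols[2]))
  y1 <- max(1L, as.integer(y1)); y2 <- min(nrow(img), as.integer(y2))
  if (c_lo > c_hi) stop("empty projection block", call. = FALSE)
  w <- img[y1:y2, c_lo:c_hi, drop = FALSE]
  structure(list(values = colSums(w), origin = c(row = y1, col = c_lo),
                 m1 = nrow(w), n1 = ncol(w)),
            class = "projection_profile")
}

#' Reference column from a projection profile
#'
#' `c = argmax_j V_j` (ties broken toward the smallest index), mapped back to
#' frame coordinates: `ref = c + origin_col - 1`, which for the default block
#' starting at column 21 gives `ref = c + 20`. The reference column marks the
#' second knuckle and anchors the ROI horizontally.
#'
#' @param profile a `projection_profile`.
#' @return list with `c` (block-local index) and `ref` (frame column).
#' @export
reference_column <- function(profile) {
  cc <- which.max(profile$values)
  list(c = cc, ref = cc + unname(profile$origin["col"]) - 1L)
}

#' Crop the ROI rectangle
#'
#' The ROI spans rows `(y1 + 2)..(y2 - 2)` (insetting past contour
#' quantization) and columns `[ref - 15, ref + 80)` -- half-open on the
#' right, so the width is exactly 95 columns. Rectangles reaching outside the
#' frame are clamped with a warning, in which case the width may be below 95.
#'
#' @param img gray image (same frame the reference column was found in).
#' @param ref reference column.
#' @param y1,y2 finger extent rows at the anchor column.
#' @param col_offsets offsets of the ROI column range relative to `ref`; the
#'   right offset is exclusive.
#' @param row_insets insets applied to `y1` and `y2`.
#' @return gray image crop.
#' @export
crop_roi <- function(img, ref, y1, y2, col_offsets = c(-15L, 80L),
                     row_insets = c(2L, -2L)) {
  img <- as_gray_image(img)
  top <- y1 + row_insets[1]; bottom <- y2 + row_insets[2]
  left <- ref + col_offsets[1]; right <- ref + col_offsets[2] - 1L
  if (top >= bottom)
    stop("degenerate ROI rectangle: row_top >= row_bottom", call. = FALSE)
  cl <- max(1L, left); cr <- min(ncol(img), right)
  rt <- max(1L, top); rb <- min(nrow(img), bottom)
  if (cl != left || cr != right || rt != top || rb != bottom)
    warning("ROI rectangle clamped to frame; width ", cr - cl + 1L,
            " columns", call. = FALSE)
  as_gray_image(img[rt:rb, cl:cr, drop = FALSE])
}

#' Geometry normalization of the ROI
#'
#' Bicubic resize of the cropped ROI to the fixed output shape (default
#' 60 x 128) so that downstream feature extraction sees a constant geometry.
#'
#' @param roi gray image crop.
#' @param out_rows,out_cols output shape.
#' @return gray image of exactly `out_rows x out_cols`.
#' @export
normalize_roi <- function(roi, out_rows = 60L, out_cols = 128L) {
  resize_image(roi, out_rows, out_cols)
}
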