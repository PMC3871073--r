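#' Least-squares fit of the finger midline
#'
#' Fits `y = k x + b` to the midpoints that are not flagged wrong, using the
#' closed-form least-squares estimates
#' `k = sum((x - xbar)(y - ybar)) / sum((x - xbar)^2)` and
#' `b = ybar - k xbar`. The signed orientation angle is `atan(k)` in degrees:
#' `x` runs along the finger-length axis and `y` down the rows, so a nonzero
#' `k` means the finger is tilted relative to the horizontal axis. The
#' unsigned magnitude `theta_mag` is reported alongside for logging.
#'
#' @param mids a `midpoint_set`; only points with `wrong = FALSE` enter the
#'   fit (at least 2, with at least 2 distinct `x`).
#' @return object of class `midline_fit` with `k`, `b`, `x_bar`, `y_bar`,
#'   `theta_deg` (signed) and `theta_mag`.
#' @export
fit_midline <- function(mids) {
  x <- mids$x[!mids$wrong]
  y <- mids$y[!mids$wrong]
  if (length(x) < 2 || length(unique(x)) < 2)
    stop("degenerate midline fit: need >= 2 distinct x values", call. = FALSE)
  x_bar <- mean(x); y_bar <- mean(y)
  k <- sum((x - x_bar) * (y - y_bar)) / sum((x - x_bar)^2)
  b <- y_bar - k * x_bar
  structure(list(k = k, b = b, x_bar = x_bar, y_bar = y_bar,
                 theta_deg = orientation_angle(k),
                 theta_mag = abs(orientation_angle(k))),
            class = "midline_fit")
}

#' @export
print.midline_fit <- function(x, ...) {
  cat(sprintf("finger midline: y = %.4f x + %.2f  (theta = %+.3f deg)\n",
              x$k, x$b, x$theta_deg))
  invisible(x)
}

#' @export
coef.midline_fit <- function(object, ...) c(k = object$k, b = object$b)

#' Signed orientation angle of a slope
#'
#' Converts the fitted midline slope to the orientation angle in degrees,
#' `theta = atan(k) * 180 / pi`. Positive angles mean the image should be
#' rotated counterclockwise, negative ones clockwise; the magnitude `|theta|`
#' is what the rotation gate compares against.
#'
#' @param k finite slope (rows per column).
#' @return signed angle in degrees.
#' @export
orientation_angle <- function(k) {
  if (!is.finite(k)) stop("slope must be finite", call. = FALSE)
  atan(k) * 180 / pi
}

#' Midline orientation of a segmented mask
#'
#' Reads the per-column finger extents off a binary mask, computes their
#' midpoints and fits the midline. This is the direct way to measure the
#' orientation of a segmentation -- e.g. to verify that the residual angle of
#' a rotation-corrected mask sits below the rotation gate -- without
#' re-running edge detection on a rotated frame, whose zero-filled corners
#' can clip the contour at the outermost columns.
#'
#' @param mask binary mask with at least 2 nonempty columns.
#' @return a `midline_fit`.
#' @export
mask_midline_angle <- function(mask) {
  mask <- as_binary_mask(mask)
  nonempty <- which(colSums(mask) > 0)
  if (length(nonempty) < 2)
    stop("mask needs >= 2 nonempty columns", call. = FALSE)
  up <- vapply(nonempty, function(j) which(mask[, j] == 1)[1], 0L)
  low <- vapply(nonempty, function(j) {
    w <- which(mask[, j] == 1); w[length(w)]
  }, 0L)
  fit_midline(structure(list(x = nonempty, y = (up + low) / 2,
                             wrong = rep(FALSE, length(nonempty)), p = 0L),
                        class = "midpoint_set"))
}

# bicubic sampling of img at fractional (row, col) coordinates, zero outside
bicubic_sample <- function(img, rr, cc) {
  m <- nrow(img); n <- ncol(img)
  out <- numeric(length(rr))
  inside <- rr >= 1 & rr <= m & cc >= 1 & cc <= n
  r0 <- floor(rr); c0 <- floor(cc)
  acc <- numeric(length(rr))
  for (dr in -1:2) {
    wr <- cubic_kernel(rr - (r0 + dr))
    ri <- pmin(pmax(r0 + dr, 1), m)
    for (dc in -1:2) {
      wc <- cubic_kernel(cc - (c0 + dc))
      ci <- pmin(pmax(c0 + dc, 1), n)
      acc <- acc + wr * wc * img[cbind(ri, ci)]
    }
  }
  out[inside] <- acc[inside]
  out
}

#' Rotate image and mask to a horizontal finger axis, if the gate fires
#'
#' If `|theta_deg|` does not exceed `min_angle_deg` (default 1 degree) the
#' inputs are returned unchanged -- small tilts cost more in interpolation
#' blur than they gain in alignment. Otherwise both are rotated about the
#' frame center by the angle that makes the fitted midline horizontal:
#' bicubic interpolation for the intensities, nearest-neighbor for the mask
#' (preserving binarity), zero fill outside the source frame, output size
#' preserved.
#'
#' @param img gray image matrix.
#' @param mask binary mask of the same shape.
#' @param theta_deg signed orientation angle from [fit_midline()].
#' @param min_angle_deg rotation gate in degrees.
#' @return list with `img`, `mask`, and logical `applied`.
#' @export
rotate_if_needed <- function(img, mask, theta_deg, min_angle_deg = 1) {
  img <- as_gray_image(img); mask <- as_binary_mask(mask)
  stopifnot_same_shape(img, mask)
  if (abs(theta_deg) <= min_angle_deg)
    return(list(img = img, mask = mask, applied = FALSE))
  m <- nrow(img); n <- ncol(img)
  cr <- (m + 1) / 2; cc <- (n + 1) / 2
  th <- theta_deg * pi / 180
  grid <- expand.grid(r = seq_len(m), c = seq_len(n))
  dx <- grid$c - cc; dy <- grid$r - cr
  # sample along the tilted finger axis so it becomes the output's horizontal
  src_c <- cc + cos(th) * dx - sin(th) * dy
  src_r <- cr + sin(th) * dx + cos(th) * dy
  vals <- bicubic_sample(img, src_r, src_c)
  rot <- matrix(pmin(pmax(vals, 0), 255), m, n)
  nn_r <- round(src_r); nn_c <- round(src_c)
  ok <- nn_r >= 1 & nn_r <= m & nn_c >= 1 & nn_c <= n
  mv <- numeric(length(nn_r))
  mv[ok] <- mask[cbind(nn_r[ok], nn_c[ok])]
  rot_mask <- matrix(mv, m, n)
  list(img = as_gray_image(rot), mask = as_binary_mask(rot_mask),
       applied = TRUE)
}
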