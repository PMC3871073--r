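#' Build the directional edge-operator pair
#'
#' Constructs the extended Prewitt-style horizontal edge operators used for
#' coarse finger segmentation. The upper operator has `(h-1)/2` rows of -1
#' above a zero center row and `(h-1)/2` rows of +1 below, replicated across
#' `w` columns, so that a dark-above / bright-below transition (the upper
#' finger contour, scanning from the image center toward the boundary) yields
#' a bright response line. The lower operator is its vertical mirror. Widening
#' the operator along the finger axis (default `w = 11`) averages out vein
#' texture and noise that a plain 3 x 3 Prewitt mask would pick up.
#'
#' @param h,w odd kernel dimensions; `h >= 3`, `w >= 1`.
#' @return a list of class `edge_kernels` with components `upper`, `lower`
#'   (numeric `h x w` matrices), `h` and `w`.
#' @examples
#' k <- build_edge_kernels(3, 3)
#' k$upper  # the Prewitt horizontal kernel
#' @export
build_edge_kernels <- function(h = 3L, w = 11L) {
  if (h %% 2 == 0 || w %% 2 == 0 || h < 3 || w < 1)
    stop("kernel dims must be odd with h >= 3", call. = FALSE)
  half <- (h - 1) / 2
  col <- c(rep(-1, half), 0, rep(1, half))
  upper <- matrix(rep(col, w), nrow = h, ncol = w)
  structure(list(upper = upper, lower = upper[h:1, , drop = FALSE],
                 h = as.integer(h), w = as.integer(w)),
            class = "edge_kernels")
}

# 2-D cross-correlation with replicate border padding
correlate2d <- function(img, kern) {
  m <- nrow(img); n <- ncol(img)
  kh <- nrow(kern); kw <- ncol(kern)
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  ridx <- pmin(pmax(seq(1 - ph, m + ph), 1L), m)
  cidx <- pmin(pmax(seq(1 - pw, n + pw), 1L), n)
  pad <- img[ridx, cidx, drop = FALSE]
  out <- matrix(0, m, n)
  for (di in seq_len(kh)) {
    for (dj in seq_len(kw)) {
      k <- kern[di, dj]
      if (k == 0) next
      out <- out + k * pad[(di - 1) + seq_len(m), (dj - 1) + seq_len(n), drop = FALSE]
    }
  }
  out
}

# row index where the upper half ends; extra row goes to the lower half
split_row <- function(m) as.integer(m %/% 2)

#' Directional edge filtering of the two half-images
#'
#' Splits the image at the horizontal center line, correlates the upper half
#' with the upper operator and the lower half with the lower operator
#' (replicate borders), min-max normalizes each filtered half independently to
#' `[0, 255]`, and re-stacks them. In the filtered image each finger contour
#' appears as a bright ridge in its half.
#'
#' @param img gray image matrix (working-size frame).
#' @param kernels an `edge_kernels` pair from [build_edge_kernels()].
#' @return gray image of the same shape holding the normalized edge responses.
#' @export
filter_halves <- function(img, kernels) {
  img <- as_gray_image(img)
  m <- nrow(img)
  sr <- split_row(m)
  upper <- img[seq_len(sr), , drop = FALSE]
  lower <- img[(sr + 1):m, , drop = FALSE]
  norm01 <- function(x, which) {
    rng <- range(x)
    if (rng[1] == rng[2])
      stop("constant ", which, " half-image: edge response undefined", call. = FALSE)
    (x - rng[1]) / (rng[2] - rng[1]) * 255
  }
  fu <- norm01(correlate2d(upper, kernels$upper), "upper")
  fl <- norm01(correlate2d(lower, kernels$lower), "lower")
  as_gray_image(rbind(fu, fl))
}

#' Trace the finger contours from a filtered image
#'
#' For every column the upper contour row is the argmax of the upper
#' half-image and the lower contour row is the argmax of the lower half-image
#' (offset into full-frame coordinates). Ties are broken toward the row
#' nearest the horizontal center line, where the finger sits by device design.
#'
#' @param filtered output of [filter_halves()].
#' @return a list of class `edge_trace` with integer vectors `up`, `low`
#'   (length `n`, full-frame row indices), and scalars `n`, `m`.
#' @export
trace_edges <- function(filtered) {
  filtered <- as_gray_image(filtered)
  m <- nrow(filtered); n <- ncol(filtered)
  sr <- split_row(m)
  up <- integer(n); low <- integer(n)
  for (j in seq_len(n)) {
    cu <- filtered[seq_len(sr), j]
    # ties toward the center line: last max in the upper half
    up[j] <- max(which(cu == max(cu)))
    cl <- filtered[(sr + 1):m, j]
    low[j] <- sr + min(which(cl == max(cl)))
  }
  structure(list(up = up, low = low, n = n, m = m), class = "edge_trace")
}

#' Fill the finger mask between traced contours
#'
#' Sets `mask[i, j] = 1` iff `up[j] <= i <= low[j]`; the finger region in each
#' column is a single contiguous vertical run.
#'
#' @param trace an `edge_trace`.
#' @param m,n output mask shape.
#' @return binary mask matrix.
#' @export
edges_to_mask <- function(trace, m, n) {
  if (length(trace$up) != n)
    stop("trace length does not match column count", call. = FALSE)
  if (any(trace$up < 1 | trace$low > m))
    stop("trace rows outside [1, m]", call. = FALSE)
  if (any(trace$up > trace$low))
    stop("inconsistent trace: up > low in ",
         sum(trace$up > trace$low), " column(s)", call. = FALSE)
  rows <- matrix(seq_len(m), m, n)
  mask <- (rows >= matrix(trace$up, m, n, byrow = TRUE)) &
          (rows <= matrix(trace$low, m, n, byrow = TRUE))
  as_binary_mask(mask * 1)
}

#' Coarse binarization of a finger-vein image
#'
#' First-pass segmentation: directional edge filtering of the two half-images,
#' per-column contour tracing, and mask fill. Runs on the resized working
#' frame. Abnormal captures (truncated finger, scattering, uneven
#' illumination) produce broken contour traces here; those are detected and
#' repaired by the elaborate-binarization path.
#'
#' @param img gray image matrix (working frame).
#' @param kernels an `edge_kernels` pair; defaults to the standard 3 x 11
#'   extended operators.
#' @return list with components `mask` (binary mask) and `trace`
#'   (`edge_trace`).
#' @export
coarse_binarize <- function(img, kernels = build_edge_kernels()) {
  filtered <- filter_halves(img, kernels)
  trace <- trace_edges(filtered)
  mask <- edges_to_mask(trace, nrow(img), ncol(img))
  list(mask = mask, trace = trace)
}
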