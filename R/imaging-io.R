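#' @title Grayscale image and binary-mask containers
#'
#' @description Images are plain numeric matrices of intensities on the 0-255
#'   scale (floating point internally; quantized to 8 bits only on write).
#'   Rows run top to bottom and columns left to right, 1-based, so `img[y, x]`
#'   addresses column `x` along the finger-length axis and row `y` across it.
#'   `as_gray_image()` and `as_binary_mask()` validate the respective
#'   invariants and are the entry checks used by every pipeline stage.
#'
#' @param x a numeric matrix (intensities in `[0, 255]` for an image; values
#'   exactly 0/1 for a mask).
#' @return the validated matrix, invisibly unchanged apart from storage mode.
#' @examples
#' img <- as_gray_image(matrix(0, 4, 5))
#' msk <- as_binary_mask(matrix(c(0, 1), 4, 6))
#' @export
as_gray_image <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("gray image must be a numeric matrix", call. = FALSE)
  if (nrow(x) < 2L || ncol(x) < 1L)
    stop("gray image needs at least 2 rows and 1 column", call. = FALSE)
  if (!all(is.finite(x)))
    stop("gray image contains non-finite intensities", call. = FALSE)
  if (min(x) < 0 || max(x) > 255)
    stop("gray image intensities must lie in [0, 255]", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' @rdname as_gray_image
#' @export
as_binary_mask <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("binary mask must be a numeric matrix", call. = FALSE)
  if (!all(x == 0 | x == 1))
    stop("binary mask values must be exactly 0 or 1", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

# check a mask against the image it was derived from
stopifnot_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

#' Load a grayscale finger image from PNG or BMP
#'
#' Reads an 8-bit PNG or an uncompressed BMP (8-bit paletted or 24-bit) and
#' returns intensities on the 0-255 scale. RGB inputs are collapsed to
#' luminance (0.299 R + 0.587 G + 0.114 B). With `bright_background = TRUE`
#' the intensities are complemented (`255 - v`) so that the finger becomes the
#' bright object and the standard dark-background filters apply unchanged --
#' the polarity reversal needed for databases captured with bright backgrounds.
#'
#' @param path path to a `.png` or `.bmp` file.
#' @param bright_background logical; complement intensities on load.
#' @return a gray image matrix (see [as_gray_image()]).
#' @export
load_image <- function(path, bright_background = FALSE) {
  if (!file.exists(path)) stop("cannot read image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = {
      a <- tryCatch(png::readPNG(path),
                    error = function(e) stop("corrupt PNG: ", path, call. = FALSE))
      if (length(dim(a)) == 3L) {
        if (dim(a)[3] >= 3L)
          a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
        else a <- a[, , 1]
      }
      a * 255
    },
    bmp = read_bmp_gray(path),
    stop("unsupported image format '", ext, "' for ", path, call. = FALSE)
  )
  if (length(px) == 0L || nrow(px) < 2L)
    stop("zero-sized or degenerate image: ", path, call. = FALSE)
  if (bright_background) px <- 255 - px
  as_gray_image(pmin(pmax(px, 0), 255))
}

#' Save a grayscale image or mask to PNG or BMP
#'
#' Intensities are clipped to `[0, 255]` and quantized to 8 bits. Masks should
#' be passed through [mask_to_image()] first, which maps `{0, 1}` to
#' `{0, 255}`.
#'
#' @param img gray image matrix.
#' @param path output path ending in `.png` or `.bmp`.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  img <- as_gray_image(img)
  q <- round(pmin(pmax(img, 0), 255))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(q / 255, path),
    bmp = write_bmp_gray(q, path),
    stop("unsupported image format '", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' @rdname save_image
#' @param mask binary mask matrix.
#' @export
mask_to_image <- function(mask) as_gray_image(as_binary_mask(mask) * 255)

# ---- minimal uncompressed BMP codec -----------------------------------------
# BITMAPFILEHEADER (14 bytes) + BITMAPINFOHEADER (40 bytes), BI_RGB only,
# 8-bit paletted or 24-bit BGR, bottom-up rows padded to 4-byte multiples.

read_u16 <- function(raw, at) sum(as.integer(raw[at + 0:1]) * c(1, 256))
read_u32 <- function(raw, at) sum(as.numeric(raw[at + 0:3]) * 256^(0:3))

read_bmp_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM")
    stop("corrupt BMP: ", path, call. = FALSE)
  off    <- read_u32(raw, 11)
  hdrsz  <- read_u32(raw, 15)
  w      <- read_u32(raw, 19)
  h      <- read_u32(raw, 23)
  bpp    <- read_u16(raw, 29)
  compr  <- read_u32(raw, 31)
  if (compr != 0) stop("compressed BMP not supported: ", path, call. = FALSE)
  if (!bpp %in% c(8, 24)) stop("only 8/24-bit BMP supported: ", path, call. = FALSE)
  if (w < 1 || h < 1) stop("zero-sized image: ", path, call. = FALSE)
  pal <- NULL
  if (bpp == 8) {
    ncol_pal <- read_u32(raw, 47)
    if (ncol_pal == 0) ncol_pal <- 256
    pstart <- 14 + hdrsz
    pal <- matrix(as.integer(raw[pstart + seq_len(ncol_pal * 4)]),
                  ncol = 4, byrow = TRUE)  # B G R reserved
  }
  bytes_px <- bpp / 8
  stride <- ((w * bytes_px + 3) %/% 4) * 4
  out <- matrix(0, nrow = h, ncol = w)
  for (r in seq_len(h)) {
    rowstart <- off + (r - 1) * stride          # bottom-up
    line <- as.integer(raw[rowstart + seq_len(w * bytes_px)])
    target <- h - r + 1
    if (bpp == 8) {
      idx <- line + 1L
      out[target, ] <- 0.299 * pal[idx, 3] + 0.587 * pal[idx, 2] + 0.114 * pal[idx, 1]
    } else {
      b <- line[seq(1, length(line), 3)]
      g <- line[seq(2, length(line), 3)]
      rr <- line[seq(3, length(line), 3)]
      out[target, ] <- 0.299 * rr + 0.587 * g + 0.114 * b
    }
  }
  out
}

write_bmp_gray <- function(q, path) {
  h <- nrow(q); w <- ncol(q)
  stride <- ((w + 3) %/% 4) * 4
  imgsz <- stride * h
  off <- 14 + 40 + 256 * 4
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  u32(off + imgsz); u32(0); u32(off)
  u32(40); u32(w); u32(h); u16(1); u16(8); u32(0); u32(imgsz)
  u32(2835); u32(2835); u32(256); u32(0)
  pal <- as.raw(rbind(0:255, 0:255, 0:255, 0L))  # B G R reserved, column-major
  writeBin(pal, con)
  pad <- as.raw(rep(0L, stride - w))
  for (r in rev(seq_len(h))) {
    writeBin(as.raw(q[r, ]), con)
    if (length(pad)) writeBin(pad, con)
  }
  invisible(path)
}

# ---- bicubic resampling -----------------------------------------------------

# Keys cubic convolution kernel, a = -0.5 (the conventional "bicubic")
cubic_kernel <- function(t) {
  a <- -0.5
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  i2 <- at > 1 & at < 2
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  w[i2] <- a * at[i2]^3 - 5 * a * at[i2]^2 + 8 * a * at[i2] - 4 * a
  w
}

# one-dimensional resampling weight matrix (target x source), replicate
# borders, antialiased (kernel widened by the scale factor) when shrinking
resample_weights <- function(n_src, n_dst) {
  scale <- n_src / n_dst
  s <- max(scale, 1)                      # kernel stretch for antialiasing
  src <- (seq_len(n_dst) - 0.5) * scale + 0.5
  half <- 2 * s
  W <- matrix(0, n_dst, n_src)
  for (i in seq_len(n_dst)) {
    lo <- floor(src[i] - half) + 1
    hi <- ceiling(src[i] + half) - 1
    idx <- lo:hi
    w <- cubic_kernel((src[i] - idx) / s)
    keep <- w != 0
    idx <- pmin(pmax(idx[keep], 1L), n_src)   # replicate at borders
    w <- w[keep]
    w <- w / sum(w)
    for (k in seq_along(idx)) W[i, idx[k]] <- W[i, idx[k]] + w[k]
  }
  W
}

#' Resize a grayscale image with bicubic interpolation
#'
#' Separable cubic-convolution resampling (Keys kernel, a = -0.5); when
#' shrinking, the kernel is widened by the scale factor so that the result is
#' antialiased. This is the fixed down-resize applied before all processing
#' (native 480 x 640 captures are reduced to the 120 x 160 working frame) and
#' also performs the final ROI geometry normalization.
#'
#' @param img gray image matrix.
#' @param target_rows,target_cols requested output shape (each >= 2).
#' @return gray image of exactly `target_rows x target_cols`, clipped to
#'   `[0, 255]`.
#' @export
resize_image <- function(img, target_rows, target_cols) {
  img <- as_gray_image(img)
  if (target_rows < 2 || target_cols < 2)
    stop("resize targets must be >= 2", call. = FALSE)
  if (target_rows == nrow(img) && target_cols == ncol(img)) return(img)
  Wr <- resample_weights(nrow(img), target_rows)
  Wc <- resample_weights(ncol(img), target_cols)
  out <- Wr %*% img %*% t(Wc)
  as_gray_image(pmin(pmax(out, 0), 255))
}
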