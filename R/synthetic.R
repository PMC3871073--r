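#' Parameters for the synthetic NIR finger-image generator
#'
#' The generator emulates the geometry a NIR finger scanner produces: a
#' bright elongated finger band (about 160 intensity) on a dark background
#' (about 20), dark smooth vein curves inside the band, a locally brighter
#' vertical knuckle band, additive Gaussian noise, and optionally one of the
#' artifact classes that break coarse segmentation in practice. Everything is
#' driven by `seed`, so a sample is bit-reproducible.
#'
#' Artifact classes:
#' * `truncated_top` / `truncated_bottom` -- the contour leaves the frame over
#'   a middle run of columns (improper finger placement), so the traced edge
#'   collapses onto vein texture there: the boundary-padding repair applies.
#' * `scatter_wedge` -- a sharp-sided haze patch washes out one contour over a
#'   run of columns (scattering), displacing the trace into the finger:
#'   midpoint clustering plus line-guided repair applies.
#' * `uneven_illum` -- a smooth multiplicative illumination ramp; segmentation
#'   should survive without routing to the repair path.
#' * `neighbor_finger` -- a partial second bright band along the frame edge
#'   (the adjacent finger sharing the IR light); the directional operators
#'   should ignore it.
#' * `parasitic_blob` -- a small very bright spot in the background (parasitic
#'   light) that hijacks the trace over a few columns.
#'
#' @param frame frame shape (rows, cols); default the 120 x 160 working size.
#' @param finger_center_row midline row at the frame center column.
#' @param finger_half_width half the finger width in rows.
#' @param tilt_deg true orientation angle phi of the finger axis, degrees.
#' @param translation `(dr, dc)`: vertical shift of the band and horizontal
#'   shift of the knuckle.
#' @param knuckle_col knuckle band center column (before `dc`).
#' @param knuckle_gain brightness multiplier of the knuckle band.
#' @param vein_count number of vein curves.
#' @param vein_depth intensity drop at a vein center.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param artifact one of `"none"`, `"truncated_top"`, `"truncated_bottom"`,
#'   `"scatter_wedge"`, `"uneven_illum"`, `"neighbor_finger"`,
#'   `"parasitic_blob"`.
#' @param seed integer seed; fully determines the sample.
#' @return a list of class `synthetic_params`.
#' @export
synthetic_params <- function(frame = c(120L, 160L),
                             finger_center_row = 60,
                             finger_half_width = 27,
                             tilt_deg = 0,
                             translation = c(0, 0),
                             knuckle_col = 45L,
                             knuckle_gain = 1.3,
                             vein_count = 3L,
                             vein_depth = 35,
                             noise_sd = 4,
                             artifact = "none",
                             seed = 1L) {
  artifact <- match.arg(artifact,
    c("none", "truncated_top", "truncated_bottom", "scatter_wedge",
      "uneven_illum", "neighbor_finger", "parasitic_blob"))
  m <- frame[1]; n <- frame[2]
  span <- abs(tan(tilt_deg * pi / 180)) * n / 2
  if (artifact %in% c("none", "uneven_illum", "neighbor_finger")) {
    top <- finger_center_row + translation[1] - span - finger_half_width
    bot <- finger_center_row + translation[1] + span + finger_half_width
    if (top < 2 || bot > m - 1)
      stop("finger band does not fit the frame with these parameters",
           call. = FALSE)
  }
  structure(list(frame = as.integer(frame),
                 finger_center_row = finger_center_row,
                 finger_half_width = finger_half_width,
                 tilt_deg = tilt_deg, translation = translation,
                 knuckle_col = as.integer(knuckle_col),
                 knuckle_gain = knuckle_gain,
                 vein_count = as.integer(vein_count),
                 vein_depth = vein_depth, noise_sd = noise_sd,
                 artifact = artifact, seed = as.integer(seed)),
            class = "synthetic_params")
}

#' Generate one synthetic finger image with ground truth
#'
#' Renders the intensity model described in [synthetic_params()] and returns
#' the image together with analytically derived ground truth: the finger mask
#' (one contiguous vertical run per column, clipped to the frame), the true
#' tilt angle, the true knuckle column, and the pipeline branch the sample is
#' constructed to exercise.
#'
#' @param params a `synthetic_params` list.
#' @return list of class `synthetic_sample` with `image`, `truth_mask`,
#'   `truth_up`, `truth_low` (fractional contour rows), `truth_angle`,
#'   `truth_knuckle_col`, `truth_case`, and `params`.
#' @export
generate_finger_image <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(params$seed)
  m <- params$frame[1]; n <- params$frame[2]
  bg <- 20; fg <- 160; edge_roll <- 1.5
  x <- seq_len(n); cx <- (n + 1) / 2
  xs <- x - params$translation[2]     # horizontal translation shifts content
  hw <- params$finger_half_width
  mid <- params$finger_center_row + params$translation[1] +
    tan(params$tilt_deg * pi / 180) * (xs - cx)
  up_true <- mid - hw
  low_true <- mid + hw

  # truncation: improper placement drives one contour monotonically out of
  # the frame toward one end -- a smooth ramp starting at column xc, gentle
  # enough (<~0.6 rows/col) that the directional operator stays coherent on
  # the in-frame part of the contour, steep enough to exit decisively
  truth_case <- "normal"
  if (params$artifact %in% c("truncated_top", "truncated_bottom")) {
    exit_right <- stats::runif(1) < 0.5
    xc <- if (exit_right) stats::runif(1, 0.30 * n, 0.56 * n)
          else stats::runif(1, 0.44 * n, 0.70 * n)
    u <- if (exit_right) x - xc else xc - x
    sm <- 6
    shape <- sm * log1p(exp(u / sm))       # smooth hinge ramp
    len <- if (exit_right) n - xc else xc - 1
    if (params$artifact == "truncated_top") {
      far <- if (exit_right) n else 1L
      required <- up_true[far] + stats::runif(1, 4, 8)
      up_true <- up_true - (required / len) * shape
      truth_case <- "broken_upper"
    } else {
      far <- if (exit_right) n else 1L
      required <- (m - low_true[far]) + stats::runif(1, 4, 8)
      low_true <- low_true + (required / len) * shape
      truth_case <- "broken_lower"
    }
    mid <- (up_true + low_true) / 2
  }

  rows <- matrix(seq_len(m), m, n)
  upM <- matrix(up_true, m, n, byrow = TRUE)
  lowM <- matrix(low_true, m, n, byrow = TRUE)
  # smooth rolloff centered on the true contour
  inside <- pmin(pmax(pmin((rows - upM) / edge_roll + 0.5,
                           (lowM - rows) / edge_roll + 0.5), 0), 1)
  img <- bg + (fg - bg) * inside

  # dark vein curves: roughly parallel (a shared base wave plus a small
  # per-vein wiggle), offsets spaced so veins neither overlap each other --
  # stacked veins would mimic a contour-strength edge -- nor come within
  # ~7 px of the finger contours
  if (params$vein_count > 0) {
    L <- max(hw - 10, 2)
    base_amp <- stats::runif(1, 2, 5)
    base_period <- stats::runif(1, 100, 220)
    base_phase <- stats::runif(1, 0, 2 * pi)
    base_wave <- base_amp * sin(2 * pi * xs / base_period + base_phase)
    spacing <- 2 * L / params$vein_count
    for (v in seq_len(params$vein_count)) {
      off <- -L + (v - 0.5) * spacing + stats::runif(1, -2, 2)
      wig <- stats::runif(1, 0, 1.5) *
        sin(2 * pi * xs / stats::runif(1, 60, 160) + stats::runif(1, 0, 2 * pi))
      yv <- mid + off + base_wave + wig
      yvM <- matrix(yv, m, n, byrow = TRUE)
      img <- img - params$vein_depth * inside * exp(-((rows - yvM)^2) / (2 * 1.6^2))
    }
  }

  # brighter knuckle band (articular cartilage transmits NIR)
  kc <- params$knuckle_col + params$translation[2]
  kcM <- matrix(kc, m, n)
  img <- img + (params$knuckle_gain - 1) * fg * inside *
    exp(-((matrix(x, m, n, byrow = TRUE) - kcM)^2) / (2 * 3.5^2))

  if (params$artifact == "scatter_wedge") {
    # A wedge is only a repairable scattering error if the variance gate can
    # see it: the displaced trace must stay inside the contour's own
    # half-frame (or the argmax cannot land on the haze boundary), and the
    # predicted trace variance must clear the gate even after the tilt trend
    # absorbs part of the displacement. Placements are rejection-sampled
    # against that prediction; sub-gate haze is a different, unrepairable
    # degradation this class does not model.
    half <- ceiling(n / 2)
    draw_wedge <- function() {
      side <- sample(c("upper", "lower"), 1)
      contour <- if (side == "upper") up_true else low_true
      gapv <- if (side == "upper") (m / 2 - 1) - up_true
              else low_true - (m / 2 + 2)
      wl <- stats::runif(1, 12, 15)        # sharp-sided: abrupt onset
      elig <- which(x >= 40 & x <= 120 & x - wl >= 1 &
                    (x + wl <= half | x - wl > half))
      x0 <- elig[sample.int(length(elig), 1)]
      in_cols <- abs(x - x0) <= wl
      dmax <- min(stats::runif(1, 18, 24), min(gapv[in_cols]) - 0.5)
      pred <- round(contour)
      pred[in_cols] <- pred[in_cols] + if (side == "upper") dmax else -dmax
      pv <- max(stats::var(pred[1:half]), stats::var(pred[(half + 1):n]))
      list(ok = dmax >= 16 && pv >= 50, side = side, contour = contour,
           in_cols = in_cols, dmax = dmax)
    }
    for (try in 1:50) { wdg <- draw_wedge(); if (wdg$ok) break }
    cM <- matrix(wdg$contour, m, n, byrow = TRUE)
    if (wdg$side == "upper") {
      haze <- (rows >= cM - 8) & (rows <= cM + wdg$dmax)
    } else {
      haze <- (rows <= cM + 8) & (rows >= cM - wdg$dmax)
    }
    haze <- haze & matrix(wdg$in_cols, m, n, byrow = TRUE)
    img[haze] <- bg + (img[haze] - bg) * 0.06   # washed down to near background
    truth_case <- if (wdg$side == "upper") "broken_upper" else "broken_lower"
  } else if (params$artifact == "uneven_illum") {
    dir <- sample(c(1, -1), 1)
    gx <- 0.65 + 0.7 * (if (dir == 1) x else rev(x)) / n
    gy <- 0.9 + 0.2 * seq_len(m) / m
    img <- img * outer(gy, gx)
  } else if (params$artifact == "neighbor_finger") {
    edge <- sample(c("top", "bottom"), 1)
    nb_rows <- if (edge == "top") 1:8 else (m - 7):m
    c_from <- round(stats::runif(1, 1, n / 2))
    c_to <- min(n, c_from + round(stats::runif(1, 60, 120)))
    img[nb_rows, c_from:c_to] <- 120
  } else if (params$artifact == "parasitic_blob") {
    bx <- stats::runif(1, 30, 130)
    rad <- 9
    by <- max(min(up_true) - 20, rad + 3)
    d2 <- (rows - by)^2 + (matrix(x, m, n, byrow = TRUE) - bx)^2
    img[d2 <= rad^2] <- 230
    truth_case <- "broken_upper"
  }

  img <- img + stats::rnorm(m * n, 0, params$noise_sd)
  img <- pmin(pmax(img, 0), 255)

  up_clip <- pmin(pmax(up_true, 1), m)
  low_clip <- pmin(pmax(low_true, 1), m)
  truth <- (rows >= matrix(round(up_clip), m, n, byrow = TRUE)) &
           (rows <= matrix(round(low_clip), m, n, byrow = TRUE))

  structure(list(image = as_gray_image(img),
                 truth_mask = as_binary_mask(truth * 1),
                 truth_up = up_clip, truth_low = low_clip,
                 truth_angle = params$tilt_deg,
                 truth_knuckle_col = kc,
                 truth_case = truth_case,
                 params = params),
            class = "synthetic_sample")
}

#' Generate a reproducible suite of synthetic samples
#'
#' Draws `n` samples whose artifact labels follow `artifact_mix` (fractions
#' summing to 1; counts are fixed by rounding, assignment order shuffled), and
#' whose nuisance parameters -- tilt, vertical translation, knuckle position
#' -- vary across the stated ranges. Per-sample seeds are derived
#' deterministically from `seed`, so two runs with the same master seed give
#' bit-identical suites. Optionally writes the images as PNG plus a CSV truth
#' manifest.
#'
#' @param n number of samples.
#' @param artifact_mix named fractions over artifact classes.
#' @param seed master seed.
#' @param tilt_range,dr_range,knuckle_shift_range uniform draw ranges for the
#'   tilt angle (degrees), vertical translation (rows) and knuckle column
#'   shift (columns).
#' @param dir if non-`NULL`, directory to write `sample_###.png` images and
#'   `manifest.csv`.
#' @return list with `samples` (list of `synthetic_sample`) and `manifest`
#'   (data frame: file, artifact, truth_case, tilt_deg, knuckle_col, seed).
#' @export
generate_suite <- function(n = 200L,
                           artifact_mix = c(none = 0.5,
                                            truncated_top = 0.1,
                                            truncated_bottom = 0.1,
                                            scatter_wedge = 0.1,
                                            uneven_illum = 0.1,
                                            neighbor_finger = 0.1),
                           seed = 1L,
                           tilt_range = c(-6, 6),
                           dr_range = c(-6, 6),
                           knuckle_shift_range = c(-10L, 10L),
                           dir = NULL) {
  if (abs(sum(artifact_mix) - 1) > 1e-8)
    stop("artifact_mix fractions must sum to 1", call. = FALSE)
  counts <- round(artifact_mix * n)
  counts[1] <- counts[1] + (n - sum(counts))
  set.seed(seed)
  labels <- sample(rep(names(counts), counts))
  tilts <- stats::runif(n, tilt_range[1], tilt_range[2])
  drs <- stats::runif(n, dr_range[1], dr_range[2])
  kshift <- round(stats::runif(n, knuckle_shift_range[1], knuckle_shift_range[2]))
  seeds <- (as.numeric(seed) + seq_len(n) * 7919) %% 2147483647
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    dr <- drs[i]
    if (labels[i] == "neighbor_finger") dr <- max(dr, -3)  # keep a clear gap
    p <- synthetic_params(tilt_deg = tilts[i], translation = c(dr, 0),
                          knuckle_col = 45L + kshift[i],
                          artifact = labels[i], seed = as.integer(seeds[i]))
    samples[[i]] <- generate_finger_image(p)
  }
  files <- sprintf("sample_%03d.png", seq_len(n))
  manifest <- data.frame(file = files, artifact = labels,
                         truth_case = vapply(samples, `[[`, "", "truth_case"),
                         tilt_deg = tilts,
                         knuckle_col = vapply(samples, function(s)
                           as.numeric(s$truth_knuckle_col), 0),
                         seed = as.integer(seeds),
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n))
      save_image(samples[[i]]$image, file.path(dir, files[i]))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(samples = samples, manifest = manifest)
}
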