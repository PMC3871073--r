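# Brute-force oracles, independent of the package's implementations.

# per-column argmax contour tracing by exhaustive scan
brute_trace <- function(filtered) {
  m <- nrow(filtered); n <- ncol(filtered)
  sr <- floor(m / 2)
  up <- integer(n); low <- integer(n)
  for (j in seq_len(n)) {
    best <- -Inf; bi <- NA
    for (i in 1:sr)                       # ties -> nearest the center: keep last
      if (filtered[i, j] >= best) { best <- filtered[i, j]; bi <- i }
    up[j] <- bi
    best <- -Inf; bi <- NA
    for (i in (sr + 1):m)                 # ties -> nearest the center: keep first
      if (filtered[i, j] > best) { best <- filtered[i, j]; bi <- i }
    low[j] <- bi
  }
  list(up = up, low = low)
}

# two-pass sample variance
brute_var <- function(x) {
  mu <- sum(x) / length(x)
  sum((x - mu)^2) / (length(x) - 1)
}

# single-linkage agglomeration by exhaustive merging; returns membership labels
brute_single_linkage <- function(pts, cut) {
  clusters <- as.list(seq_len(nrow(pts)))
  d <- as.matrix(dist(pts))
  repeat {
    if (length(clusters) == 1) break
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      link <- min(d[clusters[[a]], clusters[[b]]])
      if (link < best[1]) best <- c(link, a, b)
    }
    if (best[1] > cut) break
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  labels <- integer(nrow(pts))
  for (g in seq_along(clusters)) labels[clusters[[g]]] <- g
  labels
}

# co-membership matrix, for comparing partitions up to label permutation
comembership <- function(labels) outer(labels, labels, "==")

# double-loop block column sums
brute_projection <- function(img, y1, y2, c_lo, c_hi) {
  v <- numeric(c_hi - c_lo + 1)
  for (j in c_lo:c_hi) {
    s <- 0
    for (i in y1:y2) s <- s + img[i, j]
    v[j - c_lo + 1] <- s
  }
  v
}

# quick clean sample for tests
clean_sample <- function(seed = 1, tilt = 0, dr = 0) {
  generate_finger_image(synthetic_params(seed = seed, tilt_deg = tilt,
                                         translation = c(dr, 0)))
}

midpoint_set <- function(x, y, wrong = rep(FALSE, length(x))) {
  structure(list(x = x, y = y, wrong = wrong, p = sum(wrong)),
            class = "midpoint_set")
}
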