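# Analytic raster fixtures and brute-force oracles, built independently
# of the package internals.

# Filled disk of radius r (pixel centers), with `pad` background margin.
mk_disk <- function(r, pad = 2) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  g <- expand.grid(row = 1:n, col = 1:n)
  m <- matrix(FALSE, n, n)
  m[as.matrix(g[ (g$row - ctr)^2 + (g$col - ctr)^2 <= r^2, ])] <- TRUE
  m
}

# Axis-aligned filled rectangle h x w inside a padded frame.
mk_rect <- function(h, w, pad = 2) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- TRUE
  m
}

# Filled ellipse with semi-axes a, b rotated by theta (radians).
mk_ellipse <- function(a, b, theta = 0, pad = 2) {
  r <- ceiling(max(a, b)) + pad
  n <- 2 * r + 1
  ctr <- r + 1
  g <- expand.grid(row = 1:n, col = 1:n)
  x <- g$col - ctr; y <- g$row - ctr
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  m <- matrix(FALSE, n, n)
  m[as.matrix(g[(u / a)^2 + (v / b)^2 <= 1, ])] <- TRUE
  m
}

# L-shape: three s x s unit squares of a 2s x 2s block (concave).
mk_L <- function(s = 20, pad = 2) {
  m <- matrix(FALSE, 2 * s + 2 * pad, 2 * s + 2 * pad)
  m[pad + seq_len(2 * s), pad + seq_len(s)] <- TRUE
  m[pad + s + seq_len(s), pad + s + seq_len(s)] <- TRUE
  m
}

# Nearest-neighbour rotation of a raster mask by `deg` degrees about its
# centroid, on an enlarged canvas.
rotate_mask_nn <- function(mask, deg) {
  th <- deg * pi / 180
  idx <- which(mask, arr.ind = TRUE)
  r0 <- mean(idx[, 1]); c0 <- mean(idx[, 2])
  n <- 2 * ceiling(max(abs(idx[, 1] - r0), abs(idx[, 2] - c0))) + 11
  ctr <- (n + 1) / 2
  g <- expand.grid(row = 1:n, col = 1:n)
  # inverse rotation: sample source pixel for each target pixel
  sr <- round(r0 + (g$row - ctr) * cos(-th) - (g$col - ctr) * sin(-th))
  sc <- round(c0 + (g$row - ctr) * sin(-th) + (g$col - ctr) * cos(-th))
  ok <- sr >= 1 & sr <= nrow(mask) & sc >= 1 & sc <= ncol(mask)
  hit <- ok
  hit[ok] <- mask[cbind(sr[ok], sc[ok])]
  out <- matrix(FALSE, n, n)
  out[as.matrix(g[hit, ])] <- TRUE
  out
}

# Exhaustive Otsu oracle: scans every 8-bit split level and computes the
# between-class variance directly from the pixel values.
otsu_oracle_level <- function(g) {
  stopifnot(all(g == floor(g)), min(g) >= 0, max(g) <= 255)
  v <- as.vector(g)
  best <- -Inf; bt <- NA
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    bcv <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; bt <- t }
  }
  bt
}

# Brute-force conditional erosion oracle: per-pixel neighbour count.
erosion_oracle <- function(mask, thr) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    nb <- 0L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      bgpx <- ii < 1 || ii > nr || jj < 1 || jj > nc || !mask[ii, jj]
      if (bgpx) nb <- nb + 1L
    }
    if (nb >= thr) out[i, j] <- FALSE
  }
  out
}

# Flood fill from the border over background; anything not reached is an
# interior hole (4-connectivity, matching hole filling semantics).
count_hole_px <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  reach <- matrix(FALSE, nr, nc)
  queue <- which(!mask & (row(mask) %in% c(1, nr) | col(mask) %in% c(1, nc)))
  reach[queue] <- TRUE
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    i <- (p - 1) %% nr + 1; j <- (p - 1) %/% nr + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      q <- ii + (jj - 1) * nr
      if (!mask[q] && !reach[q]) { reach[q] <- TRUE; queue <- c(queue, q) }
    }
  }
  sum(!mask & !reach)
}

# Small, fast scene configuration for I/O and determinism tests.
tiny_config <- function(...) {
  scene_config(image_size = c(96L, 96L), pixel_size = 0.3, ...)
}

small_archetype <- function() {
  class_archetype("C", cell_area_range = c(80, 140),
                  fa_count_range = c(4, 7),
                  fa_size_meanlog = log(0.5), fa_size_sdlog = 0.6,
                  fa_elongation_range = c(1.2, 2))
}
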