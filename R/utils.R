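# Internal helpers: seeded RNG scoping, raster geometry, polygon utilities.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. All randomized famet operations route through this so that a
# given seed yields bit-identical results regardless of call order.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# Derive a child seed from a master seed, stable across platforms and
# kept inside the 32-bit integer range.
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 48271 + index * 1299709) %% 2147483647)
}

stopifnot_mask <- function(mask) {
  if (!is.matrix(mask) || !(is.logical(mask) || all(mask %in% c(0, 1))))
    stop("`mask` must be a logical (or 0/1) matrix", call. = FALSE)
  mask <- mask != 0
  if (!any(mask)) stop("mask is empty (no foreground pixels)", call. = FALSE)
  mask
}

# Shoelace area of a polygon given x/y vertex vectors (any orientation).
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Convex-hull area of a pixel set, in the rasterized-hull convention
# (the pixel count of the convexified region, as in regionprops-style
# tools): the hull polygon over pixel centers is scan-filled back onto
# the grid. Convex rasterized shapes therefore score solidity 1.
hull_area_px <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  h <- grDevices::chull(idx[, 2], idx[, 1])
  hull <- rasterize_polygon(idx[h, 1], idx[h, 2], nrow(mask), ncol(mask))
  max(sum(hull | mask), sum(mask))
}

# Raster a filled polygon onto an nr x nc grid by even-odd scanline
# crossing at pixel centers. Vertices are in (row, col) pixel coordinates.
rasterize_polygon <- function(vr, vc, nr, nc) {
  mask <- matrix(FALSE, nr, nc)
  n <- length(vr)
  rows <- max(1L, floor(min(vr))):min(nr, ceiling(max(vr)))
  for (r in rows) {
    xs <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      y1 <- vr[j]; y2 <- vr[i]
      if ((y1 <= r && y2 > r) || (y2 <= r && y1 > r)) {
        t <- (r - y1) / (y2 - y1)
        xs <- c(xs, vc[j] + t * (vc[i] - vc[j]))
      }
      j <- i
    }
    if (length(xs) >= 2) {
      xs <- sort(xs)
      for (k in seq(1, length(xs) - 1, by = 2)) {
        c1 <- max(1L, ceiling(xs[k])); c2 <- min(nc, floor(xs[k + 1]))
        if (c1 <= c2) mask[r, c1:c2] <- TRUE
      }
    }
  }
  mask
}

# Filled-ellipse raster: center (r0, c0), semi-axes (a, b) in pixels along
# an axis rotated by theta (radians).
rasterize_ellipse <- function(r0, c0, a, b, theta, nr, nc) {
  rr <- max(a, b)
  rows <- max(1L, floor(r0 - rr)):min(nr, ceiling(r0 + rr))
  cols <- max(1L, floor(c0 - rr)):min(nc, ceiling(c0 + rr))
  mask <- matrix(FALSE, nr, nc)
  if (length(rows) < 1 || length(cols) < 1) return(mask)
  dg <- expand.grid(r = rows, c = cols)
  dr <- dg$r - r0; dc <- dg$c - c0
  u <- dc * cos(theta) + dr * sin(theta)
  v <- -dc * sin(theta) + dr * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  mask[cbind(dg$r[inside], dg$c[inside])] <- TRUE
  mask
}

# Clamp intensities into [0, 1].
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

largest_component <- function(mask, connectivity = 8L) {
  lab <- .label_components_cpp(mask, as.integer(connectivity))
  if (max(lab) == 0L) stop("no object detected", call. = FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}
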