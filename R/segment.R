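# Segmentation workflow: max projection -> CLAHE -> non-local-means ->
# Otsu threshold -> conditional erosion -> hole filling (+ dilation and
# area triage for focal adhesions).

#' Segmentation parameters
#'
#' Settings for the automated feature-extraction workflow. CLAHE and NLM
#' magnitudes are deliberately configuration, not constants: the workflow
#' order is fixed but suitable strengths depend on acquisition.
#'
#' @param clahe_tiles number of CLAHE tiles per image side.
#' @param clahe_clip CLAHE contrast-clipping factor (EBImage convention;
#'   higher = stronger equalization).
#' @param nlm_patch odd patch width (px) for non-local means.
#' @param nlm_search odd search-window width (px).
#' @param nlm_strength filtering parameter `h`; `NULL` = estimated from
#'   the image noise (0.8 x a robust pseudo-residual noise estimate).
#' @param erosion_neighbor_threshold conditional-erosion neighbour count
#'   in 1..8; a foreground pixel is removed when at least this many of
#'   its 8 neighbours are background. The workflow default is 5.
#' @param fa_dilation_radius disc radius (px) of the extra dilation step
#'   applied to the FA channel before erosion.
#' @param background_area_cutoff um^2; detected adhesion components
#'   smaller than this are cytosolic background (default 0.1).
#' @param mature_area_cutoff um^2; components with area greater than or
#'   equal to this are mature FAs (default 0.2); in-between areas are
#'   nascent adhesions.
#' @param connectivity 4 or 8; pixel connectivity for connected
#'   components (8 avoids splitting thin diagonal adhesions).
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(clahe_tiles = 8L,
                                clahe_clip = 2,
                                nlm_patch = 5L,
                                nlm_search = 11L,
                                nlm_strength = NULL,
                                erosion_neighbor_threshold = 5L,
                                fa_dilation_radius = 1L,
                                background_area_cutoff = 0.1,
                                mature_area_cutoff = 0.2,
                                connectivity = 8L) {
  stopifnot(clahe_tiles >= 1, clahe_clip > 0,
            nlm_patch %% 2 == 1, nlm_search %% 2 == 1,
            is.null(nlm_strength) || nlm_strength > 0,
            erosion_neighbor_threshold >= 1,
            erosion_neighbor_threshold <= 8,
            fa_dilation_radius >= 0,
            background_area_cutoff > 0,
            background_area_cutoff < mature_area_cutoff,
            connectivity %in% c(4L, 8L))
  structure(list(clahe_tiles = as.integer(clahe_tiles),
                 clahe_clip = clahe_clip,
                 nlm_patch = as.integer(nlm_patch),
                 nlm_search = as.integer(nlm_search),
                 nlm_strength = nlm_strength,
                 erosion_neighbor_threshold =
                   as.integer(erosion_neighbor_threshold),
                 fa_dilation_radius = as.integer(fa_dilation_radius),
                 background_area_cutoff = background_area_cutoff,
                 mature_area_cutoff = mature_area_cutoff,
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

#' Maximum intensity projection
#'
#' Collapses a z-stack to a 2D image by the per-pixel maximum across
#' planes. A 2D input (single plane) is returned unchanged.
#'
#' @param stack 2D matrix or `H x W x z` array with at least one plane.
#' @return 2D matrix.
#' @export
max_projection <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3 || dim(stack)[3] < 1)
    stop("`stack` must be a matrix or a H x W x z array with >= 1 plane",
         call. = FALSE)
  apply(stack, c(1, 2), max)
}

#' Non-local-means denoising
#'
#' Edge-preserving denoiser: each pixel is replaced by a weighted average
#' of search-window pixels, weighted by the similarity of the patches
#' around them (`exp(-max(d2 - 2*sigma^2, 0)/h^2)` with `d2` the mean
#' squared patch difference). Deterministic; borders use replicate
#' padding.
#'
#' @param img 2D numeric matrix.
#' @param patch odd patch width in px.
#' @param search odd search-window width in px.
#' @param h filtering strength; `NULL` = 0.8 x estimated noise sd.
#' @param sigma noise sd used in the patch-distance offset; `NULL` =
#'   estimated from the image.
#' @return denoised matrix.
#' @export
nlm_denoise <- function(img, patch = 5L, search = 11L, h = NULL,
                        sigma = NULL) {
  stopifnot(is.matrix(img), patch %% 2 == 1, search %% 2 == 1)
  if (is.null(sigma)) sigma <- estimate_noise_sd(img)
  if (is.null(h)) h <- max(0.8 * sigma, 1e-6)
  .nlm_denoise_cpp(img, as.integer(patch), as.integer(search), h, sigma)
}

# Robust noise-sd estimate from half the IQR-scaled MAD of horizontal
# first differences (difference of two iid pixels has sd sqrt(2)*sigma).
estimate_noise_sd <- function(img) {
  d <- diff(t(img))
  stats::mad(d) / sqrt(2)
}

# Edge-replicating pad so both dimensions are multiples of `tiles`.
pad_to_multiple <- function(img, tiles) {
  nr <- nrow(img); nc <- ncol(img)
  nr2 <- ceiling(nr / tiles) * tiles
  nc2 <- ceiling(nc / tiles) * tiles
  if (nr2 == nr && nc2 == nc) return(list(img = img, nr = nr, nc = nc))
  out <- img[c(seq_len(nr), rep(nr, nr2 - nr)),
             c(seq_len(nc), rep(nc, nc2 - nc)), drop = FALSE]
  list(img = out, nr = nr, nc = nc)
}

#' Preprocess a fluorescence channel
#'
#' Rescales intensities to `[0, 1]` (linear min-max, the 8-bit
#' normalization convention), applies contrast-limited adaptive histogram
#' equalization (CLAHE), then non-local-means (NLM) edge-preserving
#' denoising, in that order.
#'
#' @param img 2D numeric matrix.
#' @param params a [segmentation_params()].
#' @return 2D matrix with intensities in `[0, 1]`.
#' @export
preprocess <- function(img, params = segmentation_params()) {
  if (!is.matrix(img)) stop("`img` must be a 2D matrix", call. = FALSE)
  if (min(dim(img)) < params$clahe_tiles)
    stop("image (", nrow(img), "x", ncol(img), ") is smaller than the ",
         "CLAHE tile grid (", params$clahe_tiles, ")", call. = FALSE)
  rng <- range(img)
  x <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img
  p <- pad_to_multiple(x, params$clahe_tiles)
  eq <- EBImage::clahe(p$img, nx = params$clahe_tiles,
                       ny = params$clahe_tiles, bins = 256,
                       limit = params$clahe_clip)
  eq <- eq[seq_len(p$nr), seq_len(p$nc), drop = FALSE]
  nlm_denoise(eq, params$nlm_patch, params$nlm_search,
              h = params$nlm_strength)
}

#' Otsu binarization
#'
#' Thresholds the image at the 8-bit gray level maximizing the
#' between-class intensity variance. Images that are already 8-bit
#' (integer values in 0..255) are used as is; other images are
#' quantized to 256 levels first. Foreground = pixels strictly above the
#' threshold; ties in the between-class variance break toward the
#' lowest level.
#'
#' @param img 2D numeric matrix with at least two distinct values.
#' @return logical mask with attributes `threshold` (0..254 gray level)
#'   and `threshold_intensity` (same, on the input intensity scale).
#' @export
otsu_binarize <- function(img) {
  if (!is.matrix(img)) stop("`img` must be a 2D matrix", call. = FALSE)
  rng <- range(img)
  if (diff(rng) == 0)
    stop("constant image: no Otsu threshold exists", call. = FALSE)
  is8bit <- rng[1] >= 0 && rng[2] <= 255 && all(img == floor(img))
  g <- if (is8bit) img else
    pmin(floor((img - rng[1]) / diff(rng) * 256), 255)
  counts <- tabulate(as.integer(g) + 1L, nbins = 256L)
  lev <- 0:255
  w0 <- cumsum(counts)
  n <- w0[256]
  s0 <- cumsum(counts * lev)
  w1 <- n - w0
  m0 <- s0 / w0
  m1 <- (s0[256] - s0) / w1
  bcv <- w0 * w1 * (m0 - m1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  t_best <- which.max(bcv[1:255]) - 1L
  mask <- g > t_best
  attributes(mask) <- list(dim = dim(img))
  attr(mask, "threshold") <- t_best
  attr(mask, "threshold_intensity") <- if (is8bit) t_best else
    rng[1] + (t_best + 0.5) / 256 * diff(rng)
  mask
}

#' Conditional erosion
#'
#' One synchronous pass over the mask: a foreground pixel becomes
#' background when the number of background pixels among its 8 neighbours
#' is greater than or equal to `neighbor_threshold`. Pixels outside the
#' image count as background.
#'
#' @param mask logical matrix.
#' @param neighbor_threshold integer in 1..8 (workflow default 5).
#' @return logical mask.
#' @export
conditional_erosion <- function(mask, neighbor_threshold = 5L) {
  stopifnot(neighbor_threshold >= 1, neighbor_threshold <= 8)
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- matrix(1, nr + 2, nc + 2)
  bg[2:(nr + 1), 2:(nc + 1)] <- !mask
  cnt <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    cnt <- cnt + bg[(2:(nr + 1)) + dr, (2:(nc + 1)) + dc]
  }
  mask & (cnt < neighbor_threshold)
}

#' Fill interior holes
#'
#' Background components not connected to the image border become
#' foreground.
#'
#' @param mask logical matrix.
#' @return logical mask.
#' @export
fill_holes <- function(mask) {
  EBImage::fillHull(mask != 0) > 0
}

# Shared single-object pipeline for the red/blue channels.
segment_object <- function(img, params) {
  img <- max_projection(img)
  pre <- preprocess(img, params)
  m <- otsu_binarize(pre)
  m <- conditional_erosion(m, params$erosion_neighbor_threshold)
  m <- fill_holes(m)
  if (!any(m)) stop("no object detected", call. = FALSE)
  largest_component(m, params$connectivity)
}

#' Segment the cell body from the actin (red) channel
#'
#' Composition preprocess -> Otsu -> conditional erosion -> hole filling,
#' keeping the largest connected component (single-cell assumption).
#'
#' @param red_img 2D matrix or z-stack.
#' @param params a [segmentation_params()].
#' @return logical cell mask.
#' @export
segment_cell <- function(red_img, params = segmentation_params()) {
  segment_object(red_img, params)
}

#' Segment the nucleus from the DAPI (blue) channel
#'
#' @inheritParams segment_cell
#' @param blue_img 2D matrix or z-stack.
#' @return logical nucleus mask.
#' @export
segment_nucleus <- function(blue_img, params = segmentation_params()) {
  segment_object(blue_img, params)
}

# Moments of a pixel set (rows/cols), pixels treated as unit squares
# (+1/12 second-moment correction), giving exact agreement with
# continuous moments for axis-aligned rasterized rectangles.
mask_moments <- function(idx) {
  n <- nrow(idx)
  r0 <- mean(idx[, 1]); c0 <- mean(idx[, 2])
  dr <- idx[, 1] - r0; dc <- idx[, 2] - c0
  list(m00 = n, r0 = r0, c0 = c0,
       mu20 = sum(dc^2) + n / 12,
       mu02 = sum(dr^2) + n / 12,
       mu11 = sum(dr * dc))
}

# Moment-equivalent ellipse axes (pixel units, full lengths).
moment_axes <- function(mom) {
  a <- mom$mu20 / mom$m00; b <- mom$mu02 / mom$m00
  c <- mom$mu11 / mom$m00
  common <- sqrt((a - b)^2 + 4 * c^2)
  l1 <- (a + b + common) / 2
  l2 <- (a + b - common) / 2
  c(major = 4 * sqrt(max(l1, 0)), minor = 4 * sqrt(max(l2, 1 / 12)))
}

#' Measure and triage adhesion components in a binary mask
#'
#' Labels connected components, measures pixel count, area, centroid and
#' moment-equivalent ellipse axes, and triages each component by area:
#' `background` below `background_area_cutoff`, `nascent` from there up
#' to (excluding) `mature_area_cutoff`, `mature` at or above
#' `mature_area_cutoff`.
#'
#' @param mask logical matrix of candidate adhesion pixels.
#' @param pixel_size um per pixel.
#' @param params a [segmentation_params()].
#' @param cell_mask optional logical matrix; components that do not
#'   intersect this mask dilated by 2 px are discarded (adhesions sit at
#'   the cell periphery, so a small tolerance is applied).
#' @return data.frame with one row per retained component: `id`,
#'   `pixel_count`, `area_um2`, `centroid_x_um`, `centroid_y_um`,
#'   `major_um`, `minor_um`, `maturity`. Coordinates are 0-based pixel
#'   indices times `pixel_size`, origin top-left, x rightward (columns),
#'   y downward (rows).
#' @export
triage_fa_components <- function(mask, pixel_size,
                                 params = segmentation_params(),
                                 cell_mask = NULL) {
  stopifnot(pixel_size > 0)
  mask <- mask != 0
  lab <- .label_components_cpp(mask, params$connectivity)
  k <- max(lab)
  keep_region <- if (!is.null(cell_mask))
    EBImage::dilate(cell_mask * 1, EBImage::makeBrush(5, "disc")) > 0
  else NULL
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    idx <- which(lab == i, arr.ind = TRUE)
    if (!is.null(keep_region) && !any(keep_region[idx])) next
    mom <- mask_moments(idx)
    axes <- moment_axes(mom)
    area <- mom$m00 * pixel_size^2
    rows[[i]] <- data.frame(
      id = i,
      pixel_count = mom$m00,
      area_um2 = area,
      centroid_x_um = (mom$c0 - 1) * pixel_size,
      centroid_y_um = (mom$r0 - 1) * pixel_size,
      major_um = axes[["major"]] * pixel_size,
      minor_um = axes[["minor"]] * pixel_size,
      maturity = if (area < params$background_area_cutoff) "background"
        else if (area < params$mature_area_cutoff) "nascent"
        else "mature")
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = integer(0), pixel_count = integer(0),
                      area_um2 = numeric(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0), major_um = numeric(0),
                      minor_um = numeric(0), maturity = character(0))
  rownames(out) <- NULL
  out
}

#' Segment focal adhesions from the vinculin (green) channel
#'
#' Pipeline: preprocess -> Otsu -> dilation (disc of radius
#' `fa_dilation_radius`) -> conditional erosion -> hole filling ->
#' connected components -> per-component measurement and area triage.
#' Components outside the 2-px-dilated cell mask are discarded;
#' components below the cytosolic-background cutoff are returned tagged
#' `background` (they are excluded from downstream metrics but kept for
#' accounting).
#'
#' @param green_img 2D matrix or z-stack.
#' @param cell_mask logical cell-body mask from [segment_cell()].
#' @param params a [segmentation_params()].
#' @param pixel_size um per pixel.
#' @return adhesion table as in [triage_fa_components()]; zero rows when
#'   nothing is detected.
#' @export
segment_focal_adhesions <- function(green_img, cell_mask,
                                    params = segmentation_params(),
                                    pixel_size) {
  stopifnot(pixel_size > 0)
  img <- max_projection(green_img)
  pre <- preprocess(img, params)
  m <- otsu_binarize(pre)
  if (params$fa_dilation_radius > 0)
    m <- EBImage::dilate(m * 1,
      EBImage::makeBrush(2L * params$fa_dilation_radius + 1L, "disc")) > 0
  m <- conditional_erosion(m, params$erosion_neighbor_threshold)
  m <- fill_holes(m)
  triage_fa_components(m, pixel_size, params, cell_mask = cell_mask)
}

#' Segment a complete scene
#'
#' Runs [segment_cell()], [segment_nucleus()] and
#' [segment_focal_adhesions()] on the three channels of a scene
#' (z-stacks are max-projected first).
#'
#' @param scene a `cell_scene` (from [generate_scene()] or
#'   [read_scene()]).
#' @param params a [segmentation_params()].
#' @return object of class `segmentation_result`: list with `cell_mask`,
#'   `nucleus_mask`, `fa` (adhesion table), `pixel_size`, `params`.
#' @export
segment_scene <- function(scene, params = segmentation_params()) {
  stopifnot(inherits(scene, "cell_scene"))
  cell <- segment_cell(scene$channels$red, params)
  nuc <- segment_nucleus(scene$channels$blue, params)
  fa <- segment_focal_adhesions(scene$channels$green, cell, params,
                                scene$pixel_size)
  structure(list(cell_mask = cell, nucleus_mask = nuc, fa = fa,
                 pixel_size = scene$pixel_size,
                 class_label = scene$class_label,
                 params = params),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result>", sum(x$cell_mask), "cell px,",
      sum(x$nucleus_mask), "nucleus px,",
      nrow(x$fa), "adhesion components (",
      sum(x$fa$maturity == "mature"), "mature )\n")
  invisible(x)
}
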