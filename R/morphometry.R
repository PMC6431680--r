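# Whole-cell and focal-adhesion size/shape metrics.

#' Cell spreading area
#'
#' @param mask logical matrix.
#' @param pixel_size um per pixel.
#' @return area in um^2 (foreground pixel count x pixel_size^2).
#' @export
cell_area <- function(mask, pixel_size) {
  stopifnot(pixel_size > 0)
  mask <- stopifnot_mask(mask)
  sum(mask) * pixel_size^2
}

#' Moment-invariant ellipticity
#'
#' Shape measure from the affine invariant of the central second-order
#' moments. With central moments `mu20`, `mu02`, `mu11` and area `m00`,
#' let `J = (mu20*mu02 - mu11^2) / m00^4`; the ellipticity is
#' `16*pi^2*J` when `J <= 1/(16*pi^2)` and `1/(16*pi^2*J)` otherwise. It
#' ranges over `[0, 1]` and peaks at 1 for any perfect (filled) ellipse,
#' regardless of axes or rotation. Pixels are treated as unit squares
#' (per-pixel 1/12 second-moment correction), so rasterized analytic
#' shapes agree with their continuous closed forms.
#'
#' @param mask logical matrix.
#' @return ellipticity in `[0, 1]`.
#' @export
ellipticity <- function(mask) {
  mask <- stopifnot_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  mom <- mask_moments(idx)
  J <- (mom$mu20 * mom$mu02 - mom$mu11^2) / mom$m00^4
  if (J <= 0) stop("degenerate (zero-variance) mask", call. = FALSE)
  k <- 16 * pi^2
  if (J <= 1 / k) k * J else 1 / (k * J)
}

#' Rectangularity
#'
#' Object area divided by the area of its axis-aligned bounding box
#' (both in pixel units). Deliberately not rotation invariant: the
#' bounding box is measured along the image x/y axes.
#'
#' @param mask logical matrix.
#' @return value in `(0, 1]`; 1 for an axis-aligned filled rectangle.
#' @export
rectangularity <- function(mask) {
  mask <- stopifnot_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  h <- diff(range(idx[, 1])) + 1
  w <- diff(range(idx[, 2])) + 1
  nrow(idx) / (h * w)
}

#' Solidity
#'
#' Object area divided by the area of the tightest fitting convex hull.
#' The hull is taken over the corners of the foreground pixels (pixels as
#' unit squares), so convex rasterized shapes score ~1 and concave
#' ("ruffled") outlines score below 1.
#'
#' @param mask logical matrix.
#' @return value in `(0, 1]`.
#' @export
solidity <- function(mask) {
  mask <- stopifnot_mask(mask)
  min(sum(mask) / hull_area_px(mask), 1)
}

#' Focal-adhesion size and shape
#'
#' Area and moment-equivalent-ellipse aspect ratio (major/minor axis
#' length) of a single adhesion pixel set. Single-pixel or collinear
#' sets get a minor axis floored at one pixel width and are flagged.
#'
#' @param mask logical matrix containing one adhesion.
#' @param pixel_size um per pixel.
#' @return list with `size_um2`, `aspect_ratio` (>= 1), `major_um`,
#'   `minor_um`, and `degenerate` flag.
#' @export
fa_shape_metrics <- function(mask, pixel_size) {
  stopifnot(pixel_size > 0)
  mask <- stopifnot_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  mom <- mask_moments(idx)
  axes <- moment_axes(mom)
  # minor-axis variance at the 1/12 pixel floor <=> single-pixel or
  # collinear pixel set
  a <- mom$mu20 / mom$m00; b <- mom$mu02 / mom$m00; cc <- mom$mu11 / mom$m00
  l2 <- (a + b - sqrt((a - b)^2 + 4 * cc^2)) / 2
  degenerate <- nrow(idx) < 2 || l2 <= 1 / 12 + 1e-9
  list(size_um2 = mom$m00 * pixel_size^2,
       aspect_ratio = axes[["major"]] / axes[["minor"]],
       major_um = axes[["major"]] * pixel_size,
       minor_um = axes[["minor"]] * pixel_size,
       degenerate = degenerate)
}

#' Assemble the per-cell feature vector
#'
#' Combines whole-cell morphometry, mature-FA statistics and the spatial
#' distribution metrics into the 7-element classifier feature vector
#' (ellipticity, rectangularity, cell area, FA size, FA aspect ratio,
#' E-slope, G-function) plus auxiliary metrics (solidity, FA count, FA
#' coverage, nascent count). FA size and aspect ratio are means over
#' mature FAs. Cells lacking computable entries get `NA` there and a QC
#' flag; such cells are dropped from classification, not imputed.
#'
#' @param seg a `segmentation_result` from [segment_scene()].
#' @param cell_id identifier for the output row.
#' @return one-row data.frame.
#' @export
assemble_features <- function(seg, cell_id = "cell") {
  stopifnot(inherits(seg, "segmentation_result"))
  px <- seg$pixel_size
  mature <- seg$fa[seg$fa$maturity == "mature", , drop = FALSE]
  n_mat <- nrow(mature)
  area <- cell_area(seg$cell_mask, px)
  nuc_idx <- which(seg$nucleus_mask, arr.ind = TRUE)
  nuc_xy <- c((mean(nuc_idx[, 2]) - 1) * px, (mean(nuc_idx[, 1]) - 1) * px)

  qc <- character(0)
  fa_size <- fa_ar <- es <- gf <- NA_real_
  if (n_mat >= 1) {
    fa_size <- mean(mature$area_um2)
    fa_ar <- mean(mature$major_um / mature$minor_um)
    ef <- e_function(cbind(mature$centroid_x_um, mature$centroid_y_um),
                     nuc_xy)
    es <- if (any(ef$distances > 0)) e_slope(ef) else NA_real_
    if (is.na(es)) qc <- c(qc, "e_slope_undefined")
  } else qc <- c(qc, "no_mature_fa")
  if (n_mat >= 2) {
    gf <- cell_g(g_function(cbind(mature$centroid_x_um,
                                  mature$centroid_y_um)))
  } else qc <- c(qc, "fewer_than_2_mature_fa")

  data.frame(
    cell_id = cell_id,
    class = if (is.null(seg$class_label)) NA_character_ else seg$class_label,
    ellipticity = ellipticity(seg$cell_mask),
    rectangularity = rectangularity(seg$cell_mask),
    cell_area = area,
    fa_size = fa_size,
    fa_aspect_ratio = fa_ar,
    e_slope = es,
    g_function = gf,
    solidity = solidity(seg$cell_mask),
    fa_count = n_mat,
    fa_coverage = 100 * sum(mature$area_um2) / area,
    n_nascent = sum(seg$fa$maturity == "nascent"),
    qc_flags = paste(qc, collapse = ";"),
    stringsAsFactors = FALSE)
}

#' Names of the 7 classifier features
#'
#' Column names of the default classification feature set, in the fixed
#' axis order I-VII (ellipticity, rectangularity, cell area, FA size,
#' FA aspect ratio, E-slope, G-function). Solidity, FA count and FA
#' coverage are computed as auxiliary metrics but are not part of the
#' default classifier feature set.
#'
#' @return character vector of length 7.
#' @export
feature_names <- function() {
  c("ellipticity", "rectangularity", "cell_area", "fa_size",
    "fa_aspect_ratio", "e_slope", "g_function")
}
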