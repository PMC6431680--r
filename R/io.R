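# Scene I/O: multi-page TIFF (channels x z-planes) plus a JSON sidecar
# carrying the pixel calibration, seed, class label and ground truth.

rle_encode_mask <- function(mask) {
  r <- rle(as.vector(mask))
  list(dim = dim(mask), lengths = r$lengths, values = as.integer(r$values))
}

rle_decode_mask <- function(enc) {
  v <- inverse.rle(list(lengths = as.integer(enc$lengths),
                        values = as.integer(enc$values)))
  matrix(v == 1L, enc$dim[1], enc$dim[2])
}

channel_planes <- function(ch) {
  if (is.matrix(ch)) list(ch) else
    lapply(seq_len(dim(ch)[3]), function(k) ch[, , k])
}

#' Write a scene to TIFF + JSON sidecar
#'
#' Writes a multi-page 32-bit float TIFF (pages ordered red, green, blue;
#' within each channel, z-planes in order) and a `<path>.json` sidecar
#' with `pixel_size`, `seed`, `class_label`, `z_planes` and the ground
#' truth (FA table as lists, masks run-length encoded).
#'
#' @param scene a `cell_scene`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "cell_scene"))
  pages <- c(channel_planes(scene$channels$red),
             channel_planes(scene$channels$green),
             channel_planes(scene$channels$blue))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  gt <- scene$ground_truth
  sidecar <- list(
    pixel_size = scene$pixel_size,
    seed = scene$seed,
    class_label = scene$class_label,
    z_planes = length(pages) / 3L,
    channel_order = c("red", "green", "blue"),
    coordinate_convention = paste("0-based pixel indices times pixel_size;",
                                  "origin top-left, x rightward, y downward"),
    ground_truth = if (is.null(gt)) NULL else list(
      cell_mask_rle = rle_encode_mask(gt$cell_mask),
      nucleus_mask_rle = rle_encode_mask(gt$nucleus_mask),
      nucleus_centroid_um = as.list(gt$nucleus_centroid_um),
      fa = gt$fa))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a scene from TIFF (+ sidecar)
#'
#' Reads a multi-page TIFF written by [write_scene()] (or any TIFF whose
#' page count is `3 * z_planes` in red/green/blue channel order) and its
#' JSON sidecar. The pixel size is unit-bearing and therefore mandatory:
#' it must come from the sidecar or the `pixel_size` argument.
#'
#' @param path TIFF path.
#' @param pixel_size um per pixel; overrides the sidecar when given.
#' @return a `cell_scene`.
#' @export
read_scene <- function(path, pixel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  sidecar_path <- paste0(path, ".json")
  sc <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE) else NULL
  if (is.null(pixel_size)) pixel_size <- sc$pixel_size
  if (is.null(pixel_size))
    stop("pixel_size is required (no sidecar found and no value given); ",
         "all metrics are unit-bearing", call. = FALSE)
  if (length(pages) %% 3L != 0L)
    stop("expected pages = 3 channels x z-planes, got ", length(pages),
         " page(s)", call. = FALSE)
  z <- length(pages) / 3L
  stack <- function(planes) {
    if (length(planes) == 1L) planes[[1]] else
      array(unlist(planes), c(dim(planes[[1]]), length(planes)))
  }
  gt <- NULL
  if (!is.null(sc$ground_truth)) {
    g <- sc$ground_truth
    fa <- as.data.frame(g$fa)
    gt <- list(cell_mask = rle_decode_mask(g$cell_mask_rle),
               nucleus_mask = rle_decode_mask(g$nucleus_mask_rle),
               nucleus_centroid_um = unlist(g$nucleus_centroid_um),
               fa = fa)
  }
  structure(list(
    channels = list(red = stack(pages[seq_len(z)]),
                    green = stack(pages[z + seq_len(z)]),
                    blue = stack(pages[2L * z + seq_len(z)])),
    pixel_size = pixel_size,
    class_label = if (is.null(sc$class_label)) NA_character_ else
      sc$class_label,
    seed = if (is.null(sc$seed)) NA_integer_ else sc$seed,
    ground_truth = gt
  ), class = "cell_scene")
}
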