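#' Confinement-state archetype definition
#'
#' A `class_archetype` captures the geometry and focal-adhesion (FA)
#' statistics of one of the four single-cell confinement states used
#' throughout the package:
#'
#' * **A** — unconfined, well-spread cells on flat substrates: elongated
#'   elliptical outlines with elongated FAs distributed across the whole
#'   cell body.
#' * **B** — cells on sparse random fiber meshes: a high-variance mixture
#'   of spread lamellar shapes with edge-biased FAs.
#' * **C** — cells on dense random meshes: small, poorly spread, nearly
#'   round cells with few FAs.
#' * **D** — cells suspended in precision-woven 3D pores: triangular,
#'   concave outlines with large, weakly elongated FAs clustered around
#'   the nucleus.
#'
#' The label-to-morphology mapping (A = ellipse/body-wide,
#' B = lamellar blob/edge-biased, C = small blob/body-wide,
#' D = concave triangle/perinuclear-clustered) is fixed; numeric ranges
#' are configurable.
#'
#' @param label one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param cell_area_range length-2 numeric, target cell area interval
#'   (um^2).
#' @param cell_aspect_range length-2 numeric >= 1, cell elongation
#'   interval (ignored for the triangle family).
#' @param fa_count_range length-2 integer, FAs per cell.
#' @param fa_size_meanlog,fa_size_sdlog log-normal parameters of the FA
#'   area distribution (um^2). `fa_size_sdlog` must be > 0 so the
#'   distribution has mass on both sides of the 0.2 um^2 maturity cutoff.
#' @param fa_elongation_range length-2 numeric >= 1, FA major/minor axis
#'   ratio interval.
#' @param placement_scale um; band width for edge-biased placement or
#'   the Gaussian scale of the perinuclear cluster.
#' @param intra_class_variance multiplier >= 0 scaling the stochastic
#'   shape-perturbation amplitude within the class.
#' @return an object of class `class_archetype`.
#' @seealso [default_archetypes()], [generate_scene()]
#' @export
class_archetype <- function(label,
                            cell_area_range,
                            cell_aspect_range = c(1, 1.4),
                            fa_count_range,
                            fa_size_meanlog,
                            fa_size_sdlog,
                            fa_elongation_range,
                            placement_scale = 4,
                            intra_class_variance = 1) {
  label <- match.arg(label, c("A", "B", "C", "D"))
  families <- c(A = "ellipse", B = "lamellar_blob",
                C = "small_blob", D = "triangle")
  placements <- c(A = "body_wide", B = "edge_biased",
                  C = "body_wide", D = "perinuclear_clustered")
  stopifnot(length(cell_area_range) == 2, all(cell_area_range > 0),
            diff(cell_area_range) >= 0,
            length(fa_count_range) == 2, fa_count_range[1] >= 1,
            fa_size_sdlog > 0,
            length(fa_elongation_range) == 2,
            all(fa_elongation_range >= 1),
            placement_scale > 0, intra_class_variance >= 0)
  structure(list(
    label = label,
    shape_family = unname(families[label]),
    cell_area_range = as.numeric(cell_area_range),
    cell_aspect_range = as.numeric(cell_aspect_range),
    fa_count_range = as.integer(fa_count_range),
    fa_size_meanlog = fa_size_meanlog,
    fa_size_sdlog = fa_size_sdlog,
    fa_elongation_range = as.numeric(fa_elongation_range),
    fa_placement = unname(placements[label]),
    placement_scale = placement_scale,
    intra_class_variance = intra_class_variance
  ), class = "class_archetype")
}

#' Default archetype set
#'
#' The stock parameterization of the four confinement-state archetypes.
#' Class B carries a strictly larger intra-class variance than A, C and D
#' (a high-variance mixture of lamellar morphologies); class C has the
#' smallest cell-area range; class D combines concave triangles with
#' large, round-ish, perinuclearly clustered FAs. FA-area distributions
#' straddle both the 0.1 um^2 cytosolic-background and the 0.2 um^2
#' maturity cutoffs so that triage is exercised.
#'
#' @return named list of [class_archetype()] objects (`A`, `B`, `C`,
#'   `D`).
#' @export
default_archetypes <- function() {
  list(
    A = class_archetype("A", cell_area_range = c(400, 750),
                        cell_aspect_range = c(1.8, 2.8),
                        fa_count_range = c(18, 32),
                        fa_size_meanlog = log(0.5), fa_size_sdlog = 0.8,
                        fa_elongation_range = c(2.5, 4.0),
                        placement_scale = 4, intra_class_variance = 1),
    B = class_archetype("B", cell_area_range = c(250, 900),
                        cell_aspect_range = c(1.2, 2.8),
                        fa_count_range = c(8, 36),
                        fa_size_meanlog = log(0.45), fa_size_sdlog = 0.9,
                        fa_elongation_range = c(1.5, 3.5),
                        placement_scale = 4, intra_class_variance = 2.5),
    C = class_archetype("C", cell_area_range = c(120, 260),
                        cell_aspect_range = c(1.0, 1.4),
                        fa_count_range = c(5, 10),
                        fa_size_meanlog = log(0.35), fa_size_sdlog = 0.8,
                        fa_elongation_range = c(1.4, 2.6),
                        placement_scale = 3, intra_class_variance = 1),
    D = class_archetype("D", cell_area_range = c(350, 700),
                        fa_count_range = c(8, 16),
                        fa_size_meanlog = log(0.9), fa_size_sdlog = 0.9,
                        fa_elongation_range = c(1.1, 1.7),
                        placement_scale = 2.0, intra_class_variance = 0.8)
  )
}

#' Scene rendering configuration
#'
#' Geometry, calibration and noise settings shared by all synthetic
#' scenes.
#'
#' @param image_size length-2 integer, image height and width in pixels.
#' @param pixel_size um per pixel (> 0).
#' @param z_planes integer >= 1; when > 1 the same 2D scene is rendered
#'   on every plane with per-plane intensity attenuation (peaking at the
#'   central plane) so that maximum projection is exercised.
#' @param noise_sd standard deviation of the additive Gaussian intensity
#'   noise (intensities live in `[0, 1]`).
#' @param cytosolic_green_level uniform diffuse vinculin signal inside
#'   the cell mask on the green channel.
#' @param seed default RNG seed used when [generate_scene()] is called
#'   without one.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(image_size = c(256L, 256L),
                         pixel_size = 0.2,
                         z_planes = 1L,
                         noise_sd = 0.02,
                         cytosolic_green_level = 0.02,
                         seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 32),
            pixel_size > 0, z_planes >= 1, noise_sd >= 0,
            cytosolic_green_level >= 0)
  structure(list(image_size = as.integer(image_size),
                 pixel_size = pixel_size,
                 z_planes = as.integer(z_planes),
                 noise_sd = noise_sd,
                 cytosolic_green_level = cytosolic_green_level,
                 seed = as.integer(seed)),
            class = "scene_config")
}
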