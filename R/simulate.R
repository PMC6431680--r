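# Synthetic-scene generation: renders calibrated 3-channel single-cell
# fluorescence images with full ground truth for the four confinement
# archetypes, plus class-conditional feature-table sampling.

# Build a closed polygon (rows vr, cols vc, pixel units) with the target
# pixel area, centred at the origin, for one archetype draw. Consumes RNG.
make_cell_polygon <- function(arch, px_area) {
  icv <- arch$intra_class_variance
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  if (arch$shape_family == "ellipse") {
    q <- runif(1, arch$cell_aspect_range[1], arch$cell_aspect_range[2])
    vr <- sin(th) / sqrt(q); vc <- cos(th) * sqrt(q)
  } else if (arch$shape_family %in% c("lamellar_blob", "small_blob")) {
    amp_max <- if (arch$shape_family == "small_blob") 0.06 else
      min(0.14 * icv, 0.45)
    k <- 2:6
    # per-cell ruffling scale: a high-variance class spans smooth,
    # ellipse-like outlines through strongly lobed lamellar shapes
    u <- runif(1, 0, amp_max)
    a <- runif(5, 0, u); ph <- runif(5, 0, 2 * pi)
    r <- 1 + colSums(a * cos(outer(k, th) + ph))
    r[r < 0.15] <- 0.15
    q <- runif(1, arch$cell_aspect_range[1], arch$cell_aspect_range[2])
    vr <- r * sin(th) / sqrt(q); vc <- r * cos(th) * sqrt(q)
  } else { # triangle with inward-bowed (concave) edges
    jit <- pmin(0.35, 0.2 * icv)
    ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3) +
      runif(3, -jit, jit)
    vx <- cos(ang); vy <- sin(ang)
    kappa <- runif(1, 0.25, 0.45)
    tt <- seq(0, 1, length.out = 21)[-21]
    vr <- vc <- numeric(0)
    for (i in 1:3) {
      j <- if (i == 3) 1 else i + 1
      mx <- (1 - tt) * vx[i] + tt * vx[j]
      my <- (1 - tt) * vy[i] + tt * vy[j]
      pull <- 1 - kappa * sin(pi * tt)
      vr <- c(vr, my * pull); vc <- c(vc, mx * pull)
    }
  }
  rot <- runif(1, 0, 2 * pi)
  vr2 <- vr * cos(rot) - vc * sin(rot)
  vc2 <- vr * sin(rot) + vc * cos(rot)
  s <- sqrt(px_area / polygon_area(vc2, vr2))
  list(vr = vr2 * s, vc = vc2 * s)
}

# Place one FA footprint; returns logical mask or NULL when no
# non-overlapping position was found within the retry budget.
place_fa <- function(area_um2, elong, cand_idx, occupied_dil, cell_mask,
                     pixel_size, retries = 40L) {
  nr <- nrow(cell_mask); nc <- ncol(cell_mask)
  apx <- area_um2 / pixel_size^2
  a <- sqrt(apx * elong / pi); b <- a / elong
  for (t in seq_len(retries)) {
    if (nrow(cand_idx) == 0L) return(NULL)
    i <- cand_idx[sample.int(nrow(cand_idx), 1L), ]
    theta <- runif(1, 0, pi)
    f <- rasterize_ellipse(i[1], i[2], max(a, 0.5), max(b, 0.5), theta,
                           nr, nc) & cell_mask
    if (!any(f)) { f <- matrix(FALSE, nr, nc); f[i[1], i[2]] <- TRUE }
    if (!any(f & occupied_dil)) return(f)
  }
  NULL
}

#' Render one synthetic single-cell scene
#'
#' Draws one cell of the given archetype and renders it as a calibrated
#' 3-channel fluorescence image: red = filled cell body with fiber-like
#' internal texture (actin), blue = one filled nuclear ellipse inside the
#' cell (DAPI), green = focal-adhesion puncta plus a uniform cytosolic
#' background restricted to the cell mask (vinculin). Additive Gaussian
#' noise of sd `config$noise_sd` is applied everywhere and intensities are
#' clipped to `[0, 1]`. Ground truth (masks, nucleus centroid, per-FA
#' centroids/areas/maturity) is attached.
#'
#' Identical `archetype`/`config`/`rng_seed` yield bit-identical scenes.
#'
#' @param archetype a [class_archetype()].
#' @param config a [scene_config()].
#' @param rng_seed integer seed; defaults to `config$seed`.
#' @return an object of class `cell_scene`: a list with `channels`
#'   (matrices, or `H x W x z` arrays when `config$z_planes > 1`),
#'   `pixel_size`, `class_label` and `ground_truth`.
#' @export
generate_scene <- function(archetype, config = scene_config(),
                           rng_seed = config$seed) {
  stopifnot(inherits(archetype, "class_archetype"),
            inherits(config, "scene_config"))
  with_seed(rng_seed, {
    nr <- config$image_size[1]; nc <- config$image_size[2]
    px <- config$pixel_size

    # -- cell outline (bounded retries for the fit-in-frame constraint)
    cell_mask <- NULL
    for (try in 1:20) {
      area <- runif(1, archetype$cell_area_range[1],
                    archetype$cell_area_range[2])
      poly <- make_cell_polygon(archetype, area / px^2)
      hr <- max(abs(poly$vr)); hc <- max(abs(poly$vc))
      margin <- 3
      if (2 * hr > nr - 2 * margin || 2 * hc > nc - 2 * margin) next
      r0 <- runif(1, hr + margin, nr - hr - margin)
      c0 <- runif(1, hc + margin, nc - hc - margin)
      m <- rasterize_polygon(poly$vr + r0, poly$vc + c0, nr, nc)
      m <- EBImage::fillHull(m) > 0
      if (sum(m) > 20) { cell_mask <- m; break }
    }
    if (is.null(cell_mask))
      stop("cell of class ", archetype$label, " (target area ~",
           round(mean(archetype$cell_area_range)), " um^2) does not fit ",
           "in a ", nr, "x", nc, " image at ", px, " um/px", call. = FALSE)

    idx <- which(cell_mask, arr.ind = TRUE)
    cen <- colMeans(idx)  # (row, col)

    # -- nucleus: ellipse of ~18% cell area at the cell centroid
    nuc_area_px <- 0.18 * sum(cell_mask)
    qn <- runif(1, 1.1, 1.5)
    an <- sqrt(nuc_area_px * qn / pi); bn <- an / qn
    nuc_mask <- rasterize_ellipse(cen[1], cen[2], an, bn,
                                  runif(1, 0, pi), nr, nc) & cell_mask
    nuc_idx <- which(nuc_mask, arr.ind = TRUE)
    nuc_cen <- colMeans(nuc_idx)

    # -- focal adhesions
    dm <- EBImage::distmap(cell_mask * 1)
    n_fa <- sample(archetype$fa_count_range[1]:archetype$fa_count_range[2], 1L)
    band_px <- archetype$placement_scale / px
    cand <- switch(archetype$fa_placement,
      body_wide = which(dm >= 2, arr.ind = TRUE),
      edge_biased = which(dm >= 1 & dm <= band_px, arr.ind = TRUE),
      perinuclear_clustered = NULL)
    if (!is.null(cand) && nrow(cand) == 0L)
      cand <- which(dm >= 1, arr.ind = TRUE)

    occupied_dil <- matrix(FALSE, nr, nc)
    fa_masks <- list()
    fa_rows <- list()
    # 3-px exclusion margin keeps puncta resolvable after the FA
    # pipeline's 1-px dilation step
    kern <- EBImage::makeBrush(7, "disc")
    for (k in seq_len(n_fa)) {
      a_um2 <- rlnorm(1, archetype$fa_size_meanlog, archetype$fa_size_sdlog)
      el <- runif(1, archetype$fa_elongation_range[1],
                  archetype$fa_elongation_range[2])
      ck <- if (archetype$fa_placement == "perinuclear_clustered") {
        pts <- cbind(round(rnorm(60, nuc_cen[1], band_px)),
                     round(rnorm(60, nuc_cen[2], band_px)))
        pts <- pts[pts[, 1] >= 1 & pts[, 1] <= nr &
                   pts[, 2] >= 1 & pts[, 2] <= nc, , drop = FALSE]
        pts <- pts[cell_mask[pts] , , drop = FALSE]
        if (nrow(pts) == 0L) which(dm >= 1, arr.ind = TRUE) else pts
      } else cand
      f <- place_fa(a_um2, el, ck, occupied_dil, cell_mask, px)
      if (is.null(f)) next
      occupied_dil <- occupied_dil | (EBImage::dilate(f * 1, kern) > 0)
      fidx <- which(f, arr.ind = TRUE)
      npx <- nrow(fidx)
      area <- npx * px^2
      fa_masks[[length(fa_masks) + 1L]] <- f
      fa_rows[[length(fa_rows) + 1L]] <- data.frame(
        row = mean(fidx[, 1]), col = mean(fidx[, 2]),
        x_um = (mean(fidx[, 2]) - 1) * px,
        y_um = (mean(fidx[, 1]) - 1) * px,
        pixel_count = npx, area_um2 = area,
        maturity = if (area < 0.1) "background" else
          if (area < 0.2) "nascent" else "mature")
    }
    fa_gt <- if (length(fa_rows)) do.call(rbind, fa_rows) else
      data.frame(row = numeric(0), col = numeric(0), x_um = numeric(0),
                 y_um = numeric(0), pixel_count = integer(0),
                 area_um2 = numeric(0), maturity = character(0))

    # -- channel rendering
    rowm <- matrix(seq_len(nr), nr, nc)
    colm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    alpha <- runif(1, 0, pi); lambda <- runif(1, 8, 14)
    stripe <- 0.5 + 0.5 * sin(2 * pi * (cos(alpha) * colm +
                                        sin(alpha) * rowm) / lambda +
                              runif(1, 0, 2 * pi))
    red <- (0.55 + 0.25 * stripe) * cell_mask
    blue <- 0.85 * nuc_mask
    green <- config$cytosolic_green_level * cell_mask
    for (f in fa_masks) green[f] <- runif(1, 0.75, 0.95)

    render <- function(clean) {
      if (config$z_planes == 1L) {
        return(clip01(clean + if (config$noise_sd > 0)
          matrix(rnorm(nr * nc, 0, config$noise_sd), nr, nc) else 0))
      }
      z <- config$z_planes
      att <- exp(-0.5 * ((seq_len(z) - (z + 1) / 2) / (z / 4))^2)
      att <- att / max(att)
      arr <- array(0, c(nr, nc, z))
      for (k in seq_len(z))
        arr[, , k] <- clip01(clean * att[k] + if (config$noise_sd > 0)
          matrix(rnorm(nr * nc, 0, config$noise_sd), nr, nc) else 0)
      arr
    }

    structure(list(
      channels = list(red = render(red), green = render(green),
                      blue = render(blue)),
      pixel_size = px,
      class_label = archetype$label,
      seed = as.integer(rng_seed),
      ground_truth = list(
        cell_mask = cell_mask,
        nucleus_mask = nuc_mask,
        nucleus_centroid_um = c(x = unname((nuc_cen[2] - 1) * px),
                                y = unname((nuc_cen[1] - 1) * px)),
        fa = fa_gt)
    ), class = "cell_scene")
  })
}

#' @export
print.cell_scene <- function(x, ...) {
  d <- dim(x$channels$red)
  cat("<cell_scene> class", x$class_label, "-",
      paste(d, collapse = "x"), "px @", x$pixel_size, "um/px;",
      nrow(x$ground_truth$fa), "ground-truth FAs\n")
  invisible(x)
}

#' Generate a labeled population of synthetic scenes
#'
#' Renders `n_per_class` scenes for each archetype, with per-scene seeds
#' derived deterministically from `master_seed`.
#'
#' @param n_per_class integer >= 1.
#' @param config a [scene_config()].
#' @param master_seed integer.
#' @param archetypes named list of archetypes (default
#'   [default_archetypes()]).
#' @return list of `cell_scene` objects, classes in archetype order.
#' @export
generate_population <- function(n_per_class, config = scene_config(),
                                master_seed = 1L,
                                archetypes = default_archetypes()) {
  stopifnot(n_per_class >= 1)
  scenes <- vector("list", n_per_class * length(archetypes))
  i <- 0L
  for (lab in names(archetypes)) {
    for (k in seq_len(n_per_class)) {
      i <- i + 1L
      scenes[[i]] <- generate_scene(archetypes[[lab]], config,
                                    rng_seed = derive_seed(master_seed, i))
    }
  }
  scenes
}

#' Sample a labeled feature table from class-conditional Gaussians
#'
#' Draws 7-element feature vectors (ellipticity, rectangularity, cell
#' area, FA size, FA aspect ratio, E-slope, G-function) directly from
#' class-conditional multivariate normal distributions — a fast fixture
#' for the classification stage that bypasses rendering and segmentation.
#'
#' * `"paper_like"` — class means reproduce the qualitative orderings of
#'   the four confinement states (C smallest cell area; D lowest
#'   ellipticity/rectangularity, largest FA size, smallest FA aspect
#'   ratio and G-function, highest E-slope) and class B gets an inflated
#'   covariance.
#' * `"strong"` — classes 8 within-class sd apart on every feature.
#' * `"weak"` — identical class means (chance-level separability).
#'
#' @param n_per_class integer >= 2.
#' @param separation `"paper_like"`, `"strong"` or `"weak"`.
#' @param seed integer RNG seed.
#' @return data.frame with `cell_id`, `class`, and the 7 feature columns.
#' @export
sample_feature_table <- function(n_per_class,
                                 separation = c("paper_like", "strong",
                                                "weak"),
                                 seed = 1L) {
  stopifnot(n_per_class >= 2)
  separation <- match.arg(separation)
  feats <- c("ellipticity", "rectangularity", "cell_area", "fa_size",
             "fa_aspect_ratio", "e_slope", "g_function")
  mu <- switch(separation,
    paper_like = rbind(
      A = c(0.85, 0.70, 650, 0.55, 3.2, 0.055, 2.2),
      B = c(0.75, 0.62, 600, 0.50, 2.6, 0.065, 2.3),
      C = c(0.78, 0.65, 150, 0.40, 2.2, 0.090, 1.8),
      D = c(0.60, 0.45, 520, 0.85, 1.5, 0.130, 1.1)),
    strong = outer(0:3, rep(8, 7)),
    weak = matrix(0, 4, 7))
  sdm <- switch(separation,
    paper_like = rbind(
      A = c(0.05, 0.05, 90, 0.12, 0.45, 0.012, 0.35),
      B = 2.5 * c(0.05, 0.05, 90, 0.12, 0.45, 0.012, 0.35),
      C = c(0.06, 0.05, 30, 0.10, 0.35, 0.020, 0.30),
      D = c(0.06, 0.05, 80, 0.18, 0.15, 0.025, 0.20)),
    strong = matrix(1, 4, 7),
    weak = matrix(1, 4, 7))
  rownames(mu) <- rownames(sdm) <- c("A", "B", "C", "D")
  with_seed(seed, {
    out <- lapply(c("A", "B", "C", "D"), function(lab) {
      x <- MASS::mvrnorm(n_per_class, mu = mu[lab, ],
                         Sigma = diag(sdm[lab, ]^2))
      colnames(x) <- feats
      data.frame(class = lab, x)
    })
    tab <- do.call(rbind, out)
    tab <- cbind(cell_id = sprintf("%s%03d", tab$class,
                                   stats::ave(seq_len(nrow(tab)), tab$class,
                                              FUN = seq_along)),
                 tab)
    rownames(tab) <- NULL
    tab$class <- factor(tab$class)
    attr(tab, "scaling_state") <- "raw"
    tab
  })
}
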