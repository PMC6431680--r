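test_that("max projection is the per-pixel maximum and is permutation invariant", {
  st <- array(0, c(2, 2, 3))
  st[1, 1, ] <- c(1, 5, 3)
  st[2, 2, ] <- c(4, 2, 0)
  mp <- max_projection(st)
  expect_equal(mp[1, 1], 5)
  expect_equal(mp[2, 2], 4)
  expect_identical(max_projection(st[, , c(3, 1, 2)]), mp)
  one <- matrix(runif(9), 3, 3)
  expect_identical(max_projection(one), one)
  expect_error(max_projection(array(0, c(2, 2, 0))), "plane")
})

test_that("preprocessing keeps constants constant and is deterministic", {
  const <- matrix(0.5, 64, 64)
  out <- preprocess(const)
  expect_lt(diff(range(out)), 1e-6)
  expect_lt(abs(mean(out) - 0.5), 0.05)
  set.seed(4)
  img <- matrix(runif(64 * 64), 64, 64)
  expect_identical(preprocess(img), preprocess(img))
  expect_error(preprocess(matrix(0, 4, 4)), "smaller")
})

test_that("non-local means reduces the MSE to the clean image", {
  set.seed(11)
  g <- outer(seq(0, 1, length.out = 80), seq(0, 1, length.out = 80),
             function(x, y) 0.3 + 0.4 * (x > 0.5) + 0.2 * sin(6 * y))
  noisy <- g + matrix(rnorm(length(g), 0, 0.05), nrow(g))
  den <- nlm_denoise(noisy)
  expect_lt(mean((den - g)^2), mean((noisy - g)^2))
})

test_that("Otsu separates a two-level image exactly and flips under inversion", {
  set.seed(2)
  img <- matrix(10, 20, 20)
  fg <- sample(400, 200)
  img[fg] <- 200
  m <- otsu_binarize(img)
  expect_identical(which(m), sort(fg))
  inv <- otsu_binarize(max(img) - img)
  expect_identical(as.vector(inv), as.vector(!m))
  expect_error(otsu_binarize(matrix(1, 5, 5)), "constant")
})

test_that("Otsu equals the exhaustive between-class-variance maximizer", {
  for (s in 1:8) {
    set.seed(s)
    n <- 40
    g <- matrix(pmin(pmax(round(c(rnorm(n * n / 2, 70, 25),
                                  rnorm(n * n / 2, 180, 30))), 0), 255), n, n)
    m <- otsu_binarize(g)
    expect_identical(attr(m, "threshold"), otsu_oracle_level(g))
  }
})

test_that("conditional erosion matches its definition on canonical cases", {
  m <- matrix(FALSE, 7, 7); m[4, 4] <- TRUE
  expect_false(any(conditional_erosion(m, 5)))   # isolated pixel: 8 >= 5
  sq <- mk_rect(10, 10, pad = 3)
  er <- conditional_erosion(sq, 5)
  expect_true(er[8, 8])                          # interior: 0 bg neighbours
  expect_false(er[4, 4])                         # corner: 5 bg neighbours
  expect_true(er[4, 8])                          # edge midpoint: 3 bg
  # synchronous single pass: result depends only on the input mask
  expect_identical(er, erosion_oracle(sq, 5))
})

test_that("conditional erosion matches the brute-force counter on random masks", {
  for (s in 1:6) {
    set.seed(100 + s)
    m <- matrix(runif(20 * 20) < 0.55, 20, 20)
    for (thr in c(1, 3, 5, 8))
      expect_identical(conditional_erosion(m, thr), erosion_oracle(m, thr))
  }
})

test_that("hole filling fills interior holes and conserves area + hole area", {
  ann <- mk_disk(10) & !mk_disk(4, pad = 8)
  expect_identical(fill_holes(ann), mk_disk(10))
  solid <- mk_disk(7)
  expect_identical(fill_holes(solid), solid)    # idempotent on hole-free
  for (s in 1:5) {
    set.seed(200 + s)
    m <- mk_rect(20, 20, pad = 3)
    holes <- sample(which(m), 25)
    m[holes] <- FALSE
    expect_equal(sum(fill_holes(m)), sum(m) + count_hole_px(m))
  }
})

test_that("mask polarity is a rendering convention: double inversion is identity", {
  set.seed(9)
  m <- matrix(runif(64) < 0.4, 8, 8)
  expect_identical(!!m, m)
})

test_that("cell and nucleus segmentation recover noise-free ground truth", {
  sc <- generate_scene(default_archetypes()$A,
                       scene_config(noise_sd = 0), rng_seed = 3)
  cell <- segment_cell(sc$channels$red)
  gt <- sc$ground_truth$cell_mask
  expect_gte(sum(cell & gt) / sum(cell | gt), 0.95)
  nuc <- segment_nucleus(sc$channels$blue)
  grown <- EBImage::dilate(cell * 1, EBImage::makeBrush(5, "disc")) > 0
  expect_true(all(grown[nuc]))                  # nucleus inside (dilated) cell
  expect_error(segment_cell(matrix(0, 64, 64)), "constant|no object")
})

test_that("FA triage obeys the area cutoffs, including the 0.2 um2 boundary", {
  # 0.05 um/px => pixel area 0.0025 um2
  m <- matrix(FALSE, 60, 80)
  m[5:10, 5:9] <- TRUE                          # 30 px -> 0.075 -> background
  m[20:29, 10:15] <- TRUE                       # 60 px -> 0.15  -> nascent
  m[40:49, 30:39] <- TRUE                       # 100 px -> 0.25 -> mature
  fa <- triage_fa_components(m, 0.05)
  fa <- fa[order(fa$pixel_count), ]
  expect_equal(fa$pixel_count, c(30, 60, 100))
  expect_equal(fa$maturity, c("background", "nascent", "mature"))
  # exactly 0.2 um2 (80 px at 0.05 um/px) is mature
  m2 <- matrix(FALSE, 30, 30); m2[10:19, 10:17] <- TRUE
  fa2 <- triage_fa_components(m2, 0.05)
  expect_equal(fa2$area_um2, 0.2)
  expect_equal(fa2$maturity, "mature")
})

test_that("component accounting is conserved and cutoff sweep is monotone", {
  set.seed(31)
  m <- matrix(FALSE, 80, 80)
  for (i in 1:12) {
    r <- sample(5:70, 1); c <- sample(5:70, 1); s <- sample(1:4, 1)
    m[r:(r + s), c:(c + s)] <- TRUE
  }
  ncomp <- max(famet:::.label_components_cpp(m, 8L))
  fa <- triage_fa_components(m, 0.2)
  expect_equal(nrow(fa), ncomp)
  prev <- Inf
  for (cutoff in c(0.1, 0.2, 0.5, 1, 2)) {
    p <- segmentation_params(mature_area_cutoff = cutoff,
                             background_area_cutoff = 0.05)
    n_mat <- sum(triage_fa_components(m, 0.2, p)$maturity == "mature")
    expect_lte(n_mat, prev)
    prev <- n_mat
  }
})

test_that("component labeling agrees with EBImage at 4-connectivity and links diagonals at 8", {
  set.seed(5)
  m <- matrix(runif(40 * 40) < 0.3, 40, 40)
  lab4 <- famet:::.label_components_cpp(m, 4L)
  expect_equal(max(lab4), max(EBImage::bwlabel(m * 1)))
  diagm <- matrix(FALSE, 4, 4); diagm[1, 1] <- diagm[2, 2] <- TRUE
  expect_equal(max(famet:::.label_components_cpp(diagm, 8L)), 1L)
  expect_equal(max(famet:::.label_components_cpp(diagm, 4L)), 2L)
})

test_that("detected FAs match ground truth on a clean scene and areas scale with pixel size", {
  arch <- class_archetype("A", cell_area_range = c(400, 500),
                          cell_aspect_range = c(1.5, 2),
                          fa_count_range = c(12, 12),
                          fa_size_meanlog = log(0.9), fa_size_sdlog = 0.15,
                          fa_elongation_range = c(1.5, 2.5))
  sc <- generate_scene(arch, scene_config(noise_sd = 0,
                                          cytosolic_green_level = 0),
                       rng_seed = 8)
  gt <- sc$ground_truth$fa
  expect_true(all(gt$area_um2 >= 0.25))
  cell <- segment_cell(sc$channels$red)
  fa <- segment_focal_adhesions(sc$channels$green, cell,
                                pixel_size = sc$pixel_size)
  expect_equal(sum(fa$maturity == "mature"), nrow(gt))
  # doubling the pixel size quadruples every reported area
  fa2 <- triage_fa_components(sc$ground_truth$cell_mask, 0.2)
  fa4 <- triage_fa_components(sc$ground_truth$cell_mask, 0.4)
  expect_equal(fa4$area_um2, 4 * fa2$area_um2)
})
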