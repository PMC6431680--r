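test_that("scene generation is bit-identical under a fixed seed", {
  arch <- small_archetype()
  s1 <- generate_scene(arch, tiny_config(), rng_seed = 5)
  s2 <- generate_scene(arch, tiny_config(), rng_seed = 5)
  expect_identical(s1, s2)
  s3 <- generate_scene(arch, tiny_config(), rng_seed = 6)
  expect_false(identical(s1$channels$green, s3$channels$green))
  # generation does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(generate_scene(arch, tiny_config(), rng_seed = 2))
  expect_identical(rnorm(3), before)
})

test_that("scenes honour the rendering contract", {
  sc <- generate_scene(default_archetypes()$B, scene_config(), rng_seed = 4)
  gt <- sc$ground_truth
  expect_identical(dim(sc$channels$red), dim(sc$channels$green))
  expect_identical(dim(sc$channels$red), dim(sc$channels$blue))
  # ground-truth FA centroids lie inside the cell mask
  px <- sc$pixel_size
  rc <- cbind(round(gt$fa$row), round(gt$fa$col))
  expect_true(all(gt$cell_mask[rc]))
  # nucleus inside cell, blue confined to nucleus
  expect_true(all(gt$cell_mask[gt$nucleus_mask]))
  # noise-free, cytosol-free scene: green exactly zero outside FA pixels
  clean <- generate_scene(small_archetype(),
                          tiny_config(noise_sd = 0,
                                      cytosolic_green_level = 0),
                          rng_seed = 9)
  fa_px <- clean$channels$green > 0
  gt_area <- sum(clean$ground_truth$fa$pixel_count)
  expect_equal(sum(fa_px), gt_area)
})

test_that("an oversized cell fails with an informative error", {
  big <- class_archetype("A", cell_area_range = c(5000, 6000),
                         fa_count_range = c(2, 3),
                         fa_size_meanlog = log(0.5), fa_size_sdlog = 0.5,
                         fa_elongation_range = c(1, 2))
  expect_error(generate_scene(big, tiny_config(), rng_seed = 1),
               "does not fit")
})

test_that("z-stacks max-project back to the attenuation-free scene", {
  cfg2 <- tiny_config(z_planes = 5L, noise_sd = 0)
  sc <- generate_scene(small_archetype(), cfg2, rng_seed = 3)
  expect_equal(length(dim(sc$channels$red)), 3)
  flat <- generate_scene(small_archetype(), tiny_config(noise_sd = 0),
                         rng_seed = 3)
  mp <- max_projection(sc$channels$red)
  expect_equal(dim(mp), dim(flat$channels$red))
})

test_that("populations have the right size, labels, and class-variance structure", {
  pop <- generate_population(1, scene_config(), master_seed = 2)
  expect_length(pop, 4)
  expect_equal(vapply(pop, `[[`, "", "class_label"), c("A", "B", "C", "D"))
  arcs <- default_archetypes()
  areas <- function(lab, n) vapply(seq_len(n), function(i) {
    sum(generate_scene(arcs[[lab]], scene_config(),
                       rng_seed = 5000 + i)$ground_truth$cell_mask)
  }, numeric(1))
  aA <- areas("A", 25); aB <- areas("B", 25)
  expect_gt(var(aB), var(aA))   # class B is the high-variance mixture
})

test_that("archetype orderings hold on ground-truth masks", {
  arcs <- default_archetypes()
  n_ok_sol <- 0L; n_ok_area <- 0L; n <- 15L
  for (i in seq_len(n)) {
    sA <- generate_scene(arcs$A, scene_config(), rng_seed = 600 + i)
    sD <- generate_scene(arcs$D, scene_config(), rng_seed = 600 + i)
    sC <- generate_scene(arcs$C, scene_config(), rng_seed = 600 + i)
    if (solidity(sD$ground_truth$cell_mask) <
        solidity(sA$ground_truth$cell_mask)) n_ok_sol <- n_ok_sol + 1L
    if (sum(sC$ground_truth$cell_mask) <
        min(sum(sA$ground_truth$cell_mask),
            sum(sD$ground_truth$cell_mask))) n_ok_area <- n_ok_area + 1L
  }
  expect_gte(n_ok_sol / n, 0.95)
  expect_gte(n_ok_area / n, 0.95)
})

test_that("class-D FA ground truth covers all three maturity bins", {
  arcs <- default_archetypes()
  mats <- unlist(lapply(1:50, function(i) {
    generate_scene(arcs$D, scene_config(),
                   rng_seed = 900 + i)$ground_truth$fa$maturity
  }))
  expect_setequal(unique(mats), c("background", "nascent", "mature"))
})

test_that("sampled feature tables are deterministic with prescribed structure", {
  t1 <- sample_feature_table(10, "paper_like", seed = 7)
  t2 <- sample_feature_table(10, "paper_like", seed = 7)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 40)
  # orderings by construction
  mu <- aggregate(. ~ class, t1[, c("class", feature_names())], mean)
  expect_equal(as.character(mu$class[which.min(mu$cell_area)]), "C")
  expect_equal(as.character(mu$class[which.min(mu$ellipticity)]), "D")
  expect_equal(as.character(mu$class[which.max(mu$fa_size)]), "D")
  expect_equal(as.character(mu$class[which.min(mu$g_function)]), "D")
  expect_error(sample_feature_table(10, "bogus"), "arg")
})

test_that("strong separation is near-perfectly classifiable, weak is at chance", {
  st <- sample_feature_table(40, "strong", seed = 3)
  acc <- classify_confinement(st, "ABCD", seed = 3)$average_accuracy
  expect_gte(acc, 95)
  accs <- vapply(1:20, function(s) {
    wk <- sample_feature_table(10, "weak", seed = s)
    x <- as.matrix(wk[, feature_names()])
    cross_validated_svm(x, wk$class, k = 5, seed = s,
                        scaling = "within_fold")$average_accuracy
  }, numeric(1))
  # binomial check: mean accuracy consistent with 25% chance
  n_total <- 20 * 40
  se <- sqrt(0.25 * 0.75 / n_total) * 100
  expect_lt(abs(mean(accs) - 25), 4 * se + 2)
})
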