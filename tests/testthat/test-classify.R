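test_that("z-scoring centers, scales, and is idempotent and affine invariant", {
  z <- zscore(cbind(a = c(2, 4, 6)))
  expect_equal(as.vector(z), c(-1, 0, 1))
  set.seed(3)
  x <- matrix(rnorm(60, 5, 3), 20)
  z1 <- zscore(x)
  expect_lt(max(abs(colMeans(z1))), 1e-9)
  expect_lt(max(abs(apply(z1, 2, sd) - 1)), 1e-9)
  expect_lt(max(abs(zscore(z1) - z1)), 1e-9)
  expect_lt(max(abs(zscore(3 * x + 7) - z1)), 1e-9)
  expect_error(zscore(cbind(const = rep(1, 5), ok = 1:5)), "const")
})

test_that("well-separated two-class data is classified perfectly", {
  set.seed(3)
  x <- rbind(matrix(rnorm(40 * 3), 40), matrix(rnorm(40 * 3, mean = 10), 40))
  y <- rep(c("a", "b"), each = 40)
  rep_ <- cross_validated_svm(zscore(x), y, k = 5, seed = 3)
  expect_equal(rep_$average_accuracy, 100)
  expect_equal(rep_$average_accuracy, mean(rep_$fold_accuracy))
  expect_equal(as.vector(rowSums(rep_$confusion)), as.vector(table(y)))
  expect_equal(sum(rep_$confusion), length(y))
})

test_that("label-shuffled data stays at chance level (leakage guard)", {
  set.seed(8)
  x <- matrix(rnorm(80 * 7), 80)
  y <- factor(rep(c("A", "B", "C", "D"), each = 20))
  accs <- vapply(1:20, function(s) {
    set.seed(s)
    ys <- sample(y)
    cross_validated_svm(x, ys, k = 5, seed = s,
                        scaling = "within_fold")$average_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 25), 3)
  expect_lt(max(accs), 25 + 10 + 15)  # no single run wildly above chance
})

test_that("fold assignment and reports are reproducible under a fixed seed", {
  tab <- sample_feature_table(10, "paper_like", seed = 2)
  x <- zscore(as.matrix(tab[, feature_names()]))
  r1 <- cross_validated_svm(x, tab$class, k = 5, seed = 9)
  r2 <- cross_validated_svm(x, tab$class, k = 5, seed = 9)
  expect_identical(r1$fold_accuracy, r2$fold_accuracy)
  expect_identical(r1$confusion, r2$confusion)
  expect_error(cross_validated_svm(x[1:8, ], tab$class[1:8], k = 5),
               "two classes")
  expect_error(cross_validated_svm(x[1:12, ], tab$class[1:12], k = 5),
               "k")
})

test_that("class merging relabels, drops, and validates", {
  y <- rep(c("A", "B", "C", "D"), each = 22)
  m <- merge_classes(y, c(A = "ABC", B = "ABC", C = "ABC", D = "D"))
  expect_equal(as.vector(table(m$labels)), c(66, 22))
  d <- merge_classes(y, c(A = "A", C = "C", D = "D"))
  expect_equal(length(d$labels), 66)
  expect_equal(nlevels(d$labels), 3)
  expect_error(merge_classes(y, c(E = "X")), "unknown")
})

test_that("univariate F scores match the ANOVA identity and closed forms", {
  x <- cbind(f = c(1, 2, 3, 4, 5, 6))
  y <- rep(c("g1", "g2"), each = 3)
  expect_equal(univariate_f_scores(x, y)$f_score, 13.5, tolerance = 1e-12)
  same <- cbind(f = c(1, 2, 3, 1, 2, 3))
  expect_equal(univariate_f_scores(same, y)$f_score, 0)
  expect_equal(univariate_f_scores(x + 100, y)$f_score, 13.5,
               tolerance = 1e-12)
  # oracle: stats::anova on random small tables
  set.seed(14)
  for (rep_i in 1:5) {
    n <- sample(6:30, 1)
    xx <- matrix(rnorm(3 * n), n)
    colnames(xx) <- paste0("v", 1:3)
    yy <- factor(sample(c("p", "q"), n, replace = TRUE))
    if (min(table(yy)) < 2) next
    us <- univariate_f_scores(xx, yy)
    for (j in 1:3) {
      fo <- stats::anova(stats::lm(xx[, j] ~ yy))[["F value"]][1]
      expect_lt(abs(us$f_score[us$feature == paste0("v", j)] - fo), 1e-10)
    }
  }
  # ranking is descending with stable column-order tie-break
  xt <- cbind(a = c(1, 1, 2, 2), b = c(1, 1, 2, 2))
  r <- univariate_f_scores(xt, c("u", "u", "v", "v"))
  expect_equal(r$feature, c("a", "b"))
})

test_that("coefficient of variation matches its definition and invariances", {
  expect_equal(coefficient_of_variation(c(8, 10, 12)), 20)
  expect_equal(coefficient_of_variation(rep(4, 5)), 0)
  v <- c(3, 5, 9, 11)
  expect_equal(coefficient_of_variation(7 * v), coefficient_of_variation(v))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("group comparison reproduces the F = t^2 identity and null behavior", {
  set.seed(6)
  a <- rnorm(15, 1); b <- rnorm(12, 2)
  gc <- group_compare(c(a, b), rep(c("a", "b"), c(15, 12)))
  tt <- stats::t.test(a, b, var.equal = TRUE)$statistic
  expect_equal(gc$anova$f, unname(tt^2), tolerance = 1e-10)
  ident <- group_compare(rep(c(1, 2, 3), 4),
                         rep(c("w", "x", "y", "z"), each = 3))
  expect_lt(ident$anova$f, 1e-10)
  expect_true(all(ident$tukey$p_adj > 0.99))
  expect_equal(nrow(ident$tukey), choose(4, 2))
  expect_error(group_compare(1:3, c("a", "a", "b")), ">= 2")
})

test_that("paper-like feature tables separate C from A on cell area with power", {
  hits <- 0L
  for (s in 1:25) {
    tab <- sample_feature_table(22, "paper_like", seed = 3000 + s)
    gc <- group_compare(tab$cell_area, tab$class)
    p_ca <- gc$tukey$p_adj[grepl("C", gc$tukey$comparison) &
                           grepl("A", gc$tukey$comparison)]
    if (p_ca < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 25, 0.9)
})

test_that("task accuracies reproduce the confinement-task ordering on sampled tables", {
  tab <- sample_feature_table(22, "paper_like", seed = 5)
  a4 <- classify_confinement(tab, "ABCD", seed = 1)$average_accuracy
  a3 <- classify_confinement(tab, "ACD", seed = 1)$average_accuracy
  a2 <- classify_confinement(tab, "ABCvD", seed = 1)$average_accuracy
  expect_gt(a3, a4)
  expect_gte(a2, a3)
})
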