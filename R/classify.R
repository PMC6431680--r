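# Confinement-state classification: z-scoring, cross-validated linear
# SVM, class merging, univariate ANOVA-F feature ranking, coefficient of
# variation, and one-way ANOVA + Tukey group comparison.

#' Z-score a feature matrix
#'
#' Centers and scales every column to zero mean and unit sample
#' standard deviation (n - 1).
#'
#' @param x numeric matrix or data.frame of features (>= 2 rows).
#' @return matrix of the same shape with attribute
#'   `scaling_state = "zscored"`.
#' @export
zscore <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need >= 2 rows to z-score", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  out <- scale(x, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "scaling_state") <- "zscored"
  out
}

# Seeded fold assignment; stratified by class unless stratify = FALSE.
make_folds <- function(labels, k, seed, stratify = TRUE) {
  n <- length(labels)
  with_seed(seed, {
    fold <- integer(n)
    if (stratify) {
      for (lv in levels(labels)) {
        idx <- which(labels == lv)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      fold <- sample(rep_len(seq_len(k), n))
    }
    fold
  })
}

#' Cross-validated linear SVM classification
#'
#' Trains a maximum-margin linear-kernel support vector machine
#' (multi-class by one-vs-one majority vote) and assesses it by k-fold
#' cross-validation: for each fold, the model is fitted on the
#' out-of-fold rows and evaluated on the in-fold rows. The reported
#' accuracy is the average percentage of correctly classified in-fold
#' data over folds; the confusion matrix pools out-of-fold predictions.
#'
#' The matrix is expected to be z-scored beforehand (see [zscore()]);
#' alternatively `scaling = "within_fold"` fits the z-scoring on each
#' fold's training rows only (leakage-safe mode).
#'
#' @param x numeric feature matrix.
#' @param labels class labels (coerced to factor).
#' @param k number of folds (default 5).
#' @param seed integer seed for the fold partition.
#' @param cost soft-margin box constraint C (default 1).
#' @param stratify stratify folds by class (default TRUE).
#' @param scaling `"none"` (input already scaled) or `"within_fold"`.
#' @param task label stored in the report.
#' @return object of class `classification_report`: list with
#'   `fold_accuracy` (percent, length k), `average_accuracy` (percent),
#'   `confusion` (true x predicted counts), `task`, `seed`, `n`.
#' @export
cross_validated_svm <- function(x, labels, k = 5L, seed = 1L, cost = 1,
                                stratify = TRUE,
                                scaling = c("none", "within_fold"),
                                task = "classification") {
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  scaling <- match.arg(scaling)
  stopifnot(nrow(x) == length(labels), k >= 2)
  if (nlevels(labels) < 2)
    stop("at least two classes are required", call. = FALSE)
  if (any(table(labels) < k))
    stop("every class needs >= k members; reduce k", call. = FALSE)
  if (anyNA(x))
    stop("missing values in the feature matrix; drop incomplete cells ",
         "before classification", call. = FALSE)
  fold <- make_folds(labels, k, seed, stratify)
  pred <- factor(rep(NA_character_, nrow(x)), levels = levels(labels))
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    if (scaling == "within_fold") {
      mu <- colMeans(xtr); sdv <- apply(xtr, 2, stats::sd)
      sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
    }
    fit <- e1071::svm(xtr, labels[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    p <- stats::predict(fit, xte)
    pred[te] <- p
    acc[f] <- 100 * mean(p == labels[te])
  }
  structure(list(task = task,
                 fold_accuracy = acc,
                 average_accuracy = mean(acc),
                 confusion = table(true = labels, predicted = pred),
                 k = k, seed = as.integer(seed), cost = cost,
                 n = nrow(x)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report>", x$task, "-", x$k, "folds, n =", x$n, "\n")
  cat("average accuracy:", sprintf("%.1f%%", x$average_accuracy),
      " (folds:", paste(sprintf("%.1f", x$fold_accuracy), collapse = ", "),
      ")\n")
  print(x$confusion)
  invisible(x)
}

#' Merge and subset classes
#'
#' Relabels classes according to `merge_spec` (a named vector mapping
#' old label -> new label); rows whose class is absent from the spec are
#' dropped.
#'
#' @param labels class labels.
#' @param merge_spec named character vector, e.g.
#'   `c(A = "ABC", B = "ABC", C = "ABC", D = "D")`.
#' @return list with `labels` (factor of retained rows) and `keep`
#'   (logical index into the input).
#' @export
merge_classes <- function(labels, merge_spec) {
  labels <- as.character(labels)
  unknown <- setdiff(names(merge_spec), unique(labels))
  if (length(unknown))
    stop("merge_spec names unknown class(es): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  keep <- labels %in% names(merge_spec)
  if (!any(keep)) stop("merge result is empty", call. = FALSE)
  list(labels = factor(unname(merge_spec[labels[keep]])), keep = keep)
}

#' Univariate ANOVA-F feature ranking
#'
#' For a two-class table, scores every feature by the one-way ANOVA F
#' ratio (between-class mean square over within-class mean square) and
#' ranks features by descending score; ties keep column order.
#'
#' @param x numeric feature matrix / data.frame.
#' @param labels class labels with exactly two classes present.
#' @return data.frame with `feature`, `f_score`, `rank`, ordered by
#'   rank.
#' @export
univariate_f_scores <- function(x, labels) {
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2)
    stop("exactly two classes required", call. = FALSE)
  if (any(table(labels) < 2))
    stop("each class needs >= 2 members", call. = FALSE)
  n <- nrow(x)
  f <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    gm <- tapply(v, labels, mean)
    gn <- tapply(v, labels, length)
    ssb <- sum(gn * (gm - mean(v))^2)
    ssw <- sum((v - gm[labels])^2)
    msb <- ssb / (nlevels(labels) - 1)
    msw <- ssw / (n - nlevels(labels))
    if (msw == 0) Inf else msb / msw
  }, numeric(1))
  ord <- order(-f, seq_along(f))
  out <- data.frame(feature = colnames(x)[ord], f_score = f[ord],
                    rank = seq_along(f))
  rownames(out) <- NULL
  out
}

#' Coefficient of variation
#'
#' `100 * sample sd / |mean|`, the heterogeneity measure used to compare
#' cell populations.
#'
#' @param values numeric vector (n >= 2, nonzero mean).
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m == 0) stop("zero mean: CV undefined", call. = FALSE)
  100 * stats::sd(values) / abs(m)
}

#' One-way ANOVA with Tukey multiple comparisons
#'
#' Compares a metric across groups with one-way ANOVA and Tukey's HSD
#' pairwise comparisons (adjusted p-values with 95% confidence intervals
#' for each mean difference).
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 groups with >= 2 values each).
#' @return list with `anova` (data.frame: `f`, `p`, `df_between`,
#'   `df_within`) and `tukey` (data.frame: `comparison`, `diff`, `lwr`,
#'   `upr`, `p_adj`).
#' @export
group_compare <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop(">= 2 groups required", call. = FALSE)
  if (any(table(groups) < 2))
    stop("every group needs >= 2 values", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$groups
  tukey <- data.frame(comparison = rownames(tk),
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"])
  rownames(tukey) <- NULL
  list(anova = data.frame(f = s[["F value"]][1],
                          p = s[["Pr(>F)"]][1],
                          df_between = s[["Df"]][1],
                          df_within = s[["Df"]][2]),
       tukey = tukey)
}

#' Run one of the three confinement classification tasks
#'
#' Convenience wrapper: selects/merges classes for the task, drops
#' incomplete rows, z-scores the 7-feature matrix, and runs the
#' cross-validated linear SVM.
#'
#' Tasks: `"ABCD"` — all four classes; `"ACD"` — drop the high-variance
#' class B; `"ABCvD"` — classes A, B, C merged into one class against D.
#'
#' @param features feature table with a `class` column and the columns
#'   of [feature_names()].
#' @param task `"ABCD"`, `"ACD"` or `"ABCvD"`.
#' @param k,seed,cost,stratify passed to [cross_validated_svm()].
#' @return a `classification_report`.
#' @export
classify_confinement <- function(features,
                                 task = c("ABCD", "ACD", "ABCvD"),
                                 k = 5L, seed = 1L, cost = 1,
                                 stratify = TRUE) {
  task <- match.arg(task)
  spec <- switch(task,
    ABCD = c(A = "A", B = "B", C = "C", D = "D"),
    ACD = c(A = "A", C = "C", D = "D"),
    ABCvD = c(A = "ABC", B = "ABC", C = "ABC", D = "D"))
  fn <- feature_names()
  complete <- stats::complete.cases(features[, fn])
  features <- features[complete, , drop = FALSE]
  m <- merge_classes(features$class, spec)
  x <- zscore(as.matrix(features[m$keep, fn]))
  cross_validated_svm(x, m$labels, k = k, seed = seed, cost = cost,
                      stratify = stratify, task = task)
}
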