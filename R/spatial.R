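# Spatial-distribution statistics of mature focal adhesions: the
# perinuclear E-function with its origin-constrained slope, and the
# nearest-neighbour G-function.

#' E-function: cumulative perinuclear FA distance distribution
#'
#' Empirical cumulative distribution of the radial Euclidean distance of
#' each FA centroid from the nuclear centroid, evaluated at the n
#' empirical step points: sorted distances `d_(i)` against cumulative
#' fractions `i/n`.
#'
#' @param fa_centroids n x 2 matrix of FA centroids (x, y) in um.
#' @param nucleus_centroid length-2 numeric (x, y) in um.
#' @return list of class `e_function` with `distances` (non-decreasing)
#'   and `cumulative_fraction` (ends at 1).
#' @export
e_function <- function(fa_centroids, nucleus_centroid) {
  fa_centroids <- rbind(fa_centroids)
  if (nrow(fa_centroids) < 1) stop("at least one FA centroid required",
                                   call. = FALSE)
  d <- sort(sqrt((fa_centroids[, 1] - nucleus_centroid[1])^2 +
                 (fa_centroids[, 2] - nucleus_centroid[2])^2))
  structure(list(distances = d,
                 cumulative_fraction = seq_along(d) / length(d)),
            class = "e_function")
}

#' Cell E-slope: origin-constrained fit of the E-function
#'
#' Least-squares slope of a straight line through the origin fitted to
#' the E-function step points `(d_i, f_i)`:
#' `slope = sum(d_i * f_i) / sum(d_i^2)`. High slopes indicate FAs
#' concentrated near the nucleus; low slopes indicate body-wide FAs.
#'
#' @param e an [e_function()].
#' @return slope in 1/um.
#' @export
e_slope <- function(e) {
  stopifnot(inherits(e, "e_function"))
  d <- e$distances; f <- e$cumulative_fraction
  if (all(d == 0)) stop("all FA-nucleus distances are zero; ",
                        "origin-constrained slope is undefined",
                        call. = FALSE)
  sum(d * f) / sum(d^2)
}

#' G-function: nearest-neighbour FA distances
#'
#' For each FA centroid, the Euclidean distance to its nearest other FA.
#'
#' @param fa_centroids n x 2 matrix (n >= 2) of centroids (x, y) in um.
#' @return list of class `g_function` with `nn_distances` (length n).
#' @export
g_function <- function(fa_centroids) {
  fa_centroids <- rbind(fa_centroids)
  n <- nrow(fa_centroids)
  if (n < 2) stop("at least two FA centroids required", call. = FALSE)
  dm <- as.matrix(stats::dist(fa_centroids))
  diag(dm) <- Inf
  structure(list(nn_distances = unname(apply(dm, 1, min))),
            class = "g_function")
}

#' Cell G-function: mean nearest-neighbour distance
#'
#' @param g a [g_function()].
#' @return mean nearest-neighbour distance in um; low values indicate
#'   clustered FAs.
#' @export
cell_g <- function(g) {
  stopifnot(inherits(g, "g_function"))
  mean(g$nn_distances)
}

#' Population means of per-cell metrics
#'
#' Arithmetic mean and sample standard deviation of a per-cell metric
#' (e.g. Cell E-slope or Cell G-function) within each group, yielding
#' the population-level "mean E-slope" / "mean G-function" metrics. The
#' standard deviation of a singleton group is reported as `NA`.
#'
#' @param values numeric vector of per-cell values.
#' @param groups vector of group labels, same length.
#' @return data.frame with `group`, `n`, `mean`, `sd`.
#' @export
population_means <- function(values, groups) {
  stopifnot(length(values) == length(groups), length(values) >= 1)
  groups <- as.factor(groups)
  if (any(tapply(values, groups, length) < 1))
    stop("empty group", call. = FALSE)
  out <- data.frame(
    group = levels(groups),
    n = as.vector(table(groups)),
    mean = as.vector(tapply(values, groups, mean)),
    sd = as.vector(tapply(values, groups, stats::sd)))
  rownames(out) <- NULL
  out
}
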