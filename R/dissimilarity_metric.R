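#' Curvature-plus-topography dissimilarity metric
#'
#' Predicted perceived dissimilarity between two samples: the Euclidean
#' distance in a space spanned by the difference in rms curvature and a
#' perpendicular axis of length \code{alpha} switched on when the two
#' topographic structures differ:
#' \deqn{D_{i,j} = \sqrt{(\kappa_i - \kappa_j)^2 + (\alpha \, [topo_i \ne topo_j])^2}.}
#' \code{alpha} (mm^-1) expresses the salience of a topography mismatch
#' relative to curvature differences.
#'
#' @param kappa_i,kappa_j rms curvatures (mm^-1); vectorized.
#' @param same_topo logical, \code{TRUE} when the two samples share their
#'   topographic structure.
#' @param alpha topography-salience parameter (mm^-1, >= 0).
#' @return Dissimilarity (mm^-1).
#' @export
metric_D <- function(kappa_i, kappa_j, same_topo, alpha) {
  stopifnot(all(alpha >= 0))
  sqrt((kappa_i - kappa_j)^2 + (alpha * !same_topo)^2)
}

#' Linear alternative to the Euclidean dissimilarity metric
#'
#' \eqn{|\kappa_i - \kappa_j| + \alpha [topo_i \ne topo_j]}; a one-free-
#' parameter comparison metric that correlates more weakly with embedding
#' distances than \code{\link{metric_D}} when the data were produced by
#' the Euclidean combination.
#'
#' @inheritParams metric_D
#' @return Dissimilarity (mm^-1).
#' @export
linear_metric <- function(kappa_i, kappa_j, same_topo, alpha) {
  stopifnot(all(alpha >= 0))
  abs(kappa_i - kappa_j) + alpha * !same_topo
}

#' Full pairwise dissimilarity matrix for a set of samples
#'
#' @param kappas named vector of rms curvatures (mm^-1); names are sample ids.
#' @param topo_ids topography labels, same length/order as \code{kappas}.
#' @param alpha topography salience (mm^-1).
#' @param variant \code{"euclidean"} (\code{\link{metric_D}}) or
#'   \code{"linear"} (\code{\link{linear_metric}}).
#' @return Symmetric matrix with zero diagonal, dimnames = sample ids.
#' @export
dissimilarity_matrix <- function(kappas, topo_ids, alpha,
                                 variant = c("euclidean", "linear")) {
  variant <- match.arg(variant)
  n <- length(kappas)
  stopifnot(length(topo_ids) == n)
  ids <- names(kappas)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ki <- matrix(kappas, n, n)
  same <- outer(topo_ids, topo_ids, `==`)
  f <- if (variant == "euclidean") metric_D else linear_metric
  D <- f(ki, t(ki), same, alpha)
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  D
}

lower_pairs <- function(D) {
  idx <- which(lower.tri(D), arr.ind = TRUE)
  data.frame(i = rownames(D)[idx[, 2]], j = rownames(D)[idx[, 1]],
             value = D[idx])
}

#' Fit the topography-salience parameter alpha
#'
#' Finds the \eqn{\alpha \ge 0} maximizing the Pearson correlation
#' between the metric dissimilarities \eqn{D_{i,j}(\alpha)} and a given
#' set of embedding distances, over all unordered sample pairs.  A dense
#' grid pre-scan over \code{[0, 10 max|\Delta\kappa|]} is refined by
#' golden-section search; exact ties prefer the smaller \eqn{\alpha}.
#'
#' @param embed_distances symmetric distance matrix (dimnames = sample
#'   ids) or a vector of lower-triangle distances ordered like
#'   \code{\link{dissimilarity_matrix}}'s lower triangle.
#' @param kappas named vector of rms curvatures (mm^-1).
#' @param topo_ids topography labels aligned with \code{kappas}.
#' @param variant metric variant to fit.
#' @param grid_n points in the pre-scan grid.
#' @return An object of class \code{"metric_fit"}: list with
#'   \code{alpha}, \code{rho} (Pearson correlation at the optimum) and
#'   \code{variant}.
#' @export
fit_alpha <- function(embed_distances, kappas, topo_ids,
                      variant = c("euclidean", "linear"), grid_n = 1000) {
  variant <- match.arg(variant)
  if (is.matrix(embed_distances)) {
    if (!is.null(rownames(embed_distances)) && !is.null(names(kappas)))
      embed_distances <- embed_distances[names(kappas), names(kappas)]
    y <- embed_distances[lower.tri(embed_distances)]
  } else y <- as.numeric(embed_distances)
  n <- length(kappas)
  if (length(y) != n * (n - 1) / 2)
    stop("embed_distances must cover all ", n * (n - 1) / 2, " unordered pairs")
  if (stats::sd(y) == 0) stop("degenerate embedding distances: zero variance")
  same <- outer(topo_ids, topo_ids, `==`)[lower.tri(diag(n))]
  dk <- outer(kappas, kappas, `-`)[lower.tri(diag(n))]
  if (all(same))
    stop("all pairs share one topography; alpha is unidentifiable")
  f <- if (variant == "euclidean") {
    function(a) sqrt(dk^2 + (a * !same)^2)
  } else {
    function(a) abs(dk) + a * !same
  }
  obj <- function(a) {
    d <- f(a)
    if (stats::sd(d) == 0) return(-1)
    stats::cor(d, y)
  }
  hi <- 10 * max(abs(dk), max(y), 1e-6)
  grid <- seq(0, hi, length.out = grid_n)
  vals <- vapply(grid, obj, numeric(1))
  best <- which.max(vals)          # which.max takes the first (smallest alpha) tie
  lo_b <- grid[max(1, best - 1)]
  hi_b <- grid[min(grid_n, best + 1)]
  opt <- stats::optimize(obj, c(lo_b, hi_b), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  alpha <- opt$maximum
  rho <- opt$objective
  if (vals[best] >= rho) { alpha <- grid[best]; rho <- vals[best] }
  structure(list(alpha = alpha, rho = rho, variant = variant),
            class = "metric_fit")
}

#' @export
print.metric_fit <- function(x, ...) {
  cat(sprintf("metric_fit (%s): alpha = %.4g mm^-1, Pearson rho = %.4f\n",
              x$variant, x$alpha, x$rho))
  invisible(x)
}

#' Compare the Euclidean and linear metric variants
#'
#' Fits \code{alpha} for both variants against the same embedding
#' distances and reports both correlations.
#'
#' @inheritParams fit_alpha
#' @return Data frame with one row per variant: \code{variant},
#'   \code{alpha}, \code{rho}.
#' @export
compare_metrics <- function(embed_distances, kappas, topo_ids) {
  fits <- lapply(c("euclidean", "linear"), function(v)
    fit_alpha(embed_distances, kappas, topo_ids, variant = v))
  data.frame(variant = vapply(fits, `[[`, "", "variant"),
             alpha = vapply(fits, `[[`, 0, "alpha"),
             rho = vapply(fits, `[[`, 0, "rho"))
}
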