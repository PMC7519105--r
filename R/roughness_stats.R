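#' Height-difference correlation curve of a surface
#'
#' Computes \eqn{G(d) = \sqrt{\langle (h(r+d) - h(r))^2 \rangle / 2}},
#' averaged isotropically over all lattice offsets whose Euclidean length
#' lies within half a pixel of \eqn{d} (periodic wrap).  With the factor
#' 1/2 inside the root the large-distance plateau of \eqn{G} equals the
#' surface rms height; setting \code{normalized = FALSE} drops the factor
#' and the plateau becomes rms times \eqn{\sqrt{2}}.
#'
#' The circular average \eqn{\langle h(r) h(r+d)\rangle} is evaluated
#' exactly for every offset at once via the FFT autocorrelation theorem,
#' then binned radially, so the cost is one FFT regardless of how many
#' distances are requested.
#'
#' @param surface a \code{rough_surface}.
#' @param distances probe distances (mm), each in \code{[pitch, size/2]}.
#' @param normalized keep the 1/2 inside the root (default \code{TRUE}).
#' @param direction \code{"ring"} (isotropic average, appropriate for
#'   isotropic surfaces) or \code{"x"}/\code{"y"} (profile correlation
#'   along one axis, the right oracle for anisotropic test patterns such
#'   as a single sinusoid).
#' @return An object of class \code{"correlation_curve"}: data frame with
#'   columns \code{distance} (mm) and \code{G} (mm).
#' @export
height_correlation <- function(surface, distances, normalized = TRUE,
                               direction = c("ring", "x", "y")) {
  direction <- match.arg(direction)
  stopifnot(inherits(surface, "rough_surface"))
  h <- surface$heights
  n <- nrow(h)
  pitch <- surface$pitch
  if (any(distances < pitch))
    stop("distances below the pixel pitch (", signif(pitch, 4), " mm) are not resolvable")
  if (any(distances > surface$size / 2))
    stop("distances beyond size/2 alias under periodic wrap")
  hh <- h - mean(h)
  F <- stats::fft(hh)
  # circular covariance per offset: <h(r) h(r+d)>
  cmat <- Re(stats::fft(F * Conj(F), inverse = TRUE)) / (as.numeric(n)^2)^2
  msq <- mean(hh^2)
  k <- 0:(n - 1L)
  k <- ifelse(k < n / 2, k, k - n)
  off <- pitch * k
  dist <- switch(direction,
    ring = sqrt(outer(off^2, off^2, `+`)),
    x = outer(abs(off), ifelse(off == 0, 0, Inf), `+`),
    y = outer(ifelse(off == 0, 0, Inf), abs(off), `+`))
  G <- vapply(distances, function(d) {
    sel <- abs(dist - d) <= pitch / 2
    if (!any(sel)) return(NA_real_)
    cov_d <- mean(cmat[sel])
    v <- msq - cov_d            # = <(h(r+d)-h(r))^2> / 2
    if (!normalized) v <- 2 * v
    sqrt(max(v, 0))
  }, numeric(1))
  structure(data.frame(distance = distances, G = G),
            class = c("correlation_curve", "data.frame"))
}

#' Estimate the Hurst exponent from a correlation curve
#'
#' Least-squares slope of \eqn{\log G} versus \eqn{\log d} over a fit
#' window inside the power-law band.  The default window 0.5--1.5 mm sits
#' at the shortest spectral wavelength (below which the surface is smooth
#' and \eqn{G \propto d}) and well below the 7 mm rolloff, where
#' saturation of the structure function flattens the curve.  Note that
#' with barely more than one spectral decade between those cutoffs the
#' slope is an increasingly compressed (downward-biased) estimate of
#' \eqn{H} as \eqn{H} grows; see the methods vignette.
#'
#' @param curve a \code{\link{height_correlation}} result.
#' @param fit_lo,fit_hi fit window bounds (mm).
#' @return The estimated Hurst exponent (log-log slope).
#' @export
estimate_hurst <- function(curve, fit_lo = 0.5, fit_hi = 1.5) {
  stopifnot(inherits(curve, "correlation_curve"))
  sel <- curve$distance >= fit_lo & curve$distance <= fit_hi & !is.na(curve$G)
  if (sum(sel) < 3) stop("need at least 3 curve points inside the fit window")
  if (any(curve$G[sel] <= 0)) stop("non-positive correlation values in fit window")
  fit <- stats::lm(log(G) ~ log(distance), data = curve[sel, ])
  unname(stats::coef(fit)[2])
}

shift_mat <- function(m, by, margin) {
  n <- dim(m)[margin]
  idx <- ((seq_len(n) - 1 + by) %% n) + 1
  if (margin == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
}

#' Root-mean-square curvature of a surface
#'
#' \eqn{\kappa = \sqrt{\langle (\partial^2 h/\partial x^2)^2 +
#' (\partial^2 h/\partial y^2)^2 \rangle}} using central second
#' differences at the grid pitch.  The mixed derivative is deliberately
#' excluded.  With \code{periodic = TRUE} (default, appropriate for
#' FFT-synthesized surfaces) the stencil wraps; otherwise boundary rows
#' and columns are trimmed.
#'
#' @param surface a \code{rough_surface}.
#' @param periodic wrap the stencil at the boundaries.
#' @return rms curvature (mm^-1).
#' @export
rms_curvature <- function(surface, periodic = TRUE) {
  stopifnot(inherits(surface, "rough_surface"))
  h <- surface$heights
  p2 <- surface$pitch^2
  hxx <- (shift_mat(h, -1, 1) - 2 * h + shift_mat(h, 1, 1)) / p2
  hyy <- (shift_mat(h, -1, 2) - 2 * h + shift_mat(h, 1, 2)) / p2
  if (!periodic) {
    n <- nrow(h); m <- ncol(h)
    hxx <- hxx[2:(n - 1), 2:(m - 1)]
    hyy <- hyy[2:(n - 1), 2:(m - 1)]
  }
  sqrt(mean(hxx^2 + hyy^2))
}

#' Root-mean-square slope of a surface
#'
#' rms of the gradient magnitude, from central first differences on both
#' axes.
#'
#' @inheritParams rms_curvature
#' @return rms slope (dimensionless).
#' @export
rms_slope <- function(surface, periodic = TRUE) {
  stopifnot(inherits(surface, "rough_surface"))
  h <- surface$heights
  tp <- 2 * surface$pitch
  hx <- (shift_mat(h, -1, 1) - shift_mat(h, 1, 1)) / tp
  hy <- (shift_mat(h, -1, 2) - shift_mat(h, 1, 2)) / tp
  if (!periodic) {
    n <- nrow(h); m <- ncol(h)
    hx <- hx[2:(n - 1), 2:(m - 1)]
    hy <- hy[2:(n - 1), 2:(m - 1)]
  }
  sqrt(mean(hx^2 + hy^2))
}

#' Roughness summary table for a sample set
#'
#' Per-surface rms curvature, rms slope and height correlation at
#' 0.75 mm, plus the Pearson correlations among the three columns (the
#' three micro-roughness proxies are expected to be near-collinear).
#'
#' @param samples a \code{sample_set}.
#' @param corr_distance distance (mm) at which the height correlation is
#'   reported (default 0.75 mm).
#' @return Data frame (class \code{"roughness_summary"}) with columns
#'   \code{id}, \code{topo_id}, \code{hurst}, \code{kappa},
#'   \code{rms_slope}, \code{g_corr}; attribute \code{"correlations"}
#'   holds the pairwise Pearson r values.
#' @export
roughness_summary <- function(samples, corr_distance = 0.75) {
  stopifnot(inherits(samples, "sample_set"))
  labels <- sample_labels(samples)
  rows <- lapply(seq_len(nrow(labels)), function(i) {
    surf <- samples[[labels$id[i]]]
    g <- height_correlation(surf, corr_distance)$G
    data.frame(id = labels$id[i], topo_id = labels$topo_id[i],
               hurst = labels$hurst[i], kappa = rms_curvature(surf),
               rms_slope = rms_slope(surf), g_corr = g)
  })
  out <- do.call(rbind, rows)
  cors <- c(kappa_g = stats::cor(out$kappa, out$g_corr),
            kappa_slope = stats::cor(out$kappa, out$rms_slope),
            g_slope = stats::cor(out$g_corr, out$rms_slope))
  structure(out, correlations = cors,
            class = c("roughness_summary", "data.frame"))
}
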