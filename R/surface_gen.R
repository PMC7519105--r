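#' Specification of a band-limited self-affine roughness spectrum
#'
#' Describes the isotropic roughness spectrum from which surfaces are
#' synthesized: a plateau of equal-amplitude modes at long wavelengths
#' (between \code{lambda_long} and \code{lambda_roll}) followed by a
#' power-law decay down to \code{lambda_short}.  In the power-law band the
#' mode amplitude scales as \eqn{q^{-1-H}} with wavevector magnitude
#' \eqn{q}, i.e. the isotropic power spectral density scales as
#' \eqn{q^{-2-2H}}, where \eqn{H} is the Hurst roughness exponent.
#'
#' Defaults reproduce the study conditions: a 1024 x 1024 grid over
#' 50 x 50 mm, wavelengths from 0.5 mm up to 25 mm with the plateau
#' between 7 mm and 25 mm, and rms height normalized to 0.4 mm.
#'
#' @param grid_n points per side (power of two).
#' @param size physical side length (mm).
#' @param lambda_long longest wavelength in the spectrum (mm).
#' @param lambda_roll rolloff wavelength separating plateau from power law (mm).
#' @param lambda_short shortest wavelength (mm).
#' @param hurst Hurst exponent, in (0, 1).
#' @param target_rms rms height after normalization (mm).
#' @return An object of class \code{"spectrum_spec"}.
#' @export
spectrum_spec <- function(grid_n = 1024L, size = 50, lambda_long = 25,
                          lambda_roll = 7, lambda_short = 0.5,
                          hurst = 0.6, target_rms = 0.4) {
  grid_n <- as.integer(grid_n)
  if (grid_n < 4L || bitwAnd(grid_n, grid_n - 1L) != 0L)
    stop("grid_n must be a power of two >= 4")
  if (!(lambda_short > 0 && lambda_short < lambda_roll &&
        lambda_roll < lambda_long && lambda_long <= size))
    stop("invalid cutoff ordering: need 0 < lambda_short < lambda_roll < lambda_long <= size")
  if (hurst <= 0 || hurst >= 1) stop("hurst must lie in (0, 1)")
  if (target_rms <= 0) stop("target_rms must be positive")
  structure(list(grid_n = grid_n, size = size, lambda_long = lambda_long,
                 lambda_roll = lambda_roll, lambda_short = lambda_short,
                 hurst = hurst, target_rms = target_rms),
            class = "spectrum_spec")
}

# Signed wavevector components (mm^-1) for the FFT grid, 0-based index
# k mapped to k for k < n/2 and k - n otherwise.
wavevector_components <- function(grid_n, size) {
  k <- 0:(grid_n - 1L)
  k <- ifelse(k < grid_n / 2, k, k - grid_n)
  2 * pi * k / size
}

#' Build the discrete amplitude spectrum for a surface specification
#'
#' Evaluates the mode amplitude on the full FFT wavevector grid: constant
#' over the plateau band, \eqn{\propto (q/q_{roll})^{-1-H}} in the
#' power-law band (continuous at the rolloff), and zero elsewhere,
#' including at \eqn{q = 0}.  The absolute amplitude scale is arbitrary
#' because synthesized surfaces are rescaled to \code{target_rms}.
#'
#' @param spec a \code{\link{spectrum_spec}}.
#' @return An object of class \code{"spectrum_table"}: a list with the
#'   wavevector-magnitude matrix \code{q} (mm^-1) and the amplitude
#'   matrix \code{amplitude}, both \code{grid_n x grid_n}.
#' @export
build_spectrum <- function(spec) {
  stopifnot(inherits(spec, "spectrum_spec"))
  qv <- wavevector_components(spec$grid_n, spec$size)
  q <- sqrt(outer(qv^2, qv^2, `+`))
  q_long <- 2 * pi / spec$lambda_long
  q_roll <- 2 * pi / spec$lambda_roll
  q_short <- 2 * pi / spec$lambda_short
  eps <- 1e-12
  amp <- matrix(0, spec$grid_n, spec$grid_n)
  plateau <- q >= q_long * (1 - eps) & q <= q_roll * (1 + eps)
  powerlaw <- q > q_roll * (1 + eps) & q <= q_short * (1 + eps)
  amp[plateau] <- 1
  amp[powerlaw] <- (q[powerlaw] / q_roll)^(-1 - spec$hurst)
  structure(list(q = q, amplitude = amp, spec = spec),
            class = "spectrum_table")
}

#' Draw a conjugate-symmetric random phase set
#'
#' Phases are uniform on \eqn{[0, 2\pi)} for independent modes and obey
#' \eqn{\phi(-q) = -\phi(q)} so that synthesized heights are real.
#' Self-conjugate modes (DC and Nyquist lines) get phase zero.  The same
#' seed always regenerates the identical phase set; surfaces sharing a
#' phase set share their topographic structure.
#'
#' @param seed integer RNG seed identifying the topography.
#' @param spec a \code{\link{spectrum_spec}} (only \code{grid_n} matters).
#' @return An object of class \code{"phase_set"} with elements
#'   \code{seed} and the \code{grid_n x grid_n} matrix \code{phases}.
#' @export
sample_phases <- function(seed, spec) {
  stopifnot(inherits(spec, "spectrum_spec"))
  n <- spec$grid_n
  phi <- with_preserved_rng(seed, matrix(stats::runif(n * n, 0, 2 * pi), n, n))
  i <- rep(0:(n - 1L), times = n)       # row (x) index, column-major order
  j <- rep(0:(n - 1L), each = n)        # col (y) index
  ic <- (n - i) %% n
  jc <- (n - j) %% n
  pos <- i + j * n + 1L
  cpos <- ic + jc * n + 1L
  selfconj <- pos == cpos
  mirror <- pos > cpos                  # canonical partner has the smaller index
  phi[mirror] <- (2 * pi - phi[cpos[mirror]]) %% (2 * pi)
  phi[selfconj] <- 0
  structure(list(seed = as.integer(seed), phases = phi, grid_n = n),
            class = "phase_set")
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

rms <- function(x) sqrt(mean(x^2))

#' Synthesize a rough surface from a spectrum and a phase set
#'
#' Builds the complex mode array \eqn{A(q) e^{i\phi(q)}}, inverts it with
#' the FFT (periodic boundaries), subtracts the mean and rescales the
#' heights so the rms height equals \code{target_rms}.
#'
#' @param table a \code{\link{build_spectrum}} result.
#' @param phases a \code{\link{sample_phases}} result on the same grid.
#' @param target_rms rms height (mm); defaults to the spec's value.
#' @param label optional list with \code{topo_id} and \code{hurst} tags.
#' @return An object of class \code{"rough_surface"}: list with
#'   \code{heights} (mm, \code{grid_n x grid_n}), \code{pitch} (mm),
#'   \code{size} (mm), \code{label} and \code{provenance}.
#' @export
synthesize_surface <- function(table, phases, target_rms = NULL, label = NULL) {
  stopifnot(inherits(table, "spectrum_table"), inherits(phases, "phase_set"))
  n <- table$spec$grid_n
  if (phases$grid_n != n) stop("phase set and spectrum table use different grids")
  if (is.null(target_rms)) target_rms <- table$spec$target_rms
  if (all(table$amplitude == 0))
    stop("degenerate surface: spectrum has no nonzero mode, cannot normalize")
  z <- table$amplitude * exp(1i * phases$phases)
  h <- Re(stats::fft(z, inverse = TRUE)) / n   # scale immaterial, rms-normalized below
  h <- h - mean(h)
  h <- h * (target_rms / rms(h))
  structure(list(heights = h, pitch = table$spec$size / n,
                 size = table$spec$size, label = label,
                 provenance = list(seed = phases$seed,
                                   hurst = table$spec$hurst,
                                   spec = table$spec)),
            class = "rough_surface")
}

#' @export
print.rough_surface <- function(x, ...) {
  cat(sprintf("rough_surface: %d x %d heights over %.3g x %.3g mm (pitch %.4g mm)\n",
              nrow(x$heights), ncol(x$heights), x$size, x$size, x$pitch))
  cat(sprintf("  rms height %.4g mm; seed %s; H = %s\n", rms(x$heights),
              x$provenance$seed %||% "?", x$provenance$hurst %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the 3 x 3 matrix of study samples
#'
#' Produces nine surfaces: three topographic families (one random phase
#' set each, identified by seed) crossed with three Hurst exponents.
#' Surfaces in one family share the identical phase sequence, so their
#' large-scale topography coincides while the small-scale roughness
#' differs; each surface is rms-normalized individually.
#'
#' @param seeds three distinct integer seeds, one per topographic family.
#' @param hursts three Hurst exponents (defaults 0.4, 0.6, 0.8).
#' @param spec base \code{\link{spectrum_spec}}; its \code{hurst} field is
#'   overridden per surface.
#' @return An object of class \code{"sample_set"}: a named list of nine
#'   \code{rough_surface} objects (names like \code{"T1_H0.4"}) with a
#'   \code{labels} data frame attribute (columns \code{id},
#'   \code{topo_id}, \code{hurst}).
#' @export
generate_sample_matrix <- function(seeds, hursts = c(0.4, 0.6, 0.8),
                                   spec = spectrum_spec()) {
  if (length(seeds) != 3L || anyDuplicated(seeds))
    stop("need exactly three distinct seeds (one per topographic family)")
  if (length(hursts) != 3L) stop("need exactly three Hurst exponents")
  surfaces <- list()
  labels <- NULL
  for (t in seq_along(seeds)) {
    phases <- sample_phases(seeds[t], spec)
    topo_id <- paste0("T", t)
    for (h in hursts) {
      s <- spec
      s$hurst <- h
      surf <- synthesize_surface(build_spectrum(s), phases,
                                 label = list(topo_id = topo_id, hurst = h))
      id <- paste0(topo_id, "_H", format(h))
      surfaces[[id]] <- surf
      labels <- rbind(labels, data.frame(id = id, topo_id = topo_id,
                                         hurst = h, seed = seeds[t]))
    }
  }
  structure(surfaces, labels = labels, class = "sample_set")
}

#' Sample labels of a sample set
#'
#' @param samples a \code{"sample_set"}.
#' @return Data frame with columns \code{id}, \code{topo_id}, \code{hurst}.
#' @export
sample_labels <- function(samples) {
  stopifnot(inherits(samples, "sample_set"))
  attr(samples, "labels")
}
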