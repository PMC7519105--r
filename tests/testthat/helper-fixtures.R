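# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small sample set for pipeline-level tests (coarse grid, fast).
small_sample_set <- function() {
  cached("small_set", function()
    generate_sample_matrix(c(11, 22, 33), spec = spectrum_spec(grid_n = 256L)))
}

small_summary <- function() {
  cached("small_summary", function() roughness_summary(small_sample_set()))
}

# Full-resolution study-default sample set (used by acceptance checks).
default_sample_set <- function() {
  cached("default_set", function()
    generate_sample_matrix(c(11, 22, 33), spec = spectrum_spec()))
}

default_summary <- function() {
  cached("default_summary", function() roughness_summary(default_sample_set()))
}

# A hand-built single-sinusoid surface h(x, y) = A cos(2 pi x / lambda),
# exact on the grid when lambda divides the side length.
sinusoid_surface <- function(grid_n = 64L, size = 64, k_mode = 4L, amp = 1) {
  x <- (0:(grid_n - 1)) * (size / grid_n)
  lambda <- size / k_mode
  h <- matrix(amp * cos(2 * pi * x / lambda), grid_n, grid_n)
  structure(list(heights = h, pitch = size / grid_n, size = size,
                 label = NULL, provenance = list(lambda = lambda, amp = amp)),
            class = "rough_surface")
}

# Roughness summary table with fabricated curvatures (fast observer tests).
fake_summary <- function(kappas = c(1.0, 2.2, 3.5, 1.3, 2.5, 3.2, 1.6, 2.8, 3.4),
                         topo = rep(c("T1", "T2", "T3"), each = 3),
                         hurst = rep(c(0.4, 0.6, 0.8), times = 3)) {
  data.frame(id = paste0(topo, "_H", hurst), topo_id = topo,
             hurst = hurst, kappa = kappas)
}
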