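test_that("spectrum plateau is H-independent and band limits are sharp", {
  s1 <- spectrum_spec(hurst = 0.4)
  s2 <- spectrum_spec(hurst = 0.8)
  t1 <- build_spectrum(s1)
  t2 <- build_spectrum(s2)
  q_roll <- 2 * pi / s1$lambda_roll
  q_long <- 2 * pi / s1$lambda_long
  q_short <- 2 * pi / s1$lambda_short
  plateau <- t1$q >= q_long & t1$q <= q_roll
  expect_true(any(plateau))
  expect_identical(t1$amplitude[plateau], t2$amplitude[plateau])
  expect_true(all(t1$amplitude[plateau] == 1))
  # no modes below the shortest wavelength or at q = 0
  expect_true(all(t1$amplitude[t1$q > q_short * (1 + 1e-9)] == 0))
  expect_identical(t1$amplitude[1, 1], 0)
})

test_that("power-law amplitude ratio across H matches the hand-computed value", {
  # with lambda_roll = 10 mm on a 50 mm grid the mode (k=10, 0) sits at
  # exactly q = 2 q_roll; amplitude ratio H=0.8 vs H=0.4 must equal
  # 2^(-1-0.8) / 2^(-1-0.4) = 2^(-0.4)
  mk <- function(h) build_spectrum(spectrum_spec(grid_n = 64L, size = 50,
                                                 lambda_long = 25, lambda_roll = 10,
                                                 lambda_short = 2, hurst = h))
  ta <- mk(0.4); tb <- mk(0.8)
  idx <- which(abs(ta$q - 2 * (2 * pi / 10)) < 1e-12)
  expect_true(length(idx) >= 2)
  expect_equal(unique(tb$amplitude[idx] / ta$amplitude[idx]),
               0.757858283255199, tolerance = 1e-12)
})

test_that("invalid configurations are rejected", {
  expect_error(spectrum_spec(lambda_short = 8, lambda_roll = 7),
               "cutoff ordering")
  expect_error(spectrum_spec(lambda_long = 60, size = 50), "cutoff ordering")
  expect_error(spectrum_spec(hurst = 1.2), "hurst")
  expect_error(spectrum_spec(grid_n = 100), "power of two")
  expect_error(generate_sample_matrix(c(1, 1, 2)), "distinct")
})

test_that("phase sets are deterministic and conjugate-symmetric", {
  spec <- spectrum_spec(grid_n = 64L)
  p1 <- sample_phases(42, spec)
  p2 <- sample_phases(42, spec)
  expect_identical(p1$phases, p2$phases)
  n <- 64L
  phi <- p1$phases
  for (probe in list(c(3, 7), c(1, 50), c(31, 2))) {
    i <- probe[1]; j <- probe[2]
    ic <- (n - i) %% n; jc <- (n - j) %% n
    s <- (phi[i + 1, j + 1] + phi[ic + 1, jc + 1]) %% (2 * pi)
    expect_lt(min(s, 2 * pi - s), 1e-12)
  }
  # full-grid reality check: synthesized field has negligible imaginary part
  tab <- build_spectrum(spec)
  z <- tab$amplitude * exp(1i * phi)
  h <- stats::fft(z, inverse = TRUE)
  expect_lt(max(abs(Im(h))) / max(abs(Re(h))), 1e-9)
})

test_that("phase sets from different seeds are uncorrelated", {
  spec <- spectrum_spec(grid_n = 128L)
  p1 <- sample_phases(1, spec)$phases
  p2 <- sample_phases(2, spec)$phases
  # circular correlation: mean resultant of phase differences near zero
  expect_lt(abs(mean(cos(p1 - p2))), 0.05)
  expect_lt(abs(mean(sin(p1 - p2))), 0.05)
})

test_that("synthesized surfaces are zero-mean, exactly rms-normalized, deterministic", {
  spec <- spectrum_spec(grid_n = 256L)
  tab <- build_spectrum(spec)
  ph <- sample_phases(7, spec)
  s1 <- synthesize_surface(tab, ph)
  expect_equal(mean(s1$heights), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(s1$heights^2)), 0.4, tolerance = 1e-12)
  s2 <- synthesize_surface(tab, ph)
  expect_identical(s1$heights, s2$heights)
})

test_that("an all-zero spectrum cannot be normalized", {
  spec <- spectrum_spec(grid_n = 64L)
  tab <- build_spectrum(spec)
  tab$amplitude[] <- 0
  expect_error(synthesize_surface(tab, sample_phases(1, spec)), "degenerate")
})

test_that("a single-mode spectrum synthesizes a sinusoid with peak rms*sqrt(2)", {
  spec <- spectrum_spec(grid_n = 64L, size = 64, lambda_long = 32,
                        lambda_roll = 16, lambda_short = 4, target_rms = 0.4)
  tab <- build_spectrum(spec)
  tab$amplitude[] <- 0
  tab$amplitude[5, 1] <- 1            # k = +4 along x
  tab$amplitude[64 - 4 + 1, 1] <- 1   # conjugate partner k = -4
  ph <- sample_phases(1, spec)
  ph$phases[] <- 0
  surf <- synthesize_surface(tab, ph)
  expect_equal(max(abs(surf$heights)), 0.4 * sqrt(2), tolerance = 1e-12)
  # pure function of x: columns identical
  expect_lt(max(abs(surf$heights[, 1] - surf$heights[, 33])), 1e-12)
})

test_that("sample matrix: same phases => matching large-scale topography, different phases => none", {
  ss <- small_sample_set()
  expect_length(ss, 9)
  labels <- sample_labels(ss)
  expect_identical(nrow(labels), 9L)
  lowpass <- function(surf) {
    spec <- surf$provenance$spec
    F <- stats::fft(surf$heights)
    qv <- 2 * pi * ifelse(0:(spec$grid_n - 1) < spec$grid_n / 2,
                          0:(spec$grid_n - 1),
                          0:(spec$grid_n - 1) - spec$grid_n) / spec$size
    q <- sqrt(outer(qv^2, qv^2, `+`))
    F[q > 2 * pi / spec$lambda_roll] <- 0
    Re(stats::fft(F, inverse = TRUE))
  }
  same_topo <- cor(as.vector(lowpass(ss[["T1_H0.4"]])),
                   as.vector(lowpass(ss[["T1_H0.8"]])))
  diff_topo <- cor(as.vector(lowpass(ss[["T1_H0.6"]])),
                   as.vector(lowpass(ss[["T2_H0.6"]])))
  expect_gt(same_topo, 0.95)
  expect_lt(abs(diff_topo), 0.2)
  # full-field correlation across topographies is also near zero
  expect_lt(abs(cor(as.vector(ss[["T1_H0.6"]]$heights),
                    as.vector(ss[["T3_H0.6"]]$heights))), 0.2)
})

test_that("correlation curves are identical across seeds while fields decorrelate", {
  spec <- spectrum_spec(grid_n = 128L, lambda_short = 1)
  mk <- function(seed) synthesize_surface(build_spectrum(spec),
                                          sample_phases(seed, spec))
  d <- c(1, 2, 4, 8, 16)
  g1 <- height_correlation(mk(5), d)$G
  g2 <- height_correlation(mk(6), d)$G
  expect_equal(g1, g2, tolerance = 1e-10)  # circular stats are phase-free
})
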