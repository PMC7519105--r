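# tactsurf

An R package and analysis workflow for the psychophysics of tactile
perception of randomly rough surfaces. It covers the complete
computational chain of a triplet-comparison roughness study:

1. **Surface synthesis** — band-limited self-affine surfaces whose
   *topographic structure* (random phase set) and *Hurst roughness
   exponent* H vary independently. The roughness spectrum has an
   equal-amplitude plateau at long wavelengths (7–25 mm) and a
   power-law decay, isotropic PSD ∝ q^(−2−2H), down to 0.5 mm; heights
   are rms-normalized to 0.4 mm.
2. **Roughness statistics** — height-difference correlation
   G(d) = sqrt(⟨(h(r+d)−h(r))²⟩/2), log–log slope Hurst estimates, rms
   slope, and rms curvature κ = sqrt(⟨h_xx² + h_yy²⟩).
3. **Synthetic 2AFC observer** — triplet similarity decisions generated
   from a planted dissimilarity structure with logistic decision noise,
   plus fingertip-friction trials whose mean coefficient rises linearly
   with κ (0.35 → 0.45 over κ = 1 → 3.5 mm⁻¹) and circular-sliding
   force traces (μ = sqrt(Fx²+Fy²)/Fz).
4. **Ordinal embedding** — a perceptual space recovered from the
   decisions by likelihood maximization (multi-start BFGS), with
   10-fold cross-validation over dimensionality, bootstrap reliability
   (CoV of pairwise distances), and Procrustes rotation aligning
   dimension 1 with H.
5. **Dissimilarity metric** — D_ij = sqrt((κ_i−κ_j)² + (α·[topo
   differs])²); the topography salience α is fitted by maximizing the
   Pearson correlation with embedding distances, with a linear
   one-parameter alternative for comparison.
6. **Psychometrics** — equal-count binning of the stimulus intensity
   S = |D(left,ref) − D(right,ref)| (or its friction analogue), Weibull
   fits P = 1 − 0.5·exp(−(kS)^d), just-noticeable differences at the
   0.75 level, and structural agreement rates with exact binomial
   tests.

Human decisions for such studies are typically not deposited, so the
package ships a first-class synthetic-data generator: every stage is
validated by recovering planted parameters at the study's own design
sizes (15×50 visual, 10×28 tapping, 13×28 sliding triplets from the
252 combinations of 9 samples).

## Worked example

```r
library(tactsurf)

# 3 topographies x H in {0.4, 0.6, 0.8} at study defaults (1024^2, 50 mm)
samples <- generate_sample_matrix(c(101, 202, 303))
summary <- roughness_summary(samples)
summary[1:3, c("id", "kappa", "rms_slope", "g_corr")]
#>        id    kappa rms_slope    g_corr
#>   T1_H0.4 8.351511  1.232382 0.2585412
#>   T1_H0.6 5.860150  0.958140 0.2271598
#>   T1_H0.8 4.036810  0.755761 0.2009735

# simulate a sliding-touch experiment (13 participants x 28 triplets)
cfg <- observer_config("sliding", noise_scale = 0.5, seed = 8)
dec <- simulate_experiment(cfg, summary)

# recover the perceptual space and the topography salience alpha
sp  <- fit_embedding(dec, n_dims = 3, n_starts = 12, seed = 8)
fit <- fit_alpha(space_distances(sp), setNames(summary$kappa, summary$id),
                 summary$topo_id)
fit
#> metric_fit (euclidean): alpha = 1.24 mm^-1, Pearson rho = 0.9528

# friction-based psychometric curve and JND
fr  <- simulate_friction(cfg, summary, decisions = dec)
psy <- psychometric_analysis(dec, friction = fr)
psy$fit; psy$jnd
#> weibull_fit: k = 18, d = 1.401, R = 0.943
#> [1] 0.0427772
```

The curvature column has one value per H: with deterministic mode
amplitudes and randomness only in the phases, circularly averaged
statistics are exactly phase-independent, so the three surfaces of one
H share their κ. The recovered α ≈ 1.2 mm⁻¹ sits near the planted
sliding-modality salience (0.97 mm⁻¹), and the friction JND of ≈ 0.043
means the synthetic observer reliably notices friction-coefficient
differences of about 0.04 at this noise level.

## The analysis workflow

The numbered scripts under `analysis/` run the full study pipeline on
synthetic data and write their tables to `results/`:

```sh
Rscript analysis/01_surfaces.R       # sample matrix + roughness stats
Rscript analysis/02_observers.R      # triplet decisions + friction trials
Rscript analysis/03_embedding.R      # perceptual spaces, CV, bootstrap
Rscript analysis/04_metric_fit.R     # alpha fits, metric comparison
Rscript analysis/05_psychometrics.R  # Weibull fits, JNDs, sensitivity
```

The whole sequence takes under a minute on one CPU.

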