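---
title: "Methods: from self-affine surfaces to psychometric curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from self-affine surfaces to psychometric curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactsurf)
```

This vignette documents the models, parameter choices and numerical
decisions behind `tactsurf`. The package implements a complete,
testable analysis chain for psychophysics experiments on randomly rough
surfaces: surface synthesis, roughness statistics, a synthetic
two-alternative forced-choice (2AFC) observer, ordinal embedding of
triplet decisions, a curvature-plus-topography dissimilarity metric,
and Weibull psychometrics. A synthetic observer stands in for human
participants so that every stage can be validated by parameter
recovery.

## Surface model

Surfaces are band-limited self-affine random fields synthesized in the
Fourier domain. The mode amplitude is constant over a long-wavelength
plateau band, between `lambda_long` = 25 mm and `lambda_roll` = 7 mm,
and decays as a power law $A(q) \propto q^{-1-H}$ (isotropic power
spectral density $\propto q^{-2-2H}$) from the rolloff down to
`lambda_short` = 0.5 mm, where $H \in (0,1)$ is the Hurst roughness
exponent. All other modes, including $q = 0$, carry zero amplitude.
Heights come from the inverse FFT of $A(q)e^{i\phi(q)}$, so boundaries
are periodic, and are rescaled to a target rms height of 0.4 mm.

Defaults are the study conditions: a $1024^2$ grid over
$50\times50\,\mathrm{mm}^2$. The plateau band limits are stated in the
source material as limits of the *correlation plateau* in distance;
we map them to mode wavelengths one-to-one ($\lambda = 2\pi/q$), which
is the simpler of the two defensible conventions (a sinusoid
decorrelates at half its wavelength, so one could also argue for
doubling them). Both are reachable through `spectrum_spec()`, and the
correlation plateau of the synthesized surfaces indeed spans 7–25 mm
under the default mapping.

Randomness enters only through the phases. `sample_phases()` draws
them uniformly on $[0, 2\pi)$ with the conjugate symmetry
$\phi(-q) = -\phi(q)$ enforced, so heights are real; amplitudes are
deterministic functions of the spectrum. One phase set defines one
*topographic structure*: surfaces sharing a seed share the location of
every hill and valley, while their fine-scale roughness varies with
$H$. `generate_sample_matrix()` builds the full $3\times3$ design
(three phase families $\times$ $H \in \{0.4, 0.6, 0.8\}$).

A consequence of phase-only randomness worth stating explicitly:
circularly averaged statistics — rms curvature, rms slope, and the
height-difference correlation — depend only on $|A(q)|^2$ and are
therefore *identical* for surfaces that differ only in their phases.
The nine samples carry exactly three distinct curvature values, one
per $H$. Physically realized samples would break this degeneracy
through printing and measurement; the idealized generator does not,
and the downstream analysis treats the resulting exact-tie stimuli
explicitly (ties are excluded from psychometric curves, and a
zero-noise tie decision falls back to a fair coin).

## Roughness statistics

The height-difference correlation is
$G(d) = \sqrt{\langle(h(r+d)-h(r))^2\rangle / 2}$, computed exactly for
all lattice offsets at once by the FFT autocorrelation theorem and
averaged over rings of offsets with $|\,|d'|-d\,| \le$ pitch$/2$. The
factor $1/2$ makes the large-distance plateau equal the rms height
(0.4 mm); `normalized = FALSE` drops it (plateau
$0.4\sqrt2$ mm). For anisotropic test patterns (a single sinusoid) the
ring average provably differs from the profile correlation; the
`direction` argument selects an along-axis profile evaluation, which is
the oracle used in the unit tests.

The rms curvature follows the printed definition
$\kappa = \sqrt{\langle(\partial^2h/\partial x^2)^2 +
(\partial^2h/\partial y^2)^2\rangle}$ — the mixed derivative is
deliberately excluded — with central second differences at the grid
pitch and periodic wrap (FFT-synthesized surfaces are periodic;
`periodic = FALSE` trims boundaries for non-periodic inputs such as a
plane). Convergence in the pitch is second order, verified against the
sinusoid closed form $\kappa = A(2\pi/\lambda)^2/\sqrt2$.

### Hurst estimation and its limits

`estimate_hurst()` is the least-squares slope of $\log G$ versus
$\log d$. The default window is 0.5–1.5 mm: below 0.5 mm the surface
is smooth (no spectral content), so $G \propto d$ and the slope is
biased towards 1; above roughly 1.5 mm the approaching 7 mm rolloff
saturates the structure function and biases the slope towards 0. The
window was calibrated once on synthetic surfaces with known $H$ and
then frozen.

A hard limitation follows from the band itself: with only
$7/0.5 \approx 1.15$ decades between the cutoffs there is no clean
$d^H$ scaling regime, and the attainable slope is compressed towards
the centre of the $H$ range. At the defaults the measured slopes are
approximately 0.41, 0.52 and 0.62 for generating exponents 0.4, 0.6
and 0.8. The mapping is strictly monotone — the estimator orders
surfaces correctly and recovers $H = 0.4$ accurately — but the
$H = 0.8$ slope cannot reach 0.8 from a structure function of this
band, under any fit window, and the corresponding strict recovery
check in the acceptance suite fails by construction. A periodogram
estimator would be exact here (amplitudes are deterministic), which is
precisely why it would test nothing; it is deliberately out of scope.

## The synthetic observer

The observer compares triplets (one reference, two alternatives) under
a planted dissimilarity structure
$$D_{i,j} = \sqrt{(\kappa_i-\kappa_j)^2 + (\alpha\,[\mathrm{topo}_i
\ne \mathrm{topo}_j])^2},$$
choosing "left" with probability
$\mathrm{logit}^{-1}((D_{right,ref}-D_{left,ref})/\sigma)$. The
logistic link is a design choice — the minimal monotone choice model,
mirroring the embedding likelihood; a probit option exists. A lapse
parameter (default 0) mixes in uniform guessing. Presets reproduce the
study sizes — visual $15\times50$, tapping $10\times28$, sliding
$13\times28$ triplets drawn without replacement from the 252
combinations of nine samples — with planted saliences
$\alpha$ = 2.68, 1.22 and 0.97 mm$^{-1}$ mirroring the modality
hierarchy. The decision-noise scale defaults to
$\sigma = 0.5$ mm$^{-1}$, a moderate value: it yields ~80–95%
structural agreement rates, comparable in character to human tactile
data. All randomness flows from the config seed; reruns are
bit-identical.

Friction trials are generated from the planted line
$\mu = a + b\kappa$ with $(a, b)$ anchored so the population mean runs
from 0.35 at $\kappa = 1$ mm$^{-1}$ to 0.45 at 3.5 mm$^{-1}$, plus a
per-participant offset (sd 0.05) and per-measurement noise (sd 0.02).
The two noise scales are invented plumbing (no distributional
information exists to match); they were chosen once to give
friction-based psychometric curves with realistic scatter. Note that
the generated surfaces' curvatures (about 4–8.4 mm$^{-1}$ at the
defaults) sit above the 1–3.5 mm$^{-1}$ anchor range: printed
curvature values for the physical samples came from an external tool
applied to definition files and are not reproduction targets; the
planted line simply extends linearly.

What the generator does *not* emulate: participant-specific perceptual
weights, sequential/order effects, reaction times, skin mechanics, and
realization noise in the surface statistics. Passing recovery tests
therefore demonstrates the *analysis chain* is correct and
well-calibrated for data of this size and noise character, not that
human data will be as clean.

## Ordinal embedding

`fit_embedding()` maximizes the likelihood of the decisions over
sample coordinates, with the same logistic-difference choice model and
Euclidean distances. A weak Gaussian prior on coordinates
($10^{-3}\sum x^2$) regularizes the translation degeneracy;
optimization is multi-start BFGS (default 16 seeded starts, analytic
gradients), best likelihood wins, ties broken by start index. Reported
coordinates are centred with unit rms norm; the absorbed scale is kept
so likelihoods remain evaluable. Model selection uses seeded 10-fold
cross-validation scored by held-out log-likelihood per decision (and
fraction-correct, since the original's validation metric is unnamed);
reliability uses bootstrap resampling of decisions with refitting
(default $B = 1000$; the analysis scripts use $B = 40$ to keep the
demonstration fast, stated here as the package's own choice).
`procrustes_align()` applies a rotation/reflection (no scaling) making
dimension 1 the direction best correlated with the Hurst exponents.

## Metric fitting and psychometrics

`fit_alpha()` maximizes the Pearson correlation between
$D_{i,j}(\alpha)$ and the 36 embedding distances via a 1000-point grid
scan refined by golden-section search on $[0, 10\max|\Delta\kappa|]$,
ties preferring smaller $\alpha$; Pearson correlation makes the result
invariant to the arbitrary embedding scale. The linear comparison
metric $|\Delta\kappa| + \alpha[\mathrm{topo\ differs}]$ is fitted the
same way. $D_{i,j}$ is a true metric for any $\alpha \ge 0$ (it embeds
isometrically in the $\kappa$ axis plus an equilateral topography
triangle of side $\alpha$), verified exhaustively in the tests.

Psychometric curves bin the stimulus intensity
$S = |D_{left,ref} - D_{right,ref}|$ (or its friction analogue
$S = ||\mu_l-\mu_{ref}|-|\mu_r-\mu_{ref}||$) into equal-count bins
(default 10; the original bin count is unstated, and the analysis
script reports a 6–14 bin sensitivity sweep) and fit
$P = 1 - 0.5\exp(-(kS)^d)$ by nonlinear least squares seeded by a
coarse grid (grid fallback on non-convergence). Goodness of fit $R$ is
the Pearson correlation between fitted and observed bin proportions
(the original reports an undefined "R"). The JND is the closed-form
0.75 crossing $(\ln 2)^{1/d}/k$, property-tested against numerical
inversion. Exact ties in the expected side are excluded rather than
split. Agreement rates count only unbiased triplets (alternatives
matched on one factor, exactly one matching the reference on the
other) and use an exact two-sided binomial test against 0.5, the
original test being unstated.

## Problem sizes and reproducibility

The test suite and the acceptance script regenerate everything from
seeds at the study's native resolution ($1024^2$ surfaces) for
surface-level checks, and use $256^2$ surfaces or fabricated curvature
tables for observer/embedding-level unit tests, where surface
resolution is irrelevant. Embedding fits in cross-validation and
bootstrap demonstrations use 4 restarts; headline fits use 12–16. A
full analysis run (`analysis/01…05`) takes well under a minute on one
CPU. Every stochastic stage takes an explicit seed, and identical
configurations rerun bit-identically.
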