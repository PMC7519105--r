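#!/usr/bin/env Rscript
# Stage 5: psychometric curves and just-noticeable differences.  For
# every modality the metric-based stimulus S = |D(left,ref) -
# D(right,ref)| (with the stage-4 fitted alpha) is binned into
# equal-count bins and fitted with the Weibull sigmoid
# P = 1 - 0.5 exp(-(kS)^d); the JND is the 0.75 crossing.  For sliding
# touch the friction-based stimulus uses the per-trial coefficients.

suppressPackageStartupMessages(library(tactsurf))

summary <- read.csv("results/roughness_summary.csv")
kappas <- setNames(summary$kappa, summary$id)
fits <- read.csv("results/metric_fits.csv")

rows <- NULL
for (m in c("visual", "tapping", "sliding")) {
  dec <- read_decisions(sprintf("results/decisions_%s.csv", m))
  alpha <- fits$alpha[fits$modality == m & fits$variant == "euclidean"]
  D <- dissimilarity_matrix(kappas, summary$topo_id, alpha)
  psy <- suppressMessages(psychometric_analysis(dec, D = D, n_bins = 10))
  cat(sprintf("%s (metric stimulus): k = %.3f, d = %.3f, R = %.3f, JND = %.3f mm^-1\n",
              m, psy$fit$k, psy$fit$d, psy$fit$R, psy$jnd))
  rows <- rbind(rows, data.frame(modality = m, stimulus = "metric",
                                 k = psy$fit$k, d = psy$fit$d,
                                 R = psy$fit$R, jnd = psy$jnd))
  write.csv(psy$curve, sprintf("results/psychometric_curve_%s.csv", m),
            row.names = FALSE)
}

dec <- read_decisions("results/decisions_sliding.csv")
fr <- read_friction("results/friction_sliding.csv")
psy_f <- suppressMessages(psychometric_analysis(dec, friction = fr, n_bins = 10))
cat(sprintf("sliding (friction stimulus): k = %.3f, d = %.3f, R = %.3f, JND = %.4f\n",
            psy_f$fit$k, psy_f$fit$d, psy_f$fit$R, psy_f$jnd))
rows <- rbind(rows, data.frame(modality = "sliding", stimulus = "friction",
                               k = psy_f$fit$k, d = psy_f$fit$d,
                               R = psy_f$fit$R, jnd = psy_f$jnd))
write.csv(psy_f$curve, "results/psychometric_curve_sliding_friction.csv",
          row.names = FALSE)
write.csv(rows, "results/weibull_fits.csv", row.names = FALSE)

# Sensitivity of the JND to the (undocumented in the original design)
# bin count.
cat("\nJND sensitivity to bin count (sliding, friction stimulus):\n")
for (nb in c(6, 8, 10, 12, 14)) {
  p <- suppressMessages(psychometric_analysis(dec, friction = fr, n_bins = nb))
  cat(sprintf("  %2d bins: JND = %.4f (R = %.3f)\n", nb, p$jnd, p$fit$R))
}
cat("Wrote results/weibull_fits.csv and per-curve CSVs\n")
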