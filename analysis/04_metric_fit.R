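#!/usr/bin/env Rscript
# Stage 4: fit the topography-salience parameter alpha of the
# dissimilarity metric D_ij against the embedding distances of each
# modality (Pearson-correlation maximization), and compare the
# Euclidean metric with the simple linear alternative.

suppressPackageStartupMessages(library(tactsurf))

summary <- read.csv("results/roughness_summary.csv")
kappas <- setNames(summary$kappa, summary$id)
coords <- read.csv("results/perceptual_spaces.csv")

fits <- NULL
for (m in c("visual", "tapping", "sliding")) {
  X <- as.matrix(coords[coords$modality == m, c("X1", "X2", "X3")])
  rownames(X) <- coords$id[coords$modality == m]
  D_embed <- as.matrix(dist(X))
  cmp <- compare_metrics(D_embed, kappas, summary$topo_id)
  cmp$modality <- m
  fits <- rbind(fits, cmp)
  eu <- cmp[cmp$variant == "euclidean", ]
  li <- cmp[cmp$variant == "linear", ]
  cat(sprintf("%s: alpha = %.3f mm^-1 (rho = %.3f); linear variant rho = %.3f\n",
              m, eu$alpha, eu$rho, li$rho))
}
write.csv(fits, "results/metric_fits.csv", row.names = FALSE)

cat("\nThe Euclidean combination correlates at least as strongly as the\n")
cat("linear one for data generated from it; the fitted alpha orders the\n")
cat("modalities by how salient a topography mismatch is relative to a\n")
cat("curvature difference.\n")
cat("Wrote results/metric_fits.csv\n")
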