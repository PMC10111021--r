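#!/usr/bin/env Rscript
# Shape encoding: supervised PLS vs unsupervised PCA on the deviation
# matrix; variance-explained-in-outcome curves, mode-variation shapes along
# the first three modes, and VIP scores.
library(lvssm)

out <- "results/encode"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cohort <- readRDS("results/align/cohort_aligned.rds")

pls <- fit_pls(cohort$deviations, cohort$outcomes, n_components = 5,
               mean_shape = cohort$mean_shape)
pca <- fit_pca(cohort$deviations, n_components = 5, y = cohort$outcomes,
               mean_shape = cohort$mean_shape)

ev_pls <- explained_variance_curve(pls, cohort$outcomes)
ev_pca <- explained_variance_curve(pca, cohort$outcomes)
write.csv(data.frame(component = 1:5,
                     pls_per_component = ev_pls$per_component,
                     pls_cumulative = ev_pls$cumulative,
                     pca_per_component = ev_pca$per_component,
                     pca_cumulative = ev_pca$cumulative),
          file.path(out, "variance_explained.csv"), row.names = FALSE)

sc <- as.data.frame(pls$scores)
names(sc) <- paste0("score_", 1:5)
write.csv(sc, file.path(out, "scores.csv"), row.names = FALSE)

for (mode in 1:3) {
  shapes <- mode_variation_meshes(pls, mode)
  for (nm in names(shapes))
    write_ply(shapes[[nm]],
              file.path(out, sprintf("mode%d_%s.ply", mode, nm)))
}

v <- vip(pls)
write.csv(data.frame(point = seq_along(v$per_point), vip = v$per_point,
                     above_threshold = v$per_point > v$threshold),
          file.path(out, "vip_per_point.csv"), row.names = FALSE)

cat("cumulative outcome variance explained (PLS):",
    sprintf("%.3f", ev_pls$cumulative), "\n")
cat("cumulative outcome variance explained (PCA):",
    sprintf("%.3f", ev_pca$cumulative), "\n")
cat(sprintf("VIP: max %.2f; %d points above %.1f\n",
            max(v$per_point), length(v$critical_points), v$threshold))
cat("outputs in", out, "\n")
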