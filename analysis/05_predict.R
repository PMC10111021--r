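#!/usr/bin/env Rscript
# Outcome prediction: linear-kernel SVR on shape scores with a leakage-safe
# per-split encoder refit, compared against PCA encoding and the bivariate
# clinical baseline (preLVMI + LVEF), plus the component-count sweep.
# Metrics are reported as medians over repeated splits because a single
# 10-subject test set is unstable.
library(lvssm)

out <- "results/predict"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cohort <- readRDS("results/align/cohort_aligned.rds")

seeds <- 1:11
runs <- lapply(seeds, function(s) list(
  pls = evaluate_prediction(cohort, "pls", 5, seed = s),
  pca = evaluate_prediction(cohort, "pca", 5, seed = s),
  base = evaluate_baseline(cohort, seed = s)))

med <- function(f) median(vapply(runs, f, numeric(1)))
summary <- data.frame(
  model = c("pls_svr", "pca_svr", "baseline"),
  rmse_test = c(med(function(r) r$pls$rmse_test),
                med(function(r) r$pca$rmse_test),
                med(function(r) r$base$rmse_test)),
  r2_test = c(med(function(r) r$pls$r2_test),
              med(function(r) r$pca$r2_test),
              med(function(r) r$base$r2_test)),
  r2_train = c(med(function(r) r$pls$r2_train),
               med(function(r) r$pca$r2_train),
               med(function(r) r$base$r2_train)))
write.csv(summary, file.path(out, "model_comparison.csv"), row.names = FALSE)

# single-split predictions for inspection
ev <- runs[[1]]$pls
pred <- data.frame(
  subject_id = c(ev$split$train, ev$split$test),
  split = rep(c("train", "test"),
              c(length(ev$split$train), length(ev$split$test))),
  y = c(ev$y[ev$split$train], ev$y[ev$split$test]),
  y_hat = c(ev$y_hat_train, ev$y_hat_test))
write.csv(pred[order(pred$subject_id), ],
          file.path(out, "predictions.csv"), row.names = FALSE)

sw <- do.call(rbind, lapply(seeds, function(s)
  cbind(seed = s, sweep_components(cohort, c(3L, 4L, 5L, 6L), seed = s))))
sw_med <- aggregate(cbind(rmse_test, r2_test, r2_train) ~ n_components,
                    data = sw, FUN = median)
write.csv(sw_med, file.path(out, "nc_sweep.csv"), row.names = FALSE)

jsonlite::write_json(list(summary = summary, nc_sweep = sw_med,
                          seeds = seeds),
                     file.path(out, "eval_report.json"),
                     auto_unbox = TRUE, digits = NA)

cat("median test metrics over", length(seeds), "splits:\n")
print(summary, row.names = FALSE)
cat("\ncomponent sweep (median over splits):\n")
print(sw_med, row.names = FALSE)
cat("outputs in", out, "\n")
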