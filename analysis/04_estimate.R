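#!/usr/bin/env Rscript
# Step 4: per-sip fluid-volume estimation.
#
# Three estimators on the liquid sips of each subject: (i) the mean-sip
# baseline (predict every sip by the subject's mean), (ii) cross-validated
# ordinary least squares with stepwise forward selection on RMSE, and
# (iii) a 15-unit tanh network trained by Levenberg-Marquardt, grown
# stepwise the same way. Reports RMSE (mL) and the mean relative estimation
# error (%), as cohort mean +/- SD across subjects.

library(swallowEMG)

seed <- 20260924
features <- read.csv("results/feature_matrix.csv")

## mean-sip baseline, per subject and across all -----------------------------
liquid <- features[features$kind == "burst" & features$volume_mL > 0, ]
baseline_tab <- mean_sip_baseline(split(liquid$volume_mL, liquid$subject))
write.csv(baseline_tab, "results/estimation_mean_sip.csv", row.names = FALSE)
across <- baseline_tab[nrow(baseline_tab), ]
cat(sprintf("mean-sip baseline: across-all mean %.2f mL (SD of means %.2f), error %.2f%%\n",
            across$mean_mL, across$sd_mL, across$error_pct))

## stepwise LR and ANN -------------------------------------------------------
run_estimator <- function(method, max_features, ...) {
  ev <- function(subset) {
    set.seed(seed)          # same folds/splits for every candidate subset
    rep <- estimate_cohort(features, subset, method, ...)
    list(metric = rep$summary$mean[rep$summary$measure == "rmse_mL"],
         per_subject = rep$per_subject$rmse_mL)
  }
  trace <- forward_select(ev, feature_names(), "minimize",
                          max_features = max_features)
  tab <- do.call(rbind, lapply(seq_len(nrow(trace$steps)), function(k) {
    set.seed(seed)
    rep <- estimate_cohort(features, trace$steps$feature[1:k], method, ...)
    s <- rep$summary
    data.frame(method = method, n_features = k,
               features = paste(trace$steps$feature[1:k], collapse = "+"),
               rmse = sprintf("%.2f +/- %.2f", s$mean[1], s$sd[1]),
               ee = sprintf("%.2f +/- %.2f", s$mean[2], s$sd[2]))
  }))
  list(trace = trace, table = tab)
}

lr <- run_estimator("lr", max_features = 3)
ann <- run_estimator("ann", max_features = 2, restarts = 2)

perf <- rbind(lr$table, ann$table)
write.csv(perf, "results/estimation_performance.csv", row.names = FALSE)
print(perf[, c("method", "features", "rmse", "ee")], row.names = FALSE)
cat(sprintf("LR stop: %s; ANN stop: %s\n", lr$trace$stopping,
            ann$trace$stopping))
cat("wrote results/estimation_performance.csv\n")
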