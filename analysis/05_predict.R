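#!/usr/bin/env Rscript
# Stage 5: BMI prediction.
#
# Per-feature simple regressions (R^2 and F-test p), then PLS1 regression
# under leave-one-subject-out cross-validation with the latent-variable
# count chosen inside every fold by inner leave-one-out PRESS (first
# non-improvement). Run three ways: combined features, structural only,
# functional only.

library(bmiconn)

data <- read_cohort("scratch/cohort")
fset <- readRDS("scratch/features.rds")
y <- data$subjects$bmi
X <- fset$X
cat(sprintf("design: %d subjects x %d features\n", nrow(X), ncol(X)))

contrib <- do.call(rbind, lapply(colnames(X), function(f) {
  r <- simple_feature_r2(X[, f], y)
  data.frame(feature = f, r_squared = r$r_squared, p_value = r$p_value)
}))
contrib <- contrib[order(-contrib$r_squared), ]
write.table(format(contrib, digits = 4), "results/05_feature_contributions.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("top single features:\n")
print(head(contrib, 5), digits = 3)

run_modality <- function(name, cols) {
  Xm <- X[, cols, drop = FALSE]
  rep <- loocv_predict(Xm, y, max_lv = min(10, ncol(Xm)))
  modal_k <- as.integer(names(sort(table(rep$per_fold_n_lv),
                                   decreasing = TRUE))[1])
  ev <- fit_plsr(Xm, y, modal_k)$explained_variance_y
  cat(sprintf("%-9s rms %.3f  pct %.2f%%  r %.4f  modal LVs %d  EV %.4f\n",
              name, rep$rms_error, rep$percent_error, rep$pearson_r,
              modal_k, ev))
  list(report = rep, modal_n_lv = modal_k, explained_variance = ev)
}

res <- list(
  combined = run_modality("combined", seq_len(ncol(X))),
  dti_only = run_modality("dti_only", which(startsWith(colnames(X), "SC:"))),
  fmri_only = run_modality("fmri_only", which(startsWith(colnames(X), "FC:")))
)

pred <- res$combined$report$predictions
pred$group <- data$subjects$group[match(pred$subject,
                                        data$subjects$subject_id)]
write.csv(pred, "results/05_predictions.csv", row.names = FALSE)

summary <- lapply(res, function(r) {
  list(rms_error = r$report$rms_error,
       percent_error = r$report$percent_error,
       pearson_r = r$report$pearson_r,
       modal_n_lv = r$modal_n_lv,
       explained_variance = r$explained_variance)
})
jsonlite::write_json(summary, "results/05_summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("wrote results/05_predictions.csv and results/05_summary.json\n")
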