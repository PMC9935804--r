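#!/usr/bin/env Rscript
# Step 4 — miscarriage-risk prediction.
#
# Trains 100-fold Monte-Carlo RF and XG-style gradient-boosting ensembles
# on the screened subset (step 3; falls back to the six selected features),
# forms the integrated classifier, and evaluates ROC / precision-
# sensitivity / confusion operating points on the balanced held-out test
# set. Writes metrics and curves under results/prediction/.

library(embryoscreen)
library(jsonlite)

seed <- 20260924L
planted <- setNames(rep(0.45, 6), unname(selected_feature_names()))
co <- generate_cohort(cohort_config(n_mc = 96, n_lb = 368,
                                    effect_map = planted, seed = seed))
sp <- split_cohort(co$labels, seed = seed)

sel_path <- "results/screening/selected_subset.json"
subset <- if (file.exists(sel_path)) {
  read_json(sel_path, simplifyVector = TRUE)$final_subset
} else {
  unname(selected_feature_names())
}

rf <- fit_ensemble(co$features[sp$train, ], co$labels[sp$train], subset,
                   model_spec("random-forest"), n_folds = 100, seed = seed,
                   profiles = co$profiles[sp$train, ])
gb <- fit_ensemble(co$features[sp$train, ], co$labels[sp$train], subset,
                   model_spec("gradient-boosting"), n_folds = 100,
                   seed = seed, profiles = co$profiles[sp$train, ])

dir.create("results/prediction", showWarnings = FALSE, recursive = TRUE)
test_x <- co$features[sp$test, ]
test_y <- co$labels[sp$test]
scores <- list(rf = predict_score(rf, test_x),
               gb = predict_score(gb, test_x),
               integrated = integrated_score(rf, gb, test_x))
metrics <- list()
for (nm in names(scores)) {
  ev <- evaluate_scores(scores[[nm]], test_y,
                        fold_aucs = if (nm == "rf") rf$val_auc
                                    else if (nm == "gb") gb$val_auc)
  write.csv(ev$roc, sprintf("results/prediction/roc_%s.csv", nm),
            row.names = FALSE)
  write.csv(ev$pr, sprintf("results/prediction/pr_%s.csv", nm),
            row.names = FALSE)
  metrics[[nm]] <- list(test_auc = ev$auc, auc_ci = ev$auc_ci,
                        precision_favoring = ev$confusion$precision_favoring[
                          c("threshold", "precision", "sensitivity")],
                        sensitivity_favoring = ev$confusion$sensitivity_favoring[
                          c("threshold", "precision", "sensitivity")])
}
metrics$validation <- list(rf = mean(rf$val_auc), gb = mean(gb$val_auc))
write_json(metrics, "results/prediction/metrics.json", auto_unbox = TRUE,
           pretty = TRUE, digits = NA)

cat("Subset (", length(subset), "): ", paste(subset, collapse = ", "),
    "\n", sep = "")
cat(sprintf("Validation AUC: RF %.3f, GB %.3f\n",
            mean(rf$val_auc), mean(gb$val_auc)))
cat(sprintf("Test AUC: RF %.3f, GB %.3f, integrated %.3f (n = %d, balanced)\n",
            auc_rank(scores$rf, test_y == "MC"),
            auc_rank(scores$gb, test_y == "MC"),
            auc_rank(scores$integrated, test_y == "MC"), length(test_y)))
pf <- metrics$integrated$precision_favoring
sf <- metrics$integrated$sensitivity_favoring
cat(sprintf("Operating points (integrated): precision-favoring thr %.2f (P %.2f, S %.2f); sensitivity-favoring thr %.2f (P %.2f, S %.2f)\n",
            pf$threshold, pf$precision, pf$sensitivity,
            sf$threshold, sf$precision, sf$sensitivity))
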