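test_that("family defaults encode the study hyperparameters", {
  gb <- model_spec("gradient-boosting")
  expect_equal(c(gb$n_trees, gb$max_depth), c(6L, 1L))
  expect_equal(gb$learning_rate, 0.25)
  rf <- model_spec("random-forest")
  expect_equal(c(rf$n_trees, rf$max_depth), c(65L, 3L))
  expect_error(model_spec(n_trees = 0), ">= 1")
  expect_error(model_spec(learning_rate = 1.5), "learning rate")
})

test_that("ensemble scores are fold-model means and stay in [0, 1]", {
  tt <- toy_table(60, p = 3, planted = c(v01 = 2), seed = 20)
  ens <- fit_ensemble(tt$table, tt$labels, c("v01", "v02"),
                      model_spec("gradient-boosting"), n_folds = 2, seed = 1)
  expect_length(ens$models, 2)
  sc <- predict_score(ens, tt$table)
  # the ensemble score is exactly the arithmetic mean of the fold scores
  per_fold <- sapply(ens$models, function(m) {
    x <- embryoscreen:::apply_impute(tt$table[, ens$subset], m$medians)
    embryoscreen:::predict_fold_model(m, ens$spec, x)
  })
  expect_equal(sc, rowMeans(per_fold), tolerance = 1e-12)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_error(predict_score(ens, tt$table[, "v02", drop = FALSE]),
               "missing required features")

  const <- tt
  const$labels <- factor(rep("MC", nrow(tt$table)), levels = c("LB", "MC"))
  expect_error(fit_ensemble(const$table, const$labels, "v01",
                            n_folds = 2, seed = 1), "constant")
})

test_that("the integrated classifier averages RF and GB scores", {
  tt <- toy_table(60, p = 2, planted = c(v01 = 1), seed = 21)
  rf <- fit_ensemble(tt$table, tt$labels, "v01",
                     model_spec("random-forest"), n_folds = 3, seed = 2)
  gb <- fit_ensemble(tt$table, tt$labels, "v01",
                     model_spec("gradient-boosting"), n_folds = 3, seed = 2)
  s <- integrated_score(rf, gb, tt$table)
  expect_equal(s, (predict_score(rf, tt$table) +
                   predict_score(gb, tt$table)) / 2)
})

test_that("every embryo appears in at least one validation fold", {
  tt <- toy_table(40, p = 2, seed = 22)
  ens <- fit_ensemble(tt$table, tt$labels, "v01", n_folds = 60, seed = 3)
  expect_true(ens$all_validated)
  expect_length(ens$val_auc, 60)
})

test_that("hyperparameter search honours its contract on degenerate inputs", {
  tt <- toy_table(60, p = 2, planted = c(v01 = 2), seed = 23)
  r1 <- search_hyperparameters(tt$table, tt$labels, "v01",
                               "gradient-boosting", budget = 1,
                               n_folds = 5, seed = 4)
  expect_s3_class(r1$spec, "model_spec")
  expect_equal(nrow(r1$trace), 1)
  r0 <- search_hyperparameters(tt$table, tt$labels, "v01",
                               "random-forest", budget = 0)
  expect_equal(r0$spec$n_trees, 65L)  # defaults on an empty budget
})

test_that("a searched spec is not materially worse than the default", {
  tt <- toy_table(120, p = 3, planted = c(v01 = 2.5), seed = 24)
  base <- mc_cv_auc("v01", tt$table, tt$labels, n_folds = 15, seed = 5)
  sr <- search_hyperparameters(tt$table, tt$labels, "v01",
                               "random-forest", budget = 8, n_folds = 15,
                               seed = 5)
  expect_gte(sr$auc, base$auc_rf - 0.02)
})

test_that("evaluation matches oracle scores and brute-force pair counting", {
  lab <- factor(c(rep("LB", 6), rep("MC", 4)), levels = c("LB", "MC"))
  y <- as.integer(lab == "MC")
  ev <- evaluate_scores(as.numeric(y), lab)
  expect_equal(ev$auc, 1)
  expect_equal(unname(ev$confusion$sensitivity_favoring$matrix["MC", "MC"]), 4)
  ev0 <- evaluate_scores(1 - y, lab)
  expect_equal(ev0$auc, 0)
  expect_error(evaluate_scores(runif(6), factor(rep("MC", 6),
               levels = c("LB", "MC"))), "single-class")

  # brute-force concordant-pair oracle with ties counted one half
  set.seed(6)
  for (i in 1:25) {
    n <- 30
    lab <- factor(ifelse(runif(n) < 0.4, "MC", "LB"), levels = c("LB", "MC"))
    if (nlevels(droplevels(lab)) < 2) next
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # many ties
    pos <- which(lab == "MC"); neg <- which(lab == "LB")
    conc <- 0
    for (a in pos) for (b in neg)
      conc <- conc + (sc[a] > sc[b]) + 0.5 * (sc[a] == sc[b])
    brute <- conc / (length(pos) * length(neg))
    expect_equal(evaluate_scores(sc, lab)$auc, brute, tolerance = 1e-12)
  }
})

test_that("confusion matrices sum to the partition size at both operating points", {
  tt <- toy_table(50, p = 2, planted = c(v01 = 1.5), seed = 25)
  ens <- fit_ensemble(tt$table, tt$labels, "v01", n_folds = 10, seed = 7)
  ev <- evaluate_scores(predict_score(ens, tt$table), tt$labels,
                        fold_aucs = ens$val_auc)
  expect_equal(sum(ev$confusion$precision_favoring$matrix), 100)
  expect_equal(sum(ev$confusion$sensitivity_favoring$matrix), 100)
  expect_length(ev$auc_ci, 2)
  expect_lte(ev$confusion$sensitivity_favoring$threshold,
             ev$confusion$precision_favoring$threshold)
})

test_that("SHAP attributions are additive and aSHAP obeys the sign rule", {
  tt <- toy_table(80, p = 3, planted = c(v01 = 1.5), seed = 26)
  ens <- fit_ensemble(tt$table, tt$labels, c("v01", "v02", "v03"),
                      model_spec("gradient-boosting"), n_folds = 5, seed = 8)
  ex <- explain_ensemble(ens, tt$table, tt$labels)
  # additivity per fold model: base + sum(phi) = margin, exactly
  for (k in seq_along(ens$models)) {
    x <- as.matrix(embryoscreen:::apply_impute(
      tt$table[, ens$subset], ens$models[[k]]$medians))
    ctr <- predict(ens$models[[k]]$model, x, predcontrib = TRUE)
    marg <- predict(ens$models[[k]]$model, x, outputmargin = TRUE)
    expect_lt(max(abs(rowSums(ctr) - marg)), 1e-6)
  }
  expect_equal(ex$margin, ex$base_value + rowSums(ex$shap), tolerance = 1e-9)
  # labels opposite to every prediction: all misclassified, aSHAP <= 0
  anti <- factor(ifelse(ex$score >= 0.5, "LB", "MC"), levels = c("LB", "MC"))
  ex_f <- explain_ensemble(ens, tt$table, anti)
  expect_true(all((ex_f$score >= 0.5) != (anti == "MC")))
  expect_true(all(ex_f$ashap <= 0))
  # a signal-free model attributes (near) nothing
  tt0 <- toy_table(80, p = 2, seed = 27)
  ens0 <- fit_ensemble(tt0$table, tt0$labels, c("v01", "v02"),
                       model_spec("gradient-boosting", n_trees = 1,
                                  min_child_weight = 1e6),
                       n_folds = 2, seed = 9)
  ex0 <- explain_ensemble(ens0, tt0$table, tt0$labels)
  expect_lt(max(abs(ex0$shap)), 1e-8)
  expect_error(explain_ensemble(fit_ensemble(tt0$table, tt0$labels, "v01",
               model_spec("random-forest"), n_folds = 2, seed = 1),
               tt0$table, tt0$labels), "gradient-boosting")
})

test_that("validation AUC agrees with test AUC (no MC-CV overfitting)", {
  # the overfitting check: across seeds, the mean validation AUC should not
  # be systematically inflated relative to the held-out balanced test AUC
  val <- tst <- numeric(6)
  planted <- c(ooplasm_r = 0.8, dlr_t2_t3 = 0.8)
  for (s in seq_along(val)) {
    co <- generate_cohort(cohort_config(n_mc = 96, n_lb = 368,
                                        effect_map = planted, seed = 40 + s))
    sp <- split_cohort(co$labels, seed = s)
    ens <- fit_ensemble(co$features[sp$train, ], co$labels[sp$train],
                        names(planted), model_spec("random-forest"),
                        n_folds = 40, seed = s)
    val[s] <- mean(ens$val_auc)
    tst[s] <- auc_rank(predict_score(ens, co$features[sp$test, ]),
                       co$labels[sp$test] == "MC")
  }
  expect_lte(abs(mean(val) - mean(tst)), 0.05)
})

test_that("the ensemble is no worse than the best single feature", {
  planted <- c(ooplasm_r = 1.0)
  co <- generate_cohort(cohort_config(n_mc = 200, n_lb = 200,
                                      effect_map = planted, seed = 50))
  best_single <- auc_rank(co$features$ooplasm_r, co$labels == "MC")
  ens <- fit_ensemble(co$features, co$labels, "ooplasm_r",
                      model_spec("random-forest"), n_folds = 40, seed = 2)
  expect_gte(mean(ens$val_auc), best_single - 0.03)
})
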