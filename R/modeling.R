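# Tree-ensemble prediction: random-forest and gradient-boosted models at the
# study hyperparameters, 100-fold Monte-Carlo cross-validated ensembles,
# score averaging, hyperparameter search, and ROC/PR/confusion evaluation.

#' Model specification for one tree-ensemble family
#'
#' Defaults are the study settings: gradient boosting with 6 trees of depth
#' 1 at learning rate 0.25; random forest with 65 trees of depth 3 and Gini
#' impurity splits.
#'
#' @param family `"random-forest"` or `"gradient-boosting"`.
#' @param n_trees,max_depth ensemble size and tree depth.
#' @param learning_rate GB shrinkage in (0, 1].
#' @param mtry_frac RF fraction of features tried per split (`NULL` =
#'   ranger's default, sqrt(p)).
#' @param min_leaf,min_split minimum terminal-node and split sizes (`NULL` =
#'   library defaults).
#' @param subsample,colsample_bytree GB row/column subsampling fractions.
#' @param min_child_weight GB minimum child weight.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("gradient-boosting", "random-forest"),
                       n_trees = NULL, max_depth = NULL, learning_rate = 0.25,
                       mtry_frac = NULL, min_leaf = NULL, min_split = NULL,
                       subsample = 1, colsample_bytree = 1,
                       min_child_weight = 1) {
  family <- match.arg(family)
  if (is.null(n_trees)) n_trees <- if (family == "gradient-boosting") 6L else 65L
  if (is.null(max_depth)) max_depth <- if (family == "gradient-boosting") 1L else 3L
  if (n_trees < 1 || max_depth < 1) stop("n_trees and max_depth must be >= 1")
  if (learning_rate <= 0 || learning_rate > 1)
    stop("learning rate must be in (0, 1]")
  structure(list(family = family, n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, mtry_frac = mtry_frac,
                 min_leaf = min_leaf, min_split = min_split,
                 subsample = subsample, colsample_bytree = colsample_bytree,
                 min_child_weight = min_child_weight),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
default_model_specs <- function() {
  list(rf = model_spec("random-forest"),
       gb = model_spec("gradient-boosting"))
}

fit_fold_model <- function(x, y, spec, seed) {
  if (spec$family == "random-forest") {
    args <- list(x = x, y = y, num.trees = spec$n_trees,
                 max.depth = spec$max_depth, probability = TRUE,
                 importance = "impurity", splitrule = "gini",
                 num.threads = 1L, seed = seed, verbose = FALSE)
    if (!is.null(spec$mtry_frac))
      args$mtry <- max(1L, floor(spec$mtry_frac * ncol(x)))
    if (!is.null(spec$min_split)) args$min.node.size <- spec$min_split
    if (!is.null(spec$min_leaf)) args$min.bucket <- spec$min_leaf
    m <- do.call(ranger::ranger, args)
    list(model = m, importance = m$variable.importance)
  } else {
    dtr <- xgboost::xgb.DMatrix(as.matrix(x),
                                label = as.integer(y == "MC"))
    params <- list(max_depth = spec$max_depth, eta = spec$learning_rate,
                   objective = "binary:logistic", nthread = 1L,
                   subsample = spec$subsample,
                   colsample_bytree = spec$colsample_bytree,
                   min_child_weight = spec$min_child_weight,
                   seed = seed)
    m <- xgboost::xgb.train(params, dtr, nrounds = spec$n_trees,
                            verbose = 0)
    imp <- stats::setNames(rep(0, ncol(x)), colnames(x))
    tab <- tryCatch(xgboost::xgb.importance(model = m),
                    error = function(e) NULL)
    if (!is.null(tab) && nrow(tab) > 0) imp[tab$Feature] <- tab$Gain
    list(model = m, importance = imp)
  }
}

predict_fold_model <- function(fit, spec, x) {
  if (spec$family == "random-forest") {
    p <- stats::predict(fit$model, data = x, num.threads = 1L)$predictions
    as.numeric(p[, "MC"])
  } else {
    as.numeric(stats::predict(fit$model, as.matrix(x)))
  }
}

# Recompute DLR columns of a fold's design matrix from regression lines
# fitted on the training-split LB embryos only (leakage control).
refit_dlr_columns <- function(x, profiles, lb_train_idx) {
  dlr_cols <- grep("^dlr_", names(x), value = TRUE)
  if (length(dlr_cols) == 0L) return(x)
  ev <- mk_events()
  for (cn in dlr_cols) {
    pair <- strsplit(sub("^dlr_", "", cn), "_", fixed = TRUE)[[1]]
    if (length(pair) != 2L || !all(pair %in% ev)) { x[[cn]] <- NA_real_; next }
    a <- profiles[[pair[1]]][lb_train_idx]
    b <- profiles[[pair[2]]][lb_train_idx]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2L || stats::var(a[ok]) == 0) { x[[cn]] <- NA_real_; next }
    slope <- stats::cov(a[ok], b[ok]) / stats::var(a[ok])
    intercept <- mean(b[ok]) - slope * mean(a[ok])
    x[[cn]] <- dlr(profiles[[pair[1]]], profiles[[pair[2]]],
                   list(slope = slope, intercept = intercept))
  }
  x
}

# Core Monte-Carlo CV driver: n_folds stratified 90/10 splits, fold-local
# median imputation (and optional fold-local DLR refitting), one model per
# fold, validation AUC per fold. Folds whose validation split would be
# single-class are redrawn (logged in `redraws`).
mc_folds <- function(x, y, spec, n_folds = 100L, seed = 1L,
                     keep_models = FALSE, profiles = NULL) {
  stopifnot(nrow(x) == length(y))
  if (nlevels(droplevels(y)) < 2L)
    stop("cannot fit: labels are constant (need both MC and LB)")
  seeds <- child_seeds(seed, n_folds)
  aucs <- numeric(n_folds)
  imp <- matrix(0, n_folds, ncol(x), dimnames = list(NULL, colnames(x)))
  models <- if (keep_models) vector("list", n_folds) else NULL
  folds <- vector("list", n_folds)
  redraws <- 0L
  for (f in seq_len(n_folds)) {
    fit <- with_seed(seeds[f], {
      repeat {
        sp <- stratified_split(y, 0.9)
        if (length(unique(y[sp$valid])) == 2L) break
        redraws <<- redraws + 1L
      }
      xf <- x
      if (!is.null(profiles))
        xf <- refit_dlr_columns(xf, profiles,
                                sp$train[y[sp$train] == "LB"])
      med <- fit_impute(xf[sp$train, , drop = FALSE])
      xf <- apply_impute(xf, med)
      fm <- fit_fold_model(xf[sp$train, , drop = FALSE], y[sp$train],
                           spec, seeds[f])
      pv <- predict_fold_model(fm, spec, xf[sp$valid, , drop = FALSE])
      list(fm = fm, med = med, split = sp,
           auc = auc_rank(pv, y[sp$valid] == "MC"))
    })
    aucs[f] <- fit$auc
    imp[f, ] <- fit$fm$importance[colnames(x)]
    folds[[f]] <- fit$split
    if (keep_models) models[[f]] <- list(model = fit$fm$model,
                                         medians = fit$med)
  }
  list(val_auc = aucs, importance = colMeans(imp, na.rm = TRUE),
       models = models, folds = folds, redraws = redraws, seeds = seeds)
}

#' Fit a Monte-Carlo cross-validated ensemble predictor
#'
#' Runs `n_folds` stratified 90/10 train/validation fits of one model
#' family on the chosen feature subset, recording each fold's model,
#' imputation medians and validation AUC. Prediction averages the fold
#' models' MC-probability scores.
#'
#' @param table feature data.frame.
#' @param labels factor with levels LB/MC.
#' @param subset character vector of feature columns to use.
#' @param spec a [model_spec()].
#' @param n_folds Monte-Carlo folds (study default 100).
#' @param seed RNG seed.
#' @param profiles optional event-time data.frame aligned with `table`;
#'   when given, DLR columns are re-fitted per fold on the training-split
#'   LB embryos.
#' @return object of class `mc_ensemble`.
#' @export
fit_ensemble <- function(table, labels, subset, spec = model_spec(),
                         n_folds = 100L, seed = 1L, profiles = NULL) {
  stopifnot(all(subset %in% names(table)))
  x <- table[, subset, drop = FALSE]
  res <- mc_folds(x, labels, spec, n_folds = n_folds, seed = seed,
                  keep_models = TRUE, profiles = profiles)
  # every train/validation embryo should appear in >= 1 validation fold
  seen <- sort(unique(unlist(lapply(res$folds, `[[`, "valid"))))
  structure(list(spec = spec, subset = subset, models = res$models,
                 folds = res$folds, val_auc = res$val_auc,
                 importance = res$importance,
                 all_validated = identical(seen, seq_len(nrow(x))),
                 redraws = res$redraws, seed = seed,
                 profiles = profiles),
            class = "mc_ensemble")
}

#' Ensemble miscarriage risk score
#'
#' The mean of the fold models' predicted MC probabilities (the operational
#' reading of averaging the cross-validated models); always in `[0, 1]` and
#' monotone in every fold model's score.
#'
#' @param ens an `mc_ensemble`.
#' @param newdata data.frame containing the ensemble's feature subset.
#' @return numeric score per row.
#' @export
predict_score <- function(ens, newdata) {
  miss <- setdiff(ens$subset, names(newdata))
  if (length(miss))
    stop("missing required features: ", paste(miss, collapse = ", "))
  x0 <- newdata[, ens$subset, drop = FALSE]
  sc <- matrix(0, nrow(x0), length(ens$models))
  for (k in seq_along(ens$models)) {
    x <- apply_impute(x0, ens$models[[k]]$medians)
    if (anyNA(x)) {
      bad <- names(x)[vapply(x, anyNA, logical(1))]
      stop("feature not imputable: ", paste(bad, collapse = ", "))
    }
    sc[, k] <- predict_fold_model(ens$models[[k]], ens$spec, x)
  }
  rowMeans(sc)
}

#' Integrated RF + GB classifier score
#'
#' Averages the Monte-Carlo scores of a random-forest and a
#' gradient-boosting ensemble.
#'
#' @param ens_rf,ens_gb fitted `mc_ensemble` objects.
#' @param newdata data.frame of features.
#' @return numeric score per row.
#' @export
integrated_score <- function(ens_rf, ens_gb, newdata) {
  (predict_score(ens_rf, newdata) + predict_score(ens_gb, newdata)) / 2
}

#' Random search over the study hyperparameter ranges
#'
#' Samples `budget` candidate specifications uniformly from the published
#' search ranges (RF: max depth 1-3, feature fraction 0.1-0.5, minimum leaf
#' and split sizes 25-50, 1-100 trees; GB: learning rate 0.01-0.3, minimum
#' child weight 25-40, max depth 1-3, subsample 0.1-1, column subsample
#' 0.1-0.4, 1-50 trees) and scores each by mean Monte-Carlo CV validation
#' AUC. Returns the best spec and the full search trace. An empty budget
#' returns the family defaults.
#'
#' @param table,labels feature table and labels.
#' @param subset feature columns.
#' @param family model family.
#' @param budget number of sampled candidates.
#' @param n_folds CV folds per candidate.
#' @param seed RNG seed.
#' @return list with `spec`, `auc`, and `trace` (data.frame).
#' @export
search_hyperparameters <- function(table, labels, subset,
                                   family = c("random-forest",
                                              "gradient-boosting"),
                                   budget = 20L, n_folds = 25L, seed = 1L) {
  family <- match.arg(family)
  if (budget < 1L)
    return(list(spec = model_spec(family), auc = NA_real_,
                trace = data.frame()))
  seeds <- child_seeds(seed, budget + 1L)
  cands <- with_seed(seeds[budget + 1L], lapply(seq_len(budget), function(i) {
    if (family == "random-forest")
      model_spec("random-forest",
                 n_trees = sample(1:100, 1),
                 max_depth = sample(1:3, 1),
                 mtry_frac = stats::runif(1, 0.1, 0.5),
                 min_leaf = sample(25:50, 1),
                 min_split = sample(25:50, 1))
    else
      model_spec("gradient-boosting",
                 n_trees = sample(1:50, 1),
                 max_depth = sample(1:3, 1),
                 learning_rate = stats::runif(1, 0.01, 0.3),
                 min_child_weight = stats::runif(1, 25, 40),
                 subsample = stats::runif(1, 0.1, 1),
                 colsample_bytree = stats::runif(1, 0.1, 0.4))
  }))
  x <- table[, subset, drop = FALSE]
  aucs <- vapply(seq_len(budget), function(i) {
    mean(mc_folds(x, labels, cands[[i]], n_folds = n_folds,
                  seed = seeds[i])$val_auc)
  }, numeric(1))
  best <- which.max(aucs)
  trace <- data.frame(candidate = seq_len(budget), mean_val_auc = aucs)
  list(spec = cands[[best]], auc = aucs[best], trace = trace)
}

confusion_at <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  pos <- labels == "MC"
  m <- matrix(c(sum(pred & pos), sum(pred & !pos),
                sum(!pred & pos), sum(!pred & !pos)), 2, 2,
              dimnames = list(predicted = c("MC", "LB"),
                              actual = c("MC", "LB")))
  prec <- if (sum(pred) > 0) m[1, 1] / sum(pred) else NA_real_
  sens <- if (sum(pos) > 0) m[1, 1] / sum(pos) else NA_real_
  list(matrix = m, threshold = threshold, precision = prec,
       sensitivity = sens)
}

#' Evaluate risk scores on a labeled partition
#'
#' Computes the ROC curve and its AUC by the rank statistic, a
#' precision-sensitivity curve, and confusion matrices at two named
#' operating points: a precision-favouring (high MC threshold) and a
#' sensitivity-favouring (low MC threshold) classifier. A fold-AUC vector,
#' if supplied, yields a percentile confidence band for the AUC.
#'
#' @param scores numeric risk scores.
#' @param labels factor with levels LB/MC (MC = positive).
#' @param fold_aucs optional per-fold validation AUCs for the band.
#' @param thresholds optional named numeric `c(precision = , sensitivity = )`
#'   operating thresholds; chosen from the precision-sensitivity curve when
#'   `NULL` (highest threshold reaching sensitivity >= 0.25, lowest
#'   threshold reaching sensitivity >= 0.75).
#' @return list with `auc`, `auc_ci`, `roc` (data.frame fpr/tpr/threshold),
#'   `pr` (data.frame), `confusion` (two operating points), `n`.
#' @export
evaluate_scores <- function(scores, labels, fold_aucs = NULL,
                            thresholds = NULL) {
  labels <- factor(labels, levels = c("LB", "MC"))
  if (nlevels(droplevels(labels)) < 2L)
    stop("AUC undefined on a single-class partition")
  auc <- auc_rank(scores, labels == "MC")
  thr <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
  pos <- labels == "MC"
  roc <- data.frame(threshold = thr,
                    tpr = vapply(thr, function(t) mean(scores[pos] >= t),
                                 numeric(1)),
                    fpr = vapply(thr, function(t) mean(scores[!pos] >= t),
                                 numeric(1)))
  pr <- data.frame(threshold = thr,
                   sensitivity = roc$tpr,
                   precision = vapply(thr, function(t) {
                     p <- scores >= t
                     if (!any(p)) NA_real_ else mean(pos[p])
                   }, numeric(1)))
  if (is.null(thresholds)) {
    fin <- pr[is.finite(pr$threshold), ]
    hi <- fin$threshold[fin$sensitivity >= 0.25]
    lo <- fin$threshold[fin$sensitivity >= 0.75]
    thresholds <- c(precision = if (length(hi)) max(hi) else stats::median(scores),
                    sensitivity = if (length(lo)) max(lo) else min(scores))
  }
  conf <- list(precision_favoring = confusion_at(scores, labels,
                                                thresholds[["precision"]]),
               sensitivity_favoring = confusion_at(scores, labels,
                                                   thresholds[["sensitivity"]]))
  ci <- if (!is.null(fold_aucs))
    stats::quantile(fold_aucs, c(0.025, 0.975), names = FALSE) else NULL
  list(auc = auc, auc_ci = ci, roc = roc, pr = pr, confusion = conf,
       n = length(scores))
}

# ---- SHAP / aSHAP explanation ----------------------------------------------

#' SHAP attributions and aSHAP importance for a gradient-boosted ensemble
#'
#' Exact additive tree attributions (TreeSHAP) of each fold model, averaged
#' across the folds, on the log-odds scale: per embryo, base value + the sum
#' of attributions reconstructs the (fold-averaged) model margin exactly.
#' Feature importance is summarised by the adjusted SHAP (aSHAP): the mean
#' over embryos of the absolute attribution signed +1 for correctly
#' classified embryos and -1 for misclassified ones (ensemble score >= the
#' classification threshold predicts MC), so it scores impact on *accurate*
#' prediction. Per-feature two-sample KS summaries of MC vs LB feature
#' values are reported alongside.
#'
#' @param ens a gradient-boosting `mc_ensemble`.
#' @param table feature data.frame.
#' @param labels factor with levels LB/MC.
#' @param threshold classification threshold for the aSHAP sign rule.
#' @return list with `shap` (n x p matrix), `base_value`, `margin`
#'   (fold-averaged log-odds), `score` (ensemble probability score),
#'   `ashap` (named vector), `ks` (data.frame feature/statistic/p).
#' @export
explain_ensemble <- function(ens, table, labels, threshold = 0.5) {
  if (ens$spec$family != "gradient-boosting")
    stop("exact tree attributions are provided for gradient-boosting ",
         "ensembles (the family the SHAP analysis targets)")
  labels <- factor(labels, levels = c("LB", "MC"))
  x0 <- table[, ens$subset, drop = FALSE]
  p <- length(ens$subset)
  phi <- matrix(0, nrow(x0), p, dimnames = list(NULL, ens$subset))
  base <- 0
  for (k in seq_along(ens$models)) {
    x <- as.matrix(apply_impute(x0, ens$models[[k]]$medians))
    contrib <- stats::predict(ens$models[[k]]$model, x, predcontrib = TRUE)
    phi <- phi + contrib[, ens$subset, drop = FALSE]
    base <- base + mean(contrib[, ncol(contrib)])  # bias/intercept column
  }
  nf <- length(ens$models)
  phi <- phi / nf; base <- base / nf
  margin <- base + rowSums(phi)
  score <- predict_score(ens, table)
  correct <- (score >= threshold) == (labels == "MC")
  sgn <- ifelse(correct, 1, -1)
  ashap <- colMeans(sgn * abs(phi))
  ks <- do.call(rbind, lapply(ens$subset, function(f) {
    xm <- table[[f]][labels == "MC"]; xl <- table[[f]][labels == "LB"]
    xm <- xm[!is.na(xm)]; xl <- xl[!is.na(xl)]
    if (length(xm) < 2 || length(xl) < 2)
      return(data.frame(feature = f, ks_stat = NA_real_, ks_p = NA_real_))
    kt <- suppressWarnings(stats::ks.test(xm, xl))
    data.frame(feature = f, ks_stat = unname(kt$statistic),
               ks_p = kt$p.value)
  }))
  list(shap = phi, base_value = base, margin = margin, score = score,
       ashap = ashap, ks = ks)
}
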