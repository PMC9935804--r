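# Feature screening cascade: per-feature statistical distances between the
# MC and LB classes, a KS x KL threshold grid defining qualified feature
# subsets, Monte-Carlo CV subset scoring, importance ranking and redundancy
# analysis, backward elimination, and two-step forward selection.

kl_histogram <- function(x_mc, x_lb, bins = 20L) {
  rng <- range(c(x_mc, x_lb))
  if (diff(rng) == 0) return(0)
  brk <- seq(rng[1], rng[2], length.out = bins + 1L)
  cm <- tabulate(findInterval(x_mc, brk, rightmost.closed = TRUE,
                              all.inside = TRUE), bins)
  cl <- tabulate(findInterval(x_lb, brk, rightmost.closed = TRUE,
                              all.inside = TRUE), bins)
  p <- (cm + 1) / (length(x_mc) + bins)   # Laplace pseudocount
  q <- (cl + 1) / (length(x_lb) + bins)
  sum(p * log(p / q))
}

#' Per-feature statistical distances between MC and LB embryos
#'
#' For every feature column: the two-sample Kolmogorov-Smirnov p-value and
#' a histogram-based Kullback-Leibler divergence estimate KL(MC || LB)
#' (shared equal-width bins over the pooled range, Laplace pseudocount,
#' nats), computed on non-missing values only. Features with fewer than two
#' values in either class are skipped (flagged); an all-constant feature
#' reports p = 1 and KL = 0.
#'
#' @param table feature data.frame.
#' @param labels factor with levels LB/MC.
#' @param bins number of histogram bins for the KL estimate.
#' @return data.frame: `feature`, `ks_p`, `kl`, `n_mc`, `n_lb`, `flag`.
#' @export
statistical_distances <- function(table, labels, bins = 20L) {
  labels <- factor(labels, levels = c("LB", "MC"))
  res <- lapply(names(table), function(f) {
    x <- table[[f]]
    xm <- x[labels == "MC"]; xl <- x[labels == "LB"]
    xm <- xm[is.finite(xm)]; xl <- xl[is.finite(xl)]
    row <- data.frame(feature = f, ks_p = NA_real_, kl = NA_real_,
                      n_mc = length(xm), n_lb = length(xl), flag = "")
    if (length(xm) < 2L || length(xl) < 2L) {
      row$flag <- "skipped: < 2 values in a class"
      return(row)
    }
    if (stats::var(c(xm, xl)) == 0) {
      row$ks_p <- 1; row$kl <- 0
      row$flag <- "constant feature"
      return(row)
    }
    row$ks_p <- suppressWarnings(stats::ks.test(xm, xl))$p.value
    row$kl <- kl_histogram(xm, xl, bins)
    row
  })
  do.call(rbind, res)
}

#' Build the KS x KL threshold grid and its qualified feature subsets
#'
#' Six KS p-value thresholds spaced +0.05 apart and three KL thresholds
#' spaced -0.1 apart define 6 x 3 = 18 threshold pairs; subset (i, j)
#' collects the features with `ks_p < lambda_i^KS` and `kl > lambda_j^KL`.
#' Empty subsets are retained and flagged.
#'
#' @param distances output of [statistical_distances()].
#' @param base_ks,base_kl the strictest (base) thresholds
#'   `lambda_1^KS`, `lambda_1^KL`.
#' @return list with `grid` (data.frame i, j, ks, kl, n, flag) and
#'   `subsets` (list of 18 character vectors).
#' @export
build_threshold_grid <- function(distances, base_ks = 0.01, base_kl = 0.25) {
  ks_thr <- base_ks + 0.05 * (0:5)
  kl_thr <- base_kl - 0.1 * (0:2)
  grid <- expand.grid(i = 1:6, j = 1:3)
  grid$ks <- ks_thr[grid$i]; grid$kl <- kl_thr[grid$j]
  ok <- !is.na(distances$ks_p) & !is.na(distances$kl)
  subsets <- lapply(seq_len(nrow(grid)), function(k) {
    distances$feature[ok & distances$ks_p < grid$ks[k] &
                        distances$kl > grid$kl[k]]
  })
  grid$n <- lengths(subsets)
  grid$flag <- ifelse(grid$n == 0L, "empty subset", "")
  list(grid = grid, subsets = subsets,
       ks_thresholds = ks_thr, kl_thresholds = kl_thr)
}

#' Monte-Carlo cross-validated AUC of a feature subset
#'
#' Scores one feature subset by `n_folds` stratified 90/10 Monte-Carlo
#' splits, training a random-forest and a gradient-boosting model per fold
#' (fold-local median imputation; optional fold-local DLR refitting) and
#' averaging validation AUCs.
#'
#' @param subset character vector of feature columns (non-empty).
#' @param table,labels feature table and LB/MC labels.
#' @param specs list with `rf` and `gb` [model_spec()]s.
#' @param n_folds Monte-Carlo folds (study default 100).
#' @param seed RNG seed.
#' @param profiles optional aligned event-time data.frame enabling fold-wise
#'   DLR refitting.
#' @return list: `auc_rf`, `auc_gb` (means), `fold_auc_rf`, `fold_auc_gb`,
#'   `importance_rf`, `importance_gb`, `redraws`.
#' @export
mc_cv_auc <- function(subset, table, labels, specs = default_model_specs(),
                      n_folds = 100L, seed = 1L, profiles = NULL) {
  stopifnot(length(subset) > 0L, all(subset %in% names(table)))
  if (min(table(labels)) < 10L)
    stop("need at least 10 embryos per class")
  x <- table[, subset, drop = FALSE]
  sds <- child_seeds(seed, 2L)
  rf <- mc_folds(x, labels, specs$rf, n_folds, sds[1], profiles = profiles)
  gb <- mc_folds(x, labels, specs$gb, n_folds, sds[2], profiles = profiles)
  list(auc_rf = mean(rf$val_auc), auc_gb = mean(gb$val_auc),
       fold_auc_rf = rf$val_auc, fold_auc_gb = gb$val_auc,
       importance_rf = rf$importance, importance_gb = gb$importance,
       redraws = rf$redraws + gb$redraws)
}

#' Rank features across the most predictive subsets and prune to a top set
#'
#' Selects the subsets with the highest combined (RF + GB) mean CV AUC
#' (ties broken toward smaller subsets), unions their features, ranks the
#' union by the models' native importance scores averaged across all
#' relevant CV fits (rank-averaged across the two families), and returns
#' the top `top_k` features with their pairwise Pearson correlation matrix.
#'
#' @param scored list of scored subsets, each
#'   `list(features = , score = mc_cv_auc result)`.
#' @param table feature table (for the correlation matrix).
#' @param top_n number of subsets retained (all non-empty if fewer).
#' @param top_k number of top-ranked features returned.
#' @return list: `top_idx`, `union`, `ranking` (data.frame), `top`
#'   (character), `pearson` (matrix).
#' @export
rank_and_prune <- function(scored, table, top_n = 10L, top_k = 8L) {
  nonempty <- which(vapply(scored, function(s) length(s$features) > 0,
                           logical(1)))
  if (length(nonempty) == 0L) stop("no non-empty scored subsets")
  comb <- vapply(scored[nonempty],
                 function(s) s$score$auc_rf + s$score$auc_gb, numeric(1))
  sizes <- lengths(lapply(scored[nonempty], `[[`, "features"))
  ord <- order(-comb, sizes)
  top_idx <- nonempty[ord[seq_len(min(top_n, length(ord)))]]
  union <- sort(unique(unlist(lapply(scored[top_idx], `[[`, "features"))))
  imp_of <- function(which_fam) {
    vapply(union, function(f) {
      vals <- unlist(lapply(scored[top_idx], function(s) {
        if (f %in% s$features) s$score[[which_fam]][[f]] else NULL
      }))
      if (length(vals)) mean(vals) else 0
    }, numeric(1))
  }
  imp_rf <- imp_of("importance_rf"); imp_gb <- imp_of("importance_gb")
  rank_rf <- rank(-imp_rf, ties.method = "average")
  rank_gb <- rank(-imp_gb, ties.method = "average")
  ranking <- data.frame(feature = union, importance_rf = imp_rf,
                        importance_gb = imp_gb,
                        mean_rank = (rank_rf + rank_gb) / 2)
  ranking <- ranking[order(ranking$mean_rank,
                           match(ranking$feature, feature_names())), ]
  rownames(ranking) <- NULL
  top <- ranking$feature[seq_len(min(top_k, nrow(ranking)))]
  pearson <- stats::cor(table[, top, drop = FALSE],
                        use = "pairwise.complete.obs")
  list(top_idx = top_idx, union = union, ranking = ranking, top = top,
       pearson = pearson)
}

#' Stepwise backward feature elimination
#'
#' Starting from the given subset, repeatedly removes the single feature
#' whose removal leaves the highest combined (RF + GB) mean CV AUC — i.e.
#' the feature with the smallest negative effect — producing a series of
#' subsets from `|subset|` down to 1 with the full score trace.
#'
#' @inheritParams mc_cv_auc
#' @return data.frame series: `size`, `features` (comma-joined), `removed`,
#'   `auc_rf`, `auc_gb`; attribute `subsets` holds the character vectors.
#' @export
backward_eliminate <- function(subset, table, labels,
                               specs = default_model_specs(),
                               n_folds = 100L, seed = 1L, profiles = NULL) {
  seeds <- child_seeds(seed, length(subset)^2 + length(subset))
  si <- 1L
  cur <- subset
  sc <- mc_cv_auc(cur, table, labels, specs, n_folds, seeds[si],
                  profiles = profiles)
  series <- list(list(features = cur, removed = NA_character_,
                      auc_rf = sc$auc_rf, auc_gb = sc$auc_gb))
  while (length(cur) > 1L) {
    cand <- lapply(seq_along(cur), function(k) {
      si <<- si + 1L
      s <- mc_cv_auc(cur[-k], table, labels, specs, n_folds, seeds[si],
                     profiles = profiles)
      list(drop = cur[k], auc_rf = s$auc_rf, auc_gb = s$auc_gb)
    })
    comb <- vapply(cand, function(s) s$auc_rf + s$auc_gb, numeric(1))
    best <- which.max(comb)
    cur <- cur[-best]
    series[[length(series) + 1L]] <-
      list(features = cur, removed = cand[[best]]$drop,
           auc_rf = cand[[best]]$auc_rf, auc_gb = cand[[best]]$auc_gb)
  }
  df <- data.frame(
    size = vapply(series, function(s) length(s$features), integer(1)),
    features = vapply(series, function(s) paste(s$features, collapse = ","),
                      character(1)),
    removed = vapply(series, `[[`, character(1), "removed"),
    auc_rf = vapply(series, `[[`, numeric(1), "auc_rf"),
    auc_gb = vapply(series, `[[`, numeric(1), "auc_gb"))
  attr(df, "subsets") <- lapply(series, `[[`, "features")
  df
}

# Walk a backward-elimination series from the full set down; accept each
# removal until one decreases both the RF and the GB AUC, mirroring the
# study's stopping argument.
backward_stop_subset <- function(series) {
  subsets <- attr(series, "subsets")
  k <- 1L
  while (k < nrow(series)) {
    if (series$auc_rf[k + 1] < series$auc_rf[k] &&
        series$auc_gb[k + 1] < series$auc_gb[k]) break
    k <- k + 1L
  }
  subsets[[k]]
}

#' Two-step forward feature selection
#'
#' Per cycle, every unordered pair from the pool is added jointly to the
#' current subset and scored; the best pair (by combined RF + GB AUC, ties
#' resolved toward the lowest catalog indices) is identified and only its
#' lower-catalog-index member is retained. Stops early when no pair
#' improves both the RF and the GB AUC over the current subset, or after
#' `max_cycles` additions.
#'
#' @inheritParams mc_cv_auc
#' @param pool candidate features, disjoint from `subset`.
#' @param max_cycles maximum number of forward additions.
#' @return list: `subset` (augmented), `added` (character), `trace`
#'   (data.frame per cycle).
#' @export
forward_select_two_step <- function(subset, pool, table, labels,
                                    specs = default_model_specs(),
                                    n_folds = 100L, seed = 1L,
                                    max_cycles = 3L, profiles = NULL) {
  stopifnot(length(intersect(subset, pool)) == 0L)
  if (length(pool) < 2L)
    return(list(subset = subset, added = character(0), trace = data.frame()))
  # catalog index: position in the frozen 314-feature catalog; columns from
  # outside the catalog fall back to name order after it
  all_feats <- union(feature_names(), sort(names(table)))
  catalog <- all_feats
  pool <- pool[order(match(pool, catalog))]
  n_eval <- max_cycles * (choose(length(pool), 2) + 1L) + 1L
  seeds <- child_seeds(seed, n_eval)
  si <- 1L
  cur <- subset
  sc <- mc_cv_auc(cur, table, labels, specs, n_folds, seeds[si],
                  profiles = profiles)
  added <- character(0)
  trace <- list()
  for (cycle in seq_len(max_cycles)) {
    if (length(pool) < 2L) break
    pairs <- utils::combn(pool, 2)  # columns already in lowest-index order
    best <- NULL
    for (k in seq_len(ncol(pairs))) {
      si <- si + 1L
      s <- mc_cv_auc(c(cur, pairs[, k]), table, labels, specs, n_folds,
                     seeds[si], profiles = profiles)
      comb <- s$auc_rf + s$auc_gb
      if (is.null(best) || comb > best$comb + 1e-12)  # strict: ties keep
        best <- list(pair = pairs[, k], comb = comb,   # earliest (lowest idx)
                     auc_rf = s$auc_rf, auc_gb = s$auc_gb)
    }
    improves <- best$auc_rf > sc$auc_rf && best$auc_gb > sc$auc_gb
    trace[[cycle]] <- data.frame(
      cycle = cycle, pair = paste(best$pair, collapse = "+"),
      auc_rf = best$auc_rf, auc_gb = best$auc_gb,
      accepted = improves)
    if (!improves) break
    keep <- best$pair[which.min(match(best$pair, catalog))]
    cur <- c(cur, keep)
    added <- c(added, keep)
    pool <- setdiff(pool, keep)
    si <- si + 1L
    sc <- mc_cv_auc(cur, table, labels, specs, n_folds, seeds[si],
                    profiles = profiles)
  }
  list(subset = cur, added = added,
       trace = if (length(trace)) do.call(rbind, trace) else data.frame())
}

#' Split a cohort into a train/validation partition and a balanced test set
#'
#' The held-out test partition has equal MC and LB counts and is disjoint
#' from the train/validation rows; no screening or training operation ever
#' touches it.
#'
#' @param labels factor with levels LB/MC.
#' @param n_test_per_class embryos per class held out (default ~15% of the
#'   minority class).
#' @param seed RNG seed.
#' @return list with `train` and `test` row indices.
#' @export
split_cohort <- function(labels, n_test_per_class = NULL, seed = 1L) {
  labels <- factor(labels, levels = c("LB", "MC"))
  n_min <- min(table(labels))
  if (is.null(n_test_per_class)) n_test_per_class <- max(1L, round(0.15 * n_min))
  if (n_test_per_class >= n_min) stop("test partition too large")
  with_seed(seed, {
    test <- c(sample(which(labels == "MC"), n_test_per_class),
              sample(which(labels == "LB"), n_test_per_class))
    list(train = setdiff(seq_along(labels), test), test = sort(test))
  })
}

#' Run the full feature-screening cascade
#'
#' End-to-end screening on the train/validation rows: per-feature KS/KL
#' statistical distances; the 6 x 3 threshold grid and its 18 qualified
#' subsets; Monte-Carlo CV scoring of every non-empty subset with RF and GB
#' models; selection of the most predictive subsets, importance ranking of
#' their union and redundancy (Pearson) analysis of the top features;
#' stepwise backward elimination with the both-models stopping rule; and
#' two-step forward selection from the top-ranked remainder.
#'
#' @param table full feature data.frame.
#' @param labels factor with levels LB/MC.
#' @param train_idx rows to screen on (e.g. `split_cohort()$train`);
#'   default all rows.
#' @param base_ks,base_kl base thresholds of the grid.
#' @param specs RF/GB [model_spec()] list.
#' @param n_folds Monte-Carlo folds for subset scoring.
#' @param n_folds_wrapper folds for the backward/forward wrapper stages.
#' @param top_n,top_k subsets and features retained by [rank_and_prune()].
#' @param forward_pool_size forward-selection pool size (top-ranked union
#'   features outside the current subset).
#' @param max_cycles forward cycles.
#' @param seed RNG seed.
#' @param profiles optional aligned event-time data.frame; when supplied,
#'   DLR columns are re-fitted within each CV fold on that fold's training
#'   LB embryos (leakage control).
#' @return object of class `screening_result`.
#' @export
screen_features <- function(table, labels, train_idx = NULL,
                            base_ks = 0.01, base_kl = 0.25,
                            specs = default_model_specs(),
                            n_folds = 100L, n_folds_wrapper = n_folds,
                            top_n = 10L, top_k = 8L,
                            forward_pool_size = 12L, max_cycles = 3L,
                            seed = 1L, profiles = NULL) {
  if (is.null(train_idx)) train_idx <- seq_along(labels)
  tab <- table[train_idx, , drop = FALSE]
  lab <- droplevels(factor(labels[train_idx], levels = c("LB", "MC")))
  prof <- if (!is.null(profiles)) profiles[train_idx, , drop = FALSE]
  seeds <- child_seeds(seed, 25L)
  distances <- statistical_distances(tab, lab)
  grid <- build_threshold_grid(distances, base_ks, base_kl)
  scored <- lapply(seq_along(grid$subsets), function(k) {
    feats <- grid$subsets[[k]]
    if (length(feats) == 0L) return(list(features = feats, score = NULL))
    list(features = feats,
         score = mc_cv_auc(feats, tab, lab, specs, n_folds,
                           seed = seeds[1] + k, profiles = prof))
  })
  gc(verbose = FALSE)  # thousands of short-lived fold models by this point
  pruned <- rank_and_prune(scored, tab, top_n = top_n, top_k = top_k)
  series <- backward_eliminate(pruned$top, tab, lab, specs,
                               n_folds_wrapper, seeds[2], profiles = prof)
  gc(verbose = FALSE)
  backward_subset <- backward_stop_subset(series)
  pool <- setdiff(pruned$ranking$feature, backward_subset)
  pool <- pool[seq_len(min(forward_pool_size, length(pool)))]
  fwd <- forward_select_two_step(backward_subset, pool, tab, lab, specs,
                                 n_folds_wrapper, seeds[3],
                                 max_cycles = max_cycles, profiles = prof)
  structure(list(distances = distances, grid = grid$grid,
                 thresholds = list(ks = grid$ks_thresholds,
                                   kl = grid$kl_thresholds),
                 subsets = grid$subsets, scored = scored,
                 top_idx = pruned$top_idx, union = pruned$union,
                 ranking = pruned$ranking, top = pruned$top,
                 pearson = pruned$pearson,
                 backward_series = series,
                 backward_subset = backward_subset,
                 forward = fwd, final_subset = fwd$subset,
                 seed = seed),
            class = "screening_result")
}
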