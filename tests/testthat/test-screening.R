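test_that("statistical distances behave at the identical / disjoint extremes", {
  set.seed(2)
  x <- rnorm(200)
  tab <- data.frame(same = c(x, x),
                    apart = c(rnorm(200, 0, 0.3), rnorm(200, 100, 0.3)),
                    const = rep(1, 400),
                    sparse = c(rnorm(2), rep(NA, 398)))
  lab <- factor(rep(c("LB", "MC"), each = 200), levels = c("LB", "MC"))
  d <- statistical_distances(tab, lab)
  same <- d[d$feature == "same", ]
  expect_gt(same$ks_p, 0.999)          # identical samples: KS statistic 0
  expect_lt(same$kl, 0.05)
  apart <- d[d$feature == "apart", ]
  expect_lt(apart$ks_p, 1e-10)         # disjoint support: maximal separation
  expect_gt(apart$kl, 1)
  cst <- d[d$feature == "const", ]
  expect_equal(cst$ks_p, 1)
  expect_equal(cst$kl, 0)
  expect_match(d$flag[d$feature == "sparse"], "skipped")
})

test_that("the histogram KL estimator recovers the Gaussian closed form", {
  set.seed(4)
  x <- rnorm(1e5); y <- rnorm(1e5, 1)
  kl <- embryoscreen:::kl_histogram(x, y, bins = 20)
  expect_equal(kl, 0.5, tolerance = 0.05)  # (mu1-mu2)^2 / (2 sigma^2)
})

test_that("the threshold grid defines 18 subsets with the prescribed spacings", {
  tt <- toy_table(100, p = 8, planted = c(v01 = 1.5), seed = 3)
  d <- statistical_distances(tt$table, tt$labels)
  g <- build_threshold_grid(d, base_ks = 0.01, base_kl = 0.25)
  expect_length(g$subsets, 18)
  expect_equal(nrow(g$grid), 18)
  expect_equal(diff(g$ks_thresholds), rep(0.05, 5))
  expect_equal(diff(g$kl_thresholds), rep(-0.1, 2))
  # excluding everything: 18 empty, flagged subsets
  g0 <- build_threshold_grid(d, base_ks = 0, base_kl = 1e6)
  expect_true(all(lengths(g0$subsets) == 0))
  expect_true(all(g0$grid$flag == "empty subset"))
  # monotone inclusion: loosening KS never shrinks a subset
  for (j in 1:3) {
    for (i in 1:5) {
      a <- g$subsets[[which(g$grid$i == i & g$grid$j == j)]]
      b <- g$subsets[[which(g$grid$i == i + 1 & g$grid$j == j)]]
      expect_true(all(a %in% b))
    }
  }
})

test_that("Monte-Carlo CV AUC separates oracle from noise features", {
  tt <- toy_table(200, p = 3, planted = c(v01 = 10), seed = 5)  # separable
  r <- mc_cv_auc("v01", tt$table, tt$labels, n_folds = 20, seed = 1)
  expect_gte(r$auc_rf, 0.99)
  expect_gte(r$auc_gb, 0.99)

  tt0 <- toy_table(200, p = 1, seed = 6)  # label-independent noise, n = 400
  r0 <- mc_cv_auc("v01", tt0$table, tt0$labels, n_folds = 100, seed = 2)
  expect_length(r0$fold_auc_rf, 100)      # exactly n_folds per-fold AUCs
  expect_length(r0$fold_auc_gb, 100)
  expect_lt(abs(r0$auc_rf - 0.5), 0.05)
  expect_lt(abs(r0$auc_gb - 0.5), 0.05)

  expect_error(mc_cv_auc(character(0), tt$table, tt$labels), "length")
  few <- toy_table(5, p = 2, seed = 7)
  expect_error(mc_cv_auc("v01", few$table, few$labels), "10 embryos")
})

test_that("rank_and_prune surfaces duplicates and planted signal", {
  tt <- toy_table(150, p = 6, planted = c(v01 = 1), seed = 8)
  tt$table$v06 <- tt$table$v01  # exact duplicate column
  scored <- lapply(list(c("v01", "v02", "v06"), c("v01", "v03"),
                        c("v04", "v05")), function(fs)
    list(features = fs,
         score = mc_cv_auc(fs, tt$table, tt$labels, n_folds = 10, seed = 3)))
  pr <- rank_and_prune(scored, tt$table, top_n = 3, top_k = 4)
  expect_true(isSymmetric(pr$pearson))
  expect_equal(unname(diag(pr$pearson)), rep(1, nrow(pr$pearson)))
  expect_equal(pr$pearson["v01", "v06"], 1.0)
  expect_equal(pr$ranking$feature[1], "v01")
})

test_that("the planted feature ranks first in most seeds", {
  wins <- 0L
  for (s in 1:10) {
    tt <- toy_table(1000, p = 6, planted = c(v03 = 1), seed = 100 + s)
    scored <- list(list(features = names(tt$table),
                        score = mc_cv_auc(names(tt$table), tt$table,
                                          tt$labels, n_folds = 8,
                                          seed = s)))
    pr <- rank_and_prune(scored, tt$table, top_n = 1, top_k = 3)
    # oracle: the planted column has the best single-feature AUC by far
    expect_gt(auc_rank(tt$table$v03, tt$labels == "MC"), 0.7)
    if (pr$ranking$feature[1] == "v03") wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("backward elimination produces a full series and drops duplicates early", {
  tt <- toy_table(150, p = 8, planted = c(v01 = 1.2, v02 = 0.8), seed = 9)
  ser <- backward_eliminate(names(tt$table), tt$table, tt$labels,
                            n_folds = 8, seed = 4)
  expect_equal(ser$size, 8:1)
  expect_true(all(diff(ser$size) == -1))

  single <- backward_eliminate("v01", tt$table, tt$labels,
                               n_folds = 8, seed = 5)
  expect_equal(nrow(single), 1)
  expect_equal(single$features, "v01")

  # an exact duplicate of an informative feature goes within two steps
  hits <- 0L
  for (s in 1:5) {
    td <- toy_table(150, p = 3, planted = c(v01 = 1.5), seed = 200 + s)
    td$table$dup <- td$table$v01
    sd2 <- backward_eliminate(c("v01", "v02", "v03", "dup"), td$table,
                              td$labels, n_folds = 10, seed = s)
    if (any(sd2$removed[2:3] %in% c("dup", "v01"))) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("two-step forward selection recovers a strong pool feature", {
  tt <- toy_table(200, p = 8, planted = c(v01 = 1, v05 = 1.5), seed = 10)
  # empty pool: unchanged
  f0 <- forward_select_two_step("v01", character(0), tt$table, tt$labels,
                                n_folds = 8, seed = 6)
  expect_equal(f0$subset, "v01")
  # the strongly informative feature sits at the lowest pool index, so the
  # lower-index retention rule keeps it once its pair wins
  hits <- 0L
  for (s in 1:5) {
    td <- toy_table(200, p = 8, planted = c(v01 = 1, v02 = 1.5),
                    seed = 300 + s)
    fw <- forward_select_two_step("v01", c("v02", "v03", "v04", "v05"),
                                  td$table, td$labels, n_folds = 10,
                                  seed = s, max_cycles = 1)
    if ("v02" %in% fw$subset) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
  # deterministic under a fixed seed (ties and all)
  a <- forward_select_two_step("v01", c("v02", "v03"), tt$table, tt$labels,
                               n_folds = 8, seed = 7)
  b <- forward_select_two_step("v01", c("v02", "v03"), tt$table, tt$labels,
                               n_folds = 8, seed = 7)
  expect_identical(a, b)
})

test_that("the balanced test partition is disjoint from training rows", {
  co <- tiny_cohort(n_mc = 20, n_lb = 60, seed = 15)
  sp <- split_cohort(co$labels, n_test_per_class = 5, seed = 1)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(as.integer(table(co$labels[sp$test])), c(5L, 5L))
  expect_setequal(c(sp$train, sp$test), seq_along(co$labels))
  expect_error(split_cohort(co$labels, n_test_per_class = 25), "too large")
})
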