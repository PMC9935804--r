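test_that("cohort composition, ordering, and reproducibility hold", {
  co <- generate_cohort(cohort_config(n_mc = 96, n_lb = 368, seed = 2))
  expect_equal(as.integer(table(co$labels)[c("MC", "LB")]), c(96L, 368L))
  expect_equal(nrow(co$features), 464)
  expect_equal(ncol(co$features), 314)
  # strict chronology among the present events of every embryo
  ev <- as.matrix(co$profiles[, mk_events()])
  ord_ok <- apply(ev, 1, function(r) !is.unsorted(r[!is.na(r)]))
  expect_true(all(ord_ok))
  expect_true(all(ev[, "tPNa"] < ev[, "tPNf"], na.rm = TRUE))
  # byte-identical regeneration under the same seed
  co2 <- generate_cohort(cohort_config(n_mc = 96, n_lb = 368, seed = 2))
  expect_identical(co, co2)
})

test_that("empty and invalid configurations behave per contract", {
  e <- generate_cohort(cohort_config(n_mc = 0, n_lb = 0))
  expect_equal(nrow(e$features), 0)
  expect_equal(length(e$labels), 0)
  expect_error(cohort_config(n_mc = -1), "negative")
  expect_error(cohort_config(effect_map = c(ooplasm_r = Inf)), "non-finite")
  expect_error(cohort_config(missing_rate = 1.5), "missing_rate")
  expect_error(cohort_config(correlation_spec = list(
    list(pair = c("t2", "t3"), slope = 1, intercept = 0, sd = 0))), "sd")
})

test_that("PN visibility follows the configured 17 +/- 2.5 h window", {
  co <- generate_cohort(cohort_config(n_mc = 0, n_lb = 800, seed = 9))
  vis <- co$profiles$tPNf - co$profiles$tPNa
  expect_equal(mean(vis), 17, tolerance = 0.05)
  expect_equal(sd(vis), 2.5, tolerance = 0.15)
})

test_that("planted effects land within 0.1 standardized units of the request", {
  req <- c(ooplasm_r = 1.0, dlr_t2_t3 = 0.5)
  co <- generate_cohort(cohort_config(n_mc = 1500, n_lb = 1500,
                                      effect_map = req, missing_rate = 0,
                                      seed = 13))
  for (f in names(req)) {
    x <- co$features[[f]]
    mc <- x[co$labels == "MC"]; lb <- x[co$labels == "LB"]
    d_emp <- (mean(mc) - mean(lb)) /
      sqrt(((length(mc) - 1) * var(mc) + (length(lb) - 1) * var(lb)) /
             (length(mc) + length(lb) - 2))
    expect_lt(abs(d_emp - req[[f]]), 0.1)
  }
  # closed form: AUC of two unit-variance normals d apart is Phi(d / sqrt 2),
  # cross-checked by the rank statistic on the simulated column
  a <- auc_rank(co$features$ooplasm_r, co$labels == "MC")
  expect_equal(a, pnorm(1 / sqrt(2)), tolerance = 0.02)
})

test_that("movie ground truth matches the trajectory kinematics", {
  st <- render_zygote_movie(movie_spec(trajectory_kind = "stationary",
                                       speed = 0, n_frames = 10, seed = 3))
  disp <- diff(st$truth$pn_small)
  expect_true(all(abs(disp) == 0))

  v <- 0.7; N <- 24
  ln <- render_zygote_movie(movie_spec(trajectory_kind = "linear", speed = v,
                                       n_frames = N, seed = 4))
  e2e <- sqrt(sum((ln$truth$pn_small[N, ] - ln$truth$pn_small[1, ])^2))
  expect_equal(e2e, v * (N - 1), tolerance = 1e-9)
  steps <- sqrt(rowSums(diff(ln$truth$pn_small)^2))
  expect_equal(sum(steps), v * (N - 1), tolerance = 1e-9)
})

test_that("default movie length derives from an N(17, 2.5^2) hour window", {
  ns <- vapply(1:200, function(s)
    movie_spec(seed = s)$n_frames, integer(1))
  hours <- (ns - 1) * 15 / 60
  expect_equal(mean(hours), 17, tolerance = 0.5)
  expect_equal(sd(hours), 2.5, tolerance = 0.5)
})

test_that("rendered PN discs agree with ground truth within a pixel (noiseless)", {
  mv <- render_zygote_movie(movie_spec(trajectory_kind = "curved", speed = 1,
                                       n_frames = 8, noise_sd = 0, seed = 6))
  tr <- mv$truth
  for (f in c(1, 4, 8)) {
    img <- mv$frames[[f]]
    for (side in c("pn_small", "pn_large")) {
      ctr <- tr[[side]][f, ]
      r <- if (side == "pn_small") tr$r_small else tr$r_large
      xs <- col(img); ys <- row(img)
      in_disc <- (xs - ctr[1])^2 + (ys - ctr[2])^2 <= r^2
      bright <- in_disc & img > 0.55  # PN level over ooplasm background
      cen <- c(mean(xs[bright]), mean(ys[bright]))
      expect_lt(sqrt(sum((cen - ctr)^2)), 1)
    }
  }
})

test_that("invalid movie specs are rejected", {
  expect_error(movie_spec(pn_radii = c(30, 40), oo_radius = 34), "smaller")
  expect_error(movie_spec(speed = -1), "speed")
  expect_error(movie_spec(n_frames = 1), "n_frames")
  expect_error(render_zygote_movie(
    movie_spec(trajectory_kind = "linear", speed = 5, n_frames = 40)),
    "speed too high")
})

test_that("cohort CSV export round-trips labels and profiles", {
  co <- tiny_cohort(n_mc = 4, n_lb = 6, seed = 1)
  dir <- tempfile()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  lab <- read.csv(file.path(dir, "labels.csv"))
  expect_equal(lab$label, as.character(co$labels))
  prof <- read.csv(file.path(dir, "profiles.csv"))
  expect_equal(prof$t2, co$profiles$t2)
  unlink(dir, recursive = TRUE)
})
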