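test_that("a static movie yields zero-step trajectories", {
  mv <- render_zygote_movie(movie_spec(trajectory_kind = "stationary",
                                       speed = 0, n_frames = 12,
                                       noise_sd = 0, seed = 8))
  tr <- mv$truth
  tj <- track_pn(mv$frames, list(center = tr$pn_small[1, ], radius = tr$r_small),
                 "forward", embryo_centers = matrix(rep(tr$oo_center, each = 12), 12),
                 seed = 2)
  expect_true(tj$reliable)
  expect_lt(max(tj$steps), 0.05)
})

test_that("forward and reverse tracking agree on a noiseless linear movie", {
  N <- 20
  mv <- render_zygote_movie(movie_spec(trajectory_kind = "linear", speed = 0.8,
                                       n_frames = N, noise_sd = 0, seed = 12))
  tr <- mv$truth
  ctr <- matrix(rep(tr$oo_center, each = N), N)
  seed_fwd <- list(center = tr$pn_large[1, ], radius = tr$r_large)
  seed_rev <- list(center = tr$pn_large[N, ], radius = tr$r_large)
  f <- track_pn(mv$frames, seed_fwd, "forward", embryo_centers = ctr, seed = 3)
  r <- track_pn(mv$frames, seed_rev, "reverse", embryo_centers = ctr, seed = 3)
  # reverse positions, re-reversed, should match the forward track per frame
  rv <- r$positions[rev(seq_len(N)), ]
  err <- sqrt(rowSums((f$positions - rv)^2))
  expect_lt(max(err), 1)
})

test_that("tracking error on rigid translation stays within a quarter PN radius", {
  mv <- render_zygote_movie(movie_spec(trajectory_kind = "linear", speed = 0.6,
                                       n_frames = 25, noise_sd = 0, seed = 14))
  tr <- mv$truth
  ctr <- matrix(rep(tr$oo_center, each = 25), 25)
  for (side in c("small", "large")) {
    pn <- tr[[paste0("pn_", side)]]
    r_pn <- tr[[paste0("r_", side)]]
    tj <- track_pn(mv$frames, list(center = pn[1, ], radius = r_pn),
                   "forward", embryo_centers = ctr, seed = 4)
    err <- sqrt(rowSums((tj$positions - sweep(pn, 2, tr$oo_center))^2))
    expect_lte(max(err) / r_pn, 0.25)
  }
})

test_that("trajectory taxonomy follows end-to-end distance and straightness", {
  r_pn <- 8
  still <- cbind(rep(3, 10), rep(4, 10))
  expect_equal(classify_trajectory(still, r_pn), "stationary")
  straight <- cbind(seq(0, 12, length.out = 10), seq(0, 6, length.out = 10))
  expect_equal(classify_trajectory(straight, r_pn), "linear")
  th <- seq(0, pi, length.out = 40)  # semicircle: straightness 2/pi ~ 0.64
  semi <- cbind(10 * cos(th), 10 * sin(th))
  expect_equal(classify_trajectory(semi, r_pn), "curved")
  expect_error(classify_trajectory(straight[1:2, ], r_pn), "3 positions")
})

test_that("the dynamics catalog has 162 entries with correct f5 and f6", {
  sm <- cbind(c(0, 2, 2, 2), c(5, 5, 5, 5))       # steps 2, 0, 0 -> max 2
  lg <- cbind(c(0, 0, 0, 0), c(-5, -1, -1, -1))   # steps 4, 0, 0 -> max 4
  v <- pn_dynamics_features(traj_pair(sm, lg), r_o = 30)
  expect_length(v, 162)
  expect_identical(names(v), pn_dynamics_feature_names())
  expect_equal(v[["step_max_ratio_fwd"]], 2.0)    # f5 = 4 / 2
  # f6: centre distances at the final (tPNf) frame: |1 - sqrt(29)|
  expect_equal(v[["cdist_absdiff_final_raw_fwd"]],
               abs(1 - sqrt(4 + 25)))
  expect_equal(v[["pndist_first_fwd"]], 10)
  # reverse features mirror the forward episode
  expect_equal(v[["step_max_ratio_rev"]], 2.0)
})

test_that("equal maximal steps give f5 = 1 and symmetric PNs give f6 = 0", {
  sm <- cbind(c(0, 3, 3), c(2, 2, 2))
  lg <- cbind(c(0, -3, -3), c(-2, -2, -2))
  v <- pn_dynamics_features(traj_pair(sm, lg), r_o = 30)
  expect_equal(v[["step_max_ratio_fwd"]], 1)
  expect_equal(v[["cdist_absdiff_final_raw_fwd"]], 0)
})

test_that("a motionless small PN flags f5 as missing", {
  sm <- cbind(c(1, 1, 1), c(1, 1, 1))
  lg <- cbind(c(0, 2, 4), c(0, 0, 0))
  v <- pn_dynamics_features(traj_pair(sm, lg), r_o = 30)
  expect_true(is.na(v[["step_max_ratio_fwd"]]))
  expect_match(paste(attr(v, "flags"), collapse = ";"), "never moves")
})

test_that("tracked coordinates live in the embryo frame of reference", {
  # the tracker subtracts the per-frame ooplasm centre, so features are
  # invariant to where the embryo sits in the image; with the centre
  # estimated from the images themselves the positions still match truth
  mv <- render_zygote_movie(movie_spec(trajectory_kind = "linear", speed = 0.5,
                                       n_frames = 10, noise_sd = 0, seed = 21))
  tr <- mv$truth
  tj <- track_pn(mv$frames, list(center = tr$pn_small[1, ], radius = tr$r_small),
                 "forward", seed = 5)  # centres estimated from the images
  rel_true <- sweep(tr$pn_small, 2, tr$oo_center)
  expect_lt(max(sqrt(rowSums((tj$positions - rel_true)^2))), 1)
})

test_that("unreliable trajectories are flagged when tracks are lost", {
  # a seed disc in the flat background has no texture: tracks fail fast
  mv <- render_zygote_movie(movie_spec(trajectory_kind = "stationary",
                                       speed = 0, n_frames = 5,
                                       noise_sd = 0.05, seed = 16))
  tj <- suppressWarnings(
    track_pn(mv$frames, list(center = c(6, 6), radius = 4), "forward",
             seed = 6))
  expect_false(tj$reliable)
})
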