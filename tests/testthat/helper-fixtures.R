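# Shared fixtures, built in code at test time.

# Small fully-observed cohort for structural checks.
tiny_cohort <- function(n_mc = 12, n_lb = 30, seed = 7, ...) {
  generate_cohort(cohort_config(n_mc = n_mc, n_lb = n_lb,
                                missing_rate = 0, seed = seed, ...))
}

# A simple labeled feature table: `p` noise features plus optional planted
# normal shifts, for screening/model tests that do not need a full cohort.
toy_table <- function(n_per_class = 200, p = 10, planted = NULL, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- factor(rep(c("LB", "MC"), each = n_per_class),
                   levels = c("LB", "MC"))
  x <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(x) <- sprintf("v%02d", seq_len(p))
  for (f in names(planted))
    x[[f]][labels == "MC"] <- x[[f]][labels == "MC"] + planted[[f]]
  list(table = x, labels = labels)
}

fast_specs <- default_model_specs()

# Geometry with every component annotated, for morphology tests.
full_geom <- function() {
  geometry_annotation(
    oo_center = c(50, 50), oo_radius = 35, zona_inner = 38, zona_outer = 45,
    pn_small = list(center = c(44, 50), radius = 7),
    pn_large = list(center = c(56, 50), radius = 9),
    npb_small = rbind(c(44, 50), c(46, 52), c(42, 49)),
    npb_large = rbind(c(56, 50), c(58, 53)),
    frag_2c = 5, frag_4c = 10, sym_2c = 1, sym_4c = 2, cleavage_angle = 30)
}

# Hand-built trajectory object (embryo frame) for dynamics-feature tests.
make_traj <- function(pos, direction = "forward", dt = 0.25, r_pn = 8) {
  pos <- as.matrix(pos)
  steps <- sqrt(diff(pos[, 1])^2 + diff(pos[, 2])^2)
  structure(list(direction = direction, positions = pos, steps = steps,
                 velocities = steps / dt, frame_interval_h = dt,
                 n_tracks = 15L, reliable = TRUE, r_pn = r_pn),
            class = "pn_trajectory")
}

traj_pair <- function(pos_small, pos_large, dt = 0.25) {
  rev_of <- function(p) p[rev(seq_len(nrow(p))), , drop = FALSE]
  list(small = list(fwd = make_traj(pos_small, "forward", dt),
                    rev = make_traj(rev_of(as.matrix(pos_small)), "reverse", dt)),
       large = list(fwd = make_traj(pos_large, "forward", dt),
                    rev = make_traj(rev_of(as.matrix(pos_large)), "reverse", dt)))
}
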