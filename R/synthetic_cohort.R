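# Synthetic labeled cohorts (annotations + planted class effects) and
# rendered zygote movies with ground truth, so every downstream stage is
# testable without clinical data.

#' Configuration for a synthetic embryo cohort
#'
#' Defaults mirror the study conditions: a 96 MC / 368 LB class imbalance
#' and pronuclei visible for 17 +/- 2.5 h between tPNa and tPNf.
#'
#' @param n_mc,n_lb miscarriage / live-birth embryo counts.
#' @param effect_map named numeric vector: feature name -> standardized
#'   effect size (Cohen's d) planted as a class-conditional mean shift on
#'   the MC rows of that feature column.
#' @param correlation_spec list of `list(pair = c(earlier, later), slope,
#'   intercept, sd)` entries; the later event is generated from the earlier
#'   one by a linear relation with Gaussian residual (hours).
#' @param pn_visibility_mean,pn_visibility_sd PN visibility window (hours).
#' @param missing_rate completely-at-random per-cell missingness fraction
#'   applied to the feature table.
#' @param day3_fraction fraction of embryos with t5..t8 truncated
#'   (day-3 transfer before those events).
#' @param seed integer RNG seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_mc = 96, n_lb = 368, effect_map = NULL,
                          correlation_spec = default_correlation_spec(),
                          pn_visibility_mean = 17, pn_visibility_sd = 2.5,
                          missing_rate = 0.03, day3_fraction = 0,
                          seed = 1L) {
  if (n_mc < 0 || n_lb < 0) stop("negative class counts rejected")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0,1]")
  if (!is.null(effect_map)) {
    if (is.null(names(effect_map)) || any(!nzchar(names(effect_map))))
      stop("effect_map must be a named vector")
    if (any(!is.finite(effect_map))) stop("non-finite effect sizes rejected")
  }
  for (cs in correlation_spec)
    if (cs$sd <= 0) stop("correlation residual sd must be positive")
  structure(list(n_mc = as.integer(n_mc), n_lb = as.integer(n_lb),
                 effect_map = effect_map, correlation_spec = correlation_spec,
                 pn_visibility_mean = pn_visibility_mean,
                 pn_visibility_sd = pn_visibility_sd,
                 missing_rate = missing_rate, day3_fraction = day3_fraction,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_correlation_spec <- function() {
  list(list(pair = c("t2", "t3"), slope = 1.2, intercept = 6, sd = 1.6),
       list(pair = c("t5", "t6"), slope = 1.0, intercept = 2.5, sd = 1.2))
}

rgamma_ms <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

# Morphokinetic profiles: monotone event times built from positive
# increments, with selected pairs tied by linear relations.
simulate_profiles <- function(config) {
  n <- config$n_mc + config$n_lb
  ev <- mk_events()
  if (n == 0L)
    return(as.data.frame(stats::setNames(rep(list(numeric(0)), 9), ev)))
  p <- data.frame(matrix(NA_real_, n, 9, dimnames = list(NULL, ev)))
  p$tPNa <- pmax(3, stats::rnorm(n, 8, 1.5))
  vis <- pmax(8, stats::rnorm(n, config$pn_visibility_mean,
                              config$pn_visibility_sd))
  p$tPNf <- p$tPNa + vis
  p$t2 <- p$tPNf + rgamma_ms(n, 2.2, 0.8)
  incr <- c(t3 = 11, t4 = 1.8, t5 = 10, t6 = 2.5, t7 = 2, t8 = 3)
  incr_sd <- c(t3 = 2.5, t4 = 0.9, t5 = 2.5, t6 = 1.2, t7 = 1, t8 = 1.5)
  prev <- c(t3 = "t2", t4 = "t3", t5 = "t4", t6 = "t5", t7 = "t6", t8 = "t7")
  corr <- config$correlation_spec
  corr_later <- vapply(corr, function(cs) cs$pair[2], character(1))
  for (e in names(prev)) {
    k <- match(e, corr_later)
    if (!is.na(k)) {
      cs <- corr[[k]]
      base <- p[[cs$pair[1]]]
      p[[e]] <- pmax(p[[prev[e]]] + 0.1,
                     cs$slope * base + cs$intercept + stats::rnorm(n, 0, cs$sd))
    } else {
      p[[e]] <- p[[prev[e]]] + rgamma_ms(n, incr[e], incr_sd[e])
    }
  }
  p
}

rand_npb <- function(k, radius, min_sep = 2) {
  pts <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(pts) < k && tries < 500L) {
    tries <- tries + 1L
    r <- radius * sqrt(stats::runif(1)); a <- stats::runif(1, 0, 2 * pi)
    p <- c(r * cos(a), r * sin(a))
    if (nrow(pts) == 0L ||
        min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_sep)
      pts <- rbind(pts, p)
  }
  pts
}

simulate_geometry_one <- function() {
  oo_c <- c(48, 48) + stats::rnorm(2, 0, 1)
  r_o <- stats::rnorm(1, 34, 2)
  zi <- r_o + abs(stats::rnorm(1, 3, 0.7))
  zo <- zi + stats::rnorm(1, 7, 0.8)
  r_l <- stats::rnorm(1, 9, 0.7)
  r_s <- max(4, r_l - abs(stats::rnorm(1, 1.4, 0.4)))
  sep <- (r_s + r_l) * 1.05 + abs(stats::rnorm(1, 1, 0.5))
  ang <- stats::runif(1, 0, 2 * pi)
  mid <- oo_c + stats::rnorm(2, 0, 1.5)
  c_s <- mid + sep / 2 * c(cos(ang), sin(ang))
  c_l <- mid - sep / 2 * c(cos(ang), sin(ang))
  npb_s <- sweep(rand_npb(1 + stats::rpois(1, 3), 0.75 * r_s, 1.2), 2, c_s, "+")
  npb_l <- sweep(rand_npb(1 + stats::rpois(1, 3), 0.75 * r_l, 1.2), 2, c_l, "+")
  geometry_annotation(
    oo_center = oo_c, oo_radius = r_o, zona_inner = zi, zona_outer = zo,
    pn_small = list(center = c_s, radius = r_s),
    pn_large = list(center = c_l, radius = r_l),
    npb_small = npb_s, npb_large = npb_l,
    frag_2c = sample(c(0, 5, 10, 15, 25), 1, prob = c(.35, .3, .2, .1, .05)),
    frag_4c = sample(c(0, 5, 10, 15, 25), 1, prob = c(.3, .3, .2, .13, .07)),
    sym_2c = sample(1:3, 1, prob = c(.6, .3, .1)),
    sym_4c = sample(1:3, 1, prob = c(.55, .3, .15)),
    cleavage_angle = stats::runif(1, 0, 180))
}

# A synthetic PN trajectory pair (embryo frame): a drifting random walk per
# PN over the visibility window; the reverse episode is the time-reversed
# forward one, as optical-flow tracking of rigid motion would return.
simulate_trajectories_one <- function(n_steps, r_s, r_l,
                                      frame_interval_h = 0.25) {
  mk <- function(r_pn) {
    scale <- stats::rlnorm(1, log(0.5), 0.45)
    drift <- stats::rnorm(2, 0, scale / 3)
    steps <- cbind(stats::rnorm(n_steps, drift[1], scale),
                   stats::rnorm(n_steps, drift[2], scale))
    pos <- rbind(stats::rnorm(2, 0, 4),
                 matrix(NA_real_, n_steps, 2))
    for (i in seq_len(n_steps)) pos[i + 1, ] <- pos[i, ] + steps[i, ]
    sl <- sqrt(rowSums(steps^2))
    fwd <- structure(list(direction = "forward", positions = pos,
                          steps = sl, velocities = sl / frame_interval_h,
                          frame_interval_h = frame_interval_h,
                          n_tracks = 15L, reliable = TRUE, r_pn = r_pn),
                     class = "pn_trajectory")
    rev_pos <- pos[rev(seq_len(nrow(pos))), , drop = FALSE]
    rev_t <- fwd
    rev_t$direction <- "reverse"; rev_t$positions <- rev_pos
    rev_t$steps <- rev(sl); rev_t$velocities <- rev(sl) / frame_interval_h
    list(fwd = fwd, rev = rev_t)
  }
  list(small = mk(r_s), large = mk(r_l))
}

#' Generate a labeled synthetic embryo cohort
#'
#' Produces morphokinetic profiles (monotone ordered event times with the
#' configured pairwise linear correlations), geometry annotations, synthetic
#' PN trajectories, MC/LB labels, and the derived 314-column feature table
#' with the configured class effects planted (a Cohen's d mean shift added
#' to the MC rows of each named feature). Byte-identical under a fixed seed.
#'
#' @param config a [cohort_config()].
#' @return object of class `embryo_cohort` with elements `profiles`,
#'   `geometry`, `trajectories`, `labels` (factor LB/MC), `features`
#'   (data.frame, 314 columns), `dlr_lines`, `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_mc + config$n_lb
    labels <- factor(c(rep("MC", config$n_mc), rep("LB", config$n_lb)),
                     levels = c("LB", "MC"))
    profiles <- simulate_profiles(config)
    if (config$day3_fraction > 0 && n > 0) {
      cut <- which(stats::runif(n) < config$day3_fraction)
      profiles[cut, c("t5", "t6", "t7", "t8")] <- NA_real_
    }
    geometry <- lapply(seq_len(n), function(i) simulate_geometry_one())
    trajectories <- lapply(seq_len(n), function(i) {
      vis <- if (n > 0) profiles$tPNf[i] - profiles$tPNa[i] else 17
      n_steps <- max(2L, round(vis / 0.25))
      g <- geometry[[i]]
      simulate_trajectories_one(n_steps, g$pn_small$radius, g$pn_large$radius)
    })
    cohort <- structure(list(profiles = profiles, geometry = geometry,
                             trajectories = trajectories, labels = labels,
                             config = config),
                        class = "embryo_cohort")
    ft <- build_feature_table(cohort)
    cohort$dlr_lines <- attr(ft, "dlr_lines")
    # planted class effects: shift MC rows by d pooled standard deviations
    if (!is.null(config$effect_map)) {
      for (f in names(config$effect_map)) {
        if (!f %in% names(ft)) stop("effect_map names unknown feature: ", f)
        s <- stats::sd(ft[[f]], na.rm = TRUE)
        if (!is.finite(s) || s == 0) s <- 1
        ft[[f]][labels == "MC"] <- ft[[f]][labels == "MC"] +
          config$effect_map[[f]] * s
      }
    }
    if (config$missing_rate > 0 && n > 0) {
      m <- as.matrix(ft)
      drop <- matrix(stats::runif(length(m)) < config$missing_rate,
                     nrow(m), ncol(m))
      m[drop] <- NA_real_
      ft <- as.data.frame(m)
    }
    cohort$features <- ft
    cohort
  })
}

#' Derive the full 314-column feature table of a cohort
#'
#' Concatenates the 35 static morphology features, the 117 morphokinetic
#' features (9 event times, 36 intervals, 36 ratios, 36 DLR statistics with
#' regression lines fitted on the LB embryos indexed by `lb_fit_idx`), and
#' the 162 PN-dynamics features.
#'
#' @param cohort an `embryo_cohort`.
#' @param lb_fit_idx row indices whose LB members fit the DLR lines
#'   (default: all rows; only LB-labeled rows are ever used).
#' @return data.frame with 314 named columns and a `dlr_lines` attribute.
#' @export
build_feature_table <- function(cohort, lb_fit_idx = NULL) {
  n <- length(cohort$labels)
  if (is.null(lb_fit_idx)) lb_fit_idx <- seq_len(n)
  lb_rows <- lb_fit_idx[cohort$labels[lb_fit_idx] == "LB"]
  lines <- fit_dlr_lines(cohort$profiles[lb_rows, , drop = FALSE])
  nm <- feature_names()
  out <- matrix(NA_real_, n, length(nm), dimnames = list(NULL, nm))
  for (i in seq_len(n)) {
    mo <- morphology_catalog(cohort$geometry[[i]])
    mk <- morphokinetics_catalog(cohort$profiles[i, ], lines)
    g <- cohort$geometry[[i]]
    pd <- pn_dynamics_features(cohort$trajectories[[i]], g$oo_radius)
    out[i, names(mo)] <- mo
    out[i, names(mk)] <- mk
    out[i, names(pd)] <- pd
  }
  out <- as.data.frame(out)
  attr(out, "dlr_lines") <- lines
  out
}

#' Names and partition of the full 314-feature catalog
#'
#' @return `feature_names()`: character vector of all 314 catalog columns;
#'   `feature_blocks()`: named list partitioning them into morphology (35),
#'   morphokinetics (117) and PN dynamics (162).
#' @export
feature_names <- function() {
  c(morphology_feature_names(), morphokinetics_feature_names(),
    pn_dynamics_feature_names())
}

#' @rdname feature_names
#' @export
feature_blocks <- function() {
  list(morphology = morphology_feature_names(),
       morphokinetics = morphokinetics_feature_names(),
       pn_dynamics = pn_dynamics_feature_names())
}

#' The feature data dictionary
#'
#' One row per catalog feature: name, block, group and a short definition.
#' The shipped copy lives at
#' `system.file("extdata", "feature_dictionary.csv", package = "embryoscreen")`.
#'
#' @return data.frame with columns `name`, `block`, `group`, `definition`.
#' @export
feature_dictionary <- function() {
  blocks <- feature_blocks()
  grp <- function(nm) {
    ifelse(grepl("^(sym|frag)_", nm), "cleavage grades",
    ifelse(grepl("^pn_", nm), ifelse(grepl("dist_center|sep", nm),
                                     "PN location", "PN size"),
    ifelse(grepl("^npb_n_", nm), "NPB counts",
    ifelse(grepl("^npb_", nm), "NPB spatial distribution",
    ifelse(nm == "cleavage_angle", "cleavage plane",
    ifelse(grepl("_r$|zona|pvs", nm), "ooplasm/zona radii",
    ifelse(nm %in% mk_events(), "event times",
    ifelse(grepl("^int_", nm), "pairwise intervals",
    ifelse(grepl("^ratio_", nm), "pairwise ratios",
    ifelse(grepl("^dlr_", nm), "DLR",
    ifelse(grepl("^(step|vel)_", nm), "PN step size and velocity",
    ifelse(grepl("^pndist_", nm), "inter-PN distance",
           "PN distance from embryo centre"))))))))))))
  }
  defs <- c(
    npb_maxdist_small_norm = "f1: max pairwise NPB distance in the small PN / R_PN",
    ooplasm_r = "f2: ooplasm radius (pixels)",
    dlr_t2_t3 = "f3: distance from the LB t2-t3 regression line (hours)",
    dlr_t5_t6 = "f4: distance from the LB t5-t6 regression line (hours)",
    step_max_ratio_fwd = "f5: max step of large PN / max step of small PN (forward)",
    cdist_absdiff_final_raw_fwd = "f6: |l_l - l_s| PN-centre distances at tPNf (pixels)")
  nm <- feature_names()
  block <- rep(names(blocks), lengths(blocks))
  dd <- data.frame(name = nm, block = block, group = grp(nm),
                   definition = ifelse(nm %in% names(defs), defs[nm], ""),
                   stringsAsFactors = FALSE)
  rownames(dd) <- NULL
  dd
}

#' Write cohort annotation tables and labels to CSV
#'
#' @param cohort an `embryo_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(cohort$labels)
  pack_pts <- function(m) if (is.null(m) || nrow(m) == 0) "" else
    paste(apply(round(m, 3), 1, paste, collapse = ":"), collapse = ";")
  geom <- do.call(rbind, lapply(seq_len(n), function(i) {
    g <- cohort$geometry[[i]]
    data.frame(embryo_id = i, oo_x = g$oo_center[1], oo_y = g$oo_center[2],
               oo_radius = g$oo_radius, zona_inner = g$zona_inner,
               zona_outer = g$zona_outer,
               pn_small_x = g$pn_small$center[1], pn_small_y = g$pn_small$center[2],
               pn_small_r = g$pn_small$radius,
               pn_large_x = g$pn_large$center[1], pn_large_y = g$pn_large$center[2],
               pn_large_r = g$pn_large$radius,
               npb_small = pack_pts(g$npb_small), npb_large = pack_pts(g$npb_large),
               frag_2c = g$frag_2c, frag_4c = g$frag_4c,
               sym_2c = g$sym_2c, sym_4c = g$sym_4c,
               cleavage_angle = g$cleavage_angle)
  }))
  paths <- file.path(dir, c("profiles.csv", "geometry.csv", "features.csv",
                            "labels.csv"))
  utils::write.csv(cbind(embryo_id = seq_len(n), cohort$profiles),
                   paths[1], row.names = FALSE)
  utils::write.csv(geom, paths[2], row.names = FALSE)
  utils::write.csv(cbind(embryo_id = seq_len(n), cohort$features),
                   paths[3], row.names = FALSE)
  utils::write.csv(data.frame(embryo_id = seq_len(n),
                              label = as.character(cohort$labels)),
                   paths[4], row.names = FALSE)
  invisible(paths)
}

# ---- Synthetic zygote movies -----------------------------------------------

#' Specification of a rendered synthetic zygote movie
#'
#' When `n_frames` is `NULL` it is derived from a PN-visibility window drawn
#' from N(17, 2.5^2) hours at the given frame interval.
#'
#' @param frame_size square frame side in pixels.
#' @param n_frames number of frames (>= 2), or `NULL` to derive.
#' @param frame_interval minutes between frames.
#' @param oo_radius ooplasm radius R_o in pixels.
#' @param pn_radii pixel radii of the (small, large) PN; must be < R_o.
#' @param npb_count NPBs rendered per PN.
#' @param trajectory_kind `"curved"`, `"linear"` or `"stationary"`.
#' @param speed nominal PN speed in pixels/frame (>= 0).
#' @param noise_sd additive Gaussian noise sd in gray-level units (`[0,1]`
#'   scale).
#' @param seed integer RNG seed.
#' @return object of class `movie_spec`.
#' @export
movie_spec <- function(frame_size = 96, n_frames = NULL, frame_interval = 15,
                       oo_radius = 34, pn_radii = c(7, 9), npb_count = 4,
                       trajectory_kind = c("curved", "linear", "stationary"),
                       speed = 0.5, noise_sd = 0.015, seed = 1L) {
  trajectory_kind <- match.arg(trajectory_kind)
  if (any(pn_radii >= oo_radius)) stop("PN radii must be smaller than R_o")
  if (speed < 0) stop("speed must be >= 0")
  if (is.null(n_frames)) {
    vis <- with_seed(seed, min(26, max(8, stats::rnorm(1, 17, 2.5))))
    n_frames <- round(vis * 60 / frame_interval) + 1L
  }
  if (n_frames < 2L) stop("need n_frames >= 2")
  structure(list(frame_size = as.integer(frame_size),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, oo_radius = oo_radius,
                 pn_radii = sort(pn_radii), npb_count = as.integer(npb_count),
                 trajectory_kind = trajectory_kind, speed = speed,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "movie_spec")
}

logistic_disc <- function(dist, radius, sigma = 0.8) {
  1 / (1 + exp((dist - radius) / sigma))
}

# Per-frame PN centre paths for the three trajectory taxa. Both PNs share
# the motion kind; they sit diametrically opposite so they never overlap.
pn_paths <- function(spec, oo_c) {
  N <- spec$n_frames; v <- spec$speed
  r_s <- spec$pn_radii[1]; r_l <- spec$pn_radii[2]
  ang0 <- stats::runif(1, 0, 2 * pi)
  orbit <- 0.5 * (spec$oo_radius - r_l - 2) + (r_s + r_l) / 4
  orbit <- min(orbit, spec$oo_radius - r_l - 2)
  if (orbit < (r_s + r_l) / 2 + 1)
    stop("PN radii too large for the ooplasm")
  kind <- spec$trajectory_kind
  if (kind == "stationary") {
    a <- rep(ang0, N)
    small <- cbind(oo_c[1] + orbit * cos(a), oo_c[2] + orbit * sin(a))
    large <- cbind(oo_c[1] - orbit * cos(a), oo_c[2] - orbit * sin(a))
  } else if (kind == "curved") {
    w <- v / orbit
    a <- ang0 + w * (seq_len(N) - 1)
    small <- cbind(oo_c[1] + orbit * cos(a), oo_c[2] + orbit * sin(a))
    large <- cbind(oo_c[1] - orbit * cos(a), oo_c[2] - orbit * sin(a))
  } else {  # linear: parallel opposite-sense paths, centred in the ooplasm
    L <- v * (N - 1)
    if (L / 2 + r_l + 2 > spec$oo_radius)
      stop("speed too high: linear path leaves the ooplasm")
    u <- c(cos(ang0), sin(ang0)); perp <- c(-u[2], u[1])
    h <- (r_s + r_l) / 2 + 1.5
    t <- v * (seq_len(N) - 1) - L / 2
    small <- cbind(oo_c[1] + t * u[1] + h * perp[1],
                   oo_c[2] + t * u[2] + h * perp[2])
    large <- cbind(oo_c[1] - t * u[1] - h * perp[1],
                   oo_c[2] - t * u[2] - h * perp[2])
  }
  list(small = small, large = large)
}

#' Render a synthetic zygote movie with ground truth
#'
#' Renders a grayscale stack: a dark ooplasm disc inside a zona ring, two
#' brighter PN discs (each carrying `npb_count` dark NPB spots rigidly
#' attached), the PNs moving per `trajectory_kind`, flat-intensity discs
#' with smooth (logistic) edges, plus additive Gaussian noise. The returned
#' ground truth holds the exact per-frame PN centres, NPB coordinates, and
#' ooplasm centre/radius used for rendering.
#'
#' @param spec a [movie_spec()].
#' @return list with `frames` (list of `[0,1]` matrices), `truth` (list:
#'   `oo_center`, `oo_radius`, `pn_small`, `pn_large` n x 2 centre paths,
#'   `npb_small`, `npb_large` per-frame coordinate lists, `r_small`,
#'   `r_large`), and `spec`.
#' @export
render_zygote_movie <- function(spec = movie_spec()) {
  stopifnot(inherits(spec, "movie_spec"))
  with_seed(spec$seed, {
    sz <- spec$frame_size
    oo_c <- c(sz, sz) / 2 + 0.5
    if (spec$oo_radius + max(spec$pn_radii) > sz / 2 - 1)
      stop("ooplasm does not fit in the frame")
    paths <- pn_paths(spec, oo_c)
    r_s <- spec$pn_radii[1]; r_l <- spec$pn_radii[2]
    d0s <- sqrt(sum(paths$small[1, ] - oo_c)^2)
    if (sqrt(sum((paths$small[1, ] - oo_c)^2)) + r_s > spec$oo_radius ||
        sqrt(sum((paths$large[1, ] - oo_c)^2)) + r_l > spec$oo_radius)
      stop("PN initially outside the ooplasm")
    npb_off_s <- rand_npb(spec$npb_count, 0.7 * r_s, 1.8)
    npb_off_l <- rand_npb(spec$npb_count, 0.7 * r_l, 1.8)
    xs <- matrix(seq_len(sz), sz, sz, byrow = TRUE)
    ys <- matrix(seq_len(sz), sz, sz)
    dist2 <- function(c) sqrt((xs - c[1])^2 + (ys - c[2])^2)
    d_oo <- dist2(oo_c)
    zona_in <- spec$oo_radius + 3; zona_out <- min(sz / 2 - 1, zona_in + 6)
    base <- matrix(0.78, sz, sz)
    w_z <- logistic_disc(d_oo, zona_out) * (1 - logistic_disc(d_oo, zona_in))
    base <- base * (1 - w_z) + 0.68 * w_z
    w_o <- logistic_disc(d_oo, spec$oo_radius)
    base <- base * (1 - w_o) + 0.45 * w_o
    frames <- vector("list", spec$n_frames)
    npb_s <- npb_l <- vector("list", spec$n_frames)
    for (f in seq_len(spec$n_frames)) {
      img <- base
      for (side in c("small", "large")) {
        c_pn <- paths[[side]][f, ]
        r_pn <- if (side == "small") r_s else r_l
        off <- if (side == "small") npb_off_s else npb_off_l
        w_pn <- logistic_disc(dist2(c_pn), r_pn)
        img <- img * (1 - w_pn) + 0.62 * w_pn
        npb_abs <- sweep(off, 2, c_pn, "+")
        for (k in seq_len(nrow(npb_abs))) {
          w_n <- logistic_disc(dist2(npb_abs[k, ]), 1.6, 0.5)
          img <- img * (1 - w_n) + 0.18 * w_n
        }
        if (side == "small") npb_s[[f]] <- npb_abs else npb_l[[f]] <- npb_abs
      }
      if (spec$noise_sd > 0)
        img <- img + matrix(stats::rnorm(sz * sz, 0, spec$noise_sd), sz, sz)
      frames[[f]] <- pmin(pmax(img, 0), 1)
    }
    list(frames = frames,
         truth = list(oo_center = oo_c, oo_radius = spec$oo_radius,
                      pn_small = paths$small, pn_large = paths$large,
                      npb_small = npb_s, npb_large = npb_l,
                      r_small = r_s, r_large = r_l),
         spec = spec)
  })
}

#' Write a rendered movie as multi-page TIFF with a JSON ground-truth sidecar
#'
#' @param movie output of [render_zygote_movie()].
#' @param path TIFF path; the sidecar is written next to it as
#'   `<path>.truth.json`.
#' @return invisibly, the two paths.
#' @export
write_movie <- function(movie, path) {
  tiff::writeTIFF(movie$frames, path)
  tr <- movie$truth
  js <- list(oo_center = tr$oo_center, oo_radius = tr$oo_radius,
             r_small = tr$r_small, r_large = tr$r_large,
             pn_small = tr$pn_small, pn_large = tr$pn_large)
  jsonlite::write_json(js, paste0(path, ".truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(c(path, paste0(path, ".truth.json")))
}
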