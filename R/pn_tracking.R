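# Pronucleus (PN) dynamics: Lucas-Kanade optical-flow tracking of the two
# PNs across the tPNa..tPNf window, trajectory classification, and the
# 162-feature dynamics catalog including f5 and f6.

# ---- Lucas-Kanade point tracking -------------------------------------------

# Bilinear sampling of img (matrix [y, x], values in [0,1]) on the grid
# (cx + xs) x (cy + ys). Returns length(ys) x length(xs) matrix; NA outside.
sample_patch <- function(img, cx, cy, xs, ys) {
  h <- nrow(img); w <- ncol(img)
  gx <- cx + xs; gy <- cy + ys
  x0 <- floor(gx); y0 <- floor(gy)
  fx <- gx - x0; fy <- gy - y0
  ok_x <- x0 >= 1 & x0 < w; ok_y <- y0 >= 1 & y0 < h
  if (!all(ok_x) || !all(ok_y)) return(NULL)
  # corner values via index arithmetic (img is column-major over x)
  i00 <- outer(y0, (x0 - 1) * h, "+")
  v00 <- img[i00]; v01 <- img[i00 + h]
  v10 <- img[i00 + 1]; v11 <- img[i00 + 1 + h]
  wy <- matrix(fy, length(ys), length(xs))
  wx <- matrix(fx, length(ys), length(xs), byrow = TRUE)
  (1 - wy) * ((1 - wx) * v00 + wx * v01) + wy * ((1 - wx) * v10 + wx * v11)
}

# One Lucas-Kanade step: track point (x, y) from frame I to frame J using a
# win x win neighbourhood and iterative translation refinement. Returns the
# new position or NULL on failure (ill-conditioned system, divergence, or
# leaving the frame).
lk_track_point <- function(I, J, x, y, win = 15L, max_iter = 12L,
                           eps = 0.01) {
  half <- (win - 1L) / 2
  off <- seq(-half - 1L, half + 1L)       # extra ring for gradients
  tpl <- sample_patch(I, x, y, off, off)
  if (is.null(tpl)) return(NULL)
  core <- seq(2L, win + 1L)
  Ix <- (tpl[core, core + 1L] - tpl[core, core - 1L]) / 2
  Iy <- (tpl[core + 1L, core] - tpl[core - 1L, core]) / 2
  T0 <- tpl[core, core]
  gxx <- sum(Ix * Ix); gxy <- sum(Ix * Iy); gyy <- sum(Iy * Iy)
  det <- gxx * gyy - gxy * gxy
  if (!is.finite(det) || det < 1e-8) return(NULL)
  inner <- seq(-half, half)
  dx <- 0; dy <- 0
  for (it in seq_len(max_iter)) {
    cur <- sample_patch(J, x + dx, y + dy, inner, inner)
    if (is.null(cur)) return(NULL)
    It <- cur - T0
    bx <- sum(It * Ix); by <- sum(It * Iy)
    sx <- (gyy * bx - gxy * by) / det
    sy <- (gxx * by - gxy * bx) / det
    dx <- dx - sx; dy <- dy - sy
    if (abs(dx) > half || abs(dy) > half) return(NULL)  # diverged
    if (sx^2 + sy^2 < eps^2) break
  }
  c(x + dx, y + dy)
}

# Select n mutually non-adjacent pixels inside a disc, randomly but
# restricted to pixels where the local structure tensor of the first frame
# is well-conditioned (flat-interior pixels carry no flow information).
select_track_pixels <- function(frame, center, radius, n = 15L,
                                min_sep = 2, win = 15L) {
  h <- nrow(frame); w <- ncol(frame)
  xs <- seq_len(w); ys <- seq_len(h)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (frame[, 3:w] - frame[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (frame[3:h, ] - frame[1:(h - 2), ]) / 2
  inside <- which(outer(ys - center[2], xs - center[1],
                        function(a, b) a^2 + b^2) <= (radius - 1)^2,
                  arr.ind = TRUE)
  if (nrow(inside) == 0L) stop("seed disc contains no pixels")
  # smoothed gradient energy as a cheap min-eigenvalue proxy
  energy <- gx^2 + gy^2
  box <- function(m) {
    k <- matrix(0, h, w)
    m2 <- rbind(0, m, 0); m2 <- cbind(0, m2, 0)
    for (dy in -1:1) for (dx in -1:1)
      k <- k + m2[2:(h + 1) + dy, 2:(w + 1) + dx]
    k
  }
  energy <- box(energy)
  e_in <- energy[inside]
  thr <- stats::quantile(e_in, 0.5)
  cand <- inside[e_in >= thr & e_in > 1e-6, , drop = FALSE]
  if (nrow(cand) < n) cand <- inside[order(e_in, decreasing = TRUE), , drop = FALSE]
  ord <- sample(nrow(cand))
  sel <- matrix(NA_real_, 0, 2)
  for (i in ord) {
    p <- c(cand[i, 2], cand[i, 1])  # (x, y)
    if (nrow(sel) == 0L ||
        min(sqrt((sel[, 1] - p[1])^2 + (sel[, 2] - p[2])^2)) >= min_sep)
      sel <- rbind(sel, p)
    if (nrow(sel) == n) break
  }
  if (nrow(sel) < n)
    warning("only ", nrow(sel), " non-adjacent track pixels available")
  sel
}

# Intensity-based estimate of the embryo (ooplasm) centre: every rendered
# structure (zona, ooplasm, PNs, NPBs) is darker than the background and
# concentric with the embryo, so the centroid of the clearly-dark mask is an
# unbiased centre estimate regardless of where the PNs sit.
estimate_embryo_center <- function(frame) {
  border <- c(frame[1, ], frame[nrow(frame), ], frame[, 1], frame[, ncol(frame)])
  bg <- stats::median(border)
  mask <- frame < bg - 0.06
  s <- sum(mask)
  if (s == 0) return(c((ncol(frame) + 1) / 2, (nrow(frame) + 1) / 2))
  xs <- col(frame); ys <- row(frame)
  c(sum(xs[mask]), sum(ys[mask])) / s
}

#' Track one pronucleus through an image stack
#'
#' Selects 15 mutually non-adjacent pixels inside the seed disc at the start
#' frame and tracks each with iterative Lucas-Kanade flow over a 15 x 15
#' neighbourhood across consecutive frames. The PN position per frame is the
#' mean of the surviving track coordinates, reported in the embryo frame of
#' reference (ooplasm centre subtracted per frame). Lost tracks are dropped
#' from the frame where flow fails; fewer than 8 survivors marks the
#' trajectory unreliable.
#'
#' @param frames list of grayscale matrices (values in `[0, 1]`), or a 3-d
#'   array `[y, x, frame]`.
#' @param pn_seed list with `center` (x, y) and `radius` of the PN at the
#'   start frame of the chosen direction.
#' @param direction `"forward"` (tPNa to tPNf) or `"reverse"`.
#' @param frame_interval_h hours between consecutive frames (for
#'   velocities).
#' @param embryo_centers optional n x 2 matrix of known per-frame ooplasm
#'   centres (image order); estimated by intensity centroid when `NULL`.
#' @param n_points,win number of tracked pixels and Lucas-Kanade window.
#' @param seed RNG seed for the pixel selection.
#' @return object of class `pn_trajectory`: positions (embryo frame),
#'   absolute positions, per-step displacements and velocities, surviving
#'   track count, `reliable` flag.
#' @export
track_pn <- function(frames, pn_seed, direction = c("forward", "reverse"),
                     frame_interval_h = 0.25, embryo_centers = NULL,
                     n_points = 15L, win = 15L, seed = 1L) {
  direction <- match.arg(direction)
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  n <- length(frames)
  if (n < 2L) stop("need at least 2 frames")
  ord <- if (direction == "forward") seq_len(n) else rev(seq_len(n))
  frames <- frames[ord]
  if (!is.null(embryo_centers)) embryo_centers <- embryo_centers[ord, , drop = FALSE]
  pts <- with_seed(seed,
    select_track_pixels(frames[[1]], pn_seed$center, pn_seed$radius,
                        n = n_points, win = win))
  k <- nrow(pts)
  alive <- rep(TRUE, k)
  pos_abs <- matrix(NA_real_, n, 2)
  track_x <- matrix(NA_real_, n, k); track_y <- matrix(NA_real_, n, k)
  track_x[1, ] <- pts[, 1]; track_y[1, ] <- pts[, 2]
  for (f in 2:n) {
    for (j in which(alive)) {
      nw <- lk_track_point(frames[[f - 1]], frames[[f]],
                           track_x[f - 1, j], track_y[f - 1, j], win = win)
      if (is.null(nw)) alive[j] <- FALSE
      else { track_x[f, j] <- nw[1]; track_y[f, j] <- nw[2] }
    }
    if (!any(alive)) break
  }
  surv <- alive
  centers <- matrix(NA_real_, n, 2)
  for (f in seq_len(n)) {
    centers[f, ] <- if (!is.null(embryo_centers)) embryo_centers[f, ]
                    else estimate_embryo_center(frames[[f]])
    pos_abs[f, ] <- c(mean(track_x[f, surv]), mean(track_y[f, surv]))
  }
  # anchor at the annotated seed centre: the mean of the sampled pixels is
  # offset from the disc centre by a constant that cancels in displacements
  pos_abs <- sweep(pos_abs, 2, pos_abs[1, ] - pn_seed$center)
  pos <- pos_abs - centers
  steps <- sqrt(diff(pos[, 1])^2 + diff(pos[, 2])^2)
  structure(list(direction = direction,
                 positions = pos, positions_abs = pos_abs,
                 embryo_centers = centers,
                 steps = steps,
                 velocities = steps / frame_interval_h,
                 frame_interval_h = frame_interval_h,
                 n_tracks = sum(surv),
                 reliable = sum(surv) >= 8L,
                 r_pn = pn_seed$radius),
            class = "pn_trajectory")
}

#' Classify a PN trajectory as curved, linear, or stationary
#'
#' Stationary if the end-to-end displacement is below `theta_s * r_pn`;
#' otherwise linear if the straightness (end-to-end distance over path
#' length) is at least `theta_l`, else curved.
#'
#' @param traj a `pn_trajectory` or an n x 2 position matrix (n >= 3).
#' @param r_pn PN radius in pixels (taken from the trajectory if absent).
#' @param theta_s,theta_l stationary and linearity thresholds.
#' @return one of `"stationary"`, `"linear"`, `"curved"`.
#' @export
classify_trajectory <- function(traj, r_pn = NULL, theta_s = 0.5,
                                theta_l = 0.8) {
  if (inherits(traj, "pn_trajectory")) {
    if (is.null(r_pn)) r_pn <- traj$r_pn
    pos <- traj$positions
  } else pos <- as.matrix(traj)
  pos <- pos[stats::complete.cases(pos), , drop = FALSE]
  if (nrow(pos) < 3L) stop("need at least 3 positions")
  if (is.null(r_pn)) stop("r_pn required")
  e2e <- sqrt(sum((pos[nrow(pos), ] - pos[1, ])^2))
  if (e2e < theta_s * r_pn) return("stationary")
  path <- sum(sqrt(diff(pos[, 1])^2 + diff(pos[, 2])^2))
  if (path == 0) return("stationary")
  if (e2e / path >= theta_l) "linear" else "curved"
}

# ---- PN-dynamics feature catalog -------------------------------------------

.pn_stats8 <- c("min", "max", "mean", "median", "sd", "first", "last", "sum")
.pn_stats9 <- c(.pn_stats8, "range")

summarise_series <- function(x, stats_set = .pn_stats8) {
  x <- x[is.finite(x)]
  if (length(x) == 0L)
    return(stats::setNames(rep(NA_real_, length(stats_set)), stats_set))
  vals <- c(min = min(x), max = max(x), mean = mean(x),
            median = stats::median(x),
            sd = if (length(x) > 1L) stats::sd(x) else 0,
            first = x[1], last = x[length(x)], sum = sum(x),
            range = max(x) - min(x))
  vals[stats_set]
}

pn_dynamics_feature_names <- function() {
  dirs <- c("fwd", "rev")
  nm <- character(0)
  for (d in dirs) {
    for (q in c("step", "vel")) for (p in c("small", "large"))
      nm <- c(nm, paste(q, .pn_stats8, p, d, sep = "_"))
    nm <- c(nm, paste0("step_max_ratio_", d), paste0("step_min_diff_", d),
            paste0("vel_max_ratio_", d), paste0("vel_min_diff_", d))
  }
  for (d in dirs) nm <- c(nm, paste("pndist", .pn_stats9, d, sep = "_"))
  for (d in dirs) for (p in c("small", "large")) for (s in c("raw", "norm"))
    nm <- c(nm, paste("cdist", .pn_stats8, p, s, d, sep = "_"))
  for (d in dirs) for (s in c("raw", "norm"))
    nm <- c(nm, paste0("cdist_absdiff_final_", s, "_", d),
            paste0("cdist_absdiff_mean_", s, "_", d))
  nm
}

#' The 162-feature PN-dynamics catalog
#'
#' Summarises forward and reverse trajectories of the small and large PN:
#' step-size and velocity statistics (72, including
#' `f5 = max step of the large PN / max step of the small PN` and the
#' smallest-step / slowest-velocity contrasts), inter-PN distance statistics
#' (18), and PN-to-embryo-centre distance statistics, raw and normalised by
#' the ooplasm radius (72, including `f6 = |l_l - l_s|` evaluated at the
#' tPNf frame). Missing trajectories propagate as missing values; a small PN
#' that never moves makes f5 missing (flagged).
#'
#' @param trajs nested list `list(small = list(fwd =, rev =), large = ...)`
#'   of [track_pn()] results (either direction may be `NULL`).
#' @param r_o ooplasm radius in pixels for normalisation.
#' @return named numeric vector of exactly 162 values with a `flags`
#'   attribute.
#' @export
pn_dynamics_features <- function(trajs, r_o) {
  nm <- pn_dynamics_feature_names()
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  flags <- character(0)
  dirs <- c(fwd = "fwd", rev = "rev")
  get_traj <- function(pn, d) {
    t <- trajs[[pn]][[d]]
    if (is.null(t)) return(NULL)
    t
  }
  for (d in dirs) {
    ts <- get_traj("small", d); tl <- get_traj("large", d)
    for (p in c("small", "large")) {
      t1 <- get_traj(p, d)
      if (is.null(t1)) next
      out[paste("step", .pn_stats8, p, d, sep = "_")] <-
        summarise_series(t1$steps)
      out[paste("vel", .pn_stats8, p, d, sep = "_")] <-
        summarise_series(t1$velocities)
      cd <- sqrt(rowSums(t1$positions^2))
      out[paste("cdist", .pn_stats8, p, "raw", d, sep = "_")] <-
        summarise_series(cd)
      out[paste("cdist", .pn_stats8, p, "norm", d, sep = "_")] <-
        summarise_series(cd / r_o)
    }
    if (!is.null(ts) && !is.null(tl)) {
      ms <- max(ts$steps); ml <- max(tl$steps)
      if (is.finite(ms) && ms > 0) {
        out[paste0("step_max_ratio_", d)] <- ml / ms       # f5 (forward)
        out[paste0("vel_max_ratio_", d)] <- max(tl$velocities) / max(ts$velocities)
      } else flags <- c(flags, paste0("small PN never moves (", d,
                                      "): max-step ratio missing"))
      out[paste0("step_min_diff_", d)] <- min(tl$steps) - min(ts$steps)
      out[paste0("vel_min_diff_", d)] <- min(tl$velocities) - min(ts$velocities)
      n <- min(nrow(ts$positions), nrow(tl$positions))
      dd <- sqrt(rowSums((ts$positions[seq_len(n), , drop = FALSE] -
                          tl$positions[seq_len(n), , drop = FALSE])^2))
      out[paste("pndist", .pn_stats9, d, sep = "_")] <-
        summarise_series(dd, .pn_stats9)
      cs <- sqrt(rowSums(ts$positions^2)); cl <- sqrt(rowSums(tl$positions^2))
      adiff <- abs(cl[seq_len(n)] - cs[seq_len(n)])
      # tPNf is the last frame of a forward episode, the first of a reverse one
      fin <- if (d == "fwd") adiff[n] else adiff[1]
      out[paste0("cdist_absdiff_final_raw_", d)] <- fin          # f6 (forward)
      out[paste0("cdist_absdiff_final_norm_", d)] <- fin / r_o
      out[paste0("cdist_absdiff_mean_raw_", d)] <- mean(adiff)
      out[paste0("cdist_absdiff_mean_norm_", d)] <- mean(adiff) / r_o
    }
  }
  attr(out, "flags") <- flags
  stopifnot(length(out) == 162L)
  out
}

#' Names of the six selected morphodynamic features
#'
#' Maps the short labels f1..f6 used throughout the analysis to their
#' catalog column names: f1 normalised maximal NPB distance in the small PN,
#' f2 ooplasm radius, f3/f4 the t2-t3 and t5-t6 DLR statistics, f5 the
#' large-over-small maximal step-size ratio, f6 the absolute difference of
#' the PN-to-centre distances at tPNf.
#'
#' @return named character vector.
#' @export
selected_feature_names <- function() {
  c(f1 = "npb_maxdist_small_norm", f2 = "ooplasm_r",
    f3 = "dlr_t2_t3", f4 = "dlr_t5_t6",
    f5 = "step_max_ratio_fwd", f6 = "cdist_absdiff_final_raw_fwd")
}
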