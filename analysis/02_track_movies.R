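#!/usr/bin/env Rscript
# Step 2 — pronucleus tracking on rendered zygote movies.
#
# Renders a 12-movie suite (curved / linear / stationary trajectories,
# moderate noise), tracks both pronuclei by Lucas-Kanade optical flow,
# classifies each trajectory, and measures tracking error against the
# renderer's ground truth. Writes per-movie fidelity and trajectory tables
# under results/tracking/, and one example movie as TIFF + JSON.

library(embryoscreen)

dir.create("results/tracking", showWarnings = FALSE, recursive = TRUE)
kinds <- rep(c("curved", "linear", "stationary"), 4)
speeds <- rep(c(1.0, 0.7, 0), 4)  # curved needs enough arc in 40 frames

rows <- list()
for (m in seq_along(kinds)) {
  mv <- render_zygote_movie(movie_spec(trajectory_kind = kinds[m],
                                       speed = speeds[m], n_frames = 40,
                                       noise_sd = 0.02, seed = m))
  tr <- mv$truth
  for (side in c("small", "large")) {
    pn <- tr[[paste0("pn_", side)]]
    r_pn <- tr[[paste0("r_", side)]]
    tj <- suppressWarnings(
      track_pn(mv$frames, list(center = pn[1, ], radius = r_pn),
               "forward", seed = m))
    err <- sqrt(rowSums((tj$positions - sweep(pn, 2, tr$oo_center))^2))
    rows[[length(rows) + 1]] <- data.frame(
      movie = m, kind = kinds[m], pn = side, r_pn = r_pn,
      n_tracks = tj$n_tracks,
      max_err_px = max(err), max_err_norm = max(err) / r_pn,
      classified = classify_trajectory(tj))
  }
  if (m == 1) write_movie(mv, "results/tracking/example_movie.tiff")
}
fid <- do.call(rbind, rows)
write.csv(fid, "results/tracking/fidelity.csv", row.names = FALSE)

cat("Tracked", nrow(fid), "PN trajectories across", length(kinds), "movies\n")
cat(sprintf("Worst tracking error: %.3f PN radii (bound used in QC: 0.25)\n",
            max(fid$max_err_norm)))
cat("Trajectory classification vs rendered kind:\n")
print(table(rendered = fid$kind, classified = fid$classified))
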