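#!/usr/bin/env Rscript
# Radius-cutoff selection: scan candidate radii 0.5-2.5 cm (0.1-cm steps)
# and score how well per-fish NOA separates the surface group from the
# Pachon group at each radius (rank-based two-sample AUC).

suppressPackageStartupMessages(library(vabtrack))

index <- read.csv("results/cohort_index.csv")
cfg <- session_config()
cfg$pixels_per_cm <- 40

load_clean <- function(paths) {
  lapply(paths, function(p) {
    ts <- read_tracks(p, cfg)[[1]]
    ts$pixels_per_cm <- derive_calibration(cfg, ts)
    suppressWarnings(qc_tracks(ts, cfg))
  })
}
surface <- load_clean(index$track_path[index$population == "surface"])
pachon <- load_clean(index$track_path[index$population == "pachon"])

scan <- scan_radius(surface, pachon)
write.csv(scan$table, "results/radius_scan.csv", row.names = FALSE)

cat("Per-radius separation of surface vs Pachon NOA (AUC):\n")
print(scan$table, row.names = FALSE, digits = 3)
cat(sprintf("\nBest-discriminating radius: %.1f cm (ties resolve to the smallest radius).\n",
            scan$best_radius_cm))
cat("Both groups' scripted approaches pass within 0.3 cm of the rod, so every\n")
cat("radius that contains the dwell zone separates them by count alone; the\n")
cat("scan's value on real data is locating where separation peaks.\n")
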