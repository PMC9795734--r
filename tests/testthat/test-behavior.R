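test_that("rod distance is Euclidean, calibrated, and translation invariant", {
  ts <- manual_track_set(hc_x = c(0, 50), hc_y = c(0, 0), pixels_per_cm = 50)
  expect_equal(rod_distance(ts, 0), 0)
  expect_equal(rod_distance(ts, 1), 1)
  shift <- ts
  for (col in grep("_(x|y)$", names(shift$coords), value = TRUE)) {
    shift$coords[[col]] <- shift$coords[[col]] + 123.4
  }
  expect_equal(rod_distance(shift, 0:1), rod_distance(ts, 0:1))
  uncal <- ts; uncal$pixels_per_cm <- NULL
  expect_error(rod_distance(uncal, 0), "uncalibrated")
  expect_error(rod_distance(ts, 2), "out of range")
})

test_that("side classification follows marker proximity with a deterministic tie-break", {
  ts <- manual_track_set(hc_x = c(0, 0, 0), hc_y = 0,
                         hl_x = c(-1, 2, -5), hr_x = c(1, 1, 5))
  expect_equal(classify_side(ts, 0), "left")
  expect_equal(classify_side(ts, 1), "right")
  # exact tie with no prior frame -> left; tie after a frame inherits
  tie <- manual_track_set(hc_x = c(0, 0, 0), hc_y = 0,
                          hl_x = c(-1, 2, -1), hr_x = c(1, 2, 1),
                          hl_y = c(0, 1, 0), hr_y = c(0, -1, 0))
  expect_equal(classify_side(tie, 1), "left")
  tie2 <- manual_track_set(hc_x = c(0, 0), hc_y = 0,
                           hl_x = c(2, 1), hr_x = c(1, 1))
  expect_equal(classify_side(tie2, 0), "right")
  expect_equal(classify_side(tie2, 1), "right")  # tie inherits previous side
})

test_that("approach detection matches hand-built crossings", {
  # walk in once and out once: distances 3,2,1,0,1,2,3 with radius 1.3
  ts <- manual_track_set(hc_x = c(-3:3), hc_y = 0,
                         hl_x = c(-3:3) - 0.5, hr_x = c(-3:3) + 0.5,
                         hl_y = -1, hr_y = 1)
  ev <- detect_approaches(ts, 1.3)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$entry_frame, 2L)
  expect_equal(ev$exit_frame, 4L)
  expect_equal(ev$dwell_s, 3 / ts$fps)
  # never inside
  far <- manual_track_set(hc_x = rep(5, 4), hc_y = 0)
  expect_equal(nrow(detect_approaches(far, 1.3)), 0L)
  expect_equal(summarize_behavior(far, 1.3)$dir_total_s, 0)
  # closed boundary: a frame exactly at the radius is inside
  on_edge <- manual_track_set(hc_x = c(5, 1.3, 5), hc_y = 0)
  expect_equal(nrow(detect_approaches(on_edge, 1.3)), 1L)
  # session starting inside counts one event classified at frame 0
  start_in <- manual_track_set(hc_x = c(0, 0.5, 5), hc_y = 0,
                               hl_x = c(-1, 0, 4), hr_x = c(1, 1, 6))
  ev <- detect_approaches(start_in, 1.3)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$entry_frame, 0L)
  expect_equal(ev$side, "left")
  expect_error(detect_approaches(ts, -1), "radius_cm")
})

test_that("detector recovers scripted events exactly on clean sessions", {
  for (seed in 1:20) {
    sim <- simulate_session(quick_params(seed + 500, noise_sd_px = 0,
                                         n_events = sample(1:4, 1)))
    ev <- detect_approaches(sim$tracks, 1.3)
    expect_equal(ev$entry_frame, sim$truth$events$entry_frame)
    expect_equal(ev$exit_frame, sim$truth$events$exit_frame)
    expect_equal(ev$side, sim$truth$events$side)
  }
})

test_that("summaries follow per-frame side attribution and accumulate distance", {
  # 6 frames inside at 10 fps, always left-facing
  ts <- manual_track_set(hc_x = rep(0, 6), hc_y = 0,
                         hl_x = rep(-1, 6), hr_x = rep(1, 6))
  s <- summarize_behavior(ts, 1.3)
  expect_equal(s$dir_total_s, 0.6)
  expect_equal(s$dir_left_s, 0.6)
  expect_equal(s$dir_right_s, 0)
  expect_equal(s$swim_distance_cm, 0)   # stationary fish
  expect_equal(s$noa_total, 1L)         # starts inside
  # swim distance sums frame-to-frame displacement in cm
  walk <- manual_track_set(hc_x = c(0, 3, 3), hc_y = c(0, 0, 4),
                           pixels_per_cm = 1)
  expect_equal(summarize_behavior(walk, 0.5)$swim_distance_cm, 7)
})

test_that("event detection is invariant under joint spatial rescaling", {
  sim <- simulate_session(quick_params(61, n_events = 3))
  ts <- sim$tracks
  scaled <- ts
  for (col in grep("_(x|y)$", names(scaled$coords), value = TRUE)) {
    scaled$coords[[col]] <- scaled$coords[[col]] * 2.5
  }
  scaled$pixels_per_cm <- ts$pixels_per_cm * 2.5
  expect_equal(detect_approaches(scaled, 1.3), detect_approaches(ts, 1.3))
})

test_that("NOA vanishes when the radius shrinks below the closest approach", {
  sim <- simulate_session(quick_params(62, n_events = 3, noise_sd_px = 0))
  # scripted closest pass is 0.3 cm less wiggle amplitude
  expect_equal(nrow(detect_approaches(sim$tracks, 0.1)), 0L)
  expect_equal(nrow(detect_approaches(sim$tracks, 1.3)), 3L)
})

test_that("radius scan scores separation by two-sample AUC and breaks ties low", {
  # group A dwells no closer than ~1.7 cm; group B reaches 0.3 cm: every
  # radius below 1.7 separates perfectly, so the tie rule returns 0.5
  mk <- function(seed, offset, radius) {
    simulate_session(quick_params(seed, n_events = 3, noise_sd_px = 0,
                                  approach_offset_cm = offset,
                                  radius_cm = radius))$tracks
  }
  low <- lapply(1:4, function(s) mk(s + 700, 1.7, 2.0))
  high <- lapply(1:4, function(s) mk(s + 800, 0.3, 1.3))
  res <- scan_radius(low, high)
  expect_equal(res$best_radius_cm, 0.5)
  expect_equal(res$table$auc[res$table$radius_cm < 1.6], rep(1, 11))
  # identical groups score at chance everywhere; smallest radius returned
  same <- lapply(1:4, function(s) mk(s + 900, 0.3, 1.3))
  res0 <- scan_radius(same, same)
  expect_true(all(abs(res0$table$auc - 0.5) < 1e-12))
  expect_equal(res0$best_radius_cm, 0.5)
  # single-radius grid returns that radius
  res1 <- scan_radius(low, high, radii = 1.3)
  expect_equal(res1$best_radius_cm, 1.3)
  expect_equal(nrow(res1$table), 1L)
  expect_error(scan_radius(low[1], high), "at least 2")
})
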