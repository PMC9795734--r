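cfg1 <- session_config(fps = 20, pixels_per_cm = 40)

test_that("write/read round-trip is the identity on coordinates and likelihoods", {
  sim <- simulate_session(quick_params(1, fps = 20))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_tracks(sim$tracks, tf)
  back <- read_tracks(tf, session_config(fps = 10, pixels_per_cm = 40))
  expect_length(back, 1)
  expect_identical(back[[1]]$coords, sim$tracks$coords)
})

test_that("a single-arena 3-frame file parses to one track set of 3 frames", {
  ts <- manual_track_set(hc_x = c(0, 1, 2), hc_y = 0)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_tracks(ts, tf)
  got <- read_tracks(tf, session_config(fps = 10, pixels_per_cm = 1))
  expect_equal(n_frames(got[[1]]), 3L)
})

test_that("two-arena files split into per-arena track sets with shared frame count", {
  roles <- c("head_left", "head_center", "head_right", "caudal", "rod")
  mm <- list(dish1 = setNames(paste0(roles, "1"), roles),
             dish2 = setNames(paste0(roles, "2"), roles))
  cfg <- session_config(fps = 20, pixels_per_cm = 40, marker_map = mm)
  a <- simulate_session(quick_params(5, fps = 20))$tracks; a$arena_id <- "dish1"
  b <- simulate_session(quick_params(6, fps = 20))$tracks; b$arena_id <- "dish2"
  tf <- withr::local_tempfile(fileext = ".csv")
  write_tracks(list(a, b), tf,
               marker_map = list(dish1 = mm$dish1, dish2 = mm$dish2))
  got <- read_tracks(tf, cfg)
  expect_length(got, 2)
  expect_equal(n_frames(got[[1]]), n_frames(got[[2]]))
  expect_identical(got[[1]]$coords, a$coords)
  expect_identical(got[[2]]$coords, b$coords)
})

test_that("an empty track set writes a header-only file that reads back empty", {
  ts <- manual_track_set(hc_x = numeric(0), hc_y = numeric(0))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_tracks(ts, tf)
  expect_length(readLines(tf), 3L)
  back <- read_tracks(tf, session_config(fps = 10, pixels_per_cm = 1))
  expect_equal(n_frames(back[[1]]), 0L)
})

test_that("ambiguous merges and malformed files fail with a named cause", {
  a <- manual_track_set(hc_x = 0:2, hc_y = 0)
  expect_error(write_tracks(list(a, a), withr::local_tempfile()),
               "arena_id")
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), tf)
  expect_error(read_tracks(tf, cfg1), "empty")
  writeLines(c("x,y", "1,2"), tf)
  expect_error(read_tracks(tf, cfg1), "3 header rows")
  writeLines(c("foo,a", "bodyparts,a", "coords,x", "0,1"), tf)
  expect_error(read_tracks(tf, cfg1), "scorer")
  # missing marker column is named in the failure
  sim <- manual_track_set(hc_x = 0:2, hc_y = 0)
  write_tracks(sim, tf)
  txt <- readLines(tf)
  txt[2] <- gsub("rod", "stick", txt[2])
  writeLines(txt, tf)
  expect_error(read_tracks(tf, cfg1), "rod")
})

test_that("calibration: explicit value wins, arena extent derives, conflicts warn", {
  cfg <- session_config(pixels_per_cm = 10)
  expect_equal(derive_calibration(cfg), 10)
  # fish spanning 500 px in a 10-cm arena -> 50 px/cm
  ts <- manual_track_set(hc_x = c(0, 500), hc_y = c(0, 0),
                         hl_x = c(0, 500), hr_x = c(0, 500))
  cfg <- session_config(arena_diameter_cm = 10, pixels_per_cm = NULL)
  expect_equal(derive_calibration(cfg, ts), 50)
  cfg_bad <- session_config(arena_diameter_cm = 10, pixels_per_cm = 30)
  expect_warning(got <- derive_calibration(cfg_bad, ts), ">5%")
  expect_equal(got, 30)
  cfg_none <- session_config(pixels_per_cm = NULL, arena_diameter_cm = NULL)
  expect_error(derive_calibration(cfg_none), "calibration")
})

test_that("event logs round-trip through line-delimited JSON", {
  ev <- data.frame(entry_frame = c(3L, 40L), exit_frame = c(10L, 55L),
                   side = c("left", "right"))
  tf <- withr::local_tempfile(fileext = ".jsonl")
  write_event_log(ev, tf)
  expect_equal(read_event_log(tf), ev)
})

test_that("session configs round-trip through YAML", {
  cfg <- session_config(confidence_threshold = 0.9, radius_cm = 1.1,
                        fps = 25, pixels_per_cm = 33)
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_session_config(cfg, tf)
  back <- read_session_config(tf)
  expect_equal(back$confidence_threshold, 0.9)
  expect_equal(back$radius_cm, 1.1)
  expect_equal(back$fps, 25)
  expect_equal(back$pixels_per_cm, 33)
  expect_equal(back$marker_map, cfg$marker_map)
})
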