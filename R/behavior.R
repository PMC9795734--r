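# Behavioral measurements from a clean, calibrated track set: left/right
# approach events toward the vibrating rod (NOA), adherence durations inside
# and outside the radius cutoff (DIR / DOR, split by facing side), swim
# distance, and the radius-scan procedure that selects the cutoff.

.require_calibration <- function(tracks) {
  if (is.null(tracks$pixels_per_cm)) {
    stop("track_set is uncalibrated; set pixels_per_cm (see derive_calibration)")
  }
  tracks$pixels_per_cm
}

# per-frame Euclidean distance (cm) between a marker and the rod center
.dist_to_rod <- function(tracks, role) {
  ppcm <- .require_calibration(tracks)
  m <- marker_xy(tracks, role)
  rod <- marker_xy(tracks, "rod")
  sqrt((m[, "x"] - rod[, "x"])^2 + (m[, "y"] - rod[, "y"])^2) / ppcm
}

#' Distance from a marker to the rod center, in centimeters
#'
#' @param tracks a calibrated [track_set].
#' @param frame 0-based frame index.
#' @param marker marker role; default `head_center`.
#' @return distance in cm.
#' @export
rod_distance <- function(tracks, frame, marker = "head_center") {
  n <- n_frames(tracks)
  if (any(frame < 0 | frame >= n)) {
    stop("rod_distance: frame out of range [0, ", n - 1L, "]")
  }
  .dist_to_rod(tracks, marker)[frame + 1L]
}

# vectorized per-frame side attribution: "left" iff the head-left marker is
# strictly closer to the rod than the head-right marker; exact ties inherit
# the previous classified frame's side, a leading tie resolves to "left".
.side_per_frame <- function(tracks) {
  dl <- .dist_to_rod(tracks, "head_left")
  dr <- .dist_to_rod(tracks, "head_right")
  side <- ifelse(dl < dr, "left", ifelse(dl > dr, "right", NA_character_))
  if (anyNA(side)) {
    known <- which(!is.na(side))
    if (length(known) == 0L) return(rep("left", length(side)))
    idx <- findInterval(seq_along(side), known)
    filled <- side[known][pmax(idx, 1L)]
    filled[idx == 0L] <- "left"
    side <- filled
  }
  side
}

#' Classify the facing side of a frame
#'
#' A frame is left-facing when the head-left marker is strictly closer to
#' the rod than the head-right marker, right-facing in the strictly farther
#' case; an exact tie inherits the side of the previous classified frame,
#' and a tie with no prior frame is "left" (deterministic).
#'
#' @param tracks a calibrated [track_set].
#' @param frame 0-based frame index (vectorized).
#' @return character, `"left"` or `"right"`.
#' @export
classify_side <- function(tracks, frame) {
  n <- n_frames(tracks)
  if (any(frame < 0 | frame >= n)) {
    stop("classify_side: frame out of range [0, ", n - 1L, "]")
  }
  .side_per_frame(tracks)[frame + 1L]
}

#' Detect approach events toward the rod
#'
#' An approach is a maximal run of frames in which the head-center marker
#' lies within `radius_cm` of the rod center (closed boundary: distance
#' exactly equal to the radius counts as inside), entered from outside. A
#' session that begins inside the radius contributes one event whose side is
#' classified at frame 0. The side of each event is the facing side
#' ([classify_side]) at its entry frame.
#'
#' @param tracks a clean (QC'd), calibrated [track_set].
#' @param radius_cm radius cutoff in cm; default 1.3.
#' @return data.frame with one row per event: 0-based `entry_frame` and
#'   `exit_frame` (last frame inside), `side`, and `dwell_s`
#'   `= (exit_frame - entry_frame + 1) / fps`.
#' @export
detect_approaches <- function(tracks, radius_cm = 1.3) {
  if (!is.numeric(radius_cm) || radius_cm <= 0) {
    stop("detect_approaches: radius_cm must be positive")
  }
  n <- n_frames(tracks)
  empty <- data.frame(entry_frame = integer(0), exit_frame = integer(0),
                      side = character(0), dwell_s = numeric(0))
  if (n == 0L) return(empty)
  inside <- .dist_to_rod(tracks, "head_center") <= radius_cm
  if (!any(inside)) return(empty)
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  entry <- starts[keep]; exit <- ends[keep]
  side <- .side_per_frame(tracks)[entry]
  data.frame(entry_frame = entry - 1L, exit_frame = exit - 1L, side = side,
             dwell_s = (exit - entry + 1L) / tracks$fps,
             stringsAsFactors = FALSE)
}

#' Summarize one session's behavior
#'
#' Computes the per-session behavioral measures: NOA (approach counts by
#' side and total), DIR (time inside the radius, attributed per frame to the
#' facing side), DOR (time outside, likewise split by facing side), and the
#' total swim distance of the head-center marker.
#'
#' @inheritParams detect_approaches
#' @return one-row data.frame with columns `noa_left`, `noa_right`,
#'   `noa_total`, `dir_left_s`, `dir_right_s`, `dir_total_s`, `dor_s`,
#'   `dor_facing_left_s`, `dor_facing_right_s`, `swim_distance_cm`,
#'   `radius_cm`, `duration_s`.
#' @export
summarize_behavior <- function(tracks, radius_cm = 1.3) {
  ev <- detect_approaches(tracks, radius_cm)
  n <- n_frames(tracks)
  fps <- tracks$fps
  ppcm <- .require_calibration(tracks)
  if (n == 0L) {
    inside <- logical(0); side <- character(0); swim <- 0
  } else {
    inside <- .dist_to_rod(tracks, "head_center") <= radius_cm
    side <- .side_per_frame(tracks)
    hc <- marker_xy(tracks, "head_center")
    swim <- if (n < 2L) 0 else
      sum(sqrt(diff(hc[, "x"])^2 + diff(hc[, "y"])^2)) / ppcm
  }
  data.frame(
    noa_left = sum(ev$side == "left"),
    noa_right = sum(ev$side == "right"),
    noa_total = nrow(ev),
    dir_left_s = sum(inside & side == "left") / fps,
    dir_right_s = sum(inside & side == "right") / fps,
    dir_total_s = sum(inside) / fps,
    dor_s = sum(!inside) / fps,
    dor_facing_left_s = sum(!inside & side == "left") / fps,
    dor_facing_right_s = sum(!inside & side == "right") / fps,
    swim_distance_cm = swim,
    radius_cm = radius_cm,
    duration_s = n / fps
  )
}

#' Select the radius cutoff by scanning candidate radii
#'
#' For each candidate radius the per-fish NOA is recomputed in both groups
#' and group separation is scored by the rank-based two-sample AUC: the
#' probability that a randomly drawn `group_high` fish has a larger NOA than
#' a randomly drawn `group_low` fish (ties count 1/2). The radius maximizing
#' the score is returned; exact ties resolve to the smallest radius.
#'
#' @param group_low list of clean calibrated [track_set]s for the
#'   low-response group (e.g. surface fish).
#' @param group_high list of [track_set]s for the high-response group
#'   (e.g. cavefish).
#' @param radii candidate radii in cm; default `seq(0.5, 2.5, by = 0.1)`.
#' @return list with `best_radius_cm` and `table`, a data.frame of
#'   `radius_cm`, `auc`, and the two group mean NOAs per radius.
#' @export
scan_radius <- function(group_low, group_high, radii = seq(0.5, 2.5, by = 0.1)) {
  if (length(group_low) < 2L || length(group_high) < 2L) {
    stop("scan_radius: each group needs at least 2 sessions to estimate ",
         "dispersion")
  }
  if (length(radii) == 0L) stop("scan_radius: empty radius grid")
  noa_at <- function(ts, r) nrow(detect_approaches(ts, r))
  rows <- lapply(radii, function(r) {
    a <- vapply(group_low, noa_at, 0L, r = r)
    b <- vapply(group_high, noa_at, 0L, r = r)
    cmp <- outer(b, a, `-`)
    auc <- (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / length(cmp)
    data.frame(radius_cm = r, auc = auc,
               mean_noa_low = mean(a), mean_noa_high = mean(b))
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$radius_cm)
  tab <- tab[ord, , drop = FALSE]
  best <- tab$radius_cm[which.max(tab$auc)]   # first maximum = smallest radius
  list(best_radius_cm = best, table = tab)
}
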