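# Confidence-threshold quality control. A frame is unreliable when any of
# the arena's five markers falls below the pose-estimator confidence
# threshold; the whole frame (all markers) is then replaced by linear
# interpolation between the nearest reliable frames on either side.

#' Flag frames with any sub-threshold marker
#'
#' @param tracks a [track_set].
#' @param threshold confidence threshold in \[0, 1); default 0.92. A
#'   threshold of 0 flags nothing (no likelihood can be below 0).
#' @return logical vector, one element per frame; `TRUE` where the minimum
#'   marker likelihood in that frame is below `threshold`.
#' @export
flag_low_confidence <- function(tracks, threshold = 0.92) {
  stopifnot(inherits(tracks, "track_set"))
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1) {
    stop("flag_low_confidence: threshold must lie in [0, 1)")
  }
  lik <- as.matrix(tracks$coords[paste0(MARKER_ROLES, "_likelihood")])
  if (nrow(lik) == 0L) return(logical(0))
  apply(lik, 1L, min) < threshold
}

#' Repair flagged frames by whole-frame linear interpolation
#'
#' For every maximal run of flagged frames bounded by unflagged frames, the
#' x and y of all five markers are linearly interpolated between the frame
#' immediately preceding and the frame immediately following the run.
#' Flagged runs touching the session start or end have only one anchor and
#' are filled by constant extrapolation from the nearest unflagged frame
#' (with a warning naming the run length). Unflagged frames are never
#' altered. Likelihoods of repaired frames are set to `threshold` and the
#' frames tagged in the attached QC report, so provenance survives
#' round-trips; re-running the repair on its own output is the identity.
#'
#' @param tracks a [track_set].
#' @param mask logical per-frame flag vector, as from [flag_low_confidence].
#' @param threshold likelihood value stamped on repaired frames (the
#'   confidence threshold). Default 0.92.
#' @return repaired [track_set] with attribute `qc_report`: a list with
#'   `n_flagged`, `run_lengths`, and 0-based `repaired_frames`.
#' @export
interpolate_frames <- function(tracks, mask, threshold = 0.92) {
  stopifnot(inherits(tracks, "track_set"))
  n <- n_frames(tracks)
  if (length(mask) != n) {
    stop("interpolate_frames: mask length ", length(mask),
         " does not match frame count ", n)
  }
  report <- list(n_flagged = sum(mask), run_lengths = integer(0),
                 repaired_frames = which(mask) - 1L)
  if (!any(mask)) {
    attr(tracks, "qc_report") <- report
    return(tracks)
  }
  if (all(mask)) {
    stop("interpolate_frames: every frame is flagged; no reliable frame to ",
         "anchor the interpolation")
  }
  r <- rle(mask)
  report$run_lengths <- r$lengths[r$values]
  if (r$values[1L]) {
    warning("interpolate_frames: ", r$lengths[1L],
            " flagged frame(s) at session start filled by constant ",
            "extrapolation from the first reliable frame")
  }
  if (r$values[length(r$values)]) {
    warning("interpolate_frames: ", r$lengths[length(r$lengths)],
            " flagged frame(s) at session end filled by constant ",
            "extrapolation from the last reliable frame")
  }
  cs <- tracks$coords
  for (role in MARKER_ROLES) {
    for (f in c("x", "y")) {
      col <- paste(role, f, sep = "_")
      v <- cs[[col]]
      v[mask] <- NA_real_
      # linear interior interpolation, constant extrapolation at the ends
      cs[[col]] <- zoo::na.approx(v, na.rm = FALSE, rule = 2)
    }
    lcol <- paste0(role, "_likelihood")
    cs[[lcol]][mask] <- threshold
  }
  out <- track_set(cs, fps = tracks$fps, pixels_per_cm = tracks$pixels_per_cm,
                   arena_id = tracks$arena_id)
  attr(out, "qc_report") <- report
  out
}

#' One-call QC: flag and repair
#'
#' @param tracks a [track_set].
#' @param config a [session_config] supplying the confidence threshold.
#' @return repaired [track_set] (see [interpolate_frames]).
#' @export
qc_tracks <- function(tracks, config = session_config()) {
  interpolate_frames(tracks, flag_low_confidence(tracks,
                                                 config$confidence_threshold),
                     threshold = config$confidence_threshold)
}
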