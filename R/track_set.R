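#' @keywords internal
"_PACKAGE"

# Marker roles tracked in the VAB assay: three head markers, the caudal fin,
# and the vibrating rod's center.
MARKER_ROLES <- c("head_left", "head_center", "head_right", "caudal", "rod")

#' Per-arena pose-track container
#'
#' A `track_set` holds the per-frame `(x, y, likelihood)` records for the five
#' tracked markers of one arena, together with the frame rate and (optional)
#' pixel calibration. Coordinates follow the image convention: origin at the
#' top-left corner, y increasing downward, units pixels, frames indexed from 0.
#'
#' @param coords data.frame with, for each role in
#'   `head_left, head_center, head_right, caudal, rod`, three numeric columns
#'   `<role>_x`, `<role>_y`, `<role>_likelihood`. One row per frame.
#' @param fps frames per second, positive.
#' @param pixels_per_cm pixel calibration (pixels per centimeter), positive,
#'   or `NULL` when not yet calibrated.
#' @param arena_id identifier of the arena within the source video.
#'
#' @return An object of class `track_set`.
#' @export
track_set <- function(coords, fps, pixels_per_cm = NULL, arena_id = "arena1") {
  stopifnot(is.data.frame(coords))
  needed <- as.vector(t(outer(MARKER_ROLES, c("x", "y", "likelihood"),
                              function(r, f) paste(r, f, sep = "_"))))
  missing_cols <- setdiff(needed, names(coords))
  if (length(missing_cols) > 0L) {
    stop("track_set: missing marker columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("track_set: fps must be a single positive number")
  }
  if (!is.null(pixels_per_cm) &&
      (!is.numeric(pixels_per_cm) || length(pixels_per_cm) != 1L || pixels_per_cm <= 0)) {
    stop("track_set: pixels_per_cm must be a single positive number or NULL")
  }
  lik <- as.matrix(coords[paste0(MARKER_ROLES, "_likelihood")])
  if (nrow(coords) > 0L && (min(lik) < 0 || max(lik) > 1)) {
    stop("track_set: likelihoods must lie in [0, 1]")
  }
  structure(
    list(coords = coords[needed], fps = fps,
         pixels_per_cm = pixels_per_cm, arena_id = as.character(arena_id)),
    class = "track_set"
  )
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> arena '%s': %d frames @ %g fps", x$arena_id,
              n_frames(x), x$fps))
  if (is.null(x$pixels_per_cm)) cat(", uncalibrated\n")
  else cat(sprintf(", %.3g px/cm\n", x$pixels_per_cm))
  invisible(x)
}

#' Number of frames in a track set
#' @param tracks a `track_set`.
#' @return integer frame count.
#' @export
n_frames <- function(tracks) {
  stopifnot(inherits(tracks, "track_set"))
  nrow(tracks$coords)
}

#' Marker coordinates as a two-column matrix
#' @param tracks a `track_set`.
#' @param role one of `head_left`, `head_center`, `head_right`, `caudal`, `rod`.
#' @return numeric matrix with columns `x`, `y` (pixels), one row per frame.
#' @export
marker_xy <- function(tracks, role) {
  role <- match.arg(role, MARKER_ROLES)
  m <- cbind(x = tracks$coords[[paste0(role, "_x")]],
             y = tracks$coords[[paste0(role, "_y")]])
  m
}

#' Marker likelihood vector
#' @inheritParams marker_xy
#' @return numeric vector of per-frame pose-estimator confidences in \[0, 1\].
#' @export
marker_likelihood <- function(tracks, role) {
  role <- match.arg(role, MARKER_ROLES)
  tracks$coords[[paste0(role, "_likelihood")]]
}

#' Session configuration for the VAB analysis
#'
#' Bundles the analysis parameters: the pose-estimator confidence threshold
#' below which a frame is repaired, the rod-radius cutoff defining an
#' approach, the frame rate, the pixel calibration (given directly or derived
#' from the known arena diameter), and the mapping from bodypart labels in the
#' track file to the five marker roles of each arena.
#'
#' @param confidence_threshold likelihood threshold in (0, 1); frames with any
#'   marker below it are interpolated. Default 0.92.
#' @param radius_cm radius cutoff around the rod in cm. Default 1.3.
#' @param fps frames per second of the recording.
#' @param pixels_per_cm explicit pixel calibration, or `NULL`.
#' @param arena_diameter_cm physical arena diameter used to derive the
#'   calibration when `pixels_per_cm` is not given. Default 10.
#' @param marker_map named list: one element per arena (names are arena ids),
#'   each a named character vector mapping the five roles to bodypart labels
#'   in the file. `NULL` means a single arena whose labels equal the role
#'   names.
#' @return An object of class `session_config`.
#' @export
session_config <- function(confidence_threshold = 0.92, radius_cm = 1.3,
                           fps = 20, pixels_per_cm = NULL,
                           arena_diameter_cm = 10, marker_map = NULL) {
  if (!is.numeric(confidence_threshold) || confidence_threshold <= 0 ||
      confidence_threshold >= 1) {
    stop("session_config: confidence_threshold must lie in (0, 1)")
  }
  if (!is.numeric(radius_cm) || radius_cm <= 0) {
    stop("session_config: radius_cm must be positive")
  }
  if (!is.numeric(fps) || fps <= 0) stop("session_config: fps must be positive")
  if (is.null(marker_map)) {
    marker_map <- list(arena1 = stats::setNames(MARKER_ROLES, MARKER_ROLES))
  }
  for (arena in names(marker_map)) {
    mm <- marker_map[[arena]]
    if (!all(MARKER_ROLES %in% names(mm))) {
      stop("session_config: marker_map for arena '", arena,
           "' must name all five roles: ", paste(MARKER_ROLES, collapse = ", "))
    }
  }
  structure(
    list(confidence_threshold = confidence_threshold, radius_cm = radius_cm,
         fps = fps, pixels_per_cm = pixels_per_cm,
         arena_diameter_cm = arena_diameter_cm, marker_map = marker_map),
    class = "session_config"
  )
}

#' Read/write a session configuration as YAML
#'
#' @param path file path.
#' @return `read_session_config` returns a `session_config`;
#'   `write_session_config` returns `path` invisibly.
#' @export
read_session_config <- function(path) {
  raw <- yaml::read_yaml(path)
  mm <- raw$marker_map
  if (!is.null(mm)) mm <- lapply(mm, function(v) unlist(v))
  session_config(
    confidence_threshold = raw$confidence_threshold %||% 0.92,
    radius_cm = raw$radius_cm %||% 1.3,
    fps = raw$fps %||% 20,
    pixels_per_cm = raw$pixels_per_cm,
    arena_diameter_cm = raw$arena_diameter_cm %||% 10,
    marker_map = mm
  )
}

#' @rdname read_session_config
#' @param config a `session_config`.
#' @export
write_session_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  yaml::write_yaml(lapply(unclass(config), function(x) {
    if (is.list(x)) lapply(x, as.list) else x
  }), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
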