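# I/O for the pose-estimator track dialect: three stacked header rows
# (scorer / bodyparts / coords), first column the 0-based frame index, then
# x, y, likelihood triplets per bodypart. Videos holding two Petri dishes
# carry two sets of the same markers under distinct labels; the session
# config's marker_map assigns labels to arenas.

#' Read pose tracks, split by arena
#'
#' Parses a track table in the multi-header pose-estimator CSV dialect and
#' returns one [track_set] per arena configured in `config$marker_map`.
#' Markers for each arena are treated independently downstream.
#'
#' @param path path to the CSV track file.
#' @param config a [session_config]; its `marker_map` names the bodypart
#'   labels filling each arena's five roles, and its `fps` /
#'   `pixels_per_cm` are stamped onto the result.
#' @return list of [track_set], one per arena, in `marker_map` order.
#' @export
read_tracks <- function(path, config = session_config()) {
  stopifnot(inherits(config, "session_config"))
  lines <- readLines(path)
  if (length(lines) == 0L || all(!nzchar(lines))) {
    stop("read_tracks: '", path, "' is empty, not a pose track file")
  }
  if (length(lines) < 3L) {
    stop("read_tracks: '", path,
         "' is not in the pose dialect: expected 3 header rows ",
         "(scorer / bodyparts / coords)")
  }
  hdr <- lapply(lines[1:3], function(l) strsplit(l, ",", fixed = TRUE)[[1]])
  labels <- tolower(vapply(hdr, `[`, "", 1L))
  if (!identical(labels, c("scorer", "bodyparts", "coords"))) {
    stop("read_tracks: malformed header in '", path,
         "': first column of the three header rows must read ",
         "'scorer', 'bodyparts', 'coords' (got: ",
         paste(labels, collapse = ", "), ")")
  }
  bodyparts <- hdr[[2]][-1L]
  coords_row <- hdr[[3]][-1L]
  if (length(bodyparts) != length(coords_row)) {
    stop("read_tracks: header rows disagree in length in '", path, "'")
  }

  has_data <- length(lines) > 3L && any(nzchar(lines[-(1:3)]))
  dat <- if (has_data) {
    utils::read.csv(path, skip = 3L, header = FALSE, colClasses = "numeric")
  } else {
    as.data.frame(matrix(numeric(0), nrow = 0,
                         ncol = length(bodyparts) + 1L))
  }
  if (ncol(dat) != length(bodyparts) + 1L) {
    stop("read_tracks: data rows have ", ncol(dat) - 1L,
         " value columns but the header declares ", length(bodyparts))
  }
  vals <- dat[, -1L, drop = FALSE]
  col_key <- paste(bodyparts, coords_row, sep = ".")

  lapply(names(config$marker_map), function(arena) {
    mm <- config$marker_map[[arena]]
    out <- as.data.frame(matrix(numeric(0), nrow = nrow(vals), ncol = 0))
    for (role in MARKER_ROLES) {
      label <- mm[[role]]
      for (f in c("x", "y", "likelihood")) {
        j <- which(col_key == paste(label, f, sep = "."))
        if (length(j) != 1L) {
          stop("read_tracks: marker '", label, "' (role ", role,
               ", field ", f, ") not found exactly once in '", path, "'")
        }
        out[[paste(role, f, sep = "_")]] <- vals[[j]]
      }
    }
    if (anyNA(out)) {
      stop("read_tracks: ragged or missing values for arena '", arena,
           "' in '", path, "'")
    }
    track_set(out, fps = config$fps, pixels_per_cm = config$pixels_per_cm,
              arena_id = arena)
  })
}

#' Write pose tracks in the multi-header dialect
#'
#' Emits the same three-header CSV dialect that [read_tracks] consumes;
#' coordinates are written with enough digits to round-trip doubles. A list
#' of track sets (one per arena) is written side by side into one file;
#' arena ids must then be distinct, and bodypart labels are taken from
#' `marker_map` (default `<role>_<arena_id>` for multi-arena files, the bare
#' role names for a single arena).
#'
#' @param tracks a [track_set] or list of them.
#' @param path output file path.
#' @param scorer scorer tag placed in the first header row.
#' @param marker_map optional named list, as in [session_config], giving the
#'   bodypart label for every role of every arena.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, scorer = "vabtrack",
                         marker_map = NULL) {
  if (inherits(tracks, "track_set")) tracks <- list(tracks)
  stopifnot(all(vapply(tracks, inherits, TRUE, "track_set")))
  ids <- vapply(tracks, `[[`, "", "arena_id")
  if (anyDuplicated(ids)) {
    stop("write_tracks: duplicate arena_id '", ids[duplicated(ids)][1L],
         "': merging two track sets of the same arena is ambiguous")
  }
  nf <- vapply(tracks, n_frames, 0L)
  if (length(unique(nf)) > 1L) {
    stop("write_tracks: arenas disagree in frame count: ",
         paste(nf, collapse = ", "))
  }
  if (is.null(marker_map)) {
    marker_map <- if (length(tracks) == 1L) {
      stats::setNames(list(stats::setNames(MARKER_ROLES, MARKER_ROLES)), ids)
    } else {
      stats::setNames(lapply(ids, function(id) {
        stats::setNames(paste0(MARKER_ROLES, "_", id), MARKER_ROLES)
      }), ids)
    }
  }

  bodyparts <- character(0); coords <- character(0); cols <- list()
  for (ts in tracks) {
    mm <- marker_map[[ts$arena_id]]
    if (is.null(mm)) stop("write_tracks: marker_map lacks arena '", ts$arena_id, "'")
    for (role in MARKER_ROLES) {
      for (f in c("x", "y", "likelihood")) {
        bodyparts <- c(bodyparts, mm[[role]])
        coords <- c(coords, f)
        cols <- c(cols, list(ts$coords[[paste(role, f, sep = "_")]]))
      }
    }
  }
  n <- nf[1L]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste(c("scorer", rep(scorer, length(bodyparts))), collapse = ","),
    paste(c("bodyparts", bodyparts), collapse = ","),
    paste(c("coords", coords), collapse = ",")
  ), con)
  if (n > 0L) {
    body <- do.call(cbind, lapply(cols, function(v) {
      formatC(v, format = "g", digits = 17)
    }))
    utils::write.table(cbind(seq_len(n) - 1L, body), con, sep = ",",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Resolve the pixel calibration of a session
#'
#' An explicit `pixels_per_cm` in the config always wins. Otherwise the scale
#' is derived from the known physical arena diameter and the arena's extent
#' in pixels, estimated as the largest axis span covered by the fish markers
#' over the session. When both sources are available and disagree by more
#' than 5\%, a warning is raised and the explicit value is used.
#'
#' @param config a [session_config].
#' @param tracks a [track_set] used for extent estimation (optional when
#'   `pixels_per_cm` is explicit).
#' @return pixels per centimeter (positive scalar).
#' @export
derive_calibration <- function(config, tracks = NULL) {
  stopifnot(inherits(config, "session_config"))
  derived <- NULL
  if (!is.null(tracks) && !is.null(config$arena_diameter_cm) &&
      n_frames(tracks) > 0L) {
    xs <- ys <- numeric(0)
    for (role in c("head_left", "head_center", "head_right", "caudal")) {
      m <- marker_xy(tracks, role)
      xs <- c(xs, m[, "x"]); ys <- c(ys, m[, "y"])
    }
    extent_px <- max(diff(range(xs)), diff(range(ys)))
    if (extent_px > 0) derived <- extent_px / config$arena_diameter_cm
  }
  if (!is.null(config$pixels_per_cm)) {
    if (!is.null(derived) &&
        abs(derived - config$pixels_per_cm) / config$pixels_per_cm > 0.05) {
      warning(sprintf(
        "derive_calibration: explicit pixels_per_cm = %.4g disagrees with arena-derived %.4g by >5%%; using the explicit value",
        config$pixels_per_cm, derived))
    }
    return(config$pixels_per_cm)
  }
  if (!is.null(derived)) return(derived)
  stop("derive_calibration: no calibration source; set pixels_per_cm or ",
       "provide arena_diameter_cm together with tracks covering the arena")
}

#' Write / read a ground-truth event log as line-delimited JSON
#'
#' One JSON object per line with fields `entry_frame`, `exit_frame`, `side`.
#'
#' @param events data.frame with columns `entry_frame`, `exit_frame`, `side`.
#' @param path file path.
#' @return `write_event_log` returns `path` invisibly; `read_event_log`
#'   returns the events data.frame.
#' @export
write_event_log <- function(events, path) {
  stopifnot(all(c("entry_frame", "exit_frame", "side") %in% names(events)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    writeLines(jsonlite::toJSON(as.list(events[i, c("entry_frame",
                                                    "exit_frame", "side")]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(entry_frame = integer(0), exit_frame = integer(0),
                      side = character(0)))
  }
  rows <- lapply(lines, function(l) as.data.frame(jsonlite::fromJSON(l)))
  out <- do.call(rbind, rows)
  out$entry_frame <- as.integer(out$entry_frame)
  out$exit_frame <- as.integer(out$exit_frame)
  out
}
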