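# Synthetic VAB sessions with known ground truth.
#
# Trajectory model: smoothed random-waypoint wandering in the outer annulus
# of a circular arena, interleaved with scripted approach arcs toward the
# central vibrating rod. Each scripted arc drives the head-center marker
# along a straight chord whose closest pass to the rod is offset by a small
# fixed distance on the intended approach side, so the head marker on that
# side is strictly nearer the rod at the entry frame by construction; the
# fish then dwells near the closest-pass point and swims out along the same
# chord. The noise-free path therefore crosses the rod radius exactly once
# per scripted event, giving unambiguous ground truth.

#' Simulation parameters for a synthetic VAB session
#'
#' Defaults emulate the assay: a 10-cm cylindrical arena with the vibrating
#' rod at its center, recorded for 3 minutes.
#'
#' @param arena_diameter_cm arena diameter (cm). Default 10.
#' @param session_duration_s recording length (s). Default 180.
#' @param fps frames per second. Default 20.
#' @param pixels_per_cm pixel calibration of the virtual camera. Default 40.
#' @param n_events number of scripted rod approaches. Default 10.
#' @param p_right probability that an approach is right-sided, in \[0, 1\].
#' @param dwell_mean_s mean dwell time inside the radius per approach (s).
#' @param dropout_rate fraction of frames given one sub-threshold marker,
#'   in \[0, 1). Default 0 (clean).
#' @param noise_sd_px Gaussian jitter (sd, pixels) added to every marker
#'   coordinate, emulating pose-estimator localization noise. Default 1.
#' @param radius_cm rod radius the scripted events cross. Default 1.3.
#' @param swim_speed_cm_s cruising speed (cm/s). Default 4.
#' @param head_half_width_cm lateral offset of the head-left/right markers
#'   from head-center, perpendicular to the heading (cm). Default 0.35.
#' @param approach_offset_cm closest-pass distance of the approach chord to
#'   the rod center (cm); must be below `radius_cm`. Default 0.3.
#' @param body_length_cm distance from head-center back to the caudal-fin
#'   marker (cm). Default 1.2.
#' @param seed RNG seed; every stochastic output is a pure function of
#'   (params, seed).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(arena_diameter_cm = 10, session_duration_s = 180,
                       fps = 20, pixels_per_cm = 40, n_events = 10,
                       p_right = 0.5, dwell_mean_s = 1.5, dropout_rate = 0,
                       noise_sd_px = 1, radius_cm = 1.3,
                       swim_speed_cm_s = 4, head_half_width_cm = 0.35,
                       approach_offset_cm = 0.3, body_length_cm = 1.2,
                       seed = 1L) {
  p <- list(arena_diameter_cm = arena_diameter_cm,
            session_duration_s = session_duration_s, fps = fps,
            pixels_per_cm = pixels_per_cm, n_events = n_events,
            p_right = p_right, dwell_mean_s = dwell_mean_s,
            dropout_rate = dropout_rate, noise_sd_px = noise_sd_px,
            radius_cm = radius_cm, swim_speed_cm_s = swim_speed_cm_s,
            head_half_width_cm = head_half_width_cm,
            approach_offset_cm = approach_offset_cm,
            body_length_cm = body_length_cm, seed = as.integer(seed))
  pos <- c("arena_diameter_cm", "session_duration_s", "fps", "pixels_per_cm",
           "dwell_mean_s", "radius_cm", "swim_speed_cm_s",
           "head_half_width_cm", "approach_offset_cm", "body_length_cm")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0) {
      stop("sim_params: ", nm, " must be a single positive number")
    }
  }
  if (p$p_right < 0 || p$p_right > 1) stop("sim_params: p_right must lie in [0, 1]")
  if (p$dropout_rate < 0 || p$dropout_rate >= 1) {
    stop("sim_params: dropout_rate must lie in [0, 1)")
  }
  if (p$n_events < 0 || p$n_events != round(p$n_events)) {
    stop("sim_params: n_events must be a non-negative integer")
  }
  if (p$noise_sd_px < 0) stop("sim_params: noise_sd_px must be non-negative")
  if (p$approach_offset_cm >= p$radius_cm) {
    stop("sim_params: approach_offset_cm must be smaller than radius_cm")
  }
  if (p$radius_cm >= p$arena_diameter_cm / 2 - 1) {
    stop("sim_params: radius_cm leaves no outer annulus to wander in")
  }
  structure(p, class = "sim_params")
}

# unit vector; zero input keeps a fallback direction
.unit <- function(v, fallback = c(1, 0)) {
  n <- sqrt(sum(v^2))
  if (n == 0) fallback else v / n
}

# anatomical-left perpendicular of a heading, in image coordinates
# (y grows downward): left = (hy, -hx).
.left_perp <- function(h) c(h[2], -h[1])

# straight segment from `from` toward `to` at `step` cm/frame, excluding the
# start point; always lands exactly on `to`.
.segment <- function(from, to, step) {
  d <- sqrt(sum((to - from)^2))
  k <- max(1L, ceiling(d / step))
  t <- seq_len(k) / k
  cbind(from[1] + t * (to[1] - from[1]), from[2] + t * (to[2] - from[2]))
}

# random point in the wander annulus (radii in cm, rod-centered coords)
.annulus_point <- function(r_in, r_out) {
  r <- sqrt(stats::runif(1, r_in^2, r_out^2))
  a <- stats::runif(1, 0, 2 * pi)
  c(r * cos(a), r * sin(a))
}

# waypoint whose connecting chord stays outside the exclusion radius
.next_waypoint <- function(from, r_in, r_out, excl) {
  for (i in 1:200) {
    w <- .annulus_point(r_in, r_out)
    seg <- w - from
    len2 <- sum(seg^2)
    tt <- if (len2 == 0) 0 else max(0, min(1, -sum(from * seg) / len2))
    closest <- from + tt * seg
    if (sqrt(sum(closest^2)) >= excl) return(w)
  }
  stop("simulate_session: could not place a wander waypoint clear of the rod radius")
}

# wander for exactly `n` frames starting at `from`; returns n x 2 matrix
.wander <- function(from, n, step, r_in, r_out, excl) {
  out <- matrix(NA_real_, nrow = n, ncol = 2)
  cur <- from
  filled <- 0L
  while (filled < n) {
    wp <- .next_waypoint(cur, r_in, r_out, excl)
    seg <- .segment(cur, wp, step)
    take <- min(nrow(seg), n - filled)
    out[(filled + 1L):(filled + take), ] <- seg[seq_len(take), , drop = FALSE]
    filled <- filled + take
    cur <- out[filled, ]
  }
  out
}

#' Simulate one VAB session with known ground truth
#'
#' Generates the head-center path described above, derives the head-left /
#' head-right markers at a fixed half-width perpendicular to the
#' instantaneous heading (frame-to-frame displacement), places the caudal
#' marker behind the head along the heading and the rod marker at the arena
#' center, converts to pixels, adds Gaussian localization noise, and (when
#' `dropout_rate > 0`) corrupts a random subset of frames via
#' [corrupt_confidence]. Ground truth (entry/exit frames and sides) is read
#' off the noise-free scripted path, on which the radius is crossed exactly
#' `n_events` times.
#'
#' @param params a [sim_params].
#' @return list with elements `tracks` (a [track_set]) and `truth` (list:
#'   `events` data.frame with 0-based `entry_frame`, `exit_frame`, `side`;
#'   `path_cm` the true head-center path in rod-centered cm coordinates;
#'   `params` the input parameters).
#' @export
simulate_session <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed, .simulate_session_impl(params))
}

.simulate_session_impl <- function(p) {
  n_total <- round(p$fps * p$session_duration_s)
  step <- p$swim_speed_cm_s / p$fps
  arena_r <- p$arena_diameter_cm / 2
  r_in <- p$radius_cm + 0.8          # wander keeps this clearance from the rod
  r_out <- arena_r - 0.7
  if (r_in >= r_out) stop("simulate_session: arena too small for the wander annulus")
  b <- p$approach_offset_cm
  excl <- p$radius_cm + 0.4          # wander chords stay outside this

  sides <- if (p$n_events > 0) {
    ifelse(stats::runif(p$n_events) < p$p_right, "right", "left")
  } else character(0)
  dwell_frames <- if (p$n_events > 0) {
    pmax(3L, round(stats::rgamma(p$n_events, shape = 4,
                                 scale = p$dwell_mean_s / 4) * p$fps))
  } else integer(0)

  segs <- list()
  used <- 0L
  cur <- .annulus_point(r_in, r_out)
  segs[[length(segs) + 1L]] <- matrix(cur, nrow = 1)
  used <- used + 1L

  for (i in seq_len(p$n_events)) {
    # lead-in wander so events spread over the session
    target_entry <- round(n_total * (i - 0.5) / max(1L, p$n_events))
    transit_est <- ceiling((sqrt(sum(cur^2)) + arena_r) / step)
    gap <- max(5L, target_entry - used - transit_est)
    # scripted arc: approach chord offset b on the intended side
    plan <- local({
      u <- .unit(-cur)
      s <- if (sides[i] == "left") -1 else 1
      q0 <- s * b * .left_perp(u)
      v <- .unit(q0 - cur, fallback = u)
      q <- s * b * .left_perp(v)           # closest pass of the chord to the rod
      v <- .unit(q - cur, fallback = u)
      # exit continues along v until comfortably outside
      tq <- sum(q * v)
      t_exit <- sqrt((p$radius_cm + 1.0)^2 - b^2)
      list(q = q, v = v, exit_pt = q + (t_exit + 0.2) * v)
    })
    approach <- .segment(cur, plan$q, step)
    # dwell: slow circular wiggle about q (non-zero displacement keeps the
    # heading defined; stays within b + 0.1 cm of the rod, inside the radius)
    ang0 <- stats::runif(1, 0, 2 * pi)
    ang <- ang0 + (seq_len(dwell_frames[i])) * (2 * pi / (3 * p$fps))
    dwell <- cbind(plan$q[1] + 0.08 * cos(ang), plan$q[2] + 0.08 * sin(ang))
    exitseg <- .segment(dwell[nrow(dwell), ], plan$exit_pt, step)
    need <- gap + nrow(approach) + nrow(dwell) + nrow(exitseg)
    if (used + need > n_total) {
      stop(sprintf(paste0(
        "simulate_session: infeasible schedule - event %d of %d needs %d ",
        "frames but only %d of %d remain; dwell times and transit exceed ",
        "the session duration"), i, p$n_events, need, n_total - used, n_total))
    }
    wpts <- .wander(cur, gap, step, r_in, r_out, excl)
    segs[[length(segs) + 1L]] <- wpts
    segs[[length(segs) + 1L]] <- approach
    segs[[length(segs) + 1L]] <- dwell
    segs[[length(segs) + 1L]] <- exitseg
    used <- used + need
    cur <- exitseg[nrow(exitseg), ]
  }
  if (used < n_total) {
    segs[[length(segs) + 1L]] <- .wander(cur, n_total - used, step,
                                         r_in, r_out, excl)
  }
  path <- do.call(rbind, segs)[seq_len(n_total), , drop = FALSE]

  # ground truth from the noise-free scripted path (closed boundary)
  d <- sqrt(rowSums(path^2))
  inside <- d <= p$radius_cm
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev_idx <- which(r$values)
  if (length(ev_idx) != p$n_events) {
    stop("simulate_session: internal error - scripted path crossed the radius ",
         length(ev_idx), " times, expected ", p$n_events)
  }
  events <- data.frame(
    entry_frame = starts[ev_idx] - 1L,   # 0-based
    exit_frame = ends[ev_idx] - 1L,
    side = sides,
    stringsAsFactors = FALSE
  )

  # headings from frame-to-frame displacement; carry forward over rests
  disp <- rbind(path[2, , drop = FALSE] - path[1, , drop = FALSE],
                diff(path))
  hx <- disp[, 1]; hy <- disp[, 2]
  nrm <- sqrt(hx^2 + hy^2)
  zero <- nrm == 0
  if (any(zero)) {
    keep <- which(!zero)
    if (length(keep) == 0L) { hx[] <- 1; hy[] <- 0; nrm[] <- 1 }
    else {
      idx <- findInterval(seq_along(hx), keep)
      idx[idx == 0L] <- 1L
      hx <- hx[keep][idx]; hy <- hy[keep][idx]; nrm <- nrm[keep][idx]
    }
  }
  hx <- hx / nrm; hy <- hy / nrm
  lx <- hy; ly <- -hx                     # anatomical left in image coords

  w <- p$head_half_width_cm
  origin <- arena_r + 0.5                 # arena center in cm image coords
  to_px <- function(m) (m + origin) * p$pixels_per_cm
  hc <- to_px(path)
  hl <- to_px(path + w * cbind(lx, ly))
  hr <- to_px(path - w * cbind(lx, ly))
  cf <- to_px(path - p$body_length_cm * cbind(hx, hy))
  rod <- to_px(matrix(0, nrow = n_total, ncol = 2))

  noise <- function(m) m + matrix(stats::rnorm(length(m), sd = p$noise_sd_px),
                                  ncol = 2)
  if (p$noise_sd_px > 0) {
    hc <- noise(hc); hl <- noise(hl); hr <- noise(hr); cf <- noise(cf)
    rod <- noise(rod)
  }
  lik <- function() stats::runif(n_total, 0.95, 1.0)
  coords <- data.frame(
    head_left_x = hl[, 1], head_left_y = hl[, 2], head_left_likelihood = lik(),
    head_center_x = hc[, 1], head_center_y = hc[, 2],
    head_center_likelihood = lik(),
    head_right_x = hr[, 1], head_right_y = hr[, 2],
    head_right_likelihood = lik(),
    caudal_x = cf[, 1], caudal_y = cf[, 2], caudal_likelihood = lik(),
    rod_x = rod[, 1], rod_y = rod[, 2], rod_likelihood = lik()
  )
  tracks <- track_set(coords, fps = p$fps, pixels_per_cm = p$pixels_per_cm)
  if (p$dropout_rate > 0) {
    tracks <- .corrupt_impl(tracks, p$dropout_rate)
  }
  list(tracks = tracks,
       truth = list(events = events,
                    path_cm = data.frame(x_cm = path[, 1], y_cm = path[, 2]),
                    params = p))
}

#' Corrupt marker confidences to emulate pose-estimator dropouts
#'
#' Each frame is independently selected with probability `dropout_rate`; in a
#' selected frame one randomly chosen marker has its likelihood redrawn below
#' the 0.92 confidence threshold (uniform on \[0, 0.92)) and its coordinates
#' displaced by a large uniform jump, emulating a mislocalization. Frame
#' count and unselected frames are untouched.
#'
#' @param tracks a [track_set].
#' @param dropout_rate per-frame corruption probability in \[0, 1).
#' @param seed RNG seed.
#' @return corrupted [track_set].
#' @export
corrupt_confidence <- function(tracks, dropout_rate, seed = 1L) {
  stopifnot(inherits(tracks, "track_set"))
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("corrupt_confidence: dropout_rate must lie in [0, 1)")
  }
  if (dropout_rate == 0) return(tracks)
  withr::with_seed(as.integer(seed), .corrupt_impl(tracks, dropout_rate))
}

.corrupt_impl <- function(tracks, dropout_rate) {
  n <- n_frames(tracks)
  hit <- which(stats::runif(n) < dropout_rate)
  if (length(hit) == 0L) return(tracks)
  which_marker <- sample(MARKER_ROLES, length(hit), replace = TRUE)
  cs <- tracks$coords
  jump <- function(k) stats::runif(k, -50, 50)
  for (role in unique(which_marker)) {
    rows <- hit[which_marker == role]
    cs[rows, paste0(role, "_likelihood")] <- stats::runif(length(rows), 0, 0.92)
    cs[rows, paste0(role, "_x")] <- cs[rows, paste0(role, "_x")] + jump(length(rows))
    cs[rows, paste0(role, "_y")] <- cs[rows, paste0(role, "_y")] + jump(length(rows))
  }
  track_set(cs, fps = tracks$fps, pixels_per_cm = tracks$pixels_per_cm,
            arena_id = tracks$arena_id)
}
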