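#' Total traveled distance of a session
#'
#' Sum of Euclidean step lengths between consecutive frames, in cm.
#'
#' @param traj A [trajectory()].
#' @return Traveled distance in cm.
#' @export
traveled_distance <- function(traj) {
  stopifnot(inherits(traj, "trajectory"), nrow(traj) >= 2L)
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Maximum frame-to-frame velocity
#'
#' @param traj A [trajectory()].
#' @return Maximum step length divided by the sampling period, in cm/s.
#' @export
max_velocity <- function(traj) {
  stopifnot(inherits(traj, "trajectory"), nrow(traj) >= 2L)
  max(sqrt(diff(traj$x)^2 + diff(traj$y)^2)) / traj_dt(traj)
}

#' Per-frame distance to an arena landmark
#'
#' In `"relative"` mode the distance is divided by the maximum possible
#' distance from the landmark to any arena corner, so 1 means the subject is
#' as far from the landmark as the arena allows and 0 means it is at the
#' landmark.
#'
#' @param traj A [trajectory()].
#' @param arena An [arena_spec()].
#' @param landmark Landmark name.
#' @param mode `"absolute"` (cm) or `"relative"` (dimensionless, in
#'   `[0, 1]`).
#' @return A data frame of class `distance_series` with columns `t` and
#'   `value`; attributes `mode` and `landmark`.
#' @export
distance_series <- function(traj, arena, landmark, mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(traj, "trajectory"))
  p <- arena_landmark(arena, landmark)
  d <- sqrt((traj$x - p[1])^2 + (traj$y - p[2])^2)
  if (mode == "relative") {
    corners <- rbind(c(0, 0), c(arena$width, 0), c(0, arena$height),
                     c(arena$width, arena$height))
    d_max <- max(sqrt((corners[, 1] - p[1])^2 + (corners[, 2] - p[2])^2))
    d <- d / d_max
  }
  structure(data.frame(t = traj$t, value = d),
            mode = mode, landmark = landmark, dt = traj_dt(traj),
            class = c("distance_series", "data.frame"))
}

#' Trailing moving average of a distance series
#'
#' Causal (trailing) mean over the previous `window` frames; the partial
#' windows at the start of the session are averaged over the frames
#' available, so the output has the same length as the input. The default of
#' 200 frames corresponds to 40 s at 5 Hz.
#'
#' @param series A `distance_series` (or any data frame with a `value`
#'   column).
#' @param window Window length in frames (>= 1).
#' @return A `distance_series` of the same length with smoothed values.
#' @export
moving_average <- function(series, window = 200L) {
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  v <- series$value
  n <- length(v)
  cs <- cumsum(v)
  lag <- c(rep(0, min(window, n)), cs[seq_len(max(0L, n - window))])
  denom <- pmin(seq_len(n), window)
  out <- series
  out$value <- (cs - lag) / denom
  out
}

#' Subject locations at event onsets
#'
#' For each event of the requested kind, returns the trajectory sample at
#' the latest timestamp at or before the event onset (at 5 Hz the
#' discretization error is at most 0.2 s). Used for "location at water
#' delivery" overlays.
#'
#' @param traj A [trajectory()].
#' @param events An `event_log`.
#' @param kind Event kind to extract (default `"delivery"`).
#' @param dispenser Optional dispenser filter.
#' @return Data frame with columns `t` (event onset), `x`, `y`.
#' @export
locations_at_events <- function(traj, events, kind = "delivery", dispenser = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  ev <- events_of(events, kind, dispenser)
  if (nrow(ev) == 0L) return(data.frame(t = numeric(), x = numeric(), y = numeric()))
  idx <- findInterval(ev$t, traj$t)
  if (any(idx == 0L)) stop("event before the first trajectory sample", call. = FALSE)
  data.frame(t = ev$t, x = traj$x[idx], y = traj$y[idx])
}

#' First-order kinematic summary of a session
#'
#' @param session A [session_record()].
#' @param landmarks Landmark names over which to compute mean distances
#'   (defaults to every arena landmark).
#' @return A one-row data frame: `traveled_distance` (cm), `max_velocity`
#'   (cm/s), and for each landmark `mean_dist_<name>` (relative units) and
#'   `mean_dist_<name>_cm` (absolute).
#' @export
kinematics_summary <- function(session, landmarks = NULL) {
  stopifnot(inherits(session, "session_record"))
  tr <- session$trajectory; a <- session$arena
  landmarks <- landmarks %||% names(a$landmarks)
  out <- data.frame(traveled_distance = traveled_distance(tr),
                    max_velocity = max_velocity(tr))
  for (nm in landmarks) {
    out[[paste0("mean_dist_", nm)]] <-
      mean(distance_series(tr, a, nm, "relative")$value)
    out[[paste0("mean_dist_", nm, "_cm")]] <-
      mean(distance_series(tr, a, nm, "absolute")$value)
  }
  out
}
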