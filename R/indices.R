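#' Coincidence index
#'
#' Fraction of deliveries for which the subject was inside a radius of the
#' dispenser at some sampled frame during the availability window
#' `[onset, onset + window]`. This is the discrete-response measure closest
#' to classical dispenser-entry recording.
#'
#' @param traj A [trajectory()].
#' @param events An `event_log`; only deliveries to `dispenser` are used.
#' @param arena An [arena_spec()].
#' @param dispenser Dispenser landmark name.
#' @param radius Coincidence radius in cm (default the arena's
#'   `entry_radius`).
#' @param window Availability window in seconds (default the arena's
#'   `availability_duration`).
#' @param min_dwell_frames Minimum number of in-radius frames for a delivery
#'   to count (default 1).
#' @param at_onset_only If `TRUE`, only the frame at (or just before) the
#'   onset is examined instead of the whole window.
#' @return Fraction in `[0, 1]`, or `NA` when there are no deliveries.
#' @export
coincidence_index <- function(traj, events, arena, dispenser,
                              radius = arena$entry_radius,
                              window = arena$availability_duration,
                              min_dwell_frames = 1L,
                              at_onset_only = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  del <- events_of(events, "delivery", dispenser)
  if (nrow(del) == 0L) return(NA_real_)
  p <- arena_landmark(arena, dispenser)
  near <- sqrt((traj$x - p[1])^2 + (traj$y - p[2])^2) <= radius
  hits <- vapply(del$t, function(onset) {
    if (at_onset_only) {
      i <- findInterval(onset, traj$t)
      return(i >= 1L && near[i])
    }
    inside <- traj$t >= onset & traj$t <= onset + window
    sum(near & inside) >= min_dwell_frames
  }, NA)
  mean(hits)
}

#' Intensity index
#'
#' Normalizes one subject-dispenser's per-session head-entry counts by the
#' maximum count that subject produced at that dispenser in any session of
#' the experiment, so the busiest session scores 1.
#'
#' @param entry_counts Non-negative per-session entry counts for one
#'   subject-dispenser pair, in session order.
#' @return Fractions in `[0, 1]`; all-`NA` with a warning when every count
#'   is zero (0/0 is undefined, not 0).
#' @export
intensity_index <- function(entry_counts) {
  stopifnot(all(entry_counts >= 0))
  m <- max(entry_counts)
  if (m == 0) {
    warning("all entry counts are zero; intensity undefined", call. = FALSE)
    return(rep(NA_real_, length(entry_counts)))
  }
  entry_counts / m
}

#' Precision index
#'
#' Of all head entries a subject made to a dispenser in a session, the
#' fraction that occurred while that dispenser's commodity was available,
#' i.e. inside some `[delivery, delivery + window]`.
#'
#' @param events An `event_log` containing the session's deliveries and
#'   head entries.
#' @param dispenser Dispenser landmark name.
#' @param window Availability window in seconds (default 3).
#' @return Fraction in `[0, 1]`, or `NA` when the session has no entries to
#'   that dispenser.
#' @export
precision_index <- function(events, dispenser, window = 3) {
  ent <- events_of(events, "head_entry", dispenser)
  if (nrow(ent) == 0L) return(NA_real_)
  del <- events_of(events, "delivery", dispenser)
  if (nrow(del) == 0L) return(0)
  in_window <- vapply(ent$t, function(t0)
    any(t0 >= del$t & t0 <= del$t + window), NA)
  mean(in_window)
}

#' Proportion of deliveries contacted
#'
#' Fraction of a dispenser's deliveries followed by at least one head entry
#' to the same dispenser during the availability window.
#'
#' @inheritParams precision_index
#' @return Fraction in `[0, 1]`, or `NA` when there are no deliveries.
#' @export
proportion_contacted <- function(events, dispenser, window = 3) {
  del <- events_of(events, "delivery", dispenser)
  if (nrow(del) == 0L) return(NA_real_)
  ent <- events_of(events, "head_entry", dispenser)
  if (nrow(ent) == 0L) return(0)
  contacted <- vapply(del$t, function(onset)
    any(ent$t >= onset & ent$t <= onset + window), NA)
  mean(contacted)
}

#' Lower-percentile filter
#'
#' Flags the values of one subject-dispenser series that fall strictly below
#' the p-th percentile (linear interpolation between order statistics),
#' used to palliate floor/ceiling effects before summarizing precision.
#'
#' @param values Numeric vector (NA allowed; NAs are retained).
#' @param p Percentile in percent (default 5).
#' @return Logical mask in input order; `TRUE` = retained.
#' @export
percentile_filter <- function(values, p = 5) {
  stopifnot(length(values) >= 1L)
  ok <- !is.na(values)
  if (!any(ok)) return(rep(TRUE, length(values)))
  thr <- stats::quantile(values[ok], probs = p / 100, type = 7, names = FALSE)
  mask <- rep(TRUE, length(values))
  mask[ok] <- !(values[ok] < thr)
  mask
}
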