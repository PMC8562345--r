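#' Construct a trajectory
#'
#' A trajectory is a uniformly sampled 2-D path: one `(t, x, y)` row per
#' video frame, with a constant sampling period `dt` (0.2 s at the 5 Hz
#' frame rate of the tracking systems this package targets).
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing
#'   with constant step `dt`.
#' @param x,y Numeric coordinate vectors in cm (origin at the arena's
#'   lower-left corner, x rightward, y upward).
#' @param dt Sampling period in seconds.
#' @return A data frame of class `trajectory` with columns `t`, `x`, `y`
#'   and attribute `dt`.
#' @export
trajectory <- function(t, x, y, dt = 0.2) {
  stopifnot(length(t) == length(x), length(x) == length(y), dt > 0)
  if (length(t) < 2L) stop("a trajectory needs at least 2 samples", call. = FALSE)
  steps <- diff(t)
  if (any(steps <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  if (any(abs(steps - dt) > 1e-6))
    stop("timestamps must advance by dt = ", dt, " (tolerance 1e-6)", call. = FALSE)
  structure(data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y)),
            dt = dt, class = c("trajectory", "data.frame"))
}

#' Sampling period of a trajectory
#' @param traj A [trajectory()].
#' @return The sampling period in seconds.
#' @export
traj_dt <- function(traj) attr(traj, "dt")

#' Parse a raw tracking table into a validated trajectory
#'
#' Applies the cleaning rules used for video-tracking exports: missing
#' (`NA`) coordinates are forward-filled from the last valid sample;
#' coordinates outside the arena are clamped to the nearest boundary. The
#' number of clamped samples and filled frames is reported via a warning
#' and stored in attributes `n_clamped` / `n_filled`.
#'
#' @param rows Data frame with numeric columns `t`, `x`, `y`.
#' @param arena An [arena_spec()] giving the bounds used for clamping.
#' @param dt Expected sampling period in seconds (default 0.2).
#' @param max_gap Maximum run of consecutive missing frames that can be
#'   forward-filled; a longer dropout invalidates the session (default 25
#'   frames, i.e. 5 s at 5 Hz).
#' @return A [trajectory()].
#' @export
parse_trajectory_table <- function(rows, arena, dt = 0.2, max_gap = 25L) {
  stopifnot(inherits(arena, "arena_spec"), dt > 0)
  rows <- as.data.frame(rows)
  if (!all(c("t", "x", "y") %in% names(rows)))
    stop("rows must have columns t, x, y", call. = FALSE)
  if (nrow(rows) == 0L) stop("empty trajectory table", call. = FALSE)
  t <- as.numeric(rows$t); x <- as.numeric(rows$x); y <- as.numeric(rows$y)
  if (anyNA(t)) stop("missing timestamps are not allowed", call. = FALSE)
  if (any(diff(t) <= 0)) stop("non-monotonic timestamps", call. = FALSE)

  miss <- is.na(x) | is.na(y)
  n_filled <- 0L
  if (any(miss)) {
    if (miss[1L])
      stop("first sample has a missing coordinate; cannot forward-fill",
           call. = FALSE)
    runs <- rle(miss)
    if (max(runs$lengths[runs$values]) > max_gap)
      stop("tracking dropout longer than ", max_gap,
           " frames; session invalid", call. = FALSE)
    for (i in which(miss)) { x[i] <- x[i - 1L]; y[i] <- y[i - 1L] }
    n_filled <- sum(miss)
  }

  cx <- pmin(pmax(x, 0), arena$width)
  cy <- pmin(pmax(y, 0), arena$height)
  n_clamped <- sum(cx != x | cy != y)
  if (n_clamped > 0L || n_filled > 0L)
    warning(sprintf("trajectory cleaned: %d sample(s) clamped to bounds, %d frame(s) forward-filled",
                    n_clamped, n_filled), call. = FALSE)

  out <- trajectory(t, cx, cy, dt = dt)
  attr(out, "n_clamped") <- n_clamped
  attr(out, "n_filled") <- n_filled
  out
}

#' Read / write trajectory CSV files
#'
#' The on-disk dialect is a comma-separated file with header `t,x,y`
#' (UTF-8). [read_trajectory()] runs the cleaning rules of
#' [parse_trajectory_table()].
#'
#' @param path File path.
#' @param arena An [arena_spec()].
#' @param dt Sampling period in seconds.
#' @param traj A [trajectory()].
#' @return [read_trajectory()]: a [trajectory()]. [write_trajectory()]:
#'   `path`, invisibly.
#' @export
read_trajectory <- function(path, arena, dt = 0.2) {
  if (!file.exists(path)) stop("trajectory file not found: ", path, call. = FALSE)
  parse_trajectory_table(utils::read.csv(path), arena, dt = dt)
}

#' @rdname read_trajectory
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  # full precision so write -> read round-trips samples exactly
  lines <- c("t,x,y", sprintf("%.17g,%.17g,%.17g", traj$t, traj$x, traj$y))
  writeLines(lines, path)
  invisible(path)
}
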