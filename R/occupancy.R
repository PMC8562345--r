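#' Zone id of a position on the arena grid
#'
#' The arena is tiled by `G x G` virtual zones. Zone ids are 0-based and
#' row-major: `id = row(y) * G + col(x)`. Bins are half-open `[lo, hi)`
#' except the last bin on each axis, which is closed so the far walls map
#' inside the grid.
#'
#' @param x,y Position(s) in cm; vectors are accepted.
#' @param arena An [arena_spec()] (its `grid_divisions` sets `G`).
#' @return Integer zone id(s) in `0 .. G^2 - 1`.
#' @export
zone_of <- function(x, y, arena) {
  stopifnot(inherits(arena, "arena_spec"))
  if (any(x < 0 | x > arena$width | y < 0 | y > arena$height))
    stop("position outside arena bounds", call. = FALSE)
  g <- arena$grid_divisions
  col <- pmin(floor(x / (arena$width / g)), g - 1L)
  row <- pmin(floor(y / (arena$height / g)), g - 1L)
  as.integer(row * g + col)
}

#' Zone series of a trajectory
#'
#' @param traj A [trajectory()].
#' @param arena An [arena_spec()].
#' @return Integer vector of zone ids, one per frame.
#' @export
zone_series <- function(traj, arena) {
  zone_of(traj$x, traj$y, arena)
}

#' Occupancy distribution over arena zones
#'
#' Fraction of session frames spent in each zone: the empirical
#' distribution of the subject's location at the grid resolution.
#'
#' @param zones Integer zone ids (from [zone_series()]).
#' @param n_zones Total number of zones `Z = G^2`.
#' @return Numeric probability vector of length `n_zones` (sums to 1).
#' @export
occupancy <- function(zones, n_zones) {
  stopifnot(length(zones) > 0L, all(zones >= 0L & zones < n_zones))
  tabulate(zones + 1L, nbins = n_zones) / length(zones)
}

#' Shannon entropy of an occupancy distribution, in bits
#'
#' \eqn{H = -\sum_k p_k \log_2 p_k} with \eqn{0 \log 0 = 0}. Ranges from 0
#' (all frames in one zone) to \eqn{\log_2 Z} (uniform over the grid);
#' higher values mean more variable use of the arena.
#'
#' @param dist Probability vector.
#' @return Entropy in bits.
#' @export
entropy_bits <- function(dist) {
  stopifnot(all(dist >= 0), abs(sum(dist) - 1) < 1e-9)
  p <- dist[dist > 0]
  -sum(p * log2(p))
}

#' Divergence between two sessions' occupancy distributions
#'
#' The default is the Jensen-Shannon divergence in base 2:
#' \eqn{\tfrac12 KL(p\|m) + \tfrac12 KL(q\|m)} with \eqn{m = (p+q)/2}. It is
#' symmetric, zero iff the distributions are identical, and at most 1
#' (disjoint supports), and is defined even when sessions leave some zones
#' unvisited. A Kullback-Leibler option with additive `1/Z` smoothing is
#' available for comparison.
#'
#' @param p,q Probability vectors over the same zone grid.
#' @param method `"js"` (default) or `"kl"` (smoothed, asymmetric).
#' @return Dimensionless divergence (bits); in `[0, 1]` for `"js"`.
#' @export
session_divergence <- function(p, q, method = c("js", "kl")) {
  method <- match.arg(method)
  if (length(p) != length(q))
    stop("distributions must be over the same grid", call. = FALSE)
  kl2 <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  if (method == "js") {
    m <- (p + q) / 2
    0.5 * kl2(p, m) + 0.5 * kl2(q, m)
  } else {
    z <- length(p)
    ps <- (p + 1 / z) / (1 + 1); qs <- (q + 1 / z) / (1 + 1)
    kl2(ps, qs)
  }
}

#' Categorical recurrence structure of a zone series
#'
#' The recurrence plot marks frame pairs `(i, j)` occupying the same zone.
#' Checkerboard patterns indicate repeated returns to the same regions;
#' solid blocks indicate permanence. Summaries are computed by streaming
#' over zone counts and run lengths, so the `T x T` matrix is only built
#' when `materialize = TRUE`.
#'
#' @param zones Integer zone ids per frame.
#' @param materialize Build the binary `T x T` matrix (only sensible for
#'   short series or plotting).
#' @return A list of class `recurrence_result` with `recurrence_rate`
#'   (off-diagonal density, in `[0, 1]`), `permanence` (mean length of
#'   maximal constant-zone runs, frames), `transition_count` (zone changes),
#'   `n_frames`, and `matrix` (or `NULL`).
#' @export
recurrence <- function(zones, materialize = FALSE) {
  n <- length(zones)
  stopifnot(n > 0L)
  counts <- table(zones)
  rate <- if (n > 1L) sum(counts * (counts - 1)) / (n * (n - 1)) else 1
  runs <- rle(zones)
  res <- list(
    recurrence_rate = rate,
    permanence = mean(runs$lengths),
    transition_count = length(runs$lengths) - 1L,
    n_frames = n,
    matrix = if (materialize) outer(zones, zones, "==") * 1L else NULL
  )
  class(res) <- "recurrence_result"
  res
}

#' @export
print.recurrence_result <- function(x, ...) {
  cat(sprintf("<recurrence_result> %d frames: rate %.4f, permanence %.2f frames, %d transitions\n",
              x$n_frames, x$recurrence_rate, x$permanence, x$transition_count))
  invisible(x)
}

#' Downsample a zone series for recurrence plotting
#'
#' Keeps every k-th frame so the materialized plot stays at or below
#' `max_cells` per side. Summary statistics should always be computed on
#' the full series.
#'
#' @param zones Integer zone ids per frame.
#' @param max_cells Maximum frames per plot side (default 1500).
#' @return The thinned zone series.
#' @export
thin_zones <- function(zones, max_cells = 1500L) {
  n <- length(zones)
  if (n <= max_cells) return(zones)
  zones[seq(1L, n, by = ceiling(n / max_cells))]
}
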