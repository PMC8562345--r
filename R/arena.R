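#' Arena specification
#'
#' Describes the experimental chamber: its dimensions, the zone-grid
#' resolution used for occupancy measures, named landmarks (dispensers,
#' center), the coincidence radius around a dispenser, and the duration a
#' delivered commodity remains available.
#'
#' @param width,height Arena dimensions in cm. Must be positive.
#' @param landmarks Named list of length-2 numeric vectors `c(x, y)` in cm.
#'   All landmarks must lie inside the arena.
#' @param grid_divisions Number of zone divisions per axis (default 10,
#'   giving a 10 x 10 grid of virtual zones).
#' @param entry_radius Radius in cm around a dispenser within which the
#'   subject counts as present at the dispenser (default 10).
#' @param availability_duration Seconds a delivery remains available
#'   (default 3).
#' @return An object of class `arena_spec`.
#' @examples
#' arena_spec(100, 100, landmarks = list(dispenser = c(50, 50)))
#' @export
arena_spec <- function(width, height, landmarks = list(),
                       grid_divisions = 10L, entry_radius = 10,
                       availability_duration = 3) {
  stopifnot(is.numeric(width), length(width) == 1L, width > 0,
            is.numeric(height), length(height) == 1L, height > 0,
            grid_divisions >= 1L, entry_radius > 0,
            availability_duration > 0)
  if (length(landmarks)) {
    if (is.null(names(landmarks)) || any(names(landmarks) == ""))
      stop("all landmarks must be named", call. = FALSE)
    for (nm in names(landmarks)) {
      p <- landmarks[[nm]]
      if (!is.numeric(p) || length(p) != 2L)
        stop("landmark '", nm, "' must be a numeric (x, y) pair", call. = FALSE)
      if (p[1] < 0 || p[1] > width || p[2] < 0 || p[2] > height)
        stop("landmark '", nm, "' lies outside the arena", call. = FALSE)
    }
  }
  structure(
    list(width = as.numeric(width), height = as.numeric(height),
         grid_divisions = as.integer(grid_divisions),
         landmarks = lapply(landmarks, as.numeric),
         entry_radius = as.numeric(entry_radius),
         availability_duration = as.numeric(availability_duration)),
    class = "arena_spec"
  )
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec> %g x %g cm, %d x %d zones\n",
              x$width, x$height, x$grid_divisions, x$grid_divisions))
  if (length(x$landmarks))
    cat("  landmarks:",
        paste(sprintf("%s (%g, %g)", names(x$landmarks),
                      vapply(x$landmarks, `[`, 0, 1),
                      vapply(x$landmarks, `[`, 0, 2)),
              collapse = ", "), "\n")
  cat(sprintf("  entry radius %g cm, availability %g s\n",
              x$entry_radius, x$availability_duration))
  invisible(x)
}

#' Retrieve a landmark position from an arena
#'
#' @param arena An [arena_spec()].
#' @param landmark Landmark name.
#' @return Numeric `c(x, y)` in cm.
#' @export
arena_landmark <- function(arena, landmark) {
  stopifnot(inherits(arena, "arena_spec"))
  p <- arena$landmarks[[landmark]]
  if (is.null(p))
    stop("unknown landmark '", landmark, "'; arena has: ",
         paste(names(arena$landmarks), collapse = ", "), call. = FALSE)
  p
}

# Minimal TOML subset reader: [table] headers, key = value lines with
# numeric scalars or [x, y] arrays, '#' comments. No installed R package
# reads TOML, and arena files only need this subset.
parse_toml_subset <- function(lines) {
  out <- list()
  tbl <- NULL
  for (raw in lines) {
    line <- sub("#.*$", "", raw)
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[[^]]+\\]$", line)) {
      tbl <- gsub("^\\[|\\]$", "", line)
      out[[tbl]] <- list()
      next
    }
    m <- regmatches(line, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", line))[[1]]
    if (length(m) != 3L)
      stop("cannot parse TOML line: ", raw, call. = FALSE)
    key <- m[2]; val <- trimws(m[3])
    parsed <-
      if (grepl("^\\[.*\\]$", val)) {
        as.numeric(strsplit(gsub("^\\[|\\]$", "", val), ",")[[1]])
      } else if (grepl('^".*"$', val)) {
        gsub('^"|"$', "", val)
      } else {
        suppressWarnings(num <- as.numeric(val))
        if (is.na(num)) val else num
      }
    if (is.null(tbl)) out[[key]] <- parsed else out[[tbl]][[key]] <- parsed
  }
  out
}

#' Read an arena specification from a TOML file
#'
#' Expects an `[arena]` table with `width`, `height` and optionally
#' `grid_divisions`, `entry_radius`, `availability_duration`, plus a
#' `[landmarks]` table mapping names to `[x, y]` positions in cm.
#'
#' @param path Path to the TOML file.
#' @return An [arena_spec()].
#' @export
read_arena <- function(path) {
  if (!file.exists(path)) stop("arena file not found: ", path, call. = FALSE)
  t <- parse_toml_subset(readLines(path, warn = FALSE))
  a <- t$arena
  if (is.null(a$width) || is.null(a$height))
    stop("arena file must declare width and height", call. = FALSE)
  arena_spec(
    width = a$width, height = a$height,
    landmarks = t$landmarks %||% list(),
    grid_divisions = a$grid_divisions %||% 10L,
    entry_radius = a$entry_radius %||% 10,
    availability_duration = a$availability_duration %||% 3
  )
}

#' Write an arena specification to a TOML file
#'
#' @param arena An [arena_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arena <- function(arena, path) {
  stopifnot(inherits(arena, "arena_spec"))
  lines <- c(
    "[arena]",
    sprintf("width = %s", format(arena$width)),
    sprintf("height = %s", format(arena$height)),
    sprintf("grid_divisions = %d", arena$grid_divisions),
    sprintf("entry_radius = %s", format(arena$entry_radius)),
    sprintf("availability_duration = %s", format(arena$availability_duration)),
    "",
    "[landmarks]",
    vapply(names(arena$landmarks), function(nm) {
      p <- arena$landmarks[[nm]]
      sprintf("%s = [%s, %s]", nm, format(p[1]), format(p[2]))
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
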