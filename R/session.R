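#' Construct a session record
#'
#' One experimental session: a subject's trajectory, its event log, and the
#' subject / condition / sequence / session-number metadata needed to place
#' it within an experiment.
#'
#' @param subject Subject identifier.
#' @param condition Condition label (e.g. `"FT"` / `"VT"`, or `"FD"` /
#'   `"WD"`).
#' @param session_number Integer session number (>= 1) within the subject's
#'   run.
#' @param trajectory A [trajectory()].
#' @param events An `event_log` (see [parse_event_table()]).
#' @param arena An [arena_spec()].
#' @param sequence Optional sequence label (deprivation-order group).
#' @return An object of class `session_record`.
#' @export
session_record <- function(subject, condition, session_number, trajectory,
                           events, arena, sequence = NA) {
  stopifnot(inherits(trajectory, "trajectory"),
            inherits(events, "event_log"),
            inherits(arena, "arena_spec"),
            session_number >= 1)
  dur <- max(trajectory$t)
  if (nrow(events) && any(events$t < 0 | events$t > dur + traj_dt(trajectory)))
    stop("event onset outside the session's trajectory extent", call. = FALSE)
  structure(
    list(subject = as.character(subject), condition = as.character(condition),
         sequence = sequence, session_number = as.integer(session_number),
         trajectory = trajectory, events = events, arena = arena),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> subject %s, %s, session %d: %d frames, %d events\n",
              x$subject, x$condition, x$session_number,
              nrow(x$trajectory), nrow(x$events)))
  invisible(x)
}

#' Validate a session record against all type invariants
#'
#' Checks the trajectory (constant sampling period, in-bounds coordinates),
#' the event log (onsets inside the session, resolvable dispensers), and the
#' metadata. Used by tests and by [load_manifest()].
#'
#' @param session A [session_record()].
#' @return `TRUE`, invisibly; errors describe the first violated invariant.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "session_record"))
  tr <- session$trajectory; a <- session$arena
  if (nrow(tr) < 2L) stop("trajectory has fewer than 2 samples", call. = FALSE)
  if (any(abs(diff(tr$t) - traj_dt(tr)) > 1e-6))
    stop("non-constant sampling period", call. = FALSE)
  if (any(tr$x < 0 | tr$x > a$width | tr$y < 0 | tr$y > a$height))
    stop("trajectory sample out of arena bounds", call. = FALSE)
  ev <- session$events
  if (nrow(ev)) {
    if (any(!ev$dispenser %in% names(a$landmarks)))
      stop("event references unknown dispenser", call. = FALSE)
    if (any(ev$t < 0 | ev$t > max(tr$t) + traj_dt(tr)))
      stop("event onset outside session", call. = FALSE)
    if (any(ev$kind == "delivery" & !(ev$availability > 0)))
      stop("delivery without positive availability", call. = FALSE)
  }
  if (session$session_number < 1L) stop("session_number must be >= 1", call. = FALSE)
  invisible(TRUE)
}

#' Load a session manifest
#'
#' The manifest is a CSV with columns
#' `subject,condition,sequence,session,trajectory_file,event_file`; file
#' paths are resolved relative to the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @param arena An [arena_spec()] shared by all sessions (or a path to an
#'   arena TOML file).
#' @param dt Sampling period in seconds.
#' @return A list of [session_record()]s in manifest order.
#' @export
load_manifest <- function(path, arena, dt = 0.2) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  if (is.character(arena)) arena <- read_arena(arena)
  stopifnot(inherits(arena, "arena_spec"))
  man <- utils::read.csv(path, colClasses = "character")
  need <- c("subject", "condition", "sequence", "session",
            "trajectory_file", "event_file")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ","), call. = FALSE)
  key <- paste(man$subject, man$session, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate (subject, session) in manifest: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    tf <- file.path(base, row$trajectory_file)
    ef <- file.path(base, row$event_file)
    for (f in c(tf, ef)) if (!file.exists(f))
      stop(sprintf("missing data file for subject %s session %s: %s",
                   row$subject, row$session, f), call. = FALSE)
    rec <- session_record(
      subject = row$subject, condition = row$condition,
      sequence = if (row$sequence %in% c("", "NA")) NA else row$sequence,
      session_number = as.integer(row$session),
      trajectory = read_trajectory(tf, arena, dt = dt),
      events = read_events(ef, arena),
      arena = arena
    )
    validate_session(rec)
    rec
  })
}

#' Write a corpus of sessions to disk
#'
#' Writes one trajectory CSV and one event CSV per session, an arena TOML,
#' and a manifest CSV tying them together, in the dialect read back by
#' [load_manifest()].
#'
#' @param sessions List of [session_record()]s sharing one arena.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(sessions, dir) {
  stopifnot(length(sessions) > 0L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(sessions, function(s) {
    stem <- sprintf("%s_s%02d", s$subject, s$session_number)
    tf <- paste0(stem, "_traj.csv"); ef <- paste0(stem, "_events.csv")
    write_trajectory(s$trajectory, file.path(dir, tf))
    write_events(s$events, file.path(dir, ef))
    data.frame(subject = s$subject, condition = s$condition,
               sequence = ifelse(is.na(s$sequence), "", as.character(s$sequence)),
               session = s$session_number,
               trajectory_file = tf, event_file = ef)
  })
  man <- do.call(rbind, rows)
  write_arena(sessions[[1L]]$arena, file.path(dir, "arena.toml"))
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
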