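#' Parse an event table
#'
#' Events are discrete session happenings: commodity deliveries (with a
#' limited availability window) and detector-registered head entries, each
#' tied to a dispenser landmark of the arena.
#'
#' @param rows Data frame with columns `t` (onset, seconds), `kind`
#'   (`"delivery"` or `"head_entry"`) and `dispenser` (landmark name).
#'   An optional `availability` column overrides the arena default for
#'   deliveries.
#' @param arena An [arena_spec()]; every `dispenser` label must name one of
#'   its landmarks.
#' @return A data frame of class `event_log` with columns `t`, `kind`,
#'   `dispenser`, `availability` (`NA` for head entries), sorted by onset.
#' @export
parse_event_table <- function(rows, arena) {
  stopifnot(inherits(arena, "arena_spec"))
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L) {
    out <- data.frame(t = numeric(), kind = character(),
                      dispenser = character(), availability = numeric())
    class(out) <- c("event_log", "data.frame")
    return(out)
  }
  if (!all(c("t", "kind", "dispenser") %in% names(rows)))
    stop("event rows must have columns t, kind, dispenser", call. = FALSE)
  t <- as.numeric(rows$t)
  kind <- as.character(rows$kind)
  dispenser <- as.character(rows$dispenser)
  if (any(t < 0)) stop("negative event onset", call. = FALSE)
  bad_kind <- setdiff(unique(kind), c("delivery", "head_entry"))
  if (length(bad_kind))
    stop("unknown event kind(s): ", paste(bad_kind, collapse = ", "), call. = FALSE)
  unknown <- setdiff(unique(dispenser), names(arena$landmarks))
  if (length(unknown))
    stop("unknown dispenser label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  availability <- if ("availability" %in% names(rows))
    as.numeric(rows$availability) else rep(NA_real_, nrow(rows))
  is_del <- kind == "delivery"
  availability[is_del & is.na(availability)] <- arena$availability_duration
  if (any(is_del & availability <= 0))
    stop("delivery availability must be positive", call. = FALSE)
  availability[!is_del] <- NA_real_
  ord <- order(t)
  out <- data.frame(t = t[ord], kind = kind[ord], dispenser = dispenser[ord],
                    availability = availability[ord])
  class(out) <- c("event_log", "data.frame")
  out
}

#' Read / write event CSV files
#'
#' Comma-separated, header `t,kind,dispenser` (UTF-8); availability is
#' re-derived from the arena default on read.
#'
#' @param path File path.
#' @param arena An [arena_spec()].
#' @param events An `event_log` from [parse_event_table()].
#' @return [read_events()]: an `event_log`. [write_events()]: `path`,
#'   invisibly.
#' @export
read_events <- function(path, arena) {
  if (!file.exists(path)) stop("event file not found: ", path, call. = FALSE)
  parse_event_table(utils::read.csv(path), arena)
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  lines <- c("t,kind,dispenser",
             if (nrow(events)) sprintf("%.17g,%s,%s", events$t, events$kind,
                                       events$dispenser))
  writeLines(lines, path)
  invisible(path)
}

#' Subset an event log
#'
#' @param events An `event_log`.
#' @param kind Event kind to keep (`"delivery"` or `"head_entry"`).
#' @param dispenser Optional dispenser label to keep.
#' @return The filtered `event_log`.
#' @export
events_of <- function(events, kind, dispenser = NULL) {
  keep <- events$kind == kind
  if (!is.null(dispenser)) keep <- keep & events$dispenser == dispenser
  events[keep, , drop = FALSE]
}
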