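new_feature_table <- function(df, features, target = "condition") {
  stopifnot(all(features %in% names(df)), target %in% names(df),
            !anyDuplicated(features), !anyNA(df[[target]]))
  structure(df, features = features, target = target,
            class = c("feature_table", "data.frame"))
}

#' Feature names / target of a feature table
#' @param table A `feature_table`.
#' @return Character vector of feature column names, or the target column
#'   name.
#' @export
feature_names <- function(table) attr(table, "features")

#' @rdname feature_names
#' @export
feature_target <- function(table) attr(table, "target")

#' Rows with no missing feature values
#'
#' Multivariate stages (ranking, embedding, projection) use only complete
#' rows; univariate summaries keep all rows. Missingness is explicit: a
#' masked cell is `NA`, never silently zero.
#'
#' @param table A `feature_table`.
#' @return Logical vector, `TRUE` where every feature is defined.
#' @export
complete_feature_rows <- function(table) {
  stats::complete.cases(as.data.frame(table)[, feature_names(table), drop = FALSE])
}

#' Numeric feature matrix
#'
#' @param table A `feature_table`.
#' @param complete_only Keep only complete rows (default `TRUE`).
#' @return Numeric matrix, feature columns in table order.
#' @export
feature_matrix <- function(table, complete_only = TRUE) {
  df <- as.data.frame(table)
  m <- as.matrix(df[, feature_names(table), drop = FALSE])
  storage.mode(m) <- "double"
  if (complete_only) m <- m[complete_feature_rows(table), , drop = FALSE]
  m
}

# Shared per-session spatial measures: occupancy entropy plus
# within-subject consecutive-session divergence (session 1 is NA).
occupancy_features <- function(sessions) {
  stopifnot(length(sessions) > 0L)
  subj <- vapply(sessions, `[[`, "", "subject")
  snum <- vapply(sessions, `[[`, 0L, "session_number")
  for (s in unique(subj)) {
    k <- sort(snum[subj == s])
    if (!identical(k, seq_along(k)))
      stop("subject ", s, ": session numbers must be contiguous from 1",
           call. = FALSE)
  }
  g <- sessions[[1L]]$arena$grid_divisions
  occ <- lapply(sessions, function(x)
    occupancy(zone_series(x$trajectory, x$arena), g^2))
  ent <- vapply(occ, entropy_bits, 0)
  div <- rep(NA_real_, length(sessions))
  for (i in seq_along(sessions)) {
    if (snum[i] == 1L) next
    prev <- which(subj == subj[i] & snum == snum[i] - 1L)
    div[i] <- session_divergence(occ[[prev]], occ[[i]])
  }
  data.frame(entropy = ent, divergence = div)
}

#' Assemble the single-dispenser feature table
#'
#' One row per session with the seven features used for the schedule
#' comparison: traveled distance, occupancy entropy, consecutive-session
#' divergence (within subject; the first session is masked missing), maximum
#' velocity, coincidence index, mean relative distance to the dispenser, and
#' session number. The condition label is the target.
#'
#' @param sessions List of [session_record()]s whose arena has a
#'   `dispenser` landmark; within each subject, session numbers must be
#'   contiguous from 1.
#' @param dispenser Dispenser landmark name (default `"dispenser"`).
#' @return A `feature_table` with metadata columns `subject`, `condition`,
#'   `session_number`.
#' @export
assemble_exp1 <- function(sessions, dispenser = "dispenser") {
  stopifnot(length(sessions) > 0L)
  ord <- order(vapply(sessions, `[[`, "", "subject"),
               vapply(sessions, `[[`, 0L, "session_number"))
  sessions <- sessions[ord]
  occ <- occupancy_features(sessions)
  rows <- lapply(sessions, function(s) {
    data.frame(
      subject = s$subject, condition = s$condition,
      session_number = s$session_number,
      traveled_distance = traveled_distance(s$trajectory),
      max_velocity = max_velocity(s$trajectory),
      coincidence_index = coincidence_index(s$trajectory, s$events, s$arena,
                                            dispenser),
      mean_dist_dispenser = mean(distance_series(s$trajectory, s$arena,
                                                 dispenser, "relative")$value),
      mean_dist_dispenser_cm = mean(distance_series(s$trajectory, s$arena,
                                                    dispenser, "absolute")$value)
    )
  })
  df <- cbind(do.call(rbind, rows), occ)
  df$session <- as.numeric(df$session_number)
  new_feature_table(df, features = c(
    "traveled_distance", "entropy", "divergence", "max_velocity",
    "coincidence_index", "mean_dist_dispenser", "session"))
}

#' Assemble the two-dispenser deprivation feature table
#'
#' One row per session with the 13 features used for the deprivation
#' comparison: mean relative distances to the food dispenser, water
#' dispenser and arena center; occupancy entropy and consecutive-session
#' divergence; intensity, precision and proportion-contacted for each
#' dispenser; session number; and sequence (encoded 1/2). Intensity is
#' normalized within subject-dispenser across the whole experiment, and
#' precision values below the subject-dispenser 5th percentile are masked.
#'
#' @param sessions List of [session_record()]s whose arena has `food`,
#'   `water` and `center` landmarks and whose records carry a sequence
#'   label.
#' @param percentile Lower percentile below which precision values are
#'   masked (default 5; set to 0 to disable).
#' @return A `feature_table` with metadata columns `subject`, `condition`,
#'   `sequence_label`, `session_number`.
#' @export
assemble_exp2 <- function(sessions, percentile = 5) {
  stopifnot(length(sessions) > 0L)
  a <- sessions[[1L]]$arena
  for (nm in c("food", "water", "center")) arena_landmark(a, nm)
  ord <- order(vapply(sessions, `[[`, "", "subject"),
               vapply(sessions, `[[`, 0L, "session_number"))
  sessions <- sessions[ord]
  occ <- occupancy_features(sessions)
  subj <- vapply(sessions, `[[`, "", "subject")
  rows <- lapply(sessions, function(s) {
    tr <- s$trajectory; ev <- s$events; ar <- s$arena
    data.frame(
      subject = s$subject, condition = s$condition,
      sequence_label = as.character(s$sequence),
      session_number = s$session_number,
      dist_food_dispenser = mean(distance_series(tr, ar, "food", "relative")$value),
      dist_water_dispenser = mean(distance_series(tr, ar, "water", "relative")$value),
      dist_center = mean(distance_series(tr, ar, "center", "relative")$value),
      entries_food = nrow(events_of(ev, "head_entry", "food")),
      entries_water = nrow(events_of(ev, "head_entry", "water")),
      precision_food = precision_index(ev, "food", ar$availability_duration),
      precision_water = precision_index(ev, "water", ar$availability_duration),
      proportion_food = proportion_contacted(ev, "food", ar$availability_duration),
      proportion_water = proportion_contacted(ev, "water", ar$availability_duration)
    )
  })
  df <- cbind(do.call(rbind, rows), occ)

  df$intensity_food <- NA_real_
  df$intensity_water <- NA_real_
  for (s in unique(subj)) {
    i <- which(subj == s)
    df$intensity_food[i] <- intensity_index(df$entries_food[i])
    df$intensity_water[i] <- intensity_index(df$entries_water[i])
    if (percentile > 0) {
      for (col in c("precision_food", "precision_water")) {
        keep <- percentile_filter(df[[col]][i], p = percentile)
        df[[col]][i][!keep] <- NA_real_
      }
    }
  }
  df$entries_food <- NULL; df$entries_water <- NULL

  seq_code <- match(df$sequence_label, sort(unique(df$sequence_label)))
  if (anyNA(seq_code)) stop("every session needs a sequence label", call. = FALSE)
  df$sequence <- as.numeric(seq_code)
  df$session <- as.numeric(df$session_number)
  new_feature_table(df, features = c(
    "dist_food_dispenser", "dist_water_dispenser", "dist_center",
    "entropy", "divergence",
    "intensity_food", "intensity_water",
    "precision_food", "precision_water",
    "proportion_food", "proportion_water",
    "session", "sequence"))
}

#' Standardize the features of a table
#'
#' Z-scores each feature over its non-missing rows. Constant features become
#' all-zero with a warning; masked cells stay masked; metadata and the
#' target are untouched.
#'
#' @param table A `feature_table` with at least 2 rows.
#' @return The standardized `feature_table`.
#' @export
standardize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table) < 2L) stop("standardize needs at least 2 rows", call. = FALSE)
  for (f in feature_names(table)) {
    v <- table[[f]]
    ok <- !is.na(v)
    s <- stats::sd(v[ok])
    if (is.na(s) || s == 0) {
      warning("feature '", f, "' is constant; standardized to zero", call. = FALSE)
      v[ok] <- 0
    } else {
      v[ok] <- (v[ok] - mean(v[ok])) / s
    }
    table[[f]] <- v
  }
  table
}

#' Write / read a feature table as CSV
#'
#' Metadata columns first, then features; masked cells are written as empty
#' fields. Attributes needed to rebuild the `feature_table` are stored in a
#' `# features:` / `# target:` comment header.
#'
#' @param table A `feature_table`.
#' @param path Output path.
#' @return [write_features()]: `path` invisibly; [read_features()]: the
#'   `feature_table`.
#' @export
write_features <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# features: ", paste(feature_names(table), collapse = ",")),
               paste0("# target: ", feature_target(table))), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  hdr <- readLines(path, n = 2L)
  feats <- strsplit(sub("^# features: ", "", hdr[1L]), ",")[[1L]]
  target <- sub("^# target: ", "", hdr[2L])
  df <- utils::read.csv(path, comment.char = "#")
  new_feature_table(df, features = feats, target = target)
}
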