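#' Per-condition feature summaries
#'
#' For each condition and feature: mean, median, standard deviation, and
#' first and third quartiles (linear interpolation), over non-missing
#' values — the five statistics shown in the package's box summaries.
#'
#' @param table A `feature_table`.
#' @return Data frame with columns `condition`, `feature`, `n`, `mean`,
#'   `median`, `sd`, `q1`, `q3`.
#' @export
summarize_features <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  target <- feature_target(table)
  df <- as.data.frame(table)
  out <- list()
  for (cond in sort(unique(df[[target]]))) {
    sub <- df[df[[target]] == cond, , drop = FALSE]
    for (f in feature_names(table)) {
      v <- sub[[f]]; v <- v[!is.na(v)]
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, feature = f, n = length(v),
        mean = mean(v), median = stats::median(v), sd = stats::sd(v),
        q1 = stats::quantile(v, 0.25, type = 7, names = FALSE),
        q3 = stats::quantile(v, 0.75, type = 7, names = FALSE))
    }
  }
  do.call(rbind, out)
}

config_stamp <- function(config) {
  flat <- paste(names(config), vapply(config, function(v)
    paste(format(v), collapse = ","), ""), sep = "=", collapse = ";")
  # order-independent additive hash of the flattened config string
  sprintf("%08x", sum(utf8ToInt(flat) * (seq_along(utf8ToInt(flat)) %% 97 + 1)) %% .Machine$integer.max)
}

write_stamped_csv <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# behavdyn config ", stamp), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

run_ml_stage <- function(ft, out_dir, stamp, config) {
  df <- as.data.frame(ft)
  target <- feature_target(ft)
  if (length(unique(df[[target]])) < 2L) {
    warning("single condition in the data; ranking/embedding skipped",
            call. = FALSE)
    return(invisible(NULL))
  }
  ranking <- rank_variables(ft, bins = config$bins)
  write_stamped_csv(ranking, file.path(out_dir, "rankings.csv"), stamp)

  std <- suppressWarnings(standardize(ft))
  emb <- tsne_embed(std, perplexity = config$perplexity, seed = config$seed)
  cl <- kmeans_cluster(emb$coords, k = config$k, seed = config$seed,
                       restarts = config$restarts,
                       labels = df[[target]][emb$rows])
  emb_df <- data.frame(
    subject = df$subject[emb$rows], session = df$session_number[emb$rows],
    condition = df[[target]][emb$rows],
    dim1 = emb$coords[, 1], dim2 = emb$coords[, 2], cluster = cl$cluster)
  if ("sequence_label" %in% names(df))
    emb_df$sequence <- df$sequence_label[emb$rows]
  write_stamped_csv(emb_df, file.path(out_dir, "embedding.csv"), stamp)

  proj <- pca_projection(ft)
  proj_df <- data.frame(subject = df$subject[proj$rows],
                        session = df$session_number[proj$rows],
                        condition = df[[target]][proj$rows],
                        pc1 = proj$scores[, 1], pc2 = proj$scores[, 2])
  write_stamped_csv(proj_df, file.path(out_dir, "projection.csv"), stamp)
  write_stamped_csv(data.frame(feature = rownames(proj$axes),
                               axis1 = proj$axes[, 1], axis2 = proj$axes[, 2]),
                    file.path(out_dir, "projection_axes.csv"), stamp)
  list(ranking = ranking, embedding = emb, cluster = cl, projection = proj,
       embedding_df = emb_df)
}

plot_session_panels <- function(session, out_dir, dispenser) {
  tr <- session$trajectory; a <- session$arena
  stem <- sprintf("%s_s%02d", session$subject, session$session_number)
  lwd_pts <- locations_at_events(tr, session$events, "delivery")

  p1 <- ggplot2::ggplot(as.data.frame(tr), ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(color = "grey60", linewidth = 0.2) +
    ggplot2::geom_point(data = lwd_pts, color = "black", size = 1) +
    ggplot2::coord_fixed(xlim = c(0, a$width), ylim = c(0, a$height)) +
    ggplot2::labs(title = sprintf("%s session %d: route + location at delivery",
                                  session$subject, session$session_number),
                  x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out_dir, paste0(stem, "_route.png")), p1,
                  width = 5, height = 5, dpi = 110)

  ds <- distance_series(tr, a, dispenser, "relative")
  sm <- moving_average(ds, 200L)
  dd <- data.frame(t = ds$t, raw = ds$value, smooth = sm$value)
  p2 <- ggplot2::ggplot(dd, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$raw), color = "grey70", size = 0.1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smooth), color = "red") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (s)", y = "relative distance to dispenser") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out_dir, paste0(stem, "_distance.png")), p2,
                  width = 7, height = 3, dpi = 110)

  z <- thin_zones(zone_series(tr, a))
  rec <- recurrence(z, materialize = TRUE)
  grDevices::png(file.path(out_dir, paste0(stem, "_recurrence.png")),
                 width = 600, height = 600)
  graphics::image(rec$matrix[, rev(seq_len(ncol(rec$matrix)))],
                  col = c("white", "black"), axes = FALSE,
                  main = sprintf("%s session %d recurrence", session$subject,
                                 session$session_number))
  grDevices::dev.off()
  invisible(NULL)
}

plot_summaries <- function(ft, ml, out_dir) {
  target <- feature_target(ft)
  df <- as.data.frame(ft)
  long <- do.call(rbind, lapply(feature_names(ft), function(f)
    data.frame(condition = df[[target]], feature = f, value = df[[f]])))
  long <- long[!is.na(long$value), ]
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$value,
                                          fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 2) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::theme_minimal() + ggplot2::theme(legend.position = "none")
  ggplot2::ggsave(file.path(out_dir, "feature_boxes.png"), p,
                  width = 9, height = 7, dpi = 110)
  if (is.null(ml)) return(invisible(NULL))

  emb <- ml$embedding_df
  p2 <- ggplot2::ggplot(emb, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                          color = .data$condition,
                                          shape = factor(.data$cluster))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(shape = "cluster") + ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out_dir, "tsne.png"), p2,
                  width = 6, height = 5, dpi = 110)

  ax <- as.data.frame(ml$projection$axes)
  ax$feature <- rownames(ml$projection$axes)
  sc <- data.frame(pc1 = ml$projection$scores[, 1],
                   pc2 = ml$projection$scores[, 2],
                   condition = emb$condition)
  r <- max(abs(sc$pc1), abs(sc$pc2))
  p3 <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$condition), size = 2) +
    ggplot2::geom_segment(data = ax,
                          ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * r,
                                       yend = .data$PC2 * r),
                          arrow = grid::arrow(length = grid::unit(0.15, "cm"))) +
    ggplot2::geom_text(data = ax, ggplot2::aes(x = .data$PC1 * r * 1.08,
                                               y = .data$PC2 * r * 1.08,
                                               label = .data$feature), size = 3) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out_dir, "pca_biplot.png"), p3,
                  width = 7, height = 6, dpi = 110)
  invisible(NULL)
}

run_analysis <- function(sessions, out_dir, assemble, dispenser, config) {
  if (length(sessions) == 0L) stop("no sessions to analyze", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  defaults <- list(grid = 10L, bins = 4L, perplexity = NULL, seed = 0L,
                   k = 2L, restarts = 10L, plots = TRUE,
                   plot_sessions = integer(0))
  config <- utils::modifyList(defaults, config)
  stamp <- config_stamp(config)

  ft <- assemble(sessions)
  write_features(ft, file.path(out_dir, "features.csv"))
  write_stamped_csv(summarize_features(ft),
                    file.path(out_dir, "summary_stats.csv"), stamp)
  ml <- run_ml_stage(ft, out_dir, stamp, config)
  if (isTRUE(config$plots)) {
    plot_summaries(ft, ml, out_dir)
    for (i in config$plot_sessions)
      plot_session_panels(sessions[[i]], out_dir, dispenser)
  }
  writeLines(c(sprintf("behavdyn run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               sprintf("config stamp: %s", stamp),
               sprintf("sessions: %d", length(sessions)),
               sprintf("seed: %d", config$seed),
               sprintf("R: %s; behavdyn: %s", R.version.string,
                       as.character(utils::packageVersion("behavdyn")))),
             file.path(out_dir, "run.log"))
  invisible(list(features = ft, summary = summarize_features(ft),
                 ranking = ml$ranking, embedding = ml$embedding,
                 cluster = ml$cluster, projection = ml$projection,
                 out_dir = out_dir))
}

#' Run the end-to-end single-dispenser analysis
#'
#' Assembles the 7-feature table from FT/VT sessions, writes `features.csv`,
#' `summary_stats.csv`, `rankings.csv`, `embedding.csv`, `projection.csv`
#' (plus axis vectors) and plots into `out_dir`, and returns the in-memory
#' results. With a single condition present, the machine-learning stage is
#' skipped with a warning and the measures are still produced. All outputs
#' carry a config stamp in a header comment; the run is deterministic given
#' `config$seed`.
#'
#' @param sessions List of [session_record()]s (e.g. from
#'   [simulate_experiment1()] or [load_manifest()]).
#' @param out_dir Output directory.
#' @param config Named list overriding defaults: `grid`, `bins`,
#'   `perplexity`, `seed`, `k`, `restarts`, `plots`, `plot_sessions`
#'   (indices of sessions to render as route/distance/recurrence panels).
#' @return Invisible list with `features`, `summary`, `ranking`,
#'   `embedding`, `cluster`, `projection`, `out_dir`.
#' @export
run_exp1_analysis <- function(sessions, out_dir, config = list()) {
  run_analysis(sessions, out_dir, assemble_exp1, "dispenser", config)
}

#' Run the end-to-end two-dispenser deprivation analysis
#'
#' Same orchestration as [run_exp1_analysis()] over the 13-feature
#' deprivation table: the subject-dispenser 5th-percentile filter is applied
#' to precision values inside [assemble_exp2()], ranking covers all 13
#' features, and the t-SNE embedding is clustered with K-means (k = 2) with
#' purity and adjusted Rand agreement against the deprivation labels.
#'
#' @inheritParams run_exp1_analysis
#' @export
run_exp2_analysis <- function(sessions, out_dir, config = list()) {
  run_analysis(sessions, out_dir, assemble_exp2, "food", config)
}
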