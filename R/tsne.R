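# Exact t-SNE (Student-t stochastic neighbor embedding) for small session
# tables. Session corpora here are tens of rows, so the O(n^2) exact
# gradient is used rather than a tree approximation.

# Conditional Gaussian affinities with per-point precision tuned by binary
# search to match the target perplexity.
tsne_input_probs <- function(x, perplexity, tol = 1e-5) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  p <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; beta_min <- -Inf; beta_max <- Inf
    di <- d2[i, -i]
    for (iter in 1:64) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      h <- log(sw) + beta * sum(di * w) / sw  # Shannon entropy (nats)
      diff <- h - log_u
      if (abs(diff) < tol) break
      if (diff > 0) {
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    p[i, -i] <- w / sum(w)
  }
  p <- (p + t(p)) / (2 * n)
  pmax(p, 1e-12)
}

#' t-SNE embedding of a feature table
#'
#' Embeds the complete rows of a (standardized) feature table into 2-D with
#' exact t-distributed stochastic neighbor embedding, so that sessions with
#' similar multivariate profiles land close together. The run is fully
#' deterministic given `seed`: initialization is the first two principal
#' components plus a small seeded jitter.
#'
#' @param table A `feature_table`, or a numeric matrix of rows to embed.
#' @param perplexity Effective neighborhood size; defaults to
#'   `min(30, (n - 1) / 3)` and is shrunk (with a warning) if it exceeds
#'   `(n - 1) / 3`.
#' @param seed Integer seed recorded in the result.
#' @param max_iter Gradient iterations (default 500, with early
#'   exaggeration for the first 100).
#' @param restarts Number of restarts; the embedding with the lowest final
#'   Kullback-Leibler divergence is kept (default 3). Restart seeds are
#'   derived from `seed`, so the result is still fully reproducible.
#' @return An object of class `embedding_result`: list with `coords`
#'   (n x 2 matrix), `perplexity`, `seed`, `kl` (final KL divergence of the
#'   kept run) and `rows` (indices of the embedded rows in the input table).
#' @export
tsne_embed <- function(table, perplexity = NULL, seed = 0L, max_iter = 500L,
                       restarts = 3L) {
  if (inherits(table, "feature_table")) {
    rows <- which(complete_feature_rows(table))
    x <- feature_matrix(table, complete_only = TRUE)
  } else {
    x <- as.matrix(table)
    rows <- seq_len(nrow(x))
  }
  n <- nrow(x)
  if (n < 4L) stop("t-SNE needs at least 4 complete rows", call. = FALSE)
  max_perp <- (n - 1) / 3
  if (is.null(perplexity)) perplexity <- min(30, max_perp * 0.95)
  if (perplexity >= max_perp) {
    warning(sprintf("perplexity %.1f too large for n = %d; shrunk to %.1f",
                    perplexity, n, max_perp * 0.99), call. = FALSE)
    perplexity <- max_perp * 0.99
  }
  p <- tsne_input_probs(x, perplexity)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  y0 <- matrix(0, n, 2)
  y0[, seq_len(k)] <- pc$x[, seq_len(k), drop = FALSE]
  y0 <- scale(y0, center = TRUE, scale = FALSE)
  y0 <- y0 / max(stats::sd(y0[, 1]), 1e-12) * 1e-4

  best <- NULL
  for (r in seq_len(max(1L, restarts))) {
    set.seed(seed + r - 1L)
    run <- tsne_gradient_descent(p, y0, n, max_iter)
    if (is.null(best) || run$kl < best$kl) best <- run
  }
  structure(list(coords = unname(best$y), perplexity = perplexity,
                 seed = as.integer(seed), kl = best$kl, rows = rows),
            class = "embedding_result")
}

# one gradient-descent run from a jittered PCA initialization; returns the
# layout and its final KL divergence (the restart selection criterion)
tsne_gradient_descent <- function(p, y0, n, max_iter) {
  y <- y0 + matrix(stats::rnorm(2L * n, sd = 1e-4), n, 2)
  gains <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  exaggeration <- 12
  lr <- max(50, n / exaggeration)  # standard small-n learning-rate heuristic
  q <- NULL
  for (iter in seq_len(max_iter)) {
    pp <- if (iter <= 100L) p * exaggeration else p
    num <- 1 / (1 + as.matrix(stats::dist(y))^2)
    diag(num) <- 0
    q <- pmax(num / sum(num), 1e-12)
    l <- (pp - q) * num
    grad <- 4 * (diag(rowSums(l)) - l) %*% y
    momentum <- if (iter <= 250L) 0.5 else 0.8
    gains <- pmax(ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8), 0.01)
    inc <- momentum * inc - lr * gains * grad
    y <- y + inc
    y <- scale(y, center = TRUE, scale = FALSE)
  }
  list(y = y[, 1:2, drop = FALSE], kl = sum(p * log(p / q)))
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> %d rows, perplexity %.1f, seed %d\n",
              nrow(x$coords), x$perplexity, x$seed))
  invisible(x)
}
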