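#' Equal-frequency discretization
#'
#' Cuts a numeric vector at its `k`-quantiles (linear interpolation).
#' Duplicate cut points are merged, so ties can yield fewer effective bins;
#' a constant vector yields a single bin. Deterministic.
#'
#' @param values Numeric vector.
#' @param k Target number of bins (default 4).
#' @return Factor of bin labels, same length as `values`.
#' @export
discretize_equal_frequency <- function(values, k = 4L) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  stopifnot(k >= 1L)
  ux <- sort(unique(values[!is.na(values)]))
  if (length(ux) <= k) return(factor(values, levels = ux))
  qs <- stats::quantile(values, probs = seq(0, 1, length.out = k + 1L),
                        type = 7, na.rm = TRUE, names = FALSE)
  breaks <- unique(qs)
  if (length(breaks) < 2L)
    return(factor(rep("bin1", length(values)))[seq_along(values)])
  cut(values, breaks = breaks, include.lowest = TRUE)
}

contingency <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  table(x[ok], y[ok])
}

entropy_of_counts <- function(n) {
  p <- n[n > 0] / sum(n)
  -sum(p * log2(p))
}

#' Information gain of a categorical predictor
#'
#' \eqn{H(Y) - \sum_v p(X = v) H(Y \mid X = v)} in bits: the reduction in
#' target entropy from knowing the (discretized) feature. Equals the mutual
#' information, so it is symmetric in its arguments.
#'
#' @param x Categorical predictor (factor or vector).
#' @param y Target labels, same length.
#' @return Information gain in bits (>= 0).
#' @export
information_gain <- function(x, y) {
  tab <- contingency(x, y)
  n <- sum(tab)
  hy <- entropy_of_counts(colSums(tab))
  hcond <- sum(apply(tab, 1L, function(row)
    if (sum(row) == 0) 0 else sum(row) / n * entropy_of_counts(row)))
  max(hy - hcond, 0)
}

#' Gini gain of a categorical predictor
#'
#' Decrease in Gini impurity \eqn{1 - \sum_c p_c^2} of the target from
#' splitting on the feature.
#'
#' @inheritParams information_gain
#' @return Gini gain (>= 0, dimensionless).
#' @export
gini_gain <- function(x, y) {
  tab <- contingency(x, y)
  n <- sum(tab)
  gini <- function(counts) {
    if (sum(counts) == 0) return(0)
    1 - sum((counts / sum(counts))^2)
  }
  g0 <- gini(colSums(tab))
  gcond <- sum(apply(tab, 1L, function(row) sum(row) / n * gini(row)))
  max(g0 - gcond, 0)
}

#' Chi-squared score of a categorical predictor
#'
#' Pearson statistic \eqn{\sum (O - E)^2 / E} over the feature-by-target
#' contingency table; all-zero rows or columns are dropped first.
#'
#' @inheritParams information_gain
#' @return Chi-squared statistic (>= 0).
#' @export
chi2_score <- function(x, y) {
  tab <- contingency(x, y)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (length(tab) == 0L || nrow(tab) < 1L || ncol(tab) < 1L) return(0)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - expected)^2 / expected)
}

#' Rank features by univariate relevance to the condition
#'
#' Discretizes each numeric feature into equal-frequency bins and scores it
#' against the target with each requested method; features are ordered by
#' descending score, ties broken by feature name. Only complete rows enter
#' the scoring.
#'
#' @param table A `feature_table` with at least two target classes.
#' @param methods Subset of `c("info_gain", "gini", "chi2")`.
#' @param bins Discretization bins (default 4).
#' @return A data frame of class `ranking_result` with columns `method`,
#'   `feature`, `score`, `rank`.
#' @export
rank_variables <- function(table, methods = c("info_gain", "gini", "chi2"),
                           bins = 4L) {
  stopifnot(inherits(table, "feature_table"))
  methods <- match.arg(methods, several.ok = TRUE)
  df <- as.data.frame(table)[complete_feature_rows(table), , drop = FALSE]
  y <- df[[feature_target(table)]]
  if (length(unique(y)) < 2L)
    stop("ranking needs at least 2 target classes", call. = FALSE)
  scorers <- list(info_gain = information_gain, gini = gini_gain,
                  chi2 = chi2_score)
  out <- do.call(rbind, lapply(methods, function(m) {
    scores <- vapply(feature_names(table), function(f) {
      x <- df[[f]]
      if (is.numeric(x)) x <- discretize_equal_frequency(x, bins)
      scorers[[m]](x, y)
    }, 0)
    ord <- order(-scores, names(scores))
    data.frame(method = m, feature = names(scores)[ord],
               score = unname(scores)[ord], rank = seq_along(scores))
  }))
  rownames(out) <- NULL
  class(out) <- c("ranking_result", "data.frame")
  out
}
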