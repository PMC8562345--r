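# brute-force contingency oracles used throughout this file
oracle_scores <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  h <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
  }
  gini <- function(counts) 1 - sum((counts / sum(counts))^2)
  hy <- h(colSums(tab))
  hc <- sum(vapply(seq_len(nrow(tab)), function(i)
    sum(tab[i, ]) / n * h(tab[i, ]), 0))
  g0 <- gini(colSums(tab))
  gc <- sum(vapply(seq_len(nrow(tab)), function(i)
    sum(tab[i, ]) / n * gini(tab[i, ]), 0))
  expected <- outer(rowSums(tab), colSums(tab)) / n
  list(info = hy - hc, gini = g0 - gc,
       chi2 = sum((tab - expected)^2 / expected))
}

# expand a 2x2 contingency table into (x, y) label vectors
from_table <- function(tab) {
  x <- rep(rep(c("a", "b"), each = 2), times = as.vector(t(tab)))
  y <- rep(rep(c("p", "q"), times = 2), times = as.vector(t(tab)))
  list(x = x, y = y)
}

test_that("equal-frequency discretization uses interpolated quantiles", {
  bins <- discretize_equal_frequency(1:8, k = 4)
  expect_equal(as.integer(bins), rep(1:4, each = 2))
  expect_equal(nlevels(bins), 4L)

  expect_equal(nlevels(discretize_equal_frequency(rep(5, 10), k = 4)), 1L)
  expect_lte(nlevels(discretize_equal_frequency(c(1, 1, 1, 2), k = 4)), 2L)
  expect_error(discretize_equal_frequency(numeric(0)), "empty")
})

test_that("scoring functions match brute-force contingency evaluation", {
  d <- from_table(matrix(c(6, 2, 2, 6), 2, byrow = TRUE))
  o <- oracle_scores(d$x, d$y)
  expect_equal(information_gain(d$x, d$y), o$info, tolerance = 1e-12)
  expect_equal(information_gain(d$x, d$y), 0.18872, tolerance = 1e-4)
  expect_equal(gini_gain(d$x, d$y), o$gini, tolerance = 1e-12)
  expect_equal(gini_gain(d$x, d$y), 0.125)
  expect_equal(chi2_score(d$x, d$y), o$chi2, tolerance = 1e-12)
  expect_equal(chi2_score(d$x, d$y), 4.0)

  diag20 <- from_table(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
  expect_equal(chi2_score(diag20$x, diag20$y), 20.0)
  # agreement with the standard Pearson statistic, no continuity correction
  expect_equal(chi2_score(diag20$x, diag20$y),
               unname(suppressWarnings(
                 stats::chisq.test(table(diag20$x, diag20$y),
                                   correct = FALSE)$statistic)))

  # perfect split of a balanced binary target
  y <- rep(c("p", "q"), each = 8)
  expect_equal(information_gain(y, y), 1.0)
  expect_equal(gini_gain(y, y), 0.5)
  # constant or proportional predictors carry nothing
  expect_equal(information_gain(rep("a", 16), y), 0)
  expect_equal(gini_gain(rep("a", 16), y), 0)
  prop <- from_table(matrix(c(6, 3, 4, 2), 2, byrow = TRUE))
  expect_equal(chi2_score(prop$x, prop$y), 0, tolerance = 1e-12)

  expect_error(information_gain(1:3, 1:4), "length mismatch")
})

test_that("information gain is symmetric and ranks signal above noise", {
  set.seed(13)
  for (i in 1:10) {
    x <- sample(letters[1:3], 60, replace = TRUE)
    y <- sample(c("p", "q"), 60, replace = TRUE)
    expect_equal(information_gain(x, y), information_gain(y, x),
                 tolerance = 1e-12)
  }
  y <- rep(c("p", "q"), each = 100)
  noise <- sample(letters[1:4], 200, replace = TRUE)
  for (fn in list(information_gain, gini_gain, chi2_score))
    expect_lt(fn(noise, y), fn(y, y))
})

test_that("rank_variables orders by independently recomputed scores", {
  set.seed(21)
  n <- 40
  cond <- rep(c("FT", "VT"), each = n / 2)
  df <- data.frame(
    subject = "R1", condition = cond, session_number = 1:n,
    perfect = as.numeric(cond == "FT"),
    informative = rnorm(n, mean = ifelse(cond == "FT", 2, 0)),
    noise = rnorm(n),
    session = as.numeric(1:n)
  )
  ft <- behavdyn:::new_feature_table(df, features = c("perfect", "informative",
                                                      "noise", "session"))
  rk <- rank_variables(ft)
  for (m in unique(rk$method)) {
    sub <- rk[rk$method == m, ]
    expect_equal(sub$feature[1], "perfect")
    expect_lt(sub$score[sub$feature == "noise"],
              sub$score[sub$feature == "perfect"])
    # orders agree with direct recomputation via the scoring functions
    scorer <- switch(m, info_gain = information_gain, gini = gini_gain,
                     chi2 = chi2_score)
    direct <- vapply(c("perfect", "informative", "noise", "session"),
                     function(f) scorer(discretize_equal_frequency(df[[f]], 4),
                                        cond), 0)
    direct <- direct[order(-direct, names(direct))]
    expect_equal(sub$feature, names(direct))
    expect_equal(sub$score, unname(direct), tolerance = 1e-12)
  }

  single <- df; single$condition <- "FT"
  ft1 <- behavdyn:::new_feature_table(single, features = c("perfect", "noise"))
  expect_error(rank_variables(ft1), "2 target classes")
})

test_that("t-SNE is reproducible and separates distinct blobs", {
  set.seed(17)
  blob <- rbind(matrix(rnorm(40 * 3, mean = 0), ncol = 3),
                matrix(rnorm(40 * 3, mean = 8), ncol = 3))
  e1 <- tsne_embed(blob, perplexity = 10, seed = 5)
  e2 <- tsne_embed(blob, perplexity = 10, seed = 5)
  expect_identical(e1$coords, e2$coords)
  expect_equal(dim(e1$coords), c(80L, 2L))

  lab <- rep(1:2, each = 40)
  d <- as.matrix(dist(e1$coords))
  within <- mean(d[lab[row(d)] == lab[col(d)] & row(d) != col(d)])
  between <- mean(d[lab[row(d)] != lab[col(d)]])
  expect_lt(within, between)

  expect_error(tsne_embed(blob[1:3, ]), "at least 4")
  expect_warning(tsne_embed(blob[1:10, ], perplexity = 5), "shrunk")
})

test_that("k-means clustering reports purity and adjusted agreement", {
  set.seed(19)
  pts <- rbind(matrix(rnorm(30, sd = 0.3), ncol = 2),
               matrix(rnorm(30, sd = 0.3, mean = 6), ncol = 2))
  lab <- rep(c("A", "B"), each = 15)
  cl <- kmeans_cluster(pts, k = 2, seed = 1, labels = lab)
  expect_equal(cl$purity, 1.0)
  expect_equal(cl$adjusted_rand, 1.0)

  # purity invariant to relabeling clusters
  flipped <- 3L - cl$cluster
  expect_equal(cluster_purity(flipped, lab), cluster_purity(cl$cluster, lab))

  one <- kmeans_cluster(pts, k = 1, seed = 1, labels = rep(c("A", "B"), c(20, 10)))
  expect_equal(one$purity, 20 / 30)

  expect_error(kmeans_cluster(pts[1, , drop = FALSE], k = 2), "fewer rows")

  # hand-rolled adjusted Rand agrees with the mclust reference
  set.seed(23)
  for (i in 1:10) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("PCA projection returns orthonormal axes matching eigen oracle", {
  set.seed(25)
  # 3 correlated features with known covariance structure
  z <- matrix(rnorm(200 * 3), ncol = 3)
  A <- matrix(c(2, 0.8, 0.3, 0, 1, 0.5, 0, 0, 0.4), 3, 3)
  x <- z %*% t(A)
  proj <- pca_projection(x)
  expect_equal(unname(crossprod(proj$axes)), diag(2), tolerance = 1e-9)
  expect_true(all(diff(proj$var_explained) <= 1e-12))
  expect_true(all(proj$var_explained >= 0 & proj$var_explained <= 1))

  ev <- eigen(stats::cov(scale(x)))$vectors[, 1:2]
  for (j in 1:2) {
    dot <- abs(sum(proj$axes[, j] * ev[, j]))
    expect_equal(dot, 1, tolerance = 1e-9)  # same axis up to sign
  }
  # sign convention: largest-magnitude loading positive
  for (j in 1:2)
    expect_gt(proj$axes[which.max(abs(proj$axes[, j])), j], 0)

  collinear <- cbind(1:20, 2 * (1:20))
  p2 <- pca_projection(collinear)
  expect_equal(p2$var_explained[1], 1.0, tolerance = 1e-12)

  expect_error(pca_projection(x[1, , drop = FALSE]), "at least 2")
})
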