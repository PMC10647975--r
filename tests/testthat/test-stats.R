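test_that("percent difference follows its sign convention", {
  expect_equal(percent_difference(1, 1), 0)
  expect_equal(percent_difference(1.077, 1.000), 7.7)
  expect_equal(percent_difference(0.9, 1.0), -10)
  expect_equal(percent_difference(0.9, 1.0, absolute = TRUE), 10)
  expect_error(percent_difference(1, 0), "non-zero")
})

test_that("coefficients of variation use the sample SD", {
  expect_equal(coefficient_of_variation(rep(5, 4)), 0)
  expect_equal(coefficient_of_variation(c(9, 11)), 100 * sqrt(2) / 10)
  expect_error(coefficient_of_variation(3), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero")
})

test_that("session CV decomposition matches a brute-force group-by oracle", {
  set.seed(14)
  sessions <- rep(1:3, each = 4)
  values <- rnorm(12, mean = 10, sd = 1)
  got <- session_cv(values, sessions)
  per <- numeric(3); mns <- numeric(3)
  for (s in 1:3) {
    v <- values[sessions == s]
    per[s] <- 100 * sd(v) / mean(v)
    mns[s] <- mean(v)
  }
  expect_equal(unname(got$per_session_cv), per)
  expect_equal(got$intra_session_cv, mean(per))
  expect_equal(got$inter_session_cv, 100 * sd(mns) / mean(mns))
})

test_that("within-subject CV matches hand arithmetic and a generative check", {
  expect_equal(within_subject_cv(5, 5)$per_subject, 0)
  expect_equal(within_subject_cv(8, 12)$per_subject, 100 * 2 * sqrt(2) / 10)
  expect_error(within_subject_cv(c(1, 2), 1), "lengths")
  expect_error(within_subject_cv(c(1, NA), c(1, 2)), "missing")
  # scan/rescan drawn with a generative CV of 10%: the expected pairwise
  # wCV is 10 * sqrt(2/pi) (half-normal mean of |a - b| / sqrt(2))
  set.seed(99)
  n <- 300
  mu <- 50
  scan <- rnorm(n, mu, 0.1 * mu); rescan <- rnorm(n, mu, 0.1 * mu)
  got <- within_subject_cv(scan, rescan)
  expect_equal(got$mean, 10 * sqrt(2 / pi), tolerance = 0.1)
})

test_that("exact Mann-Whitney matches full enumeration for all small splits", {
  vals <- c(2.3, 5.1, 1.7, 9.2, 4.4, 7.8, 3.5, 6.6)
  for (k in 2:4) {
    picks <- combn(8, k)
    for (j in seq_len(ncol(picks))) {
      a <- vals[picks[, j]]; b <- vals[-picks[, j]]
      got <- mann_whitney_u(a, b)
      expect_equal(got$method, "exact")
      expect_equal(got$p_value, enumerate_mw_p(a, b),
                   tolerance = 1e-12,
                   label = sprintf("split %d/%d", k, j))
    }
  }
})

test_that("Mann-Whitney handles the canonical toy cases", {
  got <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(got$u_statistic, 0)
  expect_equal(got$p_value, 1 / 3, tolerance = 1e-12)
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p_value, 0.9)
  expect_equal(same$method, "normal approximation")
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("a large configured shift is detected in nearly every replicate", {
  set.seed(55)
  hits <- mean(replicate(200, {
    a <- rnorm(10, 0, 1); b <- rnorm(12, 5, 1)
    mann_whitney_u(a, b)$p_value < 0.001
  }))
  expect_gte(hits, 0.95)
})

test_that("AUC equals the brute-force pairwise ordering probability", {
  # toy 6-point set
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.65, 0.9)
  labels <- c(0, 0, 1, 1, 0, 1)
  got <- roc_analysis(scores, labels, direction = ">")
  pairs <- outer(scores[labels == 1], scores[labels == 0],
                 function(d, h) (d > h) + 0.5 * (d == h))
  expect_equal(got$auc, mean(pairs))
  # random instances with ties, n <= 50
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(6:50, 1)
    sc <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    lb <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    r <- roc_analysis(sc, lb, direction = ">")
    oracle <- mean(outer(sc[lb == 1], sc[lb == 0],
                         function(d, h) (d > h) + 0.5 * (d == h)))
    expect_equal(r$auc, oracle, tolerance = 1e-12)
  }
})

test_that("ROC degenerate cases and direction handling", {
  expect_equal(roc_analysis(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_analysis(rep(1, 6), c(0, 0, 0, 1, 1, 1))$auc, 0.5)
  # lower scores in disease: direction flips and AUC >= 0.5
  r <- roc_analysis(c(10, 11, 12, 1, 2, 3), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$direction, "<")
  expect_equal(r$auc, 1)
  expect_error(roc_analysis(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("the Youden cutoff reproduces known sensitivity/specificity pairs", {
  # overlapping groups: two cutoffs tie on Youden; the tie breaks towards
  # higher specificity
  scores <- c(1, 2, 3, 6, 5, 10, 11, 12)
  labels <- c(0, 0, 0, 0, 1, 1, 1, 1)
  r <- roc_analysis(scores, labels)
  expect_equal(r$direction, ">")
  expect_gt(r$optimal_cutoff, 6); expect_lt(r$optimal_cutoff, 10)
  expect_equal(r$sensitivity, 0.75)
  expect_equal(r$specificity, 1)
  # agreement with an independent ROC implementation
  skip_if_not_installed("pROC")
  set.seed(12)
  sc <- rnorm(40); lb <- rep(0:1, 20)
  ours <- roc_analysis(sc, lb)
  theirs <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                           direction = if (ours$direction == ">") "<" else ">")))
  expect_equal(ours$auc, theirs, tolerance = 1e-12)
})

test_that("bootstrap CI is seeded, stratified and degenerate-safe", {
  scores <- c(1, 2, 3, 10, 11, 12, 13)
  labels <- c(0, 0, 0, 1, 1, 1, 1)
  b1 <- bootstrap_validate(scores, labels, "auc", n_samples = 200, seed = 7)
  b2 <- bootstrap_validate(scores, labels, "auc", n_samples = 200, seed = 7)
  expect_identical(b1, b2)
  # perfect separation in every stratified resample: CI collapses at 1
  expect_equal(b1$lower, 1); expect_equal(b1$upper, 1)
  expect_equal(b1$n_redrawn, 0L)
  expect_error(bootstrap_validate(scores, labels, n_samples = 50), ">= 100")
  expect_error(bootstrap_validate(scores, labels, level = 40), "level")
})

test_that("voxelwise Pearson matches the definitional covariance ratio", {
  a <- c(2.1, 3.4, 1.9, 5.6, 4.4, 3.3, 2.8, 6.1, 5.0, 4.7)
  b <- c(1.0, 2.2, 1.4, 4.9, 3.6, 2.1, 2.5, 5.5, 4.1, 4.0)
  got <- voxelwise_pearson(a, b)
  long_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, long_hand, tolerance = 1e-12)
  expect_equal(got$strength, "large")
  expect_equal(voxelwise_pearson(a, a)$r, 1)
  expect_equal(voxelwise_pearson(a, -a + 10)$r, -1)
  expect_error(voxelwise_pearson(a, rep(1, 10)), "zero variance")
  expect_error(voxelwise_pearson(a[1:2], b[1:2]), "at least 3")
})

test_that("Fisher-Z pooling averages on the z scale and is bounded", {
  expect_equal(fisher_z_average(c(0.5, 0.5))$r_bar, 0.5)
  expect_equal(fisher_z_average(c(0.2, 0.6))$r_bar,
               tanh((atanh(0.2) + atanh(0.6)) / 2), tolerance = 1e-12)
  expect_equal(round(fisher_z_average(c(0.2, 0.6))$r_bar, 3), 0.420)
  expect_equal(fisher_z_average(c(0.4, -0.4))$r_bar, 0)
  expect_error(fisher_z_average(c(0.5, 1)), "infinite")
  set.seed(31)
  for (i in 1:20) {
    rs <- runif(sample(2:12, 1), -0.95, 0.95)
    pooled <- fisher_z_average(rs)$r_bar
    expect_gte(pooled, min(rs)); expect_lte(pooled, max(rs))
  }
})

test_that("Dice similarity counts overlap as defined", {
  g <- function(v) array(v, c(10, 10, 2))
  a <- g(FALSE); a[1:100] <- TRUE
  b <- g(FALSE); b[41:140] <- TRUE  # |A| = |B| = 100, 60 shared
  expect_equal(dice_similarity(a, b), 0.6)
  expect_equal(dice_similarity(a, a), 1)
  d <- g(FALSE); d[101:150] <- TRUE
  expect_equal(dice_similarity(a, d), 0)
  expect_equal(dice_similarity(g(FALSE), g(FALSE)), 1)
  expect_error(dice_similarity(a, array(TRUE, c(5, 5, 2))), "grids")
})

test_that("the normality diagnostic reports without gating", {
  set.seed(2)
  out <- normality_diagnostic(rnorm(200))
  expect_true(out$p_value > 0 && out$p_value <= 1)
  expect_equal(out$n, 200L)
})
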