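cohort <- stroke_cohort()
cohort$pos <- mrs_positive(cohort$mrs)

test_that("spearman_rho matches the mid-rank convention and base R", {
  df <- tibble::tibble(x = 1:10, y = (1:10)^2)
  expect_equal(spearman_rho(df, x, y)$rho, 1)
  df$y <- -df$y
  expect_equal(spearman_rho(df, x, y)$rho, -1)
  set.seed(7)
  df <- tibble::tibble(x = rnorm(40), y = sample(0:6, 40, replace = TRUE))
  expect_equal(spearman_rho(df, x, y)$rho,
               cor(df$x, df$y, method = "spearman"), tolerance = 1e-12)
  expect_error(spearman_rho(tibble::tibble(x = 1:5, y = rep(2, 5)), x, y),
               class = "actasym_undefined_error")
  expect_error(spearman_rho(tibble::tibble(x = 1:2, y = 1:2), x, y),
               class = "actasym_validation_error")
})

test_that("shapiro wrapper flags non-normal data and rejects constants", {
  n_ok <- sum(vapply(1:100, function(s) {
    set.seed(s)
    shapiro_normality(tibble::tibble(x = rnorm(20)), x)$p_value > 0.05
  }, logical(1)))
  expect_gte(n_ok, 90)
  n_rej <- sum(vapply(1:100, function(s) {
    set.seed(s)
    shapiro_normality(tibble::tibble(x = stats::rexp(100)), x)$p_value < 0.05
  }, logical(1)))
  expect_gte(n_rej, 90)
  expect_error(shapiro_normality(tibble::tibble(x = rep(1, 10)), x),
               class = "actasym_undefined_error")
})

test_that("empirical AUC equals exhaustive pair counting and pROC", {
  df <- tibble::tibble(score = c(1, 2, 3, 10, 11, 12),
                       pos = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(roc_auc(df, score, pos)$auc, 1)
  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    df <- tibble::tibble(
      score = round(runif(n, 0, 10), sample(0:2, 1)),  # force some ties
      pos = runif(n) < 0.5)
    if (!any(df$pos) || all(df$pos)) next
    auc <- roc_auc(df, score, pos)$auc
    expect_equal(auc, brute_force_auc(df$score, df$pos), tolerance = 1e-12)
    expect_equal(auc,
                 as.numeric(pROC::auc(pROC::roc(df$pos, df$score,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
  # labels independent of scores: null AUC near 1/2
  set.seed(9)
  df <- tibble::tibble(score = runif(4000), pos = runif(4000) < 0.5)
  expect_equal(roc_auc(df, score, pos)$auc, 0.5, tolerance = 0.05)
  expect_error(roc_auc(tibble::tibble(score = 1:3, pos = rep(TRUE, 3)),
                       score, pos),
               class = "actasym_validation_error")
})

test_that("ROC operating points are monotone step functions", {
  roc <- roc_auc(cohort, ar2_abs, pos)
  pts <- dplyr::arrange(roc$points, threshold)
  expect_true(all(diff(pts$sensitivity) <= 1e-12))
  expect_true(all(diff(1 - pts$specificity) <= 1e-12))
})

test_that("youden interval matches an exhaustive threshold sweep", {
  set.seed(10)
  for (i in 1:15) {
    df <- tibble::tibble(score = runif(20, 0, 100), pos = runif(20) < 0.5)
    if (!any(df$pos) || all(df$pos)) next
    cut <- youden_cutoff(df, score, pos, nominal_digits = 3)
    bf <- brute_force_youden(df$score, df$pos)
    expect_equal(cut$sensitivity + cut$specificity, bf$max,
                 tolerance = 1e-12)
    # every threshold strictly inside the interval attains the sweep max
    # (when distinct optima tie, the reported interval is the
    # highest-sensitivity run, so containment is one-directional)
    inside <- bf$thresholds > cut$lower & bf$thresholds < cut$upper
    expect_true(any(inside))
    expect_true(all(bf$j[inside] >= bf$max - 1e-12))
    expect_gt(cut$nominal, cut$lower)
    expect_lte(cut$nominal, cut$upper)
  }
  # perfectly separated: interval spans the class gap
  df <- tibble::tibble(score = c(1, 2, 3, 7, 8, 9),
                       pos = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  cut <- youden_cutoff(df, score, pos)
  expect_equal(cut$lower, 3)
  expect_equal(cut$upper, 7)
})

test_that("diagnostic metrics obey the confusion identities", {
  set.seed(11)
  for (i in 1:10) {
    df <- tibble::tibble(score = runif(30, 0, 100), pos = runif(30) < 0.4)
    if (!any(df$pos) || all(df$pos)) next
    thr <- runif(1, 0, 100)
    m <- diagnostic_metrics(df, score, pos, thr)
    expect_equal(m$tp + m$fn, sum(df$pos))
    expect_equal(m$tn + m$fp, sum(!df$pos))
    expect_equal(m$tp + m$fp + m$tn + m$fn, nrow(df))
    expect_equal(m$sensitivity, m$tp / (m$tp + m$fn))
    expect_equal(m$specificity, m$tn / (m$tn + m$fp))
  }
  # all scores below threshold: sens 0, spec 1, ppv undefined, LR+ Inf
  df <- tibble::tibble(score = c(1, 2, 3, 4), pos = c(TRUE, FALSE, TRUE,
                                                      FALSE))
  m <- diagnostic_metrics(df, score, pos, 10)
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 1)
  expect_true(is.nan(m$ppv))
  expect_true(is.infinite(m$lr_pos))
})

test_that("post-test probability is the exact odds update", {
  expect_equal(posttest_probability(0.5, 9)$posttest_prob, 0.9)
  expect_equal(posttest_probability(0.3, 1)$posttest_prob, 0.3)
  # strictly increasing in both arguments; lr = 1 is a fixed point
  p1 <- posttest_probability(0.389, 2)$posttest_prob
  p2 <- posttest_probability(0.389, 5)$posttest_prob
  p3 <- posttest_probability(0.5, 5)$posttest_prob
  expect_true(p1 < p2 && p2 < p3)
  expect_equal(posttest_probability(0.2, 0)$posttest_prob, 0)
  expect_error(posttest_probability(1, 2),
               class = "actasym_validation_error")
  expect_error(posttest_probability(0.5, -1),
               class = "actasym_validation_error")
})

test_that("ROC sample size is the smallest n meeting the power condition", {
  res <- roc_sample_size(0.90, 0.50, 0.05, 0.20, 0.389)
  expect_equal(res$n_total, 16L)
  # the returned n_pos passes the criterion and n_pos - 1 fails it
  crit <- function(n_pos, auc0, auc1, prev, z_a, z_b) {
    n_neg <- n_pos * (1 - prev) / prev
    z_a * sqrt(actasym:::hanley_mcneil_var(auc0, n_pos, n_neg)) +
      z_b * sqrt(actasym:::hanley_mcneil_var(auc1, n_pos, n_neg))
  }
  z_a <- qnorm(0.975); z_b <- qnorm(0.8)
  expect_lte(crit(res$n_pos, 0.5, 0.9, 0.389, z_a, z_b), 0.4)
  expect_gt(crit(res$n_pos - 1, 0.5, 0.9, 0.389, z_a, z_b), 0.4)
  # monotonicity: a smaller effect needs at least as many subjects
  expect_gte(roc_sample_size(0.75, 0.50, 0.05, 0.20, 0.389)$n_total,
             res$n_total)
  expect_gte(roc_sample_size(0.90, 0.50, 0.05, 0.20, 0.389)$n_total,
             roc_sample_size(0.95, 0.50, 0.05, 0.20, 0.389)$n_total)
})

test_that("the composed analysis rejects degenerate cohorts", {
  bad <- cohort[cohort$mrs > 2, ]
  expect_error(prognostic_analysis(bad), class = "actasym_validation_error")
  prog <- prognostic_analysis(cohort, pretest_prob = 0.389)
  expect_s3_class(glance(prog), "tbl_df")
  expect_equal(glance(prog)$threshold, 32)
  expect_equal(nrow(tidy(prog)), 13)
})
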