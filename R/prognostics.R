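#' Dichotomize the modified Rankin Scale at the disability threshold
#'
#' The 90-day mRS (0-6) is split into functional independence (0-2) and
#' moderate-to-severe disability or death (> 2); the latter is the
#' positive class throughout the prognostic analysis.
#'
#' @param mrs integer vector of mRS scores in 0..6.
#' @return logical vector, `TRUE` for mRS > 2.
#' @export
mrs_positive <- function(mrs) {
  if (!all(mrs %in% 0:6)) {
    abort("mrs must be integers in 0..6", class = "actasym_validation_error")
  }
  mrs > 2
}

check_labels <- function(labels) {
  if (is.numeric(labels) && all(labels %in% c(0, 1))) labels <- labels == 1
  if (!is.logical(labels) || anyNA(labels)) {
    abort("labels must be logical (or 0/1) without missing values",
          class = "actasym_validation_error")
  }
  if (!any(labels) || all(labels)) {
    abort("need at least one positive and one negative label",
          class = "actasym_validation_error")
  }
  labels
}

#' Spearman rank correlation with mid-rank ties
#'
#' Pearson correlation of the mid-rank (average-rank) vectors, with a
#' two-sided p-value from the t approximation on n - 2 degrees of
#' freedom. Used to relate the absolute asymmetry index to the ordinal
#' 90-day mRS, where heavy ties make the exact permutation null
#' impractical and normality cannot be assumed.
#'
#' @param data data frame.
#' @param x,y unquoted column names of the two variables.
#' @return one-row tibble: `rho`, `statistic` (t), `p_value`, `n`.
#' @export
spearman_rho <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  n <- length(xv)
  if (length(yv) != n || n < 3) {
    abort("x and y must have equal length n >= 3",
          class = "actasym_validation_error")
  }
  rx <- rank(xv); ry <- rank(yv)
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("a rank vector is constant: correlation undefined",
          class = "actasym_undefined_error")
  }
  rho <- cor(rx, ry)
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  tibble::tibble(rho = rho, statistic = tt,
                 p_value = 2 * pt(-abs(tt), df = n - 2), n = n)
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper used to justify the nonparametric correlation in
#' reports: small cohorts with bimodal asymmetry distributions fail
#' normality, so Spearman rather than Pearson correlation is reported.
#'
#' @param data data frame.
#' @param x unquoted column to test (3 <= n <= 5000).
#' @return one-row tibble: `statistic` (W), `p_value`, `n`, `normal`
#'   (p > 0.05).
#' @export
shapiro_normality <- function(data, x) {
  xv <- dplyr::pull(data, {{ x }})
  if (length(unique(xv)) == 1) {
    abort("constant input: normality test undefined",
          class = "actasym_undefined_error")
  }
  ht <- shapiro.test(xv)
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n = length(xv), normal = ht$p.value > 0.05)
}

roc_curve_points <- function(scores, labels) {
  # sens / spec of the strict rule "positive iff score > t" at every
  # distinct score (plus -Inf), i.e. every attainable operating point
  thr <- c(-Inf, sort(unique(scores)))
  pos <- scores[labels]; neg <- scores[!labels]
  tibble::tibble(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(pos > t), numeric(1)),
    specificity = vapply(thr, function(t) mean(neg <= t), numeric(1)))
}

#' Empirical ROC curve and AUC
#'
#' The AUC is the Mann-Whitney concordance probability: the fraction of
#' (positive, negative) pairs in which the positive scores higher, ties
#' counting one half. Computed from mid-ranks; the ROC operating points
#' are evaluated at every distinct score under the strict
#' `score > threshold` positivity rule.
#'
#' @param data data frame with one row per patient.
#' @param score unquoted column of the continuous marker (here
#'   `|AR2|` in percent).
#' @param outcome unquoted column with the positive-class indicator
#'   (logical or 0/1; see [mrs_positive()]).
#' @return an `ar2_roc`: list with `auc`, `points` (tibble of
#'   threshold/sensitivity/specificity), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(data, score, outcome) {
  scores <- dplyr::pull(data, {{ score }})
  labels <- check_labels(dplyr::pull(data, {{ outcome }}))
  if (length(scores) != length(labels) || anyNA(scores)) {
    abort("score and outcome must be equal-length and non-missing",
          class = "actasym_validation_error")
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  rk <- rank(scores)  # mid-ranks give the ties-count-half convention
  auc <- (sum(rk[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(auc = auc, points = roc_curve_points(scores, labels),
                 n_pos = n_pos, n_neg = n_neg,
                 scores = scores, labels = labels),
            class = "ar2_roc")
}

#' @export
print.ar2_roc <- function(x, ...) {
  cat(sprintf("Empirical ROC: AUC = %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden-optimal classification threshold
#'
#' Finds the operating point maximizing sensitivity + specificity under
#' the strict `score > threshold` rule. The data determine an interval
#' of equivalent thresholds, not a point: the interval is reported as
#' `(lower, upper]` where `upper` is the smallest score classified
#' positive at the optimum and `lower` the largest score strictly below
#' it. The nominal threshold is a rounding of the interval midpoint
#' (`nominal_digits` decimal places); any threshold inside the interval
#' yields the same confusion matrix.
#'
#' @inheritParams roc_auc
#' @param nominal_digits decimals for the reported nominal threshold.
#' @return an `ar2_cutoff`: one-row tibble `lower`, `upper`, `nominal`,
#'   `sensitivity`, `specificity`, `youden`.
#' @export
youden_cutoff <- function(data, score, outcome, nominal_digits = 0) {
  scores <- dplyr::pull(data, {{ score }})
  labels <- check_labels(dplyr::pull(data, {{ outcome }}))
  pos <- scores[labels]; neg <- scores[!labels]
  # every attainable classification is "positive iff score >= c" for c in
  # the distinct scores (or no-one positive, c = Inf); a threshold t of the
  # strict rule "score > t" realizes the cut c exactly when t lies in
  # (largest score below c, c], which is the interval reported
  cand <- c(sort(unique(scores)), Inf)
  sens <- vapply(cand, function(c) mean(pos >= c), numeric(1))
  spec <- vapply(cand, function(c) mean(neg < c), numeric(1))
  j <- sens + spec
  best <- which(j >= max(j) - 1e-12)
  # contiguous run of equivalent optimal cuts, preferring the
  # highest-sensitivity (lowest-cut) run when distinct optima tie
  run_start <- best[1]
  run_end <- run_start
  while (run_end + 1 <= length(cand) && (run_end + 1) %in% best) {
    run_end <- run_end + 1
  }
  ss <- sort(unique(scores))
  c_lo <- cand[run_start]; c_hi <- cand[run_end]
  lower <- if (any(ss < c_lo)) max(ss[ss < c_lo]) else -Inf
  nominal <- round((lower + c_hi) / 2, nominal_digits)
  out <- tibble::tibble(lower = lower, upper = c_hi, nominal = nominal,
                        sensitivity = sens[run_start],
                        specificity = spec[run_start],
                        youden = j[run_start] - 1)
  class(out) <- c("ar2_cutoff", class(out))
  out
}

#' Diagnostic accuracy at a fixed threshold
#'
#' Confusion counts and accuracy measures for the strict rule
#' "predict positive iff score > threshold". Likelihood ratios are
#' `LR+ = sens / (1 - spec)` and `LR- = (1 - sens) / spec`; under
#' `lr_convention = "percent_rounded"` they are computed from
#' sensitivity and specificity first rounded to whole percents (the
#' convention of clinical reports, where e.g. spec 8/9 prints as 89% and
#' LR+ as 1/0.11 = 9.09 rather than the exact 9.0). An infinite LR+
#' (specificity 1) is represented as `Inf`; an undefined PPV or NPV
#' (empty predicted class) as `NaN`, never silently as 0.
#'
#' @inheritParams roc_auc
#' @param threshold positivity threshold (same units as `score`).
#' @param lr_convention `"exact"` or `"percent_rounded"`.
#' @return an `ar2_diag`: list with `threshold`, counts `tp fp tn fn`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `lr_pos`, `lr_neg`,
#'   `auc`, `lr_convention`.
#' @export
diagnostic_metrics <- function(data, score, outcome, threshold,
                               lr_convention = c("exact", "percent_rounded")) {
  lr_convention <- match.arg(lr_convention)
  scores <- dplyr::pull(data, {{ score }})
  labels <- check_labels(dplyr::pull(data, {{ outcome }}))
  if (!is.finite(threshold)) {
    abort("threshold must be finite", class = "actasym_validation_error")
  }
  pred <- scores > threshold
  tp <- sum(pred & labels);  fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  ppv <- if (tp + fp == 0) NaN else tp / (tp + fp)
  npv <- if (tn + fn == 0) NaN else tn / (tn + fn)
  s_lr <- if (lr_convention == "percent_rounded") round(sens, 2) else sens
  c_lr <- if (lr_convention == "percent_rounded") round(spec, 2) else spec
  lr_pos <- if (c_lr == 1) Inf else s_lr / (1 - c_lr)
  lr_neg <- if (c_lr == 0) NaN else (1 - s_lr) / c_lr
  rk <- rank(scores)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  structure(list(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
                 lr_pos = lr_pos, lr_neg = lr_neg,
                 auc = (sum(rk[labels]) - n_pos * (n_pos + 1) / 2) /
                   (n_pos * n_neg),
                 lr_convention = lr_convention),
            class = "ar2_diag")
}

#' @export
print.ar2_diag <- function(x, ...) {
  cat(sprintf("Diagnostic accuracy at score > %g (%s LRs)\n", x$threshold,
              x$lr_convention))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sens %.0f%%  spec %.0f%%  PPV %.0f%%  NPV %.0f%%\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$ppv,
              100 * x$npv))
  cat(sprintf("  LR+ %.2f  LR- %.2f  AUC %.2f\n", x$lr_pos, x$lr_neg, x$auc))
  invisible(x)
}

#' Post-test probability by the odds-form Bayes update (Fagan nomogram)
#'
#' `posttest odds = pretest odds * LR`; the nomogram is the graphical
#' form of this identity. Using a population prevalence as the pretest
#' probability decouples the predictive value from the small study
#' sample's own prevalence.
#'
#' @param pretest_prob pretest probability in (0, 1), e.g. the
#'   population prevalence of the outcome.
#' @param lr likelihood ratio (>= 0) of the observed test result.
#' @return one-row tibble: `pretest_prob`, `lr`, `posttest_prob`.
#' @export
posttest_probability <- function(pretest_prob, lr) {
  if (!is.numeric(pretest_prob) || pretest_prob <= 0 || pretest_prob >= 1) {
    abort("pretest_prob must lie strictly inside (0, 1)",
          class = "actasym_validation_error")
  }
  if (!is.numeric(lr) || lr < 0) {
    abort("lr must be nonnegative", class = "actasym_validation_error")
  }
  post_odds <- pretest_prob / (1 - pretest_prob) * lr
  post <- if (is.infinite(post_odds)) 1 else post_odds / (1 + post_odds)
  tibble::tibble(pretest_prob = pretest_prob, lr = lr, posttest_prob = post)
}

hanley_mcneil_var <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
      (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
}

#' Minimum sample size for an ROC accuracy study
#'
#' Smallest number of positive subjects such that a two-sided level
#' `alpha` test of AUC = `auc_null` has power `1 - beta` against
#' AUC = `auc_alt`, using the Hanley-McNeil variance
#' `V(A) = [A(1-A) + (n+ - 1)(Q1 - A^2) + (n- - 1)(Q2 - A^2)] / (n+ n-)`
#' with `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`. During the search the
#' negative count tracks the prevalence exactly,
#' `n- = n+ (1 - prev)/prev`; the returned `n_neg` is rounded up.
#'
#' @param auc_alt alternative (anticipated) AUC, > `auc_null`.
#' @param auc_null null AUC (0.5 = no discrimination).
#' @param alpha two-sided type-I error rate.
#' @param beta type-II error rate (power = 1 - beta).
#' @param prevalence positive-class prevalence in (0, 1).
#' @param max_n_pos search cap.
#' @return one-row tibble: design parameters plus `n_pos`, `n_neg`,
#'   `n_total`.
#' @export
roc_sample_size <- function(auc_alt = 0.90, auc_null = 0.50, alpha = 0.05,
                            beta = 0.20, prevalence = 0.389,
                            max_n_pos = 1e6) {
  stopifnot(auc_alt > auc_null, alpha > 0, alpha < 1, beta > 0, beta < 1,
            prevalence > 0, prevalence < 1)
  z_a <- qnorm(1 - alpha / 2)
  z_b <- qnorm(1 - beta)
  delta <- auc_alt - auc_null
  crit <- function(n_pos) {
    n_neg <- n_pos * (1 - prevalence) / prevalence
    z_a * sqrt(hanley_mcneil_var(auc_null, n_pos, n_neg)) +
      z_b * sqrt(hanley_mcneil_var(auc_alt, n_pos, n_neg))
  }
  n_pos <- 2
  while (n_pos <= max_n_pos && crit(n_pos) > delta) n_pos <- n_pos + 1
  if (n_pos > max_n_pos) {
    abort("required power not reachable within the search cap",
          class = "actasym_undefined_error")
  }
  n_neg <- ceiling(n_pos * (1 - prevalence) / prevalence)
  tibble::tibble(auc_alt = auc_alt, auc_null = auc_null, alpha = alpha,
                 beta = beta, prevalence = prevalence,
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 n_total = as.integer(n_pos + n_neg))
}

#' Full prognostic-accuracy analysis of a cohort
#'
#' Composes the whole statistical pipeline on a cohort table: normality
#' check of `|AR2|`, Spearman correlation of `|AR2|` with the ordinal
#' mRS, empirical ROC of `|AR2|` against the dichotomized outcome
#' (mRS > 2), Youden-optimal threshold, diagnostic accuracy at that
#' threshold under both likelihood-ratio conventions, and post-test
#' probabilities of a positive test at the supplied population pretest
#' probability and at the sample prevalence.
#'
#' @param cohort cohort tibble (schema of [read_cohort_table()]).
#' @param pretest_prob population pretest probability of mRS > 2;
#'   default 0.389, the prevalence of moderate-to-severe disability in
#'   the general stroke population.
#' @param threshold `"youden"` (default: the nominal Youden-optimal
#'   threshold) or a fixed numeric threshold in percent.
#' @return an `ar2_prognosis` object (list of the component results);
#'   see [tidy.ar2_prognosis()] and [glance.ar2_prognosis()].
#' @export
prognostic_analysis <- function(cohort, pretest_prob = 0.389,
                                threshold = "youden") {
  cohort <- validate_cohort(cohort)
  cohort$mrs_gt2 <- mrs_positive(cohort$mrs)
  if (!any(cohort$mrs_gt2) || all(cohort$mrs_gt2)) {
    abort("cohort has a single outcome class: ROC analysis undefined",
          class = "actasym_validation_error")
  }
  normality <- shapiro_normality(cohort, .data$ar2_abs)
  rho <- spearman_rho(cohort, .data$ar2_abs, .data$mrs)
  roc <- roc_auc(cohort, .data$ar2_abs, .data$mrs_gt2)
  cutoff <- youden_cutoff(cohort, .data$ar2_abs, .data$mrs_gt2)
  thr <- if (identical(threshold, "youden")) cutoff$nominal else threshold
  metrics_exact <- diagnostic_metrics(cohort, .data$ar2_abs, .data$mrs_gt2,
                                      thr, "exact")
  metrics_rounded <- diagnostic_metrics(cohort, .data$ar2_abs, .data$mrs_gt2,
                                        thr, "percent_rounded")
  prev_sample <- mean(cohort$mrs_gt2)
  posttest_population <- posttest_probability(pretest_prob,
                                              metrics_rounded$lr_pos)
  posttest_sample <- posttest_probability(prev_sample,
                                          metrics_rounded$lr_pos)
  structure(list(cohort = cohort, normality = normality, rho = rho,
                 roc = roc, cutoff = cutoff, threshold = thr,
                 metrics_exact = metrics_exact,
                 metrics_rounded = metrics_rounded,
                 pretest_prob = pretest_prob, prevalence_sample = prev_sample,
                 posttest_population = posttest_population,
                 posttest_sample = posttest_sample),
            class = "ar2_prognosis")
}

#' @export
print.ar2_prognosis <- function(x, ...) {
  cat("Prognostic accuracy of |AR2| for 90-day mRS > 2\n")
  cat(sprintf("  n = %d (%d with mRS > 2; sample prevalence %.0f%%)\n",
              nrow(x$cohort), x$roc$n_pos, 100 * x$prevalence_sample))
  cat(sprintf("  Shapiro-Wilk on |AR2|: W = %.3f, p = %.3g -> %s\n",
              x$normality$statistic, x$normality$p_value,
              if (x$normality$normal) "compatible with normality"
              else "non-normal (Spearman used)"))
  cat(sprintf("  Spearman rho(|AR2|, mRS) = %.3f (p = %.3g)\n",
              x$rho$rho, x$rho$p_value))
  cat(sprintf("  ROC AUC = %.2f; Youden-optimal thresholds (%.1f, %.1f], nominal %g%%\n",
              x$roc$auc, x$cutoff$lower, x$cutoff$upper, x$cutoff$nominal))
  m <- x$metrics_exact
  cat(sprintf("  At |AR2| > %g%%: sens %.0f%%, spec %.0f%%, PPV %.0f%%, NPV %.0f%%\n",
              x$threshold, 100 * m$sensitivity, 100 * m$specificity,
              100 * m$ppv, 100 * m$npv))
  cat(sprintf("  LR+ %.2f (exact %.2f), LR- %.2f\n",
              x$metrics_rounded$lr_pos, m$lr_pos, x$metrics_rounded$lr_neg))
  cat(sprintf("  Post-test P(mRS > 2 | positive): %.0f%% at pretest %.1f%%; %.0f%% at sample prevalence\n",
              100 * x$posttest_population$posttest_prob,
              100 * x$pretest_prob,
              100 * x$posttest_sample$posttest_prob))
  invisible(x)
}
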