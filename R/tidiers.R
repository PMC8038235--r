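#' Tidiers for asymmetry and prognosis objects
#'
#' `tidy()` returns the per-component detail as a tibble; `glance()` a
#' one-row summary, broom-style.
#'
#' @param x an `ar2_result`, `ar2_roc`, `ar2_diag` or `ar2_prognosis`.
#' @param ... unused.
#' @return a tibble.
#' @name actasym-tidiers
NULL

#' @rdname actasym-tidiers
#' @export
glance.ar2_result <- function(x, ...) {
  tibble::tibble(ar2 = x$ar2, ar2_abs = abs(x$ar2), theta_deg = x$theta_deg,
                 n_epochs = x$n_epochs, eigenvalue_ratio = x$eigenvalue_ratio,
                 degenerate = x$degenerate)
}

#' @rdname actasym-tidiers
#' @export
tidy.ar2_result <- function(x, ...) x$pairs

#' @rdname actasym-tidiers
#' @export
glance.ar2_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname actasym-tidiers
#' @export
tidy.ar2_roc <- function(x, ...) x$points

#' @rdname actasym-tidiers
#' @export
tidy.ar2_diag <- function(x, ...) {
  vals <- c(sensitivity = x$sensitivity, specificity = x$specificity,
            ppv = x$ppv, npv = x$npv, lr_pos = x$lr_pos, lr_neg = x$lr_neg,
            auc = x$auc)
  tibble::tibble(metric = names(vals), estimate = unname(vals))
}

#' @rdname actasym-tidiers
#' @export
glance.ar2_diag <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, tp = x$tp, fp = x$fp, tn = x$tn,
                 fn = x$fn, sensitivity = x$sensitivity,
                 specificity = x$specificity, ppv = x$ppv, npv = x$npv,
                 lr_pos = x$lr_pos, lr_neg = x$lr_neg, auc = x$auc,
                 lr_convention = x$lr_convention)
}

#' @rdname actasym-tidiers
#' @export
tidy.ar2_prognosis <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(metric = "spearman_rho", estimate = x$rho$rho),
    tibble::tibble(metric = "auc", estimate = x$roc$auc),
    tibble::tibble(metric = "threshold", estimate = x$threshold),
    tidy(x$metrics_exact),
    tibble::tibble(metric = "lr_pos_percent_rounded",
                   estimate = x$metrics_rounded$lr_pos),
    tibble::tibble(metric = "posttest_population",
                   estimate = x$posttest_population$posttest_prob),
    tibble::tibble(metric = "posttest_sample",
                   estimate = x$posttest_sample$posttest_prob))
}

#' @rdname actasym-tidiers
#' @export
glance.ar2_prognosis <- function(x, ...) {
  tibble::tibble(n = nrow(x$cohort), n_pos = x$roc$n_pos,
                 n_neg = x$roc$n_neg, rho = x$rho$rho,
                 rho_p = x$rho$p_value, auc = x$roc$auc,
                 threshold = x$threshold,
                 cutoff_lower = x$cutoff$lower, cutoff_upper = x$cutoff$upper,
                 sensitivity = x$metrics_exact$sensitivity,
                 specificity = x$metrics_exact$specificity,
                 ppv = x$metrics_exact$ppv, npv = x$metrics_exact$npv,
                 lr_pos_exact = x$metrics_exact$lr_pos,
                 lr_pos_rounded = x$metrics_rounded$lr_pos,
                 lr_neg = x$metrics_exact$lr_neg,
                 pretest_prob = x$pretest_prob,
                 posttest_population = x$posttest_population$posttest_prob,
                 posttest_sample = x$posttest_sample$posttest_prob)
}
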