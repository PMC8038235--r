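#' Activity-profile plot of both wrists over time
#'
#' Per-epoch activity of the right (blue) and left (red) wrist across
#' the recording: the at-a-glance view in which a hemiparesis shows as
#' one trace lying persistently under the other.
#'
#' @param pairs a `paired_activity` tibble.
#' @return a ggplot.
#' @export
plot_activity_profile <- function(pairs) {
  stopifnot(inherits(pairs, "paired_activity"))
  long <- tidyr::pivot_longer(tibble::as_tibble(pairs),
                              c("activity_right", "activity_left"),
                              names_to = "side", names_prefix = "activity_",
                              values_to = "activity")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$epoch_start / 3600,
                               y = .data$activity,
                               colour = .data$side)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(right = "#2166ac",
                                            left = "#b2182b")) +
    ggplot2::labs(x = "time (h)", y = "epoch activity (g)",
                  colour = "wrist") +
    ggplot2::theme_minimal()
}

#' @describeIn ar2_index Scatter of the paired activity cloud with the
#'   bisector (dashed; perfect epoch symmetry) and the fitted principal
#'   axis through the origin (solid).
#' @param object an `ar2_result`.
#' @param ... unused.
#' @export
autoplot.ar2_result <- function(object, ...) {
  slope <- tan(object$theta_deg * pi / 180)
  lim <- max(object$pairs$activity_right, object$pairs$activity_left)
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$activity_right,
                               y = .data$activity_left)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_abline(slope = slope, intercept = 0,
                         colour = "#b2182b") +
    ggplot2::coord_fixed(xlim = c(0, lim), ylim = c(0, lim)) +
    ggplot2::labs(x = "right-wrist activity (g)",
                  y = "left-wrist activity (g)",
                  title = sprintf("AR2 = %+.1f%% (theta = %.1f deg)",
                                  object$ar2, object$theta_deg)) +
    ggplot2::theme_minimal()
}

#' @describeIn roc_auc ROC curve (1 - specificity vs sensitivity) with
#'   the chance diagonal.
#' @param object an `ar2_roc`.
#' @param ... unused.
#' @export
autoplot.ar2_roc <- function(object, ...) {
  pts <- dplyr::arrange(object$points, 1 - .data$specificity,
                        .data$sensitivity)
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh", colour = "#2166ac") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.2f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Correlation scatter of the asymmetry index against the 90-day mRS
#'
#' @param cohort cohort tibble.
#' @return a ggplot.
#' @export
plot_mrs_correlation <- function(cohort) {
  cohort <- validate_cohort(cohort)
  ggplot2::ggplot(cohort, ggplot2::aes(x = .data$mrs, y = .data$ar2_abs)) +
    ggplot2::geom_point(size = 2, alpha = 0.7) +
    ggplot2::scale_x_continuous(breaks = 0:6) +
    ggplot2::labs(x = "90-day mRS", y = "|AR2| (%)") +
    ggplot2::theme_minimal()
}

#' Fagan-nomogram rendering of a post-test update
#'
#' The nomogram's three aligned log scales: a straight line from the
#' pretest probability through the likelihood ratio lands on the
#' post-test probability.
#'
#' @param posttest one-row tibble from [posttest_probability()].
#' @return a ggplot.
#' @export
plot_fagan <- function(posttest) {
  logit <- function(p) log(p / (1 - p))
  pre <- posttest$pretest_prob; post <- posttest$posttest_prob
  probs <- c(0.001, 0.01, 0.05, 0.1, 0.2, 0.389, 0.5, 0.7, 0.9, 0.99)
  axis_df <- tibble::tibble(
    x = rep(c(0, 2), each = length(probs)),
    y = c(-logit(probs), logit(probs)),
    lab = rep(sprintf("%g%%", 100 * probs), 2))
  lr_ticks <- c(0.01, 0.1, 0.5, 1, 2, 5, 10, 100)
  lr_df <- tibble::tibble(x = 1, y = log(lr_ticks) / 2,
                          lab = sprintf("%g", lr_ticks))
  ggplot2::ggplot() +
    ggplot2::geom_text(data = axis_df,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$lab), size = 2.6) +
    ggplot2::geom_text(data = lr_df,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$lab), size = 2.6) +
    ggplot2::annotate("segment", x = 0, xend = 2, y = -logit(pre),
                      yend = logit(post), colour = "#b2182b") +
    ggplot2::annotate("text", x = c(0, 1, 2), y = max(logit(probs)) * 1.15,
                      label = c("pretest", "LR", "post-test"), size = 3) +
    ggplot2::labs(title = sprintf("pretest %.1f%% x LR %.2f -> post-test %.1f%%",
                                  100 * pre, posttest$lr, 100 * post)) +
    ggplot2::theme_void()
}
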