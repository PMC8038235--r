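#' The 24-h Asymmetry Rate Index (AR2) from paired epoch activities
#'
#' Fits the first eigenvector of the paired activity cloud — right-wrist
#' activity on x, left-wrist activity on y, one point per synchronized
#' epoch — as the best-fitting line *through the origin* (total least
#' squares on the second-moment matrix about the origin, not the mean).
#' The angle theta of that line from the right-arm axis encodes the
#' asymmetry: points on the bisector (theta = 45 deg) are perfectly
#' symmetric epochs; the index maps the angle linearly to a signed
#' percentage,
#'
#'   AR2 = 100 * (45 - theta_deg) / 45,
#'
#' so 0% is symmetric behaviour, +100% means left activity is absent
#' (pure right prevalence, i.e. left hemiparesis/plegia) and -100% the
#' mirror image. The origin convention is what makes the anchors exact:
#' a cloud with left activity identically zero lies on the x-axis and
#' gives exactly +100%; mean-centred PCA would not.
#'
#' Epochs with both arms at rest sit at the origin and do not influence
#' the fitted angle; they are retained by default. `activity_floor`
#' optionally removes pairs whose larger activity is at or below a noise
#' floor.
#'
#' @param pairs a `paired_activity` tibble from [pair_epochs()] (or any
#'   data frame with nonnegative `activity_right`, `activity_left`).
#' @param activity_floor pairs with `max(right, left) <= activity_floor`
#'   are excluded before the fit; default 0 (off — only exact-origin
#'   points, which are angle-neutral anyway, are then inert).
#' @return an `ar2_result`: list with `ar2` (signed percent in
#'   \[-100, 100\]), `theta_deg` (degrees in \[0, 90\] from the
#'   right-arm axis), `n_epochs`, `eigenvalue_ratio` (lambda1/lambda2,
#'   cloud-elongation diagnostic, Inf for an exactly rank-1 cloud),
#'   `degenerate` (TRUE when the cloud is isotropic and the direction
#'   undefined; theta is then reported as 45, ar2 as 0), and the input
#'   `pairs` for plotting.
#' @export
ar2_index <- function(pairs, activity_floor = 0) {
  if (!all(c("activity_right", "activity_left") %in% names(pairs))) {
    abort("pairs must have activity_right and activity_left columns",
          class = "actasym_validation_error")
  }
  r <- pairs$activity_right
  l <- pairs$activity_left
  if (anyNA(r) || anyNA(l) || any(!is.finite(r)) || any(!is.finite(l))) {
    abort("activities must be finite and non-missing",
          class = "actasym_validation_error")
  }
  if (any(r < 0) || any(l < 0)) {
    abort("activities must be nonnegative", class = "actasym_validation_error")
  }
  if (length(r) < 2) {
    abort("need at least 2 paired epochs", class = "actasym_validation_error")
  }
  if (activity_floor > 0) {
    keep <- pmax(r, l) > activity_floor
    r <- r[keep]; l <- l[keep]
  }
  n <- length(r)
  if (n < 2 || all(r == 0 & l == 0)) {
    abort("all-zero activity cloud: the asymmetry index is undefined",
          class = "actasym_undefined_error")
  }
  # second-moment matrix about the origin, M = (1/n) sum (r,l)(r,l)^T
  m_rr <- mean(r * r); m_ll <- mean(l * l); m_rl <- mean(r * l)
  # closed-form principal axis of the symmetric 2x2: tan(2*theta) =
  # 2*m_rl / (m_rr - m_ll). Exact, and exactly antisymmetric under a
  # right<->left swap (atan2(y, -x) = pi - atan2(y, x)), which the sign
  # convention of the index requires.
  disc <- sqrt(((m_rr - m_ll) / 2)^2 + m_rl^2)
  lam <- c((m_rr + m_ll) / 2 + disc, (m_rr + m_ll) / 2 - disc)
  degenerate <- disc <= 1e-14 * max(lam[1], .Machine$double.xmin)
  theta <- if (degenerate) 45
           else 0.5 * atan2(2 * m_rl, m_rr - m_ll) * 180 / pi
  eigenvalue_ratio <- if (lam[2] <= 0) Inf else lam[1] / lam[2]
  structure(list(ar2 = 100 * (45 - theta) / 45,
                 theta_deg = theta,
                 n_epochs = n,
                 eigenvalue_ratio = eigenvalue_ratio,
                 degenerate = degenerate,
                 pairs = tibble::tibble(activity_right = r,
                                        activity_left = l)),
            class = "ar2_result")
}

#' @export
print.ar2_result <- function(x, ...) {
  cat(sprintf("AR2 asymmetry index: %+.2f%% (theta = %.3f deg from right-arm axis)\n",
              x$ar2, x$theta_deg))
  cat(sprintf("  %d epochs; eigenvalue ratio %.3g%s\n", x$n_epochs,
              x$eigenvalue_ratio,
              if (x$degenerate) "; DEGENERATE isotropic cloud" else ""))
  invisible(x)
}

#' Absolute asymmetry index
#'
#' The magnitude of the signed AR2 index, as tabulated per patient in
#' cohort analyses (the prognostic analysis consumes `|AR2|`; the sign
#' only encodes the side of paresis).
#'
#' @param x an `ar2_result` or a numeric vector of signed AR2 values.
#' @return percent in \[0, 100\].
#' @export
ar2_abs <- function(x) {
  if (inherits(x, "ar2_result")) abs(x$ar2) else abs(x)
}

#' Mean-activity (PIM-style) asymmetry ratio
#'
#' The classical comparator: each arm's motor activity is the area under
#' the rectified acceleration curve — per 30-minute epoch the per-epoch
#' mean is removed, the residual vector magnitude is integrated over
#' time (trapezoidal rule) — and the ratio divides the affected arm's
#' area by the unaffected arm's. A ratio of 1 means symmetric activity,
#' 0 an immobile affected arm. This is a whole-recording mean ratio, not
#' an epoch-synchronous index; it is provided for comparison only and
#' plays no role in the prognostic pipeline.
#'
#' @param dual a `dual_recording` from [pair_recordings()].
#' @param affected_side `"right"` or `"left"`.
#' @param epoch_length epoch for mean removal, seconds; default 1800.
#' @return a `pim_ratio`: list with `ratio`, `auc_affected`,
#'   `auc_unaffected`, `epoch_length`.
#' @export
pim_ratio <- function(dual, affected_side = c("right", "left"),
                      epoch_length = 1800) {
  stopifnot(inherits(dual, "dual_recording"))
  affected_side <- match.arg(affected_side)
  win <- c(dual$overlap_start, dual$overlap_end)
  if (win[2] - win[1] < epoch_length) {
    abort("overlap shorter than one epoch", class = "actasym_validation_error")
  }
  rect_auc <- function(rec) {
    t_abs <- attr(rec, "start_time") + rec$t
    keep <- t_abs >= win[1] & t_abs <= win[2]
    t_k <- t_abs[keep]
    acc <- as.matrix(tibble::as_tibble(rec)[keep, c("ax", "ay", "az")])
    idx <- pmin(floor((t_k - win[1]) / epoch_length),
                floor((win[2] - win[1]) / epoch_length) - 1) + 1L
    grp <- factor(idx, levels = sort(unique(idx)))
    cnt <- as.vector(table(grp))
    means <- rowsum(acc, grp) / cnt
    resid <- acc - means[as.integer(grp), , drop = FALSE]
    mag <- sqrt(rowSums(resid^2))
    # trapezoidal area of the rectified magnitude over the window
    sum(diff(t_k) * (head(mag, -1) + tail(mag, -1)) / 2)
  }
  auc_r <- rect_auc(dual$right)
  auc_l <- rect_auc(dual$left)
  auc_aff <- if (affected_side == "right") auc_r else auc_l
  auc_una <- if (affected_side == "right") auc_l else auc_r
  if (auc_una == 0) {
    abort("unaffected-arm activity area is zero: ratio undefined",
          class = "actasym_undefined_error")
  }
  structure(list(ratio = auc_aff / auc_una, auc_affected = auc_aff,
                 auc_unaffected = auc_una, epoch_length = epoch_length,
                 affected_side = affected_side),
            class = "pim_ratio")
}

#' @export
print.pim_ratio <- function(x, ...) {
  cat(sprintf("PIM activity ratio (affected %s / unaffected): %.3f\n",
              x$affected_side, x$ratio))
  invisible(x)
}
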