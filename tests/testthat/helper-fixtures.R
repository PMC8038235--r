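# Small builders and independent oracles shared across the suite.

# raw recording with an arbitrary signal function of time
make_recording <- function(side, fs = 10, hours = 1, start_time = 0,
                           signal = function(t) cbind(0 * t, 0 * t, 0 * t)) {
  t <- seq(0, hours * 3600 - 1 / fs, by = 1 / fs)
  acc <- signal(t)
  wrist_recording(tibble::tibble(t = t, ax = acc[, 1], ay = acc[, 2],
                                 az = acc[, 3]),
                  side = side, sample_rate = fs, start_time = start_time)
}

# paired activity straight from two nonnegative vectors
make_pairs <- function(right, left, epoch_length = 60) {
  actasym:::new_paired_activity(
    epoch_start = (seq_along(right) - 1) * epoch_length,
    activity_right = right, activity_left = left,
    epoch_length = epoch_length, n_dropped = 0L)
}

# independent oracle: best-fitting line through the origin by brute-force
# minimization of summed squared perpendicular distances (grid + refine)
brute_force_theta <- function(r, l) {
  f <- function(theta_deg) {
    th <- theta_deg * pi / 180
    sum((l * cos(th) - r * sin(th))^2)
  }
  grid <- seq(0, 90, by = 0.01)
  vals <- vapply(grid, f, numeric(1))
  i <- which.min(vals)
  lo <- max(0, grid[i] - 0.02)
  hi <- min(90, grid[i] + 0.02)
  stats::optimize(f, c(lo, hi), tol = 1e-10)$minimum
}

# independent oracle: AUC by exhaustive pair counting, ties count 1/2
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# independent oracle: exhaustive threshold sweep of sens + spec under the
# strict score > t rule, over a fine grid spanning the scores
brute_force_youden <- function(scores, labels, grid_n = 20001) {
  ts <- seq(min(scores) - 1, max(scores) + 1, length.out = grid_n)
  pos <- scores[labels]
  neg <- scores[!labels]
  j <- vapply(ts, function(t) mean(pos > t) + mean(neg <= t), numeric(1))
  list(thresholds = ts, j = j, max = max(j))
}

random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_res)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

fixture_cohort_path <- function() {
  system.file("extdata", "stroke_cohort_20.csv", package = "actasym",
              mustWork = TRUE)
}
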