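test_that("constant signals give zero activity in every epoch", {
  rec <- make_recording("right", fs = 4, hours = 0.5,
                        signal = function(t) cbind(0.2 + 0 * t, -0.1 + 0 * t,
                                                   0.97 + 0 * t))
  act <- epoch_activity(rec, c(0, 1800))
  expect_equal(nrow(act), 30)
  expect_equal(act$activity, rep(0, 30))
})

test_that("a whole-period sinusoid has activity amplitude/sqrt(2)", {
  A <- 0.3
  fs <- 1000 / 60  # 1000 samples per 60 s epoch
  rec <- make_recording("right", fs = fs, hours = 1 / 6,
                        signal = function(t) cbind(A * sin(2 * pi * t / 60),
                                                   0 * t, 0 * t))
  act <- epoch_activity(rec, c(0, 600))
  expect_equal(act$activity, rep(A / sqrt(2), 10), tolerance = 1e-9)
})

test_that("activity is invariant under fixed sensor rotations", {
  set.seed(42)
  base_sig <- function(t) cbind(0.05 * sin(t / 7) + 0.02 * rnorm(length(t)),
                                0.03 * cos(t / 13), 0.97 + 0.01 * sin(t / 3))
  set.seed(1); rec <- make_recording("right", fs = 4, hours = 0.5,
                                     signal = base_sig)
  ref <- epoch_activity(rec, c(0, 1800))$activity
  for (i in 1:5) {
    rot <- random_rotation()
    m <- as.matrix(tibble::as_tibble(rec)[c("ax", "ay", "az")]) %*% t(rot)
    rec_rot <- wrist_recording(
      tibble::tibble(t = rec$t, ax = m[, 1], ay = m[, 2], az = m[, 3]),
      side = "right", sample_rate = 4)
    rotated <- epoch_activity(rec_rot, c(0, 1800))$activity
    expect_equal(rotated, ref, tolerance = 1e-9)
  }
})

test_that("activity is scale-equivariant and gravity-insensitive", {
  set.seed(2)
  rec <- make_recording("right", fs = 4, hours = 0.25,
                        signal = function(t) matrix(rnorm(3 * length(t),
                                                          sd = 0.05),
                                                    ncol = 3))
  ref <- epoch_activity(rec, c(0, 900))$activity
  scaled <- wrist_recording(
    dplyr::mutate(tibble::as_tibble(rec), ax = 3 * ax, ay = 3 * ay,
                  az = 3 * az),
    side = "right", sample_rate = 4)
  expect_equal(epoch_activity(scaled, c(0, 900))$activity, 3 * ref,
               tolerance = 1e-12)
  shifted <- wrist_recording(
    dplyr::mutate(tibble::as_tibble(rec), ax = ax + 0.3, ay = ay - 1,
                  az = az + 0.97),
    side = "right", sample_rate = 4)
  expect_equal(epoch_activity(shifted, c(0, 900))$activity, ref,
               tolerance = 1e-12)
})

test_that("epoch grid anchors at the window start and drops partials", {
  rec <- make_recording("right", fs = 2, hours = 0.1)  # 360 s
  act <- epoch_activity(rec, c(0, 360))
  expect_equal(nrow(act), 6)
  act2 <- epoch_activity(rec, c(0, 350))  # 5 whole epochs + 50 s partial
  expect_equal(nrow(act2), 5)
  expect_error(epoch_activity(rec, c(100, 100)),
               class = "actasym_validation_error")
  expect_error(epoch_activity(rec, c(0, 30)),
               class = "actasym_validation_error")
})

test_that("sparse epochs are marked missing and dropped on pairing", {
  # 2 Hz everywhere except one epoch that keeps a single sample
  t <- seq(0, 299.5, by = 0.5)
  keep <- !(t >= 60 & t < 120) | t == 60
  rec <- wrist_recording(tibble::tibble(t = t[keep], ax = rnorm(sum(keep)),
                                        ay = 0, az = 0),
                         side = "right", sample_rate = 2)
  act <- epoch_activity(rec, c(0, 300))
  expect_true(is.na(act$activity[2]))
  expect_equal(sum(is.na(act$activity)), 1)

  left <- epoch_activity(
    make_recording("left", fs = 2, hours = 300 / 3600,
                   signal = function(t) cbind(rnorm(length(t)), 0, 0)),
    c(0, 300))
  pairs <- pair_epochs(act, left)
  expect_equal(nrow(pairs), 4)
  expect_equal(attr(pairs, "n_dropped"), 1L)
})

test_that("pairing requires aligned grids and enough epochs", {
  a <- epoch_activity(make_recording("right", fs = 2, hours = 0.1), c(0, 360))
  b <- epoch_activity(make_recording("left", fs = 2, hours = 0.1), c(0, 360))
  expect_equal(nrow(pair_epochs(a, b)), 6)
  shifted <- epoch_activity(make_recording("left", fs = 2, hours = 0.1),
                            c(30, 330))
  expect_error(pair_epochs(a, shifted), class = "actasym_pairing_error")
  short <- epoch_activity(make_recording("left", fs = 2, hours = 0.1),
                          c(0, 360), epoch_length = 90)
  expect_error(pair_epochs(a, short), class = "actasym_pairing_error")
})
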