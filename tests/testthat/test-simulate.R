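# Simulations in the suite run at 4 samples/s (240 samples per 1-min
# epoch) and shortened recordings; the index is rate-agnostic, so this
# only speeds the tests up.

sim_ar2 <- function(severity, side = "left", noise_sd = 0, hours = 4,
                    fs = 4, seed = 20) {
  pp <- sim_patient_params(severity = severity, paretic_side = side,
                           noise_sd = noise_sd, sample_rate = fs,
                           duration_h = hours, seed = seed)
  sim <- simulate_patient(pp)
  ar2_index(dual_epoch_activity(sim$dual))$ar2
}

test_that("expected_ar2 has the right anchors and sign convention", {
  expect_equal(expected_ar2(0, "left"), 0)
  expect_equal(expected_ar2(1, "left"), 100)
  expect_equal(expected_ar2(1, "right"), -100)
  expect_equal(expected_ar2(0.5, "left"),
               100 * (45 - atan(0.5) * 180 / pi) / 45)
  expect_equal(expected_ar2(0.5, "left"), 40.97, tolerance = 1e-4)
  expect_equal(expected_ar2(0.7, "none"), 0)
})

test_that("the pipeline recovers the generating asymmetry without noise", {
  for (d in c(0, 0.5, 1)) {
    expect_equal(sim_ar2(d, "left"), expected_ar2(d, "left"),
                 tolerance = 2 / max(abs(expected_ar2(d, "left")), 1),
                 label = sprintf("pipeline ar2 at d = %g", d))
  }
  # right-side paresis flips the recovered sign
  expect_lt(sim_ar2(0.8, "right"), -70)
})

test_that("recovered asymmetry is monotone in severity (noise-free)", {
  vals <- vapply(seq(0, 1, by = 0.25), sim_ar2, numeric(1), side = "left",
                 hours = 2)
  expect_true(all(diff(vals) >= -1e-9))
})

test_that("patient simulation is deterministic under a fixed seed", {
  pp <- sim_patient_params(severity = 0.4, paretic_side = "left",
                           sample_rate = 4, duration_h = 1, seed = 99)
  a <- simulate_patient(pp)
  b <- simulate_patient(pp)
  expect_identical(as.data.frame(a$dual$right), as.data.frame(b$dual$right))
  expect_identical(as.data.frame(a$dual$left), as.data.frame(b$dual$left))
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(sim_patient_params(severity = 1.2),
               class = "actasym_validation_error")
  expect_error(sim_patient_params(active_fraction = 0),
               class = "actasym_validation_error")
  expect_error(sim_patient_params(noise_sd = -1),
               class = "actasym_validation_error")
  expect_error(sim_cohort_params(n_patients = 1),
               class = "actasym_validation_error")
})

test_that("a well-separated simulated cohort yields a discriminative index", {
  cp <- sim_cohort_params(n_patients = 200, seed = 21)
  co <- simulate_cohort(cp)
  expect_equal(nrow(co), 200)
  co$pos <- mrs_positive(co$mrs)
  expect_gte(roc_auc(co, ar2_abs, pos)$auc, 0.9)
  # the analytic |AR2| agrees with the generating severity
  expect_equal(co$ar2_abs,
               abs(vapply(seq_len(200), function(i)
                 expected_ar2(co$severity[i], co$hemiparesis[i]),
                 numeric(1))))
  # bimodality of the generated index: both tails populated
  expect_gt(mean(co$ar2_abs > 60), 0.2)
  expect_gt(mean(co$ar2_abs < 40), 0.2)
})

test_that("outcomes independent of severity give a null AUC", {
  aucs <- vapply(31:35, function(s) {
    co <- simulate_cohort(sim_cohort_params(n_patients = 200, beta0 = 0,
                                            beta1 = 0, seed = s))
    co$pos <- mrs_positive(co$mrs)
    roc_auc(co, ar2_abs, pos)$auc
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.1)
})

test_that("cohort simulation is deterministic and flags degenerate mixtures", {
  a <- simulate_cohort(sim_cohort_params(n_patients = 30, seed = 5))
  b <- simulate_cohort(sim_cohort_params(n_patients = 30, seed = 5))
  expect_identical(as.data.frame(a), as.data.frame(b))
  deg <- simulate_cohort(sim_cohort_params(n_patients = 10, weight_low = 1,
                                           seed = 5))
  expect_true(attr(deg, "degenerate_mixture"))
})

test_that("slow mode pushes every patient through the raw-signal pipeline", {
  cp <- sim_cohort_params(
    n_patients = 4, mode = "slow", seed = 22,
    patient_params = sim_patient_params(sample_rate = 4, duration_h = 1,
                                        noise_sd = 0.0005))
  co <- simulate_cohort(cp)
  exp_ar2 <- vapply(seq_len(4), function(i)
    expected_ar2(co$severity[i], co$hemiparesis[i]), numeric(1))
  expect_equal(co$ar2_signed, exp_ar2, tolerance = 0.12)
  expect_true(all(abs(co$ar2_signed - exp_ar2) < 4))
})
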