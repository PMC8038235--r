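# actasym

Dual-wrist actigraphy for acute stroke: the 24-hour upper-limb
**Asymmetry Rate Index (AR2_24h)** and its accuracy as an early
predictor of 90-day disability.

## The problem

In the first days after an ischemic stroke it is hard to predict who
will be independent at 90 days (modified Rankin Scale, mRS 0–2) and who
will be left with moderate-to-severe disability or die (mRS > 2).
Bedridden patients in a stroke unit still move spontaneously, and the
*asymmetry* of that movement between the paretic and non-paretic arm is
an objective, continuously measurable signal. Two wristwatch-like
tri-axial accelerometers — one per wrist, synchronized — record 24 h of
acceleration; this package turns those raw signals into a single
percentage index and evaluates how well it predicts outcome.

## The index

1. **Epoch activity.** Each wrist's recording is cut into 1-minute
   epochs. The activity of an epoch is the Euclidean norm of the three
   within-epoch acceleration standard deviations,
   `a = sqrt(SD(ax)² + SD(ay)² + SD(az)²)` — the square root of the
   trace of the within-epoch covariance, so it is invariant to sensor
   orientation and insensitive to the constant gravity component.
2. **The data cloud.** Synchronized epochs form points
   (right activity, left activity). Points on the bisector are epochs
   of symmetric movement; points below it, right-arm prevalence.
3. **The eigenvector.** The first eigenvector of the cloud's second-
   moment matrix about the origin is the best-fitting line through the
   origin (total least squares). With θ its angle from the right-arm
   axis,

   `AR2 = 100 · (45° − θ) / 45°`

   so AR2 = 0% is perfect symmetry, +100% means left activity is absent
   (left hemiparesis/plegia), −100% the mirror image. Cohort analyses
   use |AR2|.

The prognostic layer is classical diagnostic-accuracy methodology:
Spearman correlation of |AR2| with the ordinal mRS, the empirical ROC
of |AR2| against mRS > 2 (AUC by Mann–Whitney pair counting), the
Youden-optimal cut-off (reported as the interval of equivalent
thresholds), sensitivity/specificity/PPV/NPV and likelihood ratios,
Fagan post-test probabilities at a population pretest probability, and
a Hanley–McNeil ROC sample-size calculation. A synthetic generator
produces raw dual-wrist recordings with known ground-truth asymmetry
(`expected_ar2(d) = 100·(45 − atan(1−d)·180/π)/45` for paretic-arm
attenuation `d`), so the whole pipeline is testable end to end.

## Worked example

Simulate a patient with a 60%-attenuated paretic left arm, run the raw
signals through the pipeline, and read off the index:

```r
library(actasym)

pp  <- sim_patient_params(severity = 0.6, paretic_side = "left",
                          sample_rate = 4, duration_h = 24, seed = 42)
sim <- simulate_patient(pp)
res <- sim$dual |> dual_epoch_activity() |> ar2_index()
res
#> AR2 asymmetry index: +50.79% (theta = 22.143 deg from right-arm axis)
#>   1439 epochs; eigenvalue ratio 729
expected_ar2(0.6, "left")
#> [1] 51.55242
```

The positive sign says right-arm movement dominates (left paresis); the
recovered 50.8% sits within a point of the generator's ground truth,
and the eigenvalue ratio of 729 says the cloud is strongly elongated —
the line summarizes it well. `autoplot(res)` draws the cloud with the
bisector and fitted axis.

The packaged 20-patient cohort reproduces the full prognostic analysis:

```r
prog <- prognostic_analysis(stroke_cohort(), pretest_prob = 0.389)
prog
#> Prognostic accuracy of |AR2| for 90-day mRS > 2
#>   n = 20 (11 with mRS > 2; sample prevalence 55%)
#>   Shapiro-Wilk on |AR2|: W = 0.784, p = 0.000511 -> non-normal (Spearman used)
#>   Spearman rho(|AR2|, mRS) = 0.729 (p = 0.000267)
#>   ROC AUC = 0.96; Youden-optimal thresholds (31.5, 32.6], nominal 32%
#>   At |AR2| > 32%: sens 100%, spec 89%, PPV 92%, NPV 100%
#>   LR+ 9.09 (exact 9.00), LR- 0.00
#>   Post-test P(mRS > 2 | positive): 85% at pretest 38.9%; 92% at sample prevalence
```

An asymmetry above 32% predicts a poor 90-day outcome with perfect
sensitivity in this cohort; weighting by the general stroke-population
prevalence of mRS > 2 (38.9%) gives the more conservative 85% post-test
probability. `tidy(prog)` and `glance(prog)` return the same numbers as
tibbles; `autoplot(prog$roc)`, `plot_mrs_correlation()` and
`plot_fagan()` draw the standard figures.

A thin command-line wrapper is shipped in `inst/cli/ar2`
(`ar2 index`, `ar2 epochs`, `ar2 cohort-stats`, `ar2 simulate`).

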