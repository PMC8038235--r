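---
title: "The dual-wrist asymmetry index: model, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dual-wrist asymmetry index: model, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actasym)
```

## The measurement model

Two wrist-worn tri-axial accelerometers record a bedridden acute-stroke
patient for 24 h. The quantity of clinical interest is not either arm's
activity but their epoch-by-epoch *asymmetry*: a hemiparetic arm moves
less than the non-paretic arm in the same minute, every minute.

The pipeline makes three modelling commitments, each with a reason.

**Per-epoch activity is the norm of the component standard
deviations.** For an epoch's samples, activity is
$a = \sqrt{\mathrm{SD}(a_x)^2 + \mathrm{SD}(a_y)^2 + \mathrm{SD}(a_z)^2}$,
with SDs about the epoch mean in population convention
($n$ denominator). This equals $\sqrt{\mathrm{tr}\,\Sigma}$ for the
within-epoch covariance $\Sigma$, and the trace is invariant under any
fixed rotation of the sensor axes — the only choice of "function of the
component standard deviations" that makes the index genuinely
orientation-independent, which matters because nobody controls how a
wristwatch sits on a paretic arm in a stroke unit. Removing the epoch
mean before squaring also removes the constant gravity component, so no
band-pass filtering is applied; `epoch_activity()` exposes `sum` and
`max` alternatives for sensitivity analyses, but those are *not*
rotation-invariant and are not used anywhere else. The population-SD
convention is a determinism choice: at ≥ 60 samples per epoch the
$n$ vs $n-1$ difference is below 1%, but a fixed convention makes
every worked value exactly reproducible.

**The fit is a line through the origin, not mean-centred PCA.** The
paired epoch activities (right on x, left on y) form a cloud in the
nonnegative quadrant; the index is the angle $\theta$ of the cloud's
first eigenvector, taken from the second-moment matrix **about the
origin** $M = \tfrac1n \sum_i (r_i, l_i)(r_i, l_i)^\top$. The origin
convention is forced by the index's anchor semantics: a patient whose
left arm never moves has all points on the x-axis and must score
exactly +100%; under mean-centred PCA the principal axis of such a
cloud depends on the spread of the right arm's activity, not its
direction. Epochs where both arms rest sit at the origin and are
angle-neutral, so they are retained (an optional `activity_floor`
exists, default off).

**The angle maps linearly to a signed percentage.**
$\mathrm{AR2} = 100\,(45^\circ - \theta)/45^\circ$. Three anchors are
fixed by the definition — 0% on the bisector, +100% at absent left
activity ($\theta = 0^\circ$), −100% at absent right activity — and
linear interpolation in the angle is the simplest map honouring all
three. It is the single canonical convention in this package.

## Numerical choices

- The $2\times 2$ eigenproblem is solved in closed form:
  $\theta = \tfrac12\,\mathrm{atan2}(2 M_{rl},\, M_{rr} - M_{ll})$,
  eigenvalues $\tfrac{M_{rr}+M_{ll}}{2} \pm \sqrt{(\tfrac{M_{rr}-M_{ll}}{2})^2 + M_{rl}^2}$.
  Besides speed, the closed form makes the right↔left antisymmetry
  $\mathrm{AR2}(l, r) = -\mathrm{AR2}(r, l)$ hold to machine precision
  via the identity $\mathrm{atan2}(y, -x) = \pi - \mathrm{atan2}(y, x)$.
- An isotropic cloud (discriminant ≤ $10^{-14} \lambda_1$) has no
  defined direction; it is reported as $\theta = 45^\circ$, AR2 = 0,
  with a `degenerate` flag rather than an arbitrary eigenvector.
- Within-epoch variance uses a two-pass algorithm (mean removal before
  squaring). The one-pass $\mathrm{E}[x^2]-\mathrm{E}[x]^2$ form
  cancels catastrophically against the ~1 g gravity offset and turns
  "constant signal → activity exactly 0" into "activity ≈ $10^{-8}$".
- The epoch grid anchors at the start of the two sensors' overlap
  window (not wall-clock midnight); a final partial epoch is discarded
  so every activity value summarizes equal information. Epochs with
  fewer than two samples have undefined SD and are marked missing,
  then dropped pairwise.
- Timestamps must be strictly increasing; clock skew between the two
  sensors' declared starts is tolerated up to `max_clock_skew` (default
  60 s, one epoch — the recordings are synchronized at setup, so a
  skew beyond one epoch indicates a setup failure rather than drift).

## The prognostic layer

The cohort analysis consumes |AR2| — the magnitude encodes severity,
the sign only the side of paresis — against the 90-day mRS
dichotomized at > 2.

- **AUC** is the Mann–Whitney concordance computed from mid-ranks
  (ties count one half); an exhaustive pair-counting oracle and pROC
  cross-check it in the test suite.
- **The Youden cut-off is an interval, not a point.** Finite data
  determine only which scores are classified positive at the optimum.
  With $c^\*$ the smallest positively-classified score, every
  threshold in $(\mathrm{prev}(c^\*),\, c^\*]$ (under the rule
  "positive iff score ≥ cut"; equivalently
  $[\mathrm{prev}(c^\*),\, c^\*)$ under the strict "score > t" rule
  used for reporting) yields the same confusion matrix. The package
  reports the open–closed interval plus a nominal value (interval
  midpoint, rounded; configurable). When distinct optima tie on
  sensitivity + specificity, the highest-sensitivity run is reported —
  a clinical preference for not missing poor outcomes.
- **Likelihood ratios in two conventions.** `exact` uses the raw
  fractions (e.g. specificity 8/9 gives LR+ = 9.0). `percent_rounded`
  first rounds sensitivity and specificity to whole percents, the
  convention of clinical reports (spec 89% gives LR+ = 1/0.11 = 9.09).
  Both are computed and reported; neither is "the" value, and an
  infinite LR+ (specificity 1) or undefined PPV/NPV (empty predicted
  class) is represented explicitly (`Inf`, `NaN`), never silently as 0.
- **Post-test probabilities** are the exact odds-form Bayes update
  (the Fagan nomogram is its graphical rendering). Using the general
  stroke-population prevalence of mRS > 2 (0.389) as the pretest
  probability decouples predictive value from the small sample's own
  prevalence, which is also reported for comparison.
- **Sample size** uses the Hanley–McNeil AUC variance with the
  negative:positive ratio held at $(1-p)/p$ during the integer search
  over the positive count, a two-sided $\alpha$ quantile, and the
  negative count rounded up at the end. The suite verifies the
  returned size meets the power condition and the next smaller one
  fails it.
- **Spearman correlation** uses mid-rank ties and a t-approximation
  p-value. On the packaged cohort this recomputes to ρ = 0.729. A
  smaller published value (0.69) circulates for this cohort; it is not
  reproducible from the printed per-patient values under any standard
  tie convention we tried (mid-rank, exact ranks on the rounded
  percentages), and likely reflects software-specific handling or use
  of unrounded source values. The package therefore treats the
  recomputed statistic — its sign, strength and stability under the
  documented convention — as the reportable quantity; p-values for ρ
  and the AUC are reported but small-$n$ approximations differ across
  software and are not used as decision surfaces.

## What the synthetic generator emulates

No raw recordings of this kind are publicly deposited, so the
generator is a first-class module: every pipeline stage is tested
against data with known ground truth.

A patient is a two-state (rest/active) epoch schedule with a circadian
profile: daytime epochs (08:00–22:00) are active with probability
$1.3f$ (capped at 1) and night epochs with $0.58f$, so the daily mean
equals the `active_fraction` $f$ (default 0.35 — bedridden patients
move in bouts covering roughly a third of the day). In an active epoch
a shared bilateral intensity is drawn (log-normal, median
`base_activity_scale` = 0.05 g, log-SD 0.5); the non-paretic arm's
signal is band-limited zero-mean noise (5-point moving-average of white
noise) rescaled so its per-epoch acceleration SD *equals* that
intensity, and the paretic arm's equals intensity × (1 − d) for
severity $d \in [0,1]$. Each sensor adds its own constant gravity
vector and white noise (`noise_sd`, default 0.002 g). The default
sample rate is 32 /s, a wristwatch-class figure; all downstream math is
rate-agnostic, and the test suite runs at 4 /s (240 samples per epoch)
purely for speed.

The exact per-epoch rescaling is a deliberate design choice: under it
the noise-free activity cloud is exactly rank-1 on the line
$l = (1-d)\,r$, giving the closed-form oracle
$\mathrm{AR2}(d) = 100\,(45 - \arctan(1-d)\cdot 180/\pi)/45$
(`expected_ar2()`), so parameter recovery is testable to tight
tolerance rather than "approximately". The headline recovery test runs
$d = 0, 0.1, \dots, 1$ over 24 h of 1-minute epochs with sensor noise
at 1% of the base scale and requires agreement within 2 percentage
points.

Additive sensor noise bounds what recovery can achieve at high
severity: a plegic arm's measured activity is never 0 but
$\sqrt{3}\,\sigma_{noise}$, which pulls the fitted angle off the axis.
At 1% relative noise this costs under 2 points at $d = 1$; at 10% it
would cost tens of points. That is a real property of the measurement,
not an artifact — an index of 100% is unobservable on a noisy sensor —
and is why the recovery test pins the noise level it claims.

Cohorts draw severity from a two-component Beta mixture
(Beta(2, 6) and Beta(6, 1.5), low-severity weight 0.45), reproducing
the bimodal asymmetry distribution that the prevalence of extreme
disability levels in the stroke population leads one to expect. The
outcome follows $P(\mathrm{mRS}>2 \mid d) = \mathrm{logit}^{-1}(-5 + 10d)$,
anchored so the implied population ROC AUC of |AR2| against mRS > 2 is
about 0.96, the discrimination observed in the packaged cohort. The
ordinal mRS beyond the dichotomy is an arbitrary fixed sub-model
(binomial on 0–2 or 3–6 with success probability $d$) used only so
rank-based analyses run. Fast mode assigns |AR2| from the closed form;
slow mode simulates raw signals per patient and runs the full pipeline.

What the generator does **not** emulate: nursing-care handling bursts,
device removal gaps, sleep staging, biomechanically realistic limb
kinematics, or device-specific noise spectra. Passing recovery tests
therefore shows the pipeline is faithful to its own measurement model,
not that the index is robust to every artifact of a real ward
recording.

## Problem sizes

The test suite simulates at 4 samples/s with recordings of 1–24 h
(the full 24 h × 11 severity levels only in the headline recovery
test), cohorts of up to 200 patients in fast mode and 4 in slow mode,
and 100-seed batches for the distributional properties of the
normality check; these sizes give stable assertions at interactive
runtimes. The cohort statistics themselves are 20-row computations.

## Known limitations

- The raw-CSV dialect is a reconstruction: the original device's
  sampling frequency, gap policy and logging mode are not public, so
  the sample rate is required per-file metadata rather than inferred.
- The PIM-style mean-activity ratio (`pim_ratio()`, 30-min epochs,
  rectified-signal area via the trapezoidal rule) is a comparator with
  its own literature; it is implemented for side-by-side use but plays
  no role in the prognostic pipeline and no claim of equivalence with
  any specific commercial actigraph's counts is made.
- With 20 patients the accuracy metrics carry wide (unreported)
  confidence intervals; the package intentionally reports the Bayesian
  post-test probabilities instead of small-sample CIs. DeLong or
  bootstrap intervals are a possible extension, not implemented.
- `prognostic_analysis()` requires both outcome classes; single-class
  cohorts are an error by design, not an NA.
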