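---
title: "Behavioral rhythms, multi-task learning, and what the synthetic cohorts establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral rhythms, multi-task learning, and what the synthetic cohorts establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rhythmMTL)
```

This vignette is the package's own account of its models and of the design
decisions that were genuinely open: the rhythm metrics and their numerical
conventions, the three model families and their solvers, what the
synthetic-cohort generator emulates (and deliberately does not), and the
identifiability limits that shape how the parameter-recovery tests are
scored.  It states no empirical result that the test suite does not itself
compute.

## 1. The modeling problem

Each patient contributes two asynchronous record types: continuous or
event-based sensing streams (accelerometry, ambient light and sound, screen
use, SMS/call events), and sparse EMA self-reports — ten items scored 0–3,
prompted every 2–3 days.  The prediction task is regression of each EMA
item on features of the preceding sensing window.  Because behavior is
organized in rhythms, the features quantify periodic structure at three
scales: ultradian (period < 20 h), circadian (20–30 h), and infradian
(> 30 h).  Every feature is tagged `modality ⊗ metric ⊗ window`, with
windows of 2–14 days ending at local midnight of the EMA date (the window
is `[d−w, d)`, so only data strictly before the report day is used).

## 2. Rhythm metrics: conventions and degenerate inputs

All metrics consume a regular hourly grid: event streams become counts per
hour; continuous streams hourly means, with sample-free hours masked.
Masked gaps of at most 3 h are linearly interpolated; a modality-window
with less than 70% observed hours yields missing features; rows with more
than 50% missing features are dropped and the remainder median-imputed per
patient.  These thresholds are implementation choices (the underlying study
does not state its missing-data handling); they are parameters of
`build_feature_matrix()`.

**Multiscale sample entropy.** `SampEn(m, r)` is `−ln(A/B)`, with `B` the
number of template pairs of length `m = 2` within Chebyshev tolerance
`r = 0.25 × SD` and `A` the pairs still matching at length `m + 1`;
self-matches are excluded; scales τ = 1…6 are non-overlapping block means.
Two conventions are not dictated by the definition and follow the standard
multiscale-entropy literature: the tolerance is computed once from the
*original* (τ = 1) series and held fixed across scales, and remaining
masked hours are mean-imputed before templating.  A constant series makes
`r = 0` and every scale is reported missing (the statistic is undefined),
as is any scale where no templates match.

**Periodogram band power.** The series is mean-imputed, linearly detrended,
and transformed with an FFT periodogram normalized so the one-sided
ordinates sum to the mean square of the detrended series (the Parseval
check in the acceptance suite holds this to 1e-8).  "Area under the PSD
curve" at a listed period integrates the linearly interpolated periodogram
over the frequency band bounded by the geometric midpoints to the adjacent
listed periods (log-symmetric bands at the two ends).  The band-edge rule
is ours: the source text names the periods but not the edges.  Periods
longer than the window are reported missing rather than extrapolated.  One
consequence worth knowing: a pure 24-h line falls in the 22-h band, close
to its edge with the 27-h band, so single-band assertions about 24-h
signals should sum the circadian bands.

**M10 / L5 / RA.** Computed on the average 24-h profile of the window
(hour-of-day means) with circular runs — the actigraphy convention; the
per-day-then-average alternative was rejected as noisier for short
windows.  `RA = (M10 − L5)/(M10 + L5)` is undefined when the profile is
identically zero.

**Template deviation.** The 24-h template is the hour-of-day mean over the
window; each day's deviation is the mean absolute difference from it.  The
window-level statistics are the mean, median and SD of the per-day
deviations.  The "previous day" variant summarizes a *single* number — a
single day has no spread — so the last day's deviation fills all three of
its slots rather than inventing one; this keeps the six-column layout
stable.

**IS / IV.** Interday stability compares hour-of-day means with overall
variance; it is exactly 1 for a day-periodic series and approximately
`(q−1)/(n−1)` (≈ q/n) for white noise.  Intraday variability is the
normalized mean squared successive difference — exactly 4 for an
alternating series, about 2 for white noise — with differences taken only
within unmasked runs.  Both are restricted to the continuous modalities
(acceleration, light, sound): event counts are not continuous activity
levels.  A 20-h spectral period is classified circadian (the ultradian
class is strictly "< 20 h").

## 3. Models and solvers

**Single-task LASSO** uses the objective `(1/2n)‖y − Xw‖² + α|w|₁` and is
fitted with glmnet (coordinate descent, threshold 1e-12; `α = 0` falls back
to a QR solve).  Features are z-scored per training set, labels centered,
and the intercept unpenalized; reported weights live on the standardized
scale, which is also the scale on which the interpretation layer compares
them.  Zero-variance columns receive zero weight.

**ℓ2,1 multi-task regression** minimizes
`Σ_t c_t‖y_t − X_t w_t‖² + α Σ_i ‖W[i,·]‖₂` with a monotone accelerated
proximal-gradient method: the candidate step is taken from the momentum
point; if it fails to decrease the objective the solver falls back to a
plain proximal step and restarts the momentum, so the objective is
non-increasing by construction (an invariant the acceptance suite asserts
on random instances).  Backtracking halves the step until the quadratic
upper bound holds; convergence is declared at a relative objective change
below 1e-8 (cap 5000 iterations, flagged if hit).  For the patients layout
the per-task losses are normalized by task sample size (`c_t = 1/n_t`), so
that patients with many EMA rows do not dominate the shared support; the
flag `normalize_loss` switches this off to recover the unnormalized form.
Each task's design is standardized separately — the row coupling is over
feature *identity*, not raw scale.

**Multi-output LS-SVR** uses the least-squares (equality-constrained)
variant: task regressors decompose as `w₀ + v_t` with penalties
`‖w₀‖² + (λ/T)Σ‖v_t‖²` and squared errors weighted by `C`.  The KKT system
is a single linear solve in the dual variables; a singular system is
retried with a 1e-10 ridge and flagged.  `λ → ∞` collapses all tasks onto
the pooled regressor; at `T = 1` the model equals a single-output LS-SVR
with kernel scaled by `(1 + 1/λ)` — both identities are acceptance checks
against direct linear-system oracles.  `λ = 0` is rejected: the per-task
adjustments would be unpenalized and the problem degenerates.  The
ε-insensitive SVR variant is out of scope.  The RBF bandwidth defaults to
the median pairwise distance heuristic.

**Hyperparameters.** The source study does not state how α was chosen.
`select_alpha()` implements inner 3-fold cross-validation on the training
split, ties broken toward the sparser model; the patients-layout protocol
uses a chronological 80/20 validation split within the training rows (one
fit per grid value) because a full inner CV over per-patient folds would
multiply the most expensive fits by an order of magnitude.

**Prediction** is the inner product of weights and features plus intercept,
deliberately *not* clipped to the 0–3 scale (an ill-fitted linear model can
and should reveal itself by leaving the scale); `clip = TRUE` is available.

## 4. Evaluation protocols and statistics

Each algorithm has a prescribed scheme: per-patient fivefold CV for the
personalized models and m-SVR; semi leave-one-subject-out for the
patient-coupled ℓ2,1 models (the test patient's held-in folds are joined
with the *full* data of all other patients — the other patients' test-period
rows are not excluded, following the protocol's description); plain
leave-one-subject-out for generalized models; and a chronological 80/20
split, applied per patient, as the deployment-like alternative for all.
Every EMA row receives exactly one out-of-fold prediction per symptom —
an invariant the unit tests assert.

RMSE is reported per (algorithm, patient, symptom), with the percent-of-
scale convention `RMSE/3`.  Paired comparisons use the Wilcoxon signed-rank
test (zero differences dropped; exact null for ≤ 25 untied pairs, normal
approximation with continuity and tie corrections otherwise — calibrated to
the nominal 5% level in the acceptance suite) with Holm–Bonferroni
step-down adjustment.  Aligned-rank-transform ANOVA and Tukey HSD are
routine statistics outside the bespoke surface of this package.  Bootstrap
CIs on mean RMSE use 2000 percentile resamples by default.

## 5. The synthetic cohort: what it emulates and what it does not

`generate_cohort()` emulates the *structure* of a smartphone-sensing
cohort, not the marginal distributions of any real one.  Per patient and
modality the hourly signal is

`max(0, B(day) + A_c(day)·cos(2π(h−φ_c)/24) + A_u(day)·cos(2πt/P_u−φ_u) + A_i·cos(2πt/P_i−φ_i))`,

with baseline `B`, circadian amplitude `A_c` and ultradian amplitude `A_u`
drifting day-to-day as stationary log-AR(1) multipliers (ρ = 0.6, log-sd
0.25–0.35 — amplitudes vary by tens of percent across days, our notion of
realistic short-term behavioral variability), planted periods drawn per
modality from the ultradian pool {4, 8, 16} h and infradian pool
{64, 72, 128} h, and base levels of order 1–3 units per modality.
Continuous modalities add Gaussian observation noise (sd 20% of the base
level) and mask 5% of hours in short blocks; event modalities are
inhomogeneous Poisson streams with the clean profile as rate.  EMA labels
apply a sparse weight template to the z-scored *noise-free* planted
features (for event modalities, features of the rate profile), add Gaussian
noise (sd 0.3, about a third of the typical label spread), and discretize
by round-half-to-even and clipping — so all label noise is explicit and
seeded.  EMA dates start once the longest window fits and then follow the
2–3-day cadence.

Two weight templates implement subtypes: an environmental template
("light": light and sound features) and a phone-usage template
("phone": screen-on-time and SMS features), each placing weight on
relative amplitude, planted-period band power, and M10 of its two
modalities, with magnitudes 0.15–0.45, symptom-specific signs, and 10%
multiplicative jitter within subtype.  Label standardization is per
subtype across patients, which keeps the pooled regression of EMA on
features well-specified — an earlier per-patient standardization made the
pooled model misspecified and was replaced.

What the generator deliberately does **not** emulate: real marginal
distributions, GPS trajectories (location is a daily distance-proxy
continuous stream at most), app-category taxonomies, non-stationary
clinical events such as relapses, device artifacts, or diurnal
compliance patterns in EMA response.  A green pipeline test therefore
establishes that the machinery recovers planted structure under honest
noise — not that the clinical effect sizes of the original cohort would be
reproduced.

## 6. Identifiability: why support recovery is scored on blocks

The generator's signals have, per modality, three day-varying latent
drivers (`B`, `A_c`, `A_u`).  Every circadian-band metric of a modality —
RA, M10, L5, IV, template deviation, 20–28-h band powers — is a smooth
function of the same `(B, A_c)` trajectory, so within a modality-window
these features are near-collinear *by construction*, and in the noiseless
limit exactly so.  A LASSO regression of the labels on the re-extracted
features consequently has a non-unique solution among those proxies: the
planted feature is recovered *or* an equivalent stand-in from its block is.
This is not an implementation defect, and no sinusoid-mixture generator
avoids it; the redundancy is intrinsic to the rhythm-metric catalog itself.
The parameter-recovery invariant is therefore scored at the identifiable
granularity — (modality × periodicity-class) blocks — where oracle-tuned
recovery is essentially exact, while cohort-level *contributions* (`c_p`,
which average over each factor's features) remain meaningful at face value.
This is also why interpretation in the package aggregates before ranking
factors.

## 7. The acceptance cohorts and scaling choices

The pipeline-level acceptance tests use cohorts of 20 patients in two
planted subtypes (30% phone-dominant, 70% light-dominant), four modalities,
2- and 4-day windows (d = 248 features), and a 100-day span giving roughly
39 EMA entries per patient.  The span sits between the two readings of the
criterion's "60 EMA days" (a 60-day span ≈ 22 entries; 60 entries ≈ a
155-day span) and was chosen because it is the regime in which the
multi-task advantage the original study reports is structurally active:
with ~30 training rows per patient and a shared support of ~12 features,
the patient-coupled ℓ2,1 model estimates the support from the pooled
cohort while the personalized LASSO cannot; give each patient twice as
much data and the personalized models genuinely catch up (a property of
the phenomenon, not of this implementation).  MTL and STL are compared on
the *same* per-patient chronological 80/20 split — one fit per seed, which
keeps ten seeded replicates inside a ~10-minute single-CPU budget; the
full semi-LOSO protocol is exercised at small scale by the unit suite and
the demo pipeline.  Subtype recovery clusters the patient columns of the
full-data patient-coupled fit (absolute weights, L2-normalized so patients
cluster by weight pattern rather than magnitude; Euclidean silhouette) —
normalization and distance are our choices, switchable, since the study
states neither.

## 8. Known limitations

* No temporal models: predictions use windowed features only, one day
  ahead; sequence models are explicitly out of scope.
* Feature interactions are not modeled (linear combinations only), so the
  subtype analysis inherits that limitation.
* The exact 4157-column feature space of the original study is not
  reproducible from its description; the catalog here is the documented
  cross product of its stated metrics, windows and modalities.
* The chronological split is applied per patient; whether the original
  pooled before splitting is not stated.
* Whether the original multiscale entropy recomputed the tolerance per
  scale is unknown; we follow the fixed-tolerance convention.
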