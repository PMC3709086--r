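---
title: "Methods: distribution drift and novelty detection in ward vital signs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distribution drift and novelty detection in ward vital signs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitaldrift)
```

## The problem and the data model

Post-operative patients on a surgical ward have their vital signs charted
by nursing staff every one to two hours early in the stay and every four
hours once they stabilise. Five variables are used throughout: respiratory
rate (breaths/min), heart rate (beats/min), SpO2 (%), systolic blood
pressure (mmHg) and tympanic temperature (°C), so each observation is a
vector in R^5. Patients who are re-admitted to intensive care or die on the
ward form the *abnormal* group; for them the analysis stops at the first
such event, and their "length of stay" is the time from admission to that
event. Everyone else is the *normal* group.

Two filters define the analysable cohort: observations with any missing
vital are removed (no imputation — a partially charted observation cannot
be placed in the 5-dimensional space), and patients staying fewer than 4 or
more than 29 days are excluded. Length of stay is computed from the raw
observations *before* filtering, which makes the two filters commute (a
property the test suite checks on randomized cohorts). Day indices count
calendar days since admission, with the admission day as day 1.

## Quantifying drift: the G1–G5 subgroups

Because stays have different lengths, per-day comparisons across patients
use stay-relative anchors: for a stay of L days, the subgroup days are
`1 + round(q * (L - 1))` for q = 0, 0.25, 0.5, 0.75, 1, with halves rounded
away from zero (no rounding convention is standard here; half-away keeps
the G2 day of a 4-day stay distinct from the admission day). Each patient
contributes one 5-vector per subgroup — the arithmetic mean of that day's
observations — and the per-patient vectors form the G1..G5 samples.

Distribution distances between G_i and G5 are computed per vital sign:

* **Kolmogorov–Smirnov** on the raw samples (it is defined through the
  empirical CDFs, so binning would only lose information);
* **symmetric Kullback–Leibler** and **Bhattacharyya** on histograms with
  bin edges shared within each comparison. Default widths are natural
  charting resolutions: RR 1 breaths/min, HR 5 beats/min, SpO2 1 %,
  SysBP 5 mmHg, temperature 0.2 °C. All logarithms are natural, so both
  distances are in nats.

The symmetric KL sum is undefined when a bin is empty in one histogram
only. By default each histogram receives additive smoothing of 1e-10 per
bin and is renormalised, which keeps distance maps finite while perturbing
well-populated bins negligibly; `strict = TRUE` disables smoothing and
returns `Inf` as a divergent flag (the Bhattacharyya distance likewise
returns `Inf` only for fully disjoint supports).

## Sammon projection

The subgroup vectors are z-score normalized with the per-vital mean and
sample SD over *all* observations of the filtered cohort (both outcome
groups), so each vital has comparable dynamic range; a zero-variance vital
is an error naming the variable. The 2-D embedding minimises the Sammon
stress with input-space distances in the normalising denominator — the
convention of Sammon's original formulation, which weights the relative
error of short (local) distances most heavily.

The optimiser is the classic diagonal-Newton update scaled by a step
factor of 0.3, with up to 20 step halvings whenever a proposed update
would increase the stress; if no step length decreases it the run stops
and is reported converged (a local minimum at the resolution of the
update). Iterations stop when the relative stress decrease falls below
`tol` (default 1e-7) or after `max_iter` (default 500). Initial coordinates
are uniform on [-1, 1]^2 from the caller's seed; `init = "pca"` starts from
the first two principal components instead, which is useful when a
deterministic, nearly-optimal start is wanted (for planar input data the
PCA start is already exact). Duplicate input points make the stress
undefined for that pair; such pairs are skipped in both sums with a
warning. Duplicates genuinely occur here: a 4-day stay maps G3 and G4 to
the same calendar day, so those two subgroup vectors coincide.

## The model of normality

The density of "normal" physiology is estimated from the discharge-day
observations of all normal patients — the most stable period of each stay —
after normalization. The kernel density estimate uses isotropic Gaussian
kernels with one shared width σ, set by a nearest-neighbour rule: for each
training point, the mean Euclidean distance to its 10 nearest other points;
σ is the mean of these averages. The rule is intentionally simple — it
scales exactly linearly with the data (σ(cX) = c·σ(X), a tested property)
and adapts to the local spacing of the training set. A variant that
averages *squared* neighbour distances (and takes the square root at the
end) is exposed as `bandwidth_mode = "squared"`, since both readings of
the rule appear in the novelty-detection literature. A point is never its
own neighbour; ties at the k-th distance are broken by index order, which
only matters on exactly degenerate configurations.

The novelty score z(x) = −log p(x) is always evaluated through log-sum-exp:
at episode extremes (HR near 150, 5+ SDs from the training bulk) the
density underflows double precision, while the score remains a
well-conditioned quadratic-like quantity.

The alarm threshold is k = μ_z + 3·sd_z over the novelty scores of the
normal group. The reference set is per-observation scores (every
observation of every normal patient); a per-patient variant (mean score per
patient first) is available via `unit = "patient"`. Per-observation was
chosen because the threshold is applied to scores of individual days and
observations, so its reference distribution should live on the same scale.
The SD uses the sample (n−1) convention. Note that the reference includes
admission-day observations, which score higher than discharge-day ones, so
sd_z is wider than a "stable physiology" spread — a conservative threshold.

Group trajectories average each patient's per-day mean score, then average
across patients within outcome group; the error bar is the SD across
patients divided by sqrt(patients contributing that day) — patients, not
observations, are the sampling unit. Each group's day axis is truncated at
the 75th percentile of its stays (times to event for the abnormal group),
beyond which too few patients remain for a stable mean.

## The synthetic cohort generator

No ward dataset ships with the package, so a generator reproduces the
structure the analysis assumes. Its defaults are the study conditions:
154 normal and 17 abnormal patients; admission-day marginals
RR 16.7 (2.5), HR 80.6 (12.8), SpO2 97.0 (1.3), SysBP 115.7 (16.0),
Temp 36.6 (0.5) relaxing exponentially to discharge marginals 15.7 (1.0),
81.2 (11.7), 96.3 (1.5), 132.1 (16.6), 36.4 (0.4); stays log-normal with
median 9 and IQR 5 days (quartiles near 7/12), discretized and clipped to
[4, 28]; abnormal times-to-event median 5, IQR 4 days; charting every 1–2 h
for the first 40 % of the stay and every 4 h after; 6/17 of abnormal events
are deaths. The recovery time constant is 1.5 days, chosen so trajectories
are visually and statistically stable after about day 4, matching the
clinical picture of a four-day acute recovery.

Two structural choices deserve explanation:

* **Variance decomposition.** The admission/discharge SDs above describe
  the spread of per-patient day averages, so most of the variance must be
  *between* patients. Each patient draws a stable offset per vital carrying
  a fraction ρ = 0.8 of the variance; the rest is independent Gaussian
  observation noise. Without this split, day-average distributions would be
  implausibly tight and every drift distance would saturate.
* **Deterioration episodes.** Abnormal patients receive one or two episode
  types from {tachycardia (HR → 150), bradycardia with hypertension
  (HR → 45, SysBP → 190), tachypnoea (RR → 40)}. Inside a 24 h window
  before the event the affected vitals ramp linearly toward the target,
  and the patient's baseline offset fades with the ramp — deterioration
  overrides individual baselines, so the observed vital actually reaches
  the episode extreme. The event time lands in the second half of the final
  stay day.

What the generator does **not** emulate: within-patient autocorrelation,
cross-vital correlation (a hook exists in the variance split but is off by
default), circadian rhythm, treatment effects, or informative missingness
(an optional uniform masking rate exists purely to exercise the
completeness filter). Consequently, passing tests demonstrate that the
pipeline recovers the structure it is pointed at — drift ordering,
recovery-then-plateau trajectories, pre-event score excursions — not that
it would achieve any particular sensitivity or false-alarm rate on real
ward data, where autocorrelated noise and correlated vitals would widen
the score distribution.

The detection property (abnormal patients crossing k before their event)
is checked at the generator's default scale with a fixed seed. The rate is
seed-sensitive: the event-day mean averages observations from the whole
ramp, including barely-deteriorated ones, so bradycardia episodes whose
event falls early in a charting day can stay just under threshold. This is
the expected behaviour of per-day averaging, not a tuning target.

## Numerical and testing choices

Degenerate inputs are errors with named causes: zero-variance vitals in
normalization, all-identical bandwidth training sets, empty samples in the
KS distance, all-zero pairwise distances in the Sammon stress. Empty days
return an absent value (`NULL`) from `daily_average()` so callers decide.
Duplicate charting timestamps are kept (both contribute to the daily
mean): repeated charting within the hour is legitimate nursing practice.

Test problem sizes are chosen to keep the full suite around a minute:
metric oracles run on 1,000 randomized small samples against brute-force
reimplementations; the KDE is validated against direct summation at
N ≤ 50, the closed-form single-kernel value (2π)^(−5/2), and a 10^6-sample
Monte-Carlo integral of a 2-D reduction (within 3 MC standard errors of
1); the bandwidth rule against an exhaustive all-pairs oracle at 200
points; the Sammon optimiser on 50 random starts (monotone stress traces)
plus planar-recovery, rigid-motion-invariance and a cross-check against an
independent implementation (`MASS::sammon`); end-to-end properties on the
default 171-patient cohort. All randomized tests fix their seeds.
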