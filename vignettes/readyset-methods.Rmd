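---
title: "Methods: simulating and analyzing movement-readiness potentials during visuomotor adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing movement-readiness potentials during visuomotor adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The design being modeled

`readyset` implements the analysis chain of a cognitive-motor integration
study: two groups of participants (a clinical anxiety group and controls)
perform center-out reaches on a tablet while a cursor is rotated 45 degrees
counter-clockwise, with endpoint-only feedback, and EEG is recorded to
extract movement-readiness potentials (MRPs) time-locked to movement onset.
The task schedule has four conditions — Baseline (100 trials, veridical
cursor), Adaptation (200 trials, rotated cursor), Retention (200 trials,
rotated mapping, feedback withheld) and Washout (100 trials, veridical) —
with eight radial targets at 8 cm visited once per cycle of eight trials.

Because the package must be exercisable without any recordings, it ships a
first-class synthetic-data module whose defaults *are* those study
conditions: 13 anxiety / 18 control participants, the 100/200/200/100
schedule, 45 degree rotation, 250 Hz sampling, and questionnaire score
distributions matching the study's descriptive table. Everything downstream
(kinematics, MRP extraction, workload scoring, mixed models) is written
against the generated data layout but applies unchanged to real data
arranged the same way (delimited trajectory tables; epochs as array + JSON
manifest or BrainVision triplets).

## Behavioral model

**Learner.** Trial-to-trial adaptation follows a single-rate state-space
model. The intended reach direction relative to the target is a scalar state
`x` with `x(t+1) = x(t) + B (r - x(t))` on feedback trials (`r` = rotation
magnitude, `B` = learning rate) and `x(t+1) = rho x(t)` on no-feedback
trials. A single-rate learner with `rho = 1` was chosen over a two-rate
model because the study it emulates shows flat retention — early and late
retention hand angles are statistically indistinguishable — which a single
retained state reproduces exactly; a two-rate extension would add parameters
the data cannot constrain. Explicit re-aiming strategies are not modeled
(the emulated study did not measure them). The default `B = 0.08` was fixed
once so that the early-to-late adaptation change of the simulated learning
curve (~34 degrees) has the magnitude reported for this kind of task; it is
a free parameter of the generator, as is the trial-level motor noise SD
(default 4 degrees) — neither is identified by any published quantity.

**Trajectories.** Each reach is a minimum-jerk radial path whose direction is
`target - intended + noise`: under a counter-clockwise (CCW) cursor
rotation, compensation means aiming clockwise of the target. Onset latency
is lognormal with additive stage/condition shifts (early trials slower by
0.073 s, Adaptation slower by 0.072 s — the condition structure the analysis
should detect); peak speed is normal (600 ± 100 mm/s, Retention slower by
~50 mm/s). A pre-movement hold at the start position deliberately produces
duplicated position frames, and the path overshoots the 8 cm ring by 10% so
endpoint measures must interpolate the ring crossing — both exercise the
cleaning cascade. Between-subject spread enters as additive participant
intercepts on latency, peak speed and reach direction, which is what gives
the mixed models a non-degenerate subject variance component.

**Angle conventions.** Angles use the math convention (0 degrees = +x, CCW
positive); times are in seconds relative to the go cue. Hand angle (theta)
is reported so that *compensation of a CCW rotation is positive*: for a
positive configured rotation, theta is the clockwise deviation of the hand
from the target, wrapped to (-180, 180] by circular subtraction, and full
compensation of a 45 degree rotation reads +45.

## Kinematic measures and cleaning

* **Response time**: time from the go cue to the first sample 10 mm
  (Euclidean) from the start. Never crossing the threshold flags the trial
  missing rather than erroring.
* **Sample cleaning**: consecutive duplicated positions are collapsed to
  their first frame; then samples whose successive-difference magnitude
  exceeds 10 x IQR of all successive-difference magnitudes are dropped.
  *Degenerate case*: if the IQR is zero (perfectly regular steps) nothing is
  removed — the rule targets outliers and a zero-spread distribution has
  none. A literal reading (threshold 10 x 0 = 0) would delete every sample.
* **Peak velocity**: max of `sqrt(vx^2 + vy^2)` from finite differences on
  the cleaned samples. Per participant, values above 2000 mm/s are removed
  first; then a *single-pass* 3-SD rule using the mean/SD of the
  absolute-cutoff survivors. The rule is read left-to-right and not
  iterated: iterating to convergence would remove different sets depending
  on starting point and is not what the cascade's wording implies. Whether
  the 3-SD statistics should be computed before or after the absolute cutoff
  is genuinely open; computing them after is documented here as the
  package's choice.
* **Movement onset** for the hand-angle computation is the earliest sample
  at which either coordinate deviates from the previous sample; the onset
  tolerance defaults to 0 mm (the literal definition) with 0.5 mm available
  as a noise-robust alternative. The endpoint defaults to the interpolated
  crossing of the 8 cm target ring (the task's "invisible boundary"), with
  the final sample as a fallback and as a selectable alternative.
* **Stages**: early = first 8 trials of a condition, late = last 8, by
  original trial index; removed trials are excluded from stage means but do
  not shift the windows. Conditions shorter than 16 trials trigger a warning
  and assign overlapping trials to "early".
* Washout trials are processed and labeled but excluded from the
  Group x Condition x Stage models, which use Adaptation and Retention only.

## EEG model and MRP extraction

**Template.** ROI channels carry a piecewise MRP waveform on the
-2000..+500 ms epoch axis: zero before -1500 ms; a linear ramp to the
readiness-potential amplitude `a_RP` over [-1500, -500) ms; a steeper ramp
to `a_NS` over [-500, -100) ms; a Gaussian excursion reaching `a_MP` at
0 ms within [-100, +100] ms; then relaxation to zero. Defaults
(`a_RP = -2`, `a_NS = -5`, `a_MP = -8` microvolts) follow the typical
negative-going MRP morphology. The anxiety group's attenuation is injected
as constant positive offsets *within the NS and MP analysis windows only*
(defaults 0.883 and 1.289 microvolts — the marginal group differences the
emulated study reports), with no RP offset, matching its null RP finding.
Because the offsets use exactly the window masks the extraction averages
over, the configured group differences survive the full pipeline without
discretization error — the zero-noise end-to-end identity the test suite
asserts. The participant-level amplitude intercept (default SD 1.1
microvolts, applied outside the baseline window so it survives baseline
correction) is sized so that a 13/18-participant cohort yields a
group-difference standard error near 0.4 microvolts, the uncertainty scale
of the contrasts this design emulates; it supplies the subject variance
component of the EEG mixed models. Noise is additive broadband white
(default 2 microvolts/sample)
plus 1/f noise synthesized by spectrally shaping white noise (default 5
microvolts/sample), on every channel; non-ROI channels are noise only. No
volume conduction or inter-channel covariance is modeled, so passing tests
demonstrate pipeline correctness, not realism of channel topographies.

**Windows and boundaries.** RP = mean amplitude over [-1500, -500) ms,
NS = [-500, -100) ms, MP = [-100, +100] ms, with 0 = movement onset. Shared
boundaries are closed-open toward the later window; only the MP upper edge
is inclusive. This ownership rule is declared once and tested once.

**Epoching and baseline.** Epochs span [-2000, +500] ms with baseline
correction over [-2000, -1500) ms. The study text describes 2000 ms epochs
with a 1500 ms pre-movement baseline *and* baseline correction "from
2000-1500 ms"; only a baseline window preceding -1500 ms reconciles the two
statements, and the target appears near -2000 ms, so the default baseline
is the pre-target segment. The full pre-movement mean remains selectable
via the `baseline` argument for users who read the description the other
way.

**Rejection.** Visual inspection and ICA-based artifact removal are out of
scope; the package substitutes threshold rejection (peak-to-peak > 150
microvolts or < 0.5 microvolts on any ROI channel) with per-trial reasons,
and accepts an externally supplied rejection mask for pipelines that run
their own decomposition. The generator plants rare large transients
(default 5% of trials) solely to exercise this bookkeeping. Rejection
accounting reports the cohort-mean rejected count and the retained
percentage as `100 (n - rejected)/n`.

**ROI.** Components are averaged over F3, Fz, FC1, C3, Cz. The acquisition
montage this emulates contains FC3 but not FC1 — an internal inconsistency
of the emulated acquisition description — so the ROI resolver maps FC1 to
FC3 through a configurable alias table with a loud warning rather than
failing; a missing channel with no alias is an error naming the label.

**Stage split.** Adaptation and Retention epochs are split at the median
original trial index into early/late halves (~100 trials each at full
scale; `ceiling(n/2)` on odd counts). Rejected trials occupy positions but
never enter means. Trial averaging precedes window averaging; for means the
order is immaterial, and trial-average-first is the documented choice.

## Workload scoring

Raw (unweighted) NASA-TLX is used: the emulated protocol collected no
pairwise-comparison weights, so the Hart & Staveland procedure is honored
via the raw-TLX variant. The six 21-point (0-20) dimension scores are
mapped linearly to 0-100 (0, 5, ..., 100); the overall score is their
unweighted mean, the task-related subscale averages Mental/Physical/
Temporal, and the behavior-related subscale averages Performance/Effort;
Frustration enters neither subscale. Whether the original scores were kept
on 0-20 or rescaled affects only the absolute scale, not any contrast; the
0-100 mapping is standard raw-TLX practice. The generator draws dimensions
as independent truncated rounded normals with a participant-level intercept
and injects only an Adaptation elevation (default +2.25 scale points =
+11.25 overall points), matching the null group findings.

## Statistical layer

* Demographics: pooled-variance independent-samples t tests with Cohen's d
  on the pooled SD, computable directly from printed group summaries.
* All study models are linear mixed models fit by **REML** (conventional for
  mixed designs) with **sum-to-zero contrasts**, so main effects are
  marginal ANOVA-style effects, and a **random intercept per participant**;
  random slopes are deliberately excluded. Behavioral and MRP models are
  Group x Condition x Stage on the early/late cell means (Adaptation and
  Retention); workload models are Group x Condition over Baseline/
  Adaptation/Retention.
* Degrees of freedom use the **Satterthwaite** approximation. On balanced
  data with intercept-only random effects these reproduce the classical
  between/within df — 29 between-subject and 87 within df for 31
  participants x 4 cells, 58 within df for the three-condition workload
  models — which is the structural pattern the tests assert. A singular fit
  (zero subject variance) is retained with a warning; an outright failure
  falls back to ordinary least squares, also with a warning.
* Pairwise comparisons use **estimated marginal means** with equal cell
  weights and **Sidak** adjustment, `p_adj = 1 - (1 - p)^m`, with the
  family defined as all pairwise comparisons of the tested term within one
  model (not across models); confidence intervals use the matching
  per-comparison level `conf^(1/m)`.
* The mixed-model **Cohen's d** standardizes a marginal difference by the
  total model SD (square root of the summed variance components). No
  standardizer is defined for the study this emulates, several conventions
  exist, and they can differ substantially — so reported d values from the
  literature are not comparison targets for this package, and every d it
  prints is labeled as total-SD standardized.

## Numerical choices and degenerate inputs

* Angle wrapping maps to (-180, 180]; the -180/+180 tie belongs to +180.
* Zero pooled variance: t = 0 when means agree, a flagged error otherwise.
* All-trials-rejected participants are flagged and their component means
  set missing; the pipeline continues.
* 1/f noise is generated at a 5-smooth FFT length and truncated, with an
  analytic amplitude normalization, so its per-sample SD is the configured
  value in expectation.
* Every stochastic step draws from one RNG stream seeded from the config,
  making cohorts byte-reproducible; run manifests record seeds and file
  digests.

## Problem sizes used by the shipped checks

The test suite and the acceptance script size their simulations to make
each check sharp but cheap, and these sizes are package choices documented
here: zero-noise identity checks run 31 participants with a
16/32/32/16-trial schedule (exactness does not depend on trial counts);
parameter-recovery and null-calibration runs use 200 replicate cohorts of 8
participants per group, 32 trials per condition, on the five-channel ROI
montage; oracle-equivalence suites use >= 1000 random small instances;
behavioral/workload contrasts are recomputed on one full 31-participant,
600-trial cohort. The full-scale default config (10-channel montage, 200
epochs per condition) runs the same code paths and is used in the worked
example.

## Known limitations

* The EEG generator is a template-plus-noise model: no volume conduction,
  no channel covariance beyond the ROI/non-ROI split, no ocular/EMG
  physiology behind the planted transients, and no ICA stage — so
  agreement on synthetic cohorts validates the measurement pipeline and the
  statistics, not preprocessing choices on real recordings.
* The learner omits explicit strategy; with endpoint-only feedback a real
  cohort may rely on explicit re-aiming that a single implicit state does
  not capture.
* The "too slow" redo loop of the task is reduced to a timeout flag;
  flagged trials are not re-run.
* Satterthwaite df on severely unbalanced or variance-degenerate data are
  approximations; the structural df identities asserted in tests hold on
  balanced designs.
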