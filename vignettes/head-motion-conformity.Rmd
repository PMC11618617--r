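---
title: "Head-motion conformity in passive VR driving: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Head-motion conformity in passive VR driving: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headconform)
library(dplyr)
```

## The problem

When people watch a pre-recorded driving lap through a VR headset — no
steering wheel, no motion platform — they nonetheless move their heads in a
stereotyped way: small yaw turns into upcoming corners, beginning a fraction
of a second before the vehicle itself turns. `headconform` packages the
analysis chain for such studies: it quantifies how much each observer's head
motion *conforms* to the group's normative motion pattern, whether that head
motion *anticipates* the vehicle, and how conformity relates to the
self-reported experiences the field cares about — vection (illusory
self-motion), visually induced motion sickness, and presence — measured on
1–20 single-item scales after each 60-s lap.

Because raw participant data from such studies is typically not deposited,
the package pairs every analysis stage with a seeded synthetic-cohort
generator whose ground truth is known. Every statistic the package reports
can therefore be validated by parameter recovery, and the test suite does
exactly that.

## The conformity statistic

For participant $i$, axis $a \in \{\text{pitch}, \text{yaw}, \text{roll}\}$
and speed condition $s$, let $x^{(i)}_{a,s}(t)$ be the centred angular
deviation sampled on the uniform lap grid (5400 points for 60 s at 90 Hz).
The normative reference for participant $i$ is the pointwise
**leave-one-out median**

$$m^{(-i)}_{a,s}(t) = \operatorname{median}_{j \ne i}\; x^{(j)}_{a,s}(t),$$

and the conformity score is the Pearson correlation
$r_{i,a,s} = \operatorname{cor}\big(x^{(i)}_{a,s}, m^{(-i)}_{a,s}\big)$
over all grid points. The median (not the mean) keeps a single outlying
head from contaminating everyone's reference; with an even count the two
central values are averaged. Excluding the scored participant means a
participant is never rewarded for resembling themselves. Cohort-level
summaries are the per-axis, per-speed mean and SD of the scores plus a
two-tailed one-sample t-test against zero.

Three numerical details matter:

* **Degenerate traces.** A motionless participant has zero variance and no
  defined correlation. Such scores are flagged and excluded from summaries
  with a logged count, rather than scored 0 — a zero would assert
  "uncorrelated" without evidence.
* **Location/scale invariance.** Pearson correlation is invariant to adding
  a constant or positive scaling of either series, so centring conventions
  cannot change a score; this is tested directly.
* **Multiple laps per cell.** If a design yields several laps per
  participant and condition, per-lap scores are averaged on the Fisher-z
  scale and back-transformed.

The cohort implementation sorts each time point's cross-participant values
once; removing the rank-$k$ element from a sorted row shifts the remaining
order statistics by at most one index, so all $N$ leave-one-out medians
come from a single global sort. The test suite verifies this fast path
against a naive per-participant sort-and-pick oracle to $10^{-9}$.

## Velocity and lag

Mean absolute angular velocity per axis is
$M = \frac{1}{T-1}\sum_t |x(t+1) - x(t)| \cdot f_s$ in deg/s, computed from
first differences with **no smoothing** — a smoother would bias $M$
downward, and the velocity definition names no filter. Yaw-versus-pitch and
yaw-versus-roll comparisons are paired t-tests per speed condition, with
zero-variance differences flagged degenerate rather than reported as
infinite t.

The anticipatory-lag analysis finds the signed delay $\delta$ maximising
$\operatorname{cor}\big(\text{head}(t), \text{vehicle}(t - \delta)\big)$
over a grid of lags (default ±2000 ms at one-sample, ≈11.1 ms, resolution).
Negative $\delta$ means the head *leads* the vehicle. Correlations use the
overlapping region of the shifted series (truncation, not padding, which
would bias r toward zero asymmetrically), and ties break toward the
smallest $|\delta|$ — conservative against over-claiming anticipation. The
per-participant mode is the default; cohort summaries report the median and
IQR of individual lags.

## Preprocessing

Raw logs arrive as per-trial CSVs (timestamp plus pitch/yaw/roll in
degrees; dialects map foreign column names and radian units). Preprocessing
is deliberately minimal and ordered:

1. **Unwrap**: successive differences are mapped into (−180, 180], so a
   359→1 degree crossing reads as +2 degrees. If genuine cumulative
   rotation exceeds half a turn, continuity wins over range.
2. **Centre**: each channel is shifted so the first sample — the
   forward-facing orientation at lap start — is zero.
3. **Resample**: linear interpolation onto the uniform grid of
   `round(rate × duration)` points. Timestamp gaps up to 100 ms (9 frames
   at 90 Hz) are interpolated; anything longer flags the trial as excluded
   from head-motion analysis, because bridging a longer gap could fabricate
   a head turn. Traces covering less than 95 % of the lap are rejected
   outright.

Nothing is imputed at read time, and validation never coerces: malformed
files raise typed errors naming the offending row and column.

## The factorial designs and self-report statistics

Both study designs are encoded: experiment 1 crosses posture
(upright/reclined) × world alignment (aligned/misaligned) × speed
(slow/fast) in 12 trials over two main blocks of two sub-blocks, and
experiment 2 crosses driving direction (forward/reverse/lateral) × speed in
9 trials over three blocks. Every (sub-)block opens with a stationary
baseline trial. The counterbalancing enumerations are 16 orders for
experiment 1 (four independent binary choices: posture-block order, the
alignment order inside each main block, and the participant's fixed speed
order — the only four binary choices the block structure admits) and
3! × 2 = 12 for experiment 2.

Self-report ANOVAs are within-subject factorials computed through R's
`aov()` error strata; partial eta squared is
$\eta^2_p = SS_\text{effect} / (SS_\text{effect} + SS_\text{error})$ with
each within effect tested against its effect-by-participant stratum. No
sphericity correction is applied by default (Greenhouse–Geisser is
available behind a flag) and p-values are reported raw, matching the
reporting conventions of the field; stationary baselines are excluded from
condition ANOVAs. The test suite checks every F and $\eta^2_p$ against an
independent inclusion–exclusion cell-means decomposition on randomly
generated balanced designs.

Associations between conformity and ratings are Pearson correlations across
participants, one row per measure × axis × speed (18 rows), using ratings
from the upright, world-aligned, forward-facing lap of the matching speed —
the condition common to both designs, which is also what justifies pooling
the two cohorts (52 + 36 = 88) for head-motion analysis.

## The synthetic cohort: what it emulates

`generate_cohort()` produces a complete study — schedules, vehicle traces,
head traces, ratings — as a pure function of a configuration and a seed.
Per-participant substreams are derived from the master seed by a counter
scheme, so enlarging a cohort never perturbs earlier participants.

**Track.** The lap is `n_turns = 12` alternating raised-cosine yaw lobes
(amplitude 30° ± 30 % jitter, fixed by a track seed so every participant
sees the same lap), each 2.2 s long with straight segments between — the
corner cadence of a fast one-minute segment of a long, twisty circuit.
Raised cosines have zero value *and* zero slope at their ends, so the
velocity profile is continuous and the velocity summary well defined. The
slow lap is the fast lap replayed at half speed:
$\text{slow}(t) = \text{fast}(t/2)$, covering half the distance in the same
60 s.

**Head model.** Per participant,
$\text{yaw}(t) = g \cdot \text{vehicle}(t + \lambda) + \text{tremor}(t) +
\text{drift}(t)$, with gain $g \sim N(0.12, 0.04)$ (head turns of roughly
2.4–4.8°), anticipatory lead $\lambda \sim N(750, 100)$ ms, white
sample-level tracker tremor (SD 0.016°), and a smooth postural wander:
integrated AR(1) velocity with a 0.15-s correlation time, scaled to a 6.3°
position SD at lap end. The split matters: a head that drifts several
degrees per minute while adding only ~1 deg/s of mean absolute velocity
must have noise that is *smooth at the sample scale* — a single
AR(1)-position noise cannot be both mobile enough to keep conformity near
0.45 and slow enough to keep velocity near 2 deg/s at 90 Hz. Pitch and roll
are attenuated copies of the yaw signal (gains 0.35 and 0.22) with their
own smaller noise, reproducing the yaw-dominant axis ordering.

These defaults were calibrated once against the descriptive ranges the
study design implies — yaw excursions of a few degrees, yaw mean |velocity|
near 2.2/2.7 deg/s (slow/fast), yaw conformity means near 0.45 with SD near
0.27, pitch and roll lower on both measures — and then frozen; they are
deliberately not tuned per analysis.

**Ratings.** Each measure (vection magnitude, sickness, presence) is an
integer 1–20 from a rounded, clamped Gaussian latent: intercept + condition
effects + participant effects + conformity coupling + residual (SD 2).
Planted condition effects reproduce the qualitative structure: fast laps
raise vection (+1.5), sickness (+0.8) and presence (+1.2); reduced visual
cue availability lowers vection (−0.8); reverse and lateral driving lower
vection (−1.2 / −2.4); stationary baselines sit near the scale floor.
Vection and presence share a participant-level "responsiveness" component
(SD 2), which is what makes their participant-mean correlation strongly
positive while sickness, with an independent participant effect, stays
uncoupled. The conformity coupling adds $\beta z_i$ rating points, where
$z_i$ is the participant's yaw conformity standardised within speed;
$\beta$ defaults (1.45 / 0.75 / 1.1 for vection / sickness / presence) were
chosen so the population-level correlation between analysis-side yaw
conformity and vection is ≈ 0.3 at n = 88, with sickness and presence
couplings of matching relative size. Vection onset and duration are drawn
only when magnitude ≥ 2 (a magnitude of 1 means no vection), with onset +
duration never exceeding the lap.

**What the generator does not emulate.** Ratings are conditionally Gaussian
latents, not a cognitive model; the posture × alignment mechanism is only an
effect coefficient; head kinematics are condition-independent apart from
speed (one trace per participant and speed, standing for the upright,
aligned, forward lap the pooled analysis uses); there is no eye tracking,
no biomechanics, no vestibular dynamics. Passing recovery tests on this
generator shows the *analysis chain* is correct and well calibrated — it
does not validate the generator against real heads.

## Design choices in genuinely open territory

* **Even-count medians** use the mean of the central pair (the common
  convention).
* **One- vs two-tailed**: all one-sample and association tests are
  two-tailed.
* **Participants reporting no vection** are not excluded from head-motion
  analysis.
* **Lag tie-breaks** go to the smallest absolute lag; **lag mode** is
  per-participant, with pooled estimation available by passing a median
  trace.
* **The vehicle signal** for lag analysis is vehicle yaw/heading; the
  interface accepts any single channel, since recorders differ in what they
  export.
* **Order components for experiment 1**: the 16 counterbalancing levels are
  decomposed as the four binary choices described above; the block
  structure admits no other reading with exactly 16 levels.
* **Cohorts not divisible by the order count** (e.g. 52 over 16 orders) are
  assigned round-robin, as evenly as possible, with a warning.

## Problem sizes used by the test suite

The unit and property suites run the full analysis logic at reduced problem
sizes chosen once: oracle-equivalence checks use up to 10 participants ×
300 points (100 random instances per operation, tolerance $10^{-9}$);
Monte-Carlo recovery suites use 60-s laps at 10–30 Hz, which preserves
every statistic's structure (conformity and association values are grid-
rate-invariant in expectation) while keeping each suite in the minutes
range. The acceptance script runs the full 90 Hz × 60 s × 88-participant
configuration. Lag-recovery checks run at the native 90 Hz because their
tolerance is expressed in grid steps.

## Known limitations

Conformity is zero-lag by design (no dynamic time warping), matching the
definition it implements; strongly heterogeneous per-participant lags would
depress conformity rather than realign it. The ANOVA layer expects balanced
complete within-subject data and refuses anything else, naming the first
offending cell. Ratings are treated as interval-scaled by the ANOVA, as is
conventional for these scales; ordinal mixed models are out of scope.
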