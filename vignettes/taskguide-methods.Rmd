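---
title: "Guidance, scoring and simulation methods in taskguide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guidance, scoring and simulation methods in taskguide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taskguide)
```

`taskguide` models a camera-based cognitive prosthesis for activities of
daily living: an object detector and a hand tracker observe the scene, a
state machine decides which step of a multi-step task the user is on, and
the system intervenes with instructions, feedback and escalating cues.
This vignette explains the model behind each component, the parameters
that matter, and the design decisions taken where the underlying system
description left the behaviour open.

## The task model

A *task module* is a declarative YAML document: an ordered list of steps,
each with a completion condition, optional error conditions (each carrying
a corrective instruction), a per-step time limit, and a cue schedule.
Conditions are conjunctions over the detector's class vocabulary —
classes that must be present, classes that must be absent, spatial
predicates between detected objects (`contains`, `overlaps`, `above`, all
in normalised image coordinates with y pointing down), and a *dwell
requirement*: the number of consecutive smoothed frames the condition must
hold before it counts.

Scene states are encoded as distinct classes (`pot_empty`,
`pot_with_water`, `cooker_on`, …) rather than attributes, which is how a
single-stage object detector naturally represents state: recognising the
state of a step reduces to class-set membership. The shipped egg-boiling
module has six steps — place the pot on the cooker, fetch the pitcher,
pour water, place the egg, close the lid, press the cook switch — and a
20-class vocabulary. The six steps themselves are this package's own
concrete instantiation of a six-step boiling task; the engine is
step-set agnostic and any module that validates will run.

### EFPT components

The modified Executive Function Performance Test has a 0–25 range with a
0–5 cue scale per scored item, which forces five scored components over a
six-step task. Components are therefore configurable groupings of steps;
the default groups the two water-and-egg steps (`pour_water`,
`place_egg`) into one `fill_pot` component. This is a declared convention,
not a reconstruction of how a human assessor would group them; any
disjoint grouping validates.

## Detection smoothing

Raw per-frame detections flicker. Before any state decision the engine
smooths each class's per-frame presence with a trailing rolling average
over `smoothing_window` frames (default 5). The per-frame presence value
is the maximum confidence among that class's detections in the frame (0
if absent); a binary 0/1 mode is available via
`engine_params(smoothing_mode = "binary")`. Maximum-over-duplicates makes
the signal robust to multiple boxes of one class in a frame; ties for
spatial predicates resolve deterministically (highest confidence, then
smaller x, then smaller y).

Warm-up frames average over the frames available so far rather than being
withheld — a live guidance loop must be able to react from the first
frame. Presence decisions use an inclusive threshold of 0.5: the midpoint
of the score range, chosen so that three positive binary frames in a
five-frame window count as present. Spatial predicates cannot be averaged,
so they are evaluated on the highest-confidence detections in the most
recent frame within the smoothing window where both endpoints were seen;
the dwell requirement then supplies the stability that smoothing supplies
for presence.

The nominal camera sampling interval is carried in the module
(`frame_period_ms`, default 5 ms as in the deployed system) but is
informational: the engine is entirely driven by the timestamps in the
stream. A 5 ms interval implies a 200 Hz loop, which is unusually fast
for a webcam pipeline; treating the period as data sidesteps the
question.

## The guidance state machine

`run_session()` walks the steps strictly in order. Within each frame the
engine processes, in this order: stall/cue escalation, error conditions,
completion. The ordering encodes two decisions. First, cue escalation is
purely time-based (elapsed time since the step's instruction), so it must
not depend on what else happens in the frame. Second, when an error
condition and the completion condition stabilise on the same smoothed
state, *the error wins* — conservative guidance never congratulates a
user mid-mistake.

Error episodes are edge-triggered: when an error condition has held for
its dwell frames, one `error_detected` event is logged (plus a
`corrective_shown` in assisted mode), the completion dwell counter is
reset, and the episode must clear before it can fire again. Requiring the
completion condition afresh after the error clears implements
"repeat the step correctly before proceeding" with the least additional
machinery.

Cue levels follow the five-level assistance hierarchy (verbal, gestural,
direct verbal, physical, performed-by-assessor) with default stall
timeouts of 15/30/45/60/75 s, configurable per step. Whether a deployed
system would force-advance after sustained failure is an open question;
here level 5 marks the step `performed_by_assessor` and force-advances,
because the session must terminate and the scoring rules already assign
such steps zero credit.

Unassisted sessions run the identical recognition path but emit no
feedback, corrective or cue events. The same stall milestones are tracked
silently in `max_cue_level`, which is what makes the modified EFPT
scorable for unassisted runs — mirroring a paired with/without-device
design where an assessor would have cued at those moments. Errors and all
timings are logged in both modes, so assisted and unassisted replays of
the same stream agree exactly on condition-satisfaction times (a property
the test suite asserts).

Timing semantics: initiation time is the delay from a step's instruction
to the first frame with a hand present; if no hand is ever seen it is
reported as missing, never as zero. Total completion time spans the first
instruction to session end and is `NA` for unfinished sessions — a
truncated stream marks remaining steps incomplete rather than erroring.

## Scoring instruments

**Daily task completion** scores each step 2 (completed, no errors,
within its time limit), 1 (completed but with at least one corrective
episode or over the limit), or 0 (not completed, or assistance reached
the assessor-performs level), summing to 0–12 for six steps. "Partially
incorrect" is not further specified by the instrument, so it is
operationalised as completed-with-error-or-overtime — the only signals
the engine records that speak to accuracy and completion time. The time
criterion is per-step; an absolute whole-task limit would double-penalise
slow early steps.

**Modified EFPT** scores each component as the maximum cue level over its
member steps, summing to 0–25; higher is worse. This is monotone by
construction: adding a cue can never lower the total.

**SUS** uses the standard transformation (odd items positively worded)
and the standard interpretation bands: below 50 significant usability issues, 50 to
below 68 marginal, 68 to 80 acceptable, above 80 excellent. The
band description is ambiguous at exactly 80 ("68 to 80" vs
"above 80"); 80 is placed inclusively in *acceptable*, so scores
strictly above 80 are *excellent* — which is also the band the stated
rule assigns to the overall score of 80.53 reported for this class of
device, even though prose summaries sometimes call such scores merely
acceptable.

## The synthetic-participant simulator

The simulator exists so the entire pipeline runs with no camera, model or
download. It is a semi-Markov behaviour script per step — hesitate, then
act or err, then correct — rather than a physics simulation: the engine
consumes only detection states, so this is the minimal sufficient
structure.

Per step the virtual participant draws a log-normal hesitation (capped at
120 s to keep sessions finite), enters the step's error state with a
Bernoulli probability, and recovers at periodic opportunities — with
probability `cue_responsiveness[1]` per interval under guidance (the
corrective instruction is doing the work) or a lower fixed probability
(default 0.3) unguided, reflecting that unguided participants do finish
tasks, only more slowly. Stalled participants respond to each cue level
with the profile's responsiveness for that level; guidance also scales
hesitation by `assisted_hesitation_factor`, the mechanism by which
explicit instructions relieve planning load. The scene evolves by
applying each step's completion condition to a cumulative scene state
(add required classes, remove forbidden ones, place subjects to satisfy
spatial predicates), so the generator works for any valid module, not
just the shipped one.

Default profiles: the patient-like profile (median 10 s hesitation,
error probability 0.35, action 5 s, assisted factor 0.6) and control-like
profile (2 s, 0.05, 3 s, 1.05) were chosen once so that simulated
sessions land in the magnitude range a mild-dementia feasibility cohort
reports — unassisted patients around two minutes with a clear assisted
speed-up, controls around half a minute with no benefit. They are
plausibility settings, not estimates of any real cohort, and the
reporting tests assert directions and orderings, not clinical point
values.

Detection noise is applied per frame: true classes dropped with a
false-negative rate, spurious vocabulary classes added with a
false-positive rate, Gaussian jitter on confidences (base 0.9) and box
coordinates. Defaults (FN 0.05, FP 0.01, jitters 0.05/0.01) produce
cumulative precision/recall in the mid-0.9s — the regime a well-trained
single-stage detector reports — while leaving the 5-frame rolling average
with real work to do.

Reproducibility: each session runs one generator seeded by a
deterministic hash of (experiment seed, participant id, condition), so
paired sessions share participant-level draws (hesitation frailty,
error-propensity shift, sex) while condition-dependent draws differ, and
identical seeds give byte-identical streams. The simulator restores the
caller's RNG state on exit. The default simulated frame period is 100 ms
— a minutes-scale session is then ~10^3 frames, convenient for
interactive work and testing — while the engine accepts any period the
stream carries.

What the simulator does **not** emulate: pixel appearance, correlated
detector failures (occlusion, lighting), label confusion between visually
similar classes, drifting bounding boxes during motion, or mid-action
hand withdrawal. Passing tests therefore demonstrate the correctness of
the guidance, scoring and evaluation logic under the stated noise model,
not the field performance of any detector.

## Detection evaluation

`evaluate_detections()` works at frame level on class-set membership
(whether precision/recall of such systems is reported frame-level or
event-level is usually unstated; frame-level is implemented and
declared). Frames are grouped by the step active at their timestamp per
the ground-truth log; within a step, precision and recall are
micro-averaged over frames. The *cumulative* summary is the mean and SD
of per-step values across steps — population SD by default (the summary
describes exactly these steps), sample SD by flag. Steps with undefined
metrics (zero denominators) are excluded from the cumulative summary
with a warning rather than silently treated as zero. Box-level matching
(IoU thresholds, mAP) is deliberately out of scope: the guidance engine
consumes class sets, so class-set metrics are the ones that predict its
behaviour.

## Group reporting

`summarize_cohort()` reports median (Q1–Q3) with linear-interpolation
quantiles, Mann-Whitney rank-sum tests between groups, Wilcoxon
signed-rank tests within group across conditions (exact null for n ≤ 25
without ties, normal approximation otherwise — appropriate for
feasibility-scale samples), and Fisher's exact test for binary
covariates; all two-sided. A paired test with no non-tied pairs is
reported as not computable rather than erroring. Published tables of
this kind sometimes print IQR endpoints that coincide with the median in
ways no standard quantile definition reproduces; this package makes no
attempt to guess such conventions and reports standard Q1/Q3.
`percent_change(before, after)` is `100(before − after)/before` to one
decimal — positive for improvements in quantities where lower is better.

## Numerical and testing notes

Problem sizes in the shipped suites were chosen for breadth per unit
time: the state machine is checked against an independent quadratic-time
replay interpreter on 200 random module/stream pairs (up to 500 frames),
smoothing against a brute-force sliding mean on 1000 random streams,
rank-sum statistics against exhaustive enumeration of the null for group
sizes up to 8, and the stochastic monotonicity suites (error-rate trend,
false-negative invariance, cue monotonicity) on seed grids of 25–30
replicates. All random tests fix their seeds; every assertion of a
specific number was computed first by an oracle independent of the code
under test.
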