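---
title: "Methods: simulating the MOA task battery and analysing its scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating the MOA task battery and analysing its scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moabattery)
```

## What this package models

The Multiple Object Avoidance (MOA) task is an interactive measure of
visuomotor attention: a mouse-controlled blue disc must avoid an
accumulating set of red hazard discs that bounce around an 800 × 800 px
window. Because all hazard motion is piecewise linear, the task is fully
predictable in principle, and skill amounts to anticipating object motion
and steering away in time. Performance is the survival time in seconds,
averaged over the recorded trials of a session. The battery's companion
measures are a Multiple Object Tracking (MOT) task — covert tracking of
five flash-designated squares among ten, scored by selection accuracy —
and a Digit Symbol Substitution Test (DSST) measuring processing speed as
the number of symbols correctly transcribed in 60 s.

`moabattery` reimplements all three tasks as deterministic, headless
simulations driven by parametric synthetic agents, plus the statistical
toolkit used to analyse such scores. Nothing here requires a display or a
human: sessions are pure functions of a seed.

## The MOA engine

**Geometry and integration.** Coordinates are continuous floats at disc
centers, origin at the top-left, x rightwards, y downwards; the window is
the half-open box [0, W) × [0, H). Motion is integrated by explicit
fixed-timestep Euler at the display refresh (tick = 1/85 s). Between
contacts motion is linear, so Euler is exact between events; the only
approximation is that contacts are detected on the tick grid. A
tunnelling guard sub-steps the physics whenever a hazard could move more
than half a radius per tick; at the default maximum speed (680 px/s, 8 px
per tick, radius 20 px) it never triggers.

**Collision model.** Wall contacts mirror the velocity component normal
to the violated edge and reflect the center back inside. Hazard–hazard
contacts specularly reflect *each* disc's velocity about the
center-to-center normal, preserving each disc's own speed exactly, and
separate the pair to exact tangency. We chose per-disc specular
reflection over equal-mass elastic exchange deliberately: the original
task randomizes a speed *per circle* and treats it as that circle's
property for the trial, which only the specular model preserves (elastic
exchange would swap normal speed components between partners). Both
models are "consistent with 2D vector physics"; the choice is a modelling
decision, recorded here. Tangency (distance exactly equal to the radius
sum) is deliberately *not* a collision — the predicate is a strict
inequality, a measure-zero, deterministic tie-break.

**Trial state machine.** A trial starts with the user disc at the window
center and three hazards placed uniformly at random, mutually
non-overlapping and not overlapping the user, each with a uniform
direction and a speed drawn uniformly from [0, 680] px/s. All hazards
(initial and spawned) are unfilled — visible but non-lethal — for a 1-s
grace period; they move and bounce normally throughout, only the
user-collision is disabled. A new hazard spawns at every multiple of
10 s of the trial clock (the clock starts at 0 and also drives scoring),
placed uniformly anywhere not overlapping an existing disc; no minimum
spawn distance from the user is enforced — the grace second is what
prevents unfair instant deaths. The first overlap between a *filled*
hazard and the user terminates the trial with the clock as the survival
time. A session is 2 practice + 8 recorded trials; the score is the mean
recorded survival time.

**Censoring.** The original task has no duration cap (observed human
scores top out near a minute), but degenerate configurations (e.g.
all-stationary hazards) would never terminate, so trials are censored at
`max_trial_duration` (default 300 s) and flagged as such in the record.

**Pointer semantics.** The user disc center teleports to the clamped
pointer sample each tick, with no engine-side speed limit — a real mouse
imposes none. Speed caps, latency and noise belong to the *agent*, not
the engine.

## Synthetic controllers

Three controllers stand in for participants:

* `stationary` parks at the starting position — the skill floor.
* `random_walk` moves at the capped pointer speed in a uniformly random
  direction each tick.
* `greedy_avoid` computes, for every live threat, the time-to-collision
  (TTC) from relative position and velocity — the projection of relative
  velocity onto the center line; receding hazards have infinite TTC —
  and steps directly away from the most imminent threat. It is the
  canonical "skilled" agent because the task's motion is fully
  predictable; richer planners (e.g. potential fields over all hazards)
  can be added behind the same interface.

Human-like imperfection enters through three parameters: *reaction
latency* (the agent perceives the world as it was `latency` seconds ago,
rounded to whole ticks; unfilled hazards that will activate within the
latency window are already treated as threats, since they will be live
by the time the action lands), a *pointer speed cap* (px/s), and *motor
noise* (isotropic Gaussian jitter per proposed displacement, px). With
defaults, mean survival orders as greedy > stationary and degrades with
latency, and survival falls as the hazard speed cap rises — the suite
asserts both orderings over 200 seeds.

## The MOT engine and the capacity-k observer

Ten 30-px squares are placed uniformly in a 1014 × 758 px window
(overlap permitted), five are designated targets, and each square gets a
heading from the published 12-direction set and a speed from
{60, 134, 180} px/s. Squares never inter-collide; they reflect off the
window edges by axis-aligned mirroring. The direction set constrains the
*initial* assignment only — it is not closed under mirroring, so
reflected headings may leave the set mid-trial. Flash (2.5 s) and
movement (8 s) durations are not published; both are exposed as config
defaults and do not affect headless scoring. Because squares are
independent and motion is piecewise linear, the movement phase has an
exact closed-form solution (a triangle-wave fold of the unfolded
trajectory); sessions use it, the tick-wise `mot_step()` implements the
stepping contract, and a property test pins the two against each other.

The synthetic observer tracks `k` targets perfectly and fills its
five-item selection uniformly from the squares it was not tracking. Its
expected number of correct selections is `k + (5 − k)² / (10 − k)`
(hypergeometric fill), verified in the suite both by exhaustive
enumeration of fill subsets and by Monte-Carlo at 2,000 trials per `k`.
Per-trial accuracy is always a multiple of 1/5, matching the published
scoring granularity.

## The DSST

Forms are 93 prompt digits (the published maximum) drawn uniformly from
1–9 with no two consecutive prompts equal — the standard form-building
convention; the published form's exact prompt order is unpublished — plus
a random bijective key from digits to nine abstract symbol ids. Symbols
are opaque integers: the published glyphs are copyrighted and scoring is
glyph-independent. The simulated responder works at `rate` symbols/s for
60 s, erring with probability `error_prob` per symbol, so its expected
score is `min(floor(rate·60), 93)·(1 − error_prob)`.

## Synthetic cohorts

`simulate_cohort()` emulates a two-group individual-differences design:
each synthetic participant draws latent skills (controller latency and
pointer speed, tracking capacity, DSST rate, plus an age covariate) from
their group's normal distributions, then *runs the full battery* — scores
are always produced by the engines, never sampled directly. The default
design mirrors the published two-group comparison in size (21 vs 26) and
direction (group A advantaged), with parameter values chosen once as
plausible for young adults: latency ≈ 0.22–0.30 s (simple visuomotor
reaction times), pointer speed 600 px/s, capacity ≈ 2.5–3.5 targets
(typical tracking capacity), DSST rate ≈ 0.74–0.84 symbols/s (giving
scores near the published mean of ~47). For parameter-recovery
experiments the manipulated parameter is set as a point mass (e.g.
capacity 4 vs 2, latency 0 vs 0.5 s) with all other distributions
identical, so the designed contrast is the only group difference.

**What a green test does and does not establish.** The generator
reproduces the tasks' published mechanics and gives agents designed,
recoverable skill differences. It does not model fatigue, learning
across trials, strategy shifts, eye movements, or the heavy-tailed
trial-to-trial variability of humans; session scores are roughly normal
within agent, unlike some human score distributions. Green acceptance
tests therefore certify the *machinery* — engines, agents, statistics —
not any claim about human populations.

## Psychometrics

The analysis toolkit mirrors what is conventionally reported for such
batteries: Pearson correlations with t-based two-sided p-values; paired
t tests (identical vectors give t = 0; constant nonzero differences are
rejected as degenerate rather than dividing by zero); one-way ANOVA
(all-equal data give F = 0); hierarchical OLS in two predictor blocks
with raw slopes, standardized β (z-scoring both sides), adjusted R², and
the nested-model F-change
`((RSS₁ − RSS₂)/df_num) / (RSS₂/(n − p₂ − 1))`; a Pillai-trace
multivariate group test with an optional covariate partialled out
(covariate entered as a regressor, hypothesis matrix taken from the
group term, approximate F by the standard transformation); and a
test–retest report bundling descriptives, paired t and Pearson r.

Numerical choices: proportions are transformed by the *empirical* logit
`ln((p + ε)/(1 − p + ε))` with `ε = 1/(2·n_units)` and
`n_units = trials × targets = 150` at MOT defaults, so boundary scores
of 0 and 1 stay finite — the published analyses say only that a logit
was used; this is the standard boundary-safe variant. Driving-experience
style covariates use the natural log (the base only rescales slopes).
All p-values are two-sided. OLS is fit by `lm()`; the suite checks it to
1e-8 against an independent normal-equations oracle, checks F-change
against its R² identity, and null-calibrates the nested F, the ANOVA and
the Pillai test by Kolmogorov–Smirnov uniformity of p-values over 500
null replicates.

## Determinism and seeding

Every source of randomness flows from explicit integer seeds. A session
expands its `master_seed` into per-trial seeds through a counter-based
Lehmer-style hash (`derive_seed(master, stream, index)`), so any single
trial can be reproduced without replaying the session, and different
tasks use disjoint stream ids. The MOA inner loop is compiled (Rcpp) for
cohort-scale runs; it consumes R's own RNG in exactly the draw order of
the pure-R reference loop, and the suite asserts bit-identical trial
records between the two paths across controllers and seeds. Session logs
embed a config hash and default to a fixed header timestamp so identical
runs serialize byte-identically.

## Known limitations

* Contact detection is tick-quantized: survival times are exact only to
  one tick (1/85 s), which is also the stated tolerance of the
  closed-form acceptance check.
* Whether the original implementation exchanged or reflected velocities
  on red–red contact, measured its 10-s spawn interval from trial start
  or from the previous fill-in, and re-snapped reflected MOT headings to
  the 12-direction set are all unstated in the source material; this
  package fixes one deterministic choice for each (reflection;
  trial-start clock; no re-snapping) and exposes the surrounding
  parameters in config.
* The interactive renderer of the original tasks is out of scope; the
  CLI accepts but rejects `--display`.
* Config files are JSON only (no YAML parser in the supported
  dependency set).
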