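---
title: "The intensity-driven mobility model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The intensity-driven mobility model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(surf)
```

## The behavioural model

`surf` does not give agents fixed daily schedules. Instead, every activity
an agent can perform carries a motivation *intensity*, and at every
5-minute step a free agent performs the activity with the highest total
intensity. The total is the sum of two components.

The **background intensity** $B_a$ encodes the recurrence of an activity:
it grows linearly by $r^+_a$ per step while the activity is not performed
and drains by $r^-_a$ per step (clipped at zero) while it is. The
invariant $r^-_a > r^+_a \ge 0$ guarantees that performing an activity
always reduces the accumulated urge faster than it builds, so an hour of
shopping can discharge a need that accumulated over several days.

The **time intensity** encodes when the activity is normally done: a
rectangular profile with amplitude $A_a$ inside the characteristic window
$[t^{start}_a, t^{end}_a)$ and zero outside. Windows may wrap midnight.
Rectangles are the simplest shape consistent with "zero outside the key
interval"; any in-window shape would add parameters without a calibration
target to pin them down.

An agent keeps its current activity until a **minimal duration** has
elapsed; afterwards it re-evaluates every step. Exact ties keep the
current activity (preventing oscillation); ties among other activities are
broken by a fixed canonical order (`surf_activities()`). Being at home is
the fallback: its amplitude of 1 is present around the clock and anchors
the intensity scale — every other amplitude is pitched against the
competitor the activity must displace, so the *switching threshold* of a
flexible activity is an amplitude difference. For evening and daytime
activities of retired people the competitor is the home floor
($B^* \approx 1 - A_a$); for the commuter lunch break it is the office
($B^* \approx A_{work} - A_a$), which is why the lunch amplitude is close
to the work amplitude rather than to the home floor.

### Why episode durations are floor-controlled

A consequence of linear dynamics plus argmax switching deserves emphasis,
because it drove several calibration decisions. In steady state, an
activity that recurs every $T > 1$ days must remove roughly $T$ days of
accumulated growth per episode. If episodes ended exactly when the total
intensity fell below the competitor, the background would stop at the
switching threshold, never reset, and the activity would re-trigger the
next day — multi-day recurrence would be impossible. Multi-day recurrence
therefore *requires* that the minimal-duration lock drains the background
to zero, and then the lock itself ends the episode: durations equal the
minimal duration almost surely, with only a small overshoot tail.
"Duration controlled by the decay rate" and "recurrence slower than daily"
are mutually exclusive in this model class.

The shipped parameterisation embraces this: minimal durations are set at
the observed *median* episode lengths (27 min for commuter food shopping,
45 min for retired food shopping, 60 min for sports and evening
activities), decay rates are fast enough to guarantee a full reset within
the lock, and the observed right-skew of episode durations (mean 41 vs
median 30 min for commuter food shopping; 69 vs 50 for retired) is
reproduced by a third heterogeneity channel: a per-agent lognormal
multiplier on minimal durations (`sigma_duration`, default 0.9, truncated
to [0.25, 4.5]). People differ in how long they shop; rates alone cannot
express that here.

### Heterogeneity and noise

Three per-agent channels (drawn once at population synthesis) plus one
per-day channel:

* `sigma_rate` (default 0.2): lognormal multiplier on each activity's
  *grow* rate. It spreads recurrence intervals, hence participation, and
  is deliberately applied to the grow side only — a multiplier applied to
  both rates cancels out of the recurrence interval (growth per day and
  removal per episode scale together) and would leave agents effectively
  homogeneous.
* `sigma_duration` (default 0.9): lognormal multiplier on minimal
  durations (see above).
* `window_offset_min` (default ±30 min): a uniform shift applied to all
  of an agent's windows — some people are early, some late.
* `daily_jitter_min` (default ±10 min): redrawn each day per activity;
  without it all agents of a group move in lockstep and footfall peaks
  are implausibly sharp.

### Space

Buildings carry exactly one of seven function tags (one per
away-from-home activity, plus `residential` and `office` anchors), and
both buildings and sensors snap to their nearest street-network node; all
movement happens on the network. Flexible activities are allocated to a
uniformly random building of the required function within a Euclidean
search radius of the agent's current position (default 500 m, roughly a
six-minute walk), doubled up to 6 times until candidates exist. Routes
are A\* shortest paths — the straight-line heuristic is admissible
because edge lengths are validated to be at least the Euclidean distance
— walked at a constant 1.4 m/s (≈5 km/h). Travel is committed: an agent
en route completes the journey, its backgrounds keep growing meanwhile,
and the destination activity's clock starts on arrival. No congestion,
road classes or transport modes are modelled.

Sensors count *disc entries*: an event is recorded when a step
sub-segment enters the 20 m detection disc around the sensor's node from
outside. Dwelling inside produces no further counts, and the
segment–disc intersection is computed geometrically because a 420 m step
can jump across a small disc between samples.

## Simulation protocol

Runs last 14 days at 5-minute steps. The model settles into its
equilibrium daily cycle within about two days, but only the *final* day
is reported, which leaves ample margin for the slowest recurrence
(~22 days of growth are pre-seeded by the uniform background
initialisation, `init_max`, set near each activity's switching
threshold). Replicates are independent: replicate $i$ uses seed
$s + i$ from the master seed $s$, all randomness flows through R's RNG
(also inside the compiled core), and agents are updated in an order
reshuffled every step — agents do not interact, so order only fixes the
RNG stream, making every run bit-reproducible. Per sensor-hour cell the
replicate mean is reported with percentile bootstrap confidence intervals
(default 99%, 1000 resamples).

Within a step the engine decides first and performs second: a free agent
whose lock has elapsed re-evaluates, then the chosen activity (or travel)
is what that step is spent on. A logged episode therefore spans exactly
its performed steps, so schedule statistics are free of off-by-one-step
bias; the arrival step still counts as travel.

With all noise channels at zero the model is deterministic, and
day-periodic *provided every configured activity recurs daily* (as in the
test configurations). Under the shipped defaults several activities
deliberately recur every 2–22 days, so individual noise-free agents
follow multi-day limit cycles rather than day-periodic ones; the
population aggregate is still stationary day to day.

## Calibration

Following the field's practice, the defaults were calibrated manually
against printed weekday time-use-survey statistics (packaged in
`inst/extdata/uktus_targets.csv`): participation is set through grow
rates ($p \approx$ daily growth / switching threshold), durations through
minimal durations and `sigma_duration`, and office hours through the work
window. Calibration runs used the synthetic demo town with 1,000–2,000
agents per group and 3–10 replicates; the shipped values reproduce all
fourteen targets at desk scale (2,000 + 2,000 agents, 10 replicates,
about 20 s on one CPU). `evaluate_targets()` applies the tolerances
packaged with the targets: ±3 percentage points for participation, ±15%
for durations, ±30 min for the 8-hour office mean.

## What the synthetic data do and do not show

`fixture_spec()`/`make_demo_inputs()` generate the full input set with no
external data: a gridded town (blocks of 150 m, buildings along streets,
one statistical zone per block, sensors on the most central nodes), a
random commuting origin–destination matrix, per-zone retired counts, and
a pseudo-observed footfall series — an internal two-group reference run
plus a configurable un-modelled component (a Gaussian "school pulse"
peaking at 15:00, scaled to 35% of the peak hourly count) plus Poisson
noise. The pulse exists so the diversification workflow (compare → find
residual → add group) can be demonstrated and tested: the Z-score
residual of a commuter+retired run against these observations peaks at
the pulse hour.

Passing tests on this world show that the behavioural and counting
machinery is correct and that the calibrated schedule statistics match
the survey; they do not show that a real town's footfall would be
reproduced. Real street networks are not grids, building functions
cluster, commuting flows have spatial structure, sensor detection is
noisy and direction-blind, and the survey statistics are national, not
local. The model also inherits a known behavioural artefact: agents
without a fixed out-of-home anchor (retired people) tend to start their
flexible activities soon after their windows open, front-loading the
morning.

## Numerical choices

* Time windows: membership is evaluated on the agent-shifted clock,
  wrapped into [0, 1440); `start == end` denotes an empty window,
  [0, 1440) the whole day.
* Minimal durations are converted to steps with a ceiling, so an
  agent-specific duration is never rounded below its floor, and the
  median of discretised durations stays on the calibrated grid point.
* Backgrounds are clipped at zero; initialisation draws
  $B \sim U(0, \text{init\_max})$ approximate the stationary spread so
  agents de-synchronise from day one.
* The bootstrap uses percentile intervals; at very small replicate
  counts (n < 8) they are noticeably narrow, which is why the
  width-scaling test runs at 8 vs 32 replicates.
* The presentation smoother is a local-linear loess
  (`smooth_curve()`); it reproduces constants and straight lines exactly
  and never feeds any quantitative comparison — all metrics (Z-scores,
  RMSE, Pearson r, residuals) use raw hourly values.
* Z-scores use the population (divide-by-*n*) standard deviation.

## Parameter files

Parameters are read and written as YAML (`read_params()`,
`write_params()`) with the same nesting as `default_params()`; YAML is
the plainest widely-supported format for this nested structure in the R
ecosystem. All rates are intensity units per 5-minute step, windows are
minutes of day, and minimal durations minutes.

## Known limitations

Weekday-only behaviour (no weekends), no households or school children,
no congestion or transport modes, no memory of preferred locations, no
Wi-Fi detection physics (every pass counts exactly once), and a single
projected coordinate system (planar metres). These match the scope of the
first modelling iteration the package implements; the fixture's school
pulse exists precisely to demonstrate how the next group would be
identified.
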