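---
title: "Methods: simulating phased CFR alerting policies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating phased CFR alerting policies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfrsim)
```

`cfrsim` estimates how a community-first-responder (CFR) alerting policy
affects out-of-hospital cardiac arrest (OHCA) outcomes and volunteer burden.
This vignette documents the model, its assumptions, the tunable parameters,
and the numerical and design choices, so results can be interpreted — and
challenged — precisely.

## The incident model

An incident is resolved on two clocks. The *collapse clock* starts at the
OHCA; after a witness delay (default 60 s, collapse to emergency call) and a
triage delay (default 124 s, call to CFR-system activation) the *activation
clock* starts. Policies, alerts, replies and the coverage KPI live on the
activation clock; survival lives on the collapse clock.

**Geometry.** Volunteers are placed uniformly at random over a disk of
radius `R` (default 1000 m) centred on the patient. Because the patient sits
at the centre, only distances matter; we sample them directly by the radial
inverse CDF `D = R√U`, so `P(D ≤ d) = (d/R)²` and `E[D] = 2R/3`. Distances
are sorted ascending and define the alerting ranks: every policy alerts a
more distant volunteer only when all closer ones are already alerted. Ties
in the sort are broken by draw order — a measure-zero event under continuous
sampling, so any rule is consistent. Travel time for distance `x` meters is

```
travelTime(x) = 60·x / (1000·a + 1000·b·x)   minutes,
```

the time implied by a linear speed law `speed(x) = a + b·x` km/h with
defaults `a = 1.83`, `b = 0.0108` (so `60x/(1830 + 10.8x)` min; 4.75 min at
1 km). Speed *increases* with distance because distant responders tend to
use faster modes. The law is not clamped: with the defaults the speed at
`x = 0` is 1.83 km/h > 0, so no singularity exists; parameter combinations
implying non-positive speed anywhere on `[0, R]` are rejected at
construction.

`fit_speed_model()` reproduces how such coefficients are estimated from
observed (distance, travel time) pairs: zero travel times are excluded,
distances are binned into 100-m blocks, the 0–100 m block is dropped
(short-range GPS on-scene detection is unreliable), block median speeds are
computed, and ordinary least squares regresses the medians on block
midpoints. Two open choices here were resolved as follows: the block is
represented by its midpoint (150 m for [100, 200)), and the regression is
*unweighted* — block medians are treated as equally informative summary
points rather than weighting by block counts, since the heavier near blocks
would otherwise dominate a curve that must extrapolate to 1 km.

**Behavior.** A volunteer's response is a joint draw of *view delay* (alert
to reply; infinite if never seen) and *reply* (accept / reject / not seen).
Two sources are supported. In bootstrap mode whole records are resampled
with replacement from a response log, preserving the empirical dependence
between slow viewing and rejection. In synthetic mode (the default, since no
public log ships with the package) replies are generated as: seen with
probability `1 − p_notseen`; seen view delays log-normal; acceptance given a
seen delay `d` equal to `plogis(α − β·log d)`, with `α` calibrated by
Gauss quadrature (`integrate` + `uniroot`) so the *marginal* acceptance
equals `p_accept` exactly. Draws are i.i.d. across volunteers and alerts; a
volunteer is never alerted twice for the same incident.

**Policies.** Four families, all under two global stopping rules — nothing
is sent at or after the first accept decision, nor at or after the cutoff
(default 600 s):

* `send_all` — everyone at time 0;
* `send:<n1>` — the n1 closest at time 0, nothing after;
* `keep:<n2>` — n2 at time 0, each explicit reject replaced immediately (the
  replacement alert carries the reject's timestamp; the published rule
  states no lag) by the next-closest unalerted volunteer; not-seen alerts
  produce no reply event and never trigger replacement;
* `batched:<size>:<interval>` — `size` alerts at 0 and at each interval
  multiple strictly before the first accept and the cutoff, while unalerted
  volunteers remain (so the policy is pool-limited at low density). The stop
  rule is evaluated continuously, not only at batch instants: an accept at
  90 s cancels the 120-s batch.

Boundary cases resolve toward *fewer* alerts: a reject arriving exactly at
the first accept instant spawns no replacement, and a batch due exactly at an
accept instant is not sent. Under continuous delays these ties have measure
zero; the convention only matters for discrete test fixtures.

`enumerate_policies()` yields the 27-policy study set: send-all, send-n1 for
n1 = 1..15, keep-n2 for n2 = 1..10, and the batched 3-per-minute policy
currently used by GoodSAM New Zealand.

**Outcomes.** Every accepter arrives, at alert time + view delay + travel
time, and all arrivals are counted — there is no arrival cutoff at ambulance
time, because redundant arrivals burden volunteers whenever they occur. Only
the survival conversion truncates: `T_CPR = min(witness + triage + first
arrival, T_EMS)` with `T_EMS = 13` min constant, converted by the Waalewijn
logistic curve

```
survival(T_CPR, T_EMS) = 1 / (1 + exp(0.04 + 0.3·T_CPR + 0.14·(T_EMS − T_CPR)))
```

and scaled by 5,141 OHCAs/year. A transcription of this curve that
circulates with a leading "1 −" *increases* with CPR delay; that variant is
nonphysical and inconsistent with the zero-volunteer reference of 98
survivors/year (which requires probability ≈ 0.019 at `T_CPR = 13`), so the
package implements the decreasing branch and exposes the complement behind
`one_minus = TRUE` for auditing. Coverage counts a first arrival at exactly
the 300-s threshold as covered (inclusive boundary; measure zero again).

## Nested Monte Carlo and seeds

`run_policy()` draws `n_outer` location sets and `n_inner` behavior vectors
per set. Inner results are collapsed to means per outer replication; 95%
two-sided t-intervals over those outer means summarise Monte Carlo error
(the confidence level is a package choice; the interval construction follows
the one-halfwidth-per-design convention of the published tables, and
`max_ci_halfwidth_frac` skips KPIs with mean zero). Every stream is derived
from the master seed by hashing `(stream label, policy, replication)` with a
Lehmer-style string hash modulo 2³¹−1: adding or reordering policies never
perturbs another policy's draws, and `couple = TRUE` keys the behavior
stream by replication only, giving common random numbers across policies for
sharper comparisons (the default is independent streams, matching an
uncoupled experimental design; per-incident dominance and monotonicity
checks in the test suite use coupling).

Scheduling inside an incident is event-driven. For `keep:<n2>` a pending-
decision set is processed in time order (accept checked before reject on
ties); for `batched` only the running minimum accept time matters, since
rejects never spawn anything. The test suite cross-checks both against an
independent discrete-time reference that steps through integer seconds.

One structural fact worth knowing: keep-n2 alert *counts are not monotone in
n2 stream by stream*. A larger n2 can reach a fast accepter sooner and
thereby cancel replacement alerts the smaller n2 would still have sent (for
example, rejects with 10-s delays ranked ahead of an accepter with a 1-s
delay). Monotonicity of mean alerts, coverage and survival in n2 — the
pattern visible in the published tables — holds in expectation and is what
the tests assert.

## The synthetic behavior generator

The generator stands in for a proprietary alert log of 29,307 GoodSAM New
Zealand alerts that is not publicly deposited. Its defaults are fixed at the
published marginal counts — accept (including accept-then-drop) 5208/29307 ≈
17.77%, reject 7925/29307, not seen 16,174/29,307 — and at a qualitative
description of the response-time data: right-skewed view delays and an
acceptance probability that declines with view delay. The quantitative shape
is not published, so the package chooses a log-normal with median 30 s
(`meanlog = log 30`, a plausible glance-at-phone delay) and `sdlog = 1`, and
a logistic decline of one logit per log-delay unit; all three are exposed in
`behavior_model()`.

Consequences for interpretation:

* KPIs that depend only on the acceptance *marginal* — alert counts,
  redundant arrivals, 2+-arrival fractions under send-all — are reproduced
  faithfully (they also admit closed forms: with acceptance `p` and `n`
  volunteers, expected redundant arrivals are `np − (1 − (1−p)ⁿ)` and
  `P(2+ arrivals) = 1 − (1−p)ⁿ − np(1−p)ⁿ⁻¹`; the test suite checks the
  engine against both).
* KPIs that depend on the *timing* of replies — coverage, survival, and the
  alert volume of time-phased policies — shift with the assumed delay
  distribution and should be read as structural comparisons between
  policies, not calibrated absolute predictions, until a real log is
  supplied via `load_records()` + `behavior_model("bootstrap", ...)`.

The generator does not emulate per-volunteer heterogeneity, time-of-day
effects, en-route drop-out after acceptance, or any dependence between
volunteers — the bootstrap design it replaces has none of these either.

## Problem sizes

The published experimental design is 1000 location sets × 10,000 behavior
draws. The package defaults (`sim_config()`) keep that design; the examples,
tests and the acceptance script run scaled-down designs (tens of outer
replications × hundreds of inner draws for structural checks; 100 × 1000 =
10⁵ incidents for the stochastic headline quantities), chosen so the full
suite runs in minutes at interactive precision — relative CI halfwidths of a
few percent — while remaining unbiased: scaling replication counts changes
variance only.

## Known limitations

* The survival curve assumes volunteer CPR quality equals that of the cohort
  the curve was fitted on, and `T_EMS` is a constant 13 min, not a
  distribution.
* Accept-then-drop is treated as accept (as in the source data handling);
  en-route abandonment is not simulated, so arrival-based KPIs are
  optimistic about accepters reaching the scene.
* One incident at a time: no volunteer exhaustion across incidents and no
  competing simultaneous alerts.
* Straight-line distance with a distance-dependent speed proxies real
  routing; no travel-mode differentiation.
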