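---
title: "Modelling chronic-disease progression with continuous-time Markov chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chronic-disease progression with continuous-time Markov chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctmccohort)
library(dplyr)
```

## The modelling problem

Chronic cardiovascular disease unfolds as a sequence of episodes — myocardial
infarction (MI), stroke, congestive heart failure (CHF), angina — recorded in
cohort registries as little more than a patient identifier, an episode name,
and a day count from the patient's baseline. `ctmccohort` turns such minimal
episodic records into a continuous-time Markov chain (CTMC): a model in which
a patient occupies exactly one state at a time, holds there for an
exponentially distributed number of days, and then jumps to another state
with probabilities that do not depend on history. The fitted model yields
time-variant transition probability matrices $P(t) = e^{Qt}$, progression
patterns over a review grid, cohort state-mix forecasts, and stratified
comparisons between subcohorts.

The CTMC is deliberately simple. Its assumptions — memorylessness,
exponential holding times, homogeneity over calendar time and across
patients within a cohort — are approximations that practitioners accept in
exchange for a model that is estimable from sparse episodic data and
interpretable at the cohort level. None of the machinery here attempts
covariate-dependent intensities, censoring-aware likelihoods, or
semi-Markov holding times; those are out of scope by design.

## From raw episodes to Markov-valid trajectories

Raw registry rows violate the Markov state model in three systematic ways,
and the preprocessing stage (`build_trajectories()`) repairs each one:

1. **Same-day multimorbidity.** Several episodes recorded on one day would
   put a patient in two states at once. Instead, every distinct label set
   occurring on a day becomes a single *composite state*. Names are
   deterministic: each component label has a short code (CHF → `CH`,
   angina → `AN`, MI → `MI`, stroke → `ST`) and codes concatenate in the
   fixed order `CH < AN < MI < ST`, so {angina, CHF, MI} always composes to
   `CHANMI` regardless of row order. Composition is idempotent and
   permutation-invariant, which the test suite checks property-style.
   A day that mixes the absorbing death label with other episodes resolves
   to death: records cannot continue past absorption, and treating the
   competing same-day episode as a separate prior visit would fabricate a
   zero-day transition. This is a package decision — registries are silent
   on the convention — and it is logged as a warning whenever it fires.

2. **Consecutive duplicate reports.** The same ongoing condition reported
   again days later is not a re-entry; a chronic state rarely remits
   completely between nearby reports. Maximal runs of identical consecutive
   states collapse to one visit dated at the run's first day, so the hold
   spans the interim. A genuine return after an intervening different state
   is preserved.

3. **Post-death records and rare states.** Episodes after a patient's
   absorbing visit are registry noise; they are discarded with a warning
   rather than an error. States too rare to support rate estimation are
   pruned below a user-supplied `min_count`; there is no universal default
   because "negligible" depends on cohort size. Pruning has two policies:
   `drop_records` (default) removes the records *and breaks the patient's
   sequence* at each removal, so no transition is counted across a dropped
   visit; `splice` leaves the neighbours adjacent and counts the bridge as
   a direct transition. The default is conservative — it fabricates no
   transitions — at the cost of discarding the two bridging jumps.

The result satisfies the trajectory invariants relied on downstream:
strictly increasing entry days, no consecutive repeats, at most one
absorbing visit and only as the last.

## Estimating the generator

Let $n_{ij}$ be the number of observed one-step $i \to j$ jumps and
$r_{ij}$ the total days spent in $i$ by exactly those patients before
jumping to $j$. Two estimators of the intensity matrix $Q$ are offered:

* **`mode = "mle"`** — the maximum-likelihood estimator for a continuously
  observed Markov jump process:
  $\hat q_{ij} = n_{ij} / T_i$, with $T_i = \sum_j r_{ij}$ the total
  observed holding time in $i$. This is the estimator to use for
  inference: on cohorts simulated from a known $Q^*$ it converges to
  $q^*_{ij}$ itself.

* **`mode = "paper"`** (default) — the destination-specific ratio
  $\hat q_{ij} = n_{ij} / r_{ij}$. Because an exponential holding time is
  independent of the destination drawn, this ratio converges not to
  $q^*_{ij}$ but to the state's total exit rate $\lambda_i = -q^*_{ii}$,
  for every destination actually realized. It reproduces the accounting of
  the published worked example this package mirrors (31 MI→CHF jumps over
  16,633 destination-specific waiting days giving 0.001864 per day), which
  is why it remains the default; the difference between the two modes is
  demonstrated, not hidden, by a simulation-based test that recovers
  $q^*_{ij}$ under `mle` and $\lambda_i$ under `paper` from the same
  cohort.

Both modes set $q_{ii} = -\sum_{j \ne i} q_{ij}$, leave $q_{ij} = 0$
where no jump was observed (no pseudo-counts or smoothing — published jump
tables show exact zeros), and zero the absorbing rows. Time after a
patient's last visit is ignored entirely: there is no censoring exposure
in either mode, consistent with the destination-specific accounting. The
consequence — rates estimated from fully observed spells only, with a mild
length-biased selection near the end of follow-up — is accepted as part of
the method, not corrected.

Descriptive statistics follow the same counting conventions. Transition
time summaries use the *population* standard deviation (divisor $n$), so a
pair observed once reports SD 0 rather than NA. Percent tables round
half-up to one decimal, matching the convention of published transition
matrices (base R's round-half-even would disagree in cells like 13.45).

## Transition probabilities and progression patterns

`transition_probability()` evaluates $P(t) = e^{Qt}$ with the
scaling-and-squaring Padé implementation in `Matrix::expm`. The accuracy
contract is stated in units a user can check rather than as a named
algorithm: rows must sum to 1 within $10^{-9}$ (they are *never*
renormalized — drift beyond that is an error), agreement with the 2-state
closed form $P_{11}(t) = (b + a e^{-(a+b)t})/(a+b)$ within $10^{-10}$,
and the Chapman–Kolmogorov identity $P(s+t) = P(s)P(t)$ within $10^{-8}$,
all verified over randomized generators in the test suite. Entries more
negative than $-10^{-12}$ are likewise an error; only exponential-roundoff
negatives above that are clipped to zero.

`progression_series()` evaluates the start-state row of $P(t)$ on a grid
of multiples of `interval_days` up to `horizon_days`. The defaults — 90-day
steps to 1800 days, i.e. 20 quarterly review points over five years — encode
the common cardiology review cadence, with "3 months" fixed as 90 days and
"5 years" as $20 \times 90$ days. `forecast_state_mix()` propagates an
initial cohort distribution by the same matrices.

## The cohort simulator

Access to large episodic registries is typically restricted, so the package
ships a simulator that makes every pipeline stage testable from code alone.
`simulate_cohort()` is a Gillespie walk: draw the start state at day 0,
hold $\textrm{Exponential}(\lambda_i)$ days, jump with embedded-chain
probabilities $q_{ij}/\lambda_i$, stop at absorption or the end of
follow-up. Defaults emulate a long observational cohort: follow-up of
5,800 days (~16 years) and whole-day recording. Entry times are rounded
*up* to integer days with a minimum one-day hold, so simulated tables
already satisfy the preprocessing postconditions; this ceiling convention
adds well under 1% bias at the 100-to-1000-day mean holds typical of
chronic disease, which the recovery tests absorb.

`roughen_episodes()` then re-introduces, in a controlled way, exactly the
raw-data pathologies preprocessing exists to fix: composite states are
split into their component episode rows on the same day, and with a
configurable per-visit probability a duplicate same-state row is injected
strictly inside the holding interval. By construction
`build_trajectories(roughen(simulate(cfg)))` recovers the clean
trajectories *exactly*, and a seeded test asserts that identity on a
200-patient cohort with both controls on.

What the simulator does **not** emulate: non-exponential holding times,
calendar-time or covariate effects on intensities, measurement error in
day stamps, or informative loss to follow-up. Passing tests therefore
show that the estimators and preprocessing are correct under the model's
own assumptions — they cannot show that real cohorts satisfy those
assumptions.

## Study sizes and numerical choices in the test suite

Simulation-backed tests use sizes chosen to keep Monte-Carlo error well
inside the asserted bounds while running comfortably on one CPU: 10,000
patients for the exponential-mean check (3-standard-error band), 3,000 for
embedded-jump fractions and estimator consistency (relative errors within
10%; the rarest transition pair still collects several hundred counts),
2,000 for the fixed four-state recovery study, and 200 for the exact
roughening round trip. The four-state recovery truth uses day-scale rates
between $10^{-3}$ and $5 \times 10^{-3}$ per day (mean holds of roughly
140–350 days) over a CHF/Stroke/MI/Death topology with death absorbing —
sizes and rates in the regime the episodic-cohort setting implies. At
2,000 patients the 10% recovery band sits less than two binomial standard
errors from the truth for the rarest pair, so individual draws can land
just outside it; the consistency claim is the 3,000-patient test.

All randomness is seeded; simulation is a pure function of its
configuration and restores the caller's RNG state.

## Open design points, resolved

* **Patients with no episodes.** Only episode rows enter the tool; a
  cohort member with zero episodes contributes nothing, so denominators
  for "first episode" statistics are over patients with at least one
  visit. `first_episode_distribution(restrict_to =)` exposes restricted
  denominators instead of guessing an unstated subset.
* **Pruning threshold.** Required configuration, no default; the shipped
  demo uses small thresholds appropriate to its size.
* **Ten-state demo scenario.** `inst/extdata/cvd_demo_scenario.yaml`
  pairs the packaged jump-frequency structure with *invented* exit rates
  (1/200 to 1/450 per day); it exists for documentation and smoke runs and
  is never used as ground truth in tests, because no published
  holding-time parameters exist to calibrate it.
* **Composability.** Any two non-special labels co-occurring on a day must
  be composable under the naming scheme; an unknown combination is an
  error rather than a silently invented state.

## Known limitations

Estimates carry no uncertainty quantification (no confidence intervals or
asymptotic covariance for $Q$). Ignoring post-last-visit exposure biases
rates upward slightly when follow-up truncates many spells. Labels are
opaque strings — there is no ontology mapping — and date handling is
baseline-relative whole days only. The stratified comparison reuses the
full pipeline per stratum and requires the stratifying covariate to be
constant within each patient.
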