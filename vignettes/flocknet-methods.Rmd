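---
title: "Methods: arrival-time networks, de-lifed fitness and selection on sociality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arrival-time networks, de-lifed fitness and selection on sociality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `flocknet`, the conventions and
numerical choices the implementation commits to, and what the synthetic
data generator does and does not emulate.

## The association model

RFID feeders log `(timestamp, tag)` detections; they do not observe
groups. The package's central assumption is behavioral: in gregarious
passerines, nonrandom associations are established *before* birds reach a
feeder, so association is best read from co-**arrival**, not from shared
presence.

Two parameters with units of seconds govern inference:

* `delta_i` (default **300 s**) — the absence gap. A detection opens a new
  arrival bout only when the gap since the bird's previous detection is
  *strictly greater* than `delta_i`; the strictness follows from defining
  re-appearance as absence *exceeding* the threshold. A bout runs from its
  first to its last detection.
* `delta_t` (default **150 s**) — the co-arrival window. Two birds are
  associated when their arrivals differ by *at most* `delta_t` ("within"
  is read inclusively; the choice only matters on exact ties, which have
  measure zero in continuous time but are honored deterministically).

Repeat co-arrivals accumulate within a window (the Simple Ratio Index
needs numerators), with **greedy one-to-one matching** per dyad in time
order so that one arrival never counts against several bouts of the same
partner. The rule is deliberately dyadic and non-transitive: A–B and B–C
within the window do not imply A–C. Two classical alternatives are
implemented for contrast: gambit-of-the-group (single-linkage clustering
of arrivals with threshold `gap`, every within-group dyad linked — a
superset of the arrival-time edges at `gap = delta_t`, prone to chaining
separate flocks) and time-window overlap (presence intervals extended by
`delta_t`, prone to linear A–B–C chains at a busy feeder). An optional
`counting = "binary_per_window"` flag caps each dyad at one association
per window, since observation protocols differ on this; accumulation is
the default.

Weeks are 7-day blocks anchored at each event's start date, half-open
`[start, start + 7d)`; a bout belongs to the week of its arrival time, and
bouts never span slice boundaries because bout detection runs within
slices.

## Networks and centrality

Dyads are weighted by the Simple Ratio Index
`SRI = x / (x + y_a + y_b)`, where `x` counts co-arrivals and
`y_a = n_a − x` the arrivals of `a` without `b`. Because the sampling unit
is an arrival rather than a survey scan, there is no "both seen apart in
the same sampling period" joint term in the denominator. `0/0` is defined
as 0. Networks keep every positive-SRI edge (no thresholding); vertices
with degree 0 — birds that never arrived in a dyad — are removed.

Per bird and window the package reports:

* **degree** — number of associates;
* **strength** — *net association quality*
  `S_i = d_i · (Σ_j SRI_ij) / N(V)`, the summed index scaled by
  connectedness relative to network size. The printed form of this
  transform is typographically ambiguous in its source material, so the
  plain `Σ_j SRI_ij` is available via `strength = "sum"` and both are
  documented; the scaled form is the default.
* **eigenvector centrality** — leading eigenvector of the SRI-weighted
  adjacency, normalized so the maximum score is 1 (the `igraph`
  convention, which keeps event-level values comparable across networks).
  On a disconnected network the dominant eigenvector of the full
  adjacency is used and a message is emitted: scores in non-dominant
  components are near zero by construction, which is the honest answer
  rather than a per-component renormalization.
* **opposite-sex degree** — the raw *count* of opposite-sex associates in
  the male–female bipartite sub-graph (same-sex edges dropped before the
  degree filter). A weighted variant would also be defensible; the count
  was chosen as the primary definition because the measure stands for the
  pool of prospective partners, and a pool is counted.

## Fitness from the pedigree

A **recruit** is an offspring that survived and produced genetic
offspring itself — a grand-offspring criterion evaluated on the pedigree.
Annual recruit counts for year *t* sum a parent's cohort-*t* offspring
that are recruits. Two analysis exclusions are applied as *absent rows*
(not zeros): birds dead before the April census of *t*, and yearlings
with zero recruits.

**De-lifed fitness** measures the change in realized population growth
when a bird and its offspring are removed:

```
p_ti = (xi_t(i) − w_t) / (N_t − 1)
```

with `N_t` the April census, `w_t = N_{t+1}/N_t`, and
`xi_t(i) = share × (surviving cohort-t offspring of i) + 1{i survived to t+1}`.
Whether an offspring contributes 1.0 to each parent or 0.5 split between
its two genetic parents is not uniquely determined by the formula's usual
presentation; the package defaults to **0.5** because that convention
yields an exact conservation law in a closed, fully censused sexual
population — `Σ_i p_ti = 0` every year, at machine precision — which the
test suite uses as a bookkeeping invariant (any violation localizes an
accounting bug). `share = 1.0` is available. "Survived to the following
breeding period" is operationalized as alive at April 1 of `t + 1`, and
census membership at *t* as born in an earlier cohort with
`death_year ≥ t`. The restriction of de-lifed values to birds with at
least one recruit is an *output filter* (`delifed_filter = TRUE`), never a
computation change.

## Repeatability and selection models

All Bayesian models run on a Gibbs/Metropolis sampler (JAGS, with the
`glm` block-sampling module) under an explicit contract: total
iterations, burn-in, thinning interval and seed. The default contract is
343,000 / 3,000 / 200 (1,700 retained samples); any contract must retain
at least 1,000. Variance components get univariate inverse-Wishart priors
`IW(V = 1, ν = 0.002)`, i.e. precision `~ Gamma(0.001, 0.001)` — the
conventional weakly-informative default of the mixed-model software this
contract mirrors; fixed effects get diffuse Gaussians (`τ = 10⁻⁸`).
Posterior point summaries are **modes** located by a kernel-density
maximizer (means are also reported); intervals are 95% highest-posterior-
density intervals; a fixed effect is *significant* exactly when its
interval excludes zero.

* **Repeatability**: per measure and event, a Gaussian intercept-only
  model of weekly centrality with a bird-identity random intercept;
  `R = V_id / (V_id + V_res)` computed per retained sample and summarized.
  Events are fitted separately.
* **Annual selection**:
  `response ~ c + c² + sex + age + age² + age:sex + (1|bird) + (1|cohort)`
  with `c` the measure mean-centered within year (eliminating between-year
  differences; raw values are kept alongside). Age is calendar-year age
  and is deliberately *not* centered before squaring. Recruit responses
  are Poisson with log link plus an observation-level latent Gaussian for
  overdispersion; de-lifed responses are Gaussian.
* **Lifetime selection**:
  `response ~ c + c² + sex + lifespan + lifespan:sex + (1|cohort)` — each
  bird appears once, so no identity effect; lifespan replaces age and is
  censored at the final pedigree year.

Chains are never silently accepted: effective sample size and lag-1
autocorrelation are computed for every parameter, and a fit is flagged
non-converged when any fixed effect has ESS below 1,000 or
|autocorrelation| ≥ 0.1. At the short contracts used in the package's
replicated experiments these flags fire by design (ESS of a few hundred);
the experiments rely on interval coverage, which is robust to that, and
the flags document it.

## Null models and dominance

The node-permutation null applies a uniform random **bijection of
identities** (a label permutation) within each scope unit — the arrival
times, the identity set, and the multiset of per-individual arrival
counts are all conserved exactly, while any individual-level link between
sociality and fitness is broken. Scope defaults to within-event
(within-week is available); the coarser scope is the more conservative
randomization and matches how event networks are built. Across
permutations the per-bird **mode** of each measure is reported: exact
mode for integer measures (smallest value on ties), and the
**half-sample mode** for continuous ones — a deterministic, robust
estimator chosen over a binned or kernel mode because it needs no
bandwidth or bin-origin choice.

Elo dominance ratings update chronologically with
`p_w = 1 / (1 + 10^((R_l − R_w)/400))`, winner gaining `k(1 − p_w)` and
loser losing the same (zero-sum; start 1000, k = 100, the common
behavioral-ecology convention). The dominance–centrality check is a
Spearman rank correlation with a label-permutation p-value, run on
observed centralities only.

## The synthetic-data generator

`simulate_population()` builds a closed population: founders are the
standing population at the study start (their survival clock is
conditioned on being alive in the first event year), spread over the four
cohorts up to that year; each subsequent breeding year pairs surviving
males and females at random, draws Poisson offspring per pair
(mean 2), and applies first-year (0.5) and adult (0.6) annual survival —
values in the range reported for island passerine systems, chosen once to
keep the census roughly stationary. Every simulated offspring has both
parents in the pedigree, which is what makes the de-lifing conservation
law exact.

`simulate_visits()` emulates a single open-access feeder recording
06:00–24:00, seven days a week, across two non-breeding events (defaults:
15 weeks from 2015-11-02 and 13 weeks from 2016-11-07). Flocks arrive as
a Poisson process through each operating day (a modeling choice — the
simplest process producing clustered arrivals; no field-calibrated
arrival model is implied). An attending flock member arrives with its
flock (Normal jitter, default SD 15 s) with probability
`flock_membership_concentration` (default 0.9), otherwise alone at a
random time — keeping networks from being block-diagonal, as in the messy
real system. Attendance probability varies by bird and week through a
latent propensity whose between-individual variance share equals
`target_icc` (default 0.3), so weekly centrality is individually
repeatable by construction and the repeatability machinery can be tested
against known truth. Each arrival spawns an exponential-length bout of
detections; re-arrival is blocked until an exponential revisit gap has
passed.

What the generator does **not** emulate: spatial movement or multiple
antennas, weather and seasonal covariates, dominance interactions at the
feeder, assortment by sex or kinship, age-dependent sociality, and any
feedback from fitness to behavior. Passing recovery tests therefore
demonstrates that the estimators recover what this generative family
encodes — not that real feeder data satisfy its assumptions.

`simulate_fitness()` couples fitness to any sociality vector through
`η = baseline + β₁c + β₂c² + β_sex·sex + β_age·age`, with Poisson recruit
counts (`exp` link) or Gaussian de-lifed values; it is the truth source
for selection-recovery and null-attenuation experiments.

## Problem sizes used by the test suite

The replicated experiments run at desk scale, chosen to finish in minutes
while leaving the pass thresholds at their stated proportions:
association-oracle equivalence on 1,000 random streams of up to 200
arrivals; eigenvector agreement with a power-iteration oracle on 100
random graphs of up to 50 vertices; the de-lifing identity on 10 seeded
populations; repeatability recovery with 100 birds × 14 weeks over 30
replicates (95% CI covering ICC 0.30 in ≥ 90%); selection recovery with
n = 500 over 20 replicates per scenario (linear 0.25, quadratic −0.15,
and an all-zero null with ≤ 10% false significance per term); and
20 permutation replicates for coupling attenuation. MCMC runs in these
experiments use a shortened contract (`mcmc_config_short()`: 2,600
iterations, burn-in 500, thin 2, ~1,050 retained).

## Degenerate inputs and tie-breaks

Empty visit logs warn and return empty tables; a population of one bird
is rejected (`n_individuals ≥ 2`), while an explicitly allowed empty
population returns empty tables. Simultaneous detections at one antenna
are accepted as ties and sorted stably by tag. `N_t = 1` makes de-lifing
undefined and errors. Integer modes break ties toward the smaller value;
the half-sample mode of a 3-point sample takes the mean of the closer
pair. A constant MCMC chain is flagged degenerate rather than scored.

## Known limitations

Inverse-Wishart priors at `ν = 0.002` are weakly informative but not
uninformative near zero variance; repeatability modes under a true ICC of
0 concentrate near zero but are not exactly zero. The Poisson models'
observation-level residual makes bird identity and overdispersion
variances individually weakly identified when most birds contribute one
row (their sum is identified; fixed effects are unaffected). Eigenvector
centrality on disconnected networks scores non-dominant components near
zero, which compresses that measure's variance in fragmented weekly
networks. The arrival-time rule needs the feeder to be open-access; at a
single-perch feeder queueing would violate the co-arrival assumption.
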