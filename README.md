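# flocknet

Social-network inference and selection analysis for RFID feeder data from
closed, pedigreed bird populations.

Passive-transponder (PIT-tag) feeders record *when* each bird visits, but
not *who it is with*. In gregarious species such as house sparrows, flocks
form before they reach a feeder, so co-membership shows up as birds
**arriving together**. `flocknet` turns a raw detection stream into
weighted social networks using an arrival-time association rule, links the
resulting centrality measures to pedigree-derived fitness, and asks whether
selection acts on sociality.

The full chain, each step an exported function over plain tibbles:

1. **Arrival inference** — detections are split into *bouts*: a new arrival
   starts when a bird has been absent for more than Δi seconds
   (default 300). Two birds are *associated* when their arrivals fall
   within Δt seconds of each other (default 150), with greedy one-to-one
   matching per dyad. The classical *gambit of the group* (single-linkage
   temporal clustering) and *time-window overlap* definitions are provided
   for comparison; the arrival-time rule avoids the group-chaining the
   other two suffer at a busy feeder.
2. **Networks** — dyads are weighted by the Simple Ratio Index
   `SRI_ab = x_ab / (x_ab + y_a + y_b)` (association probability, 0–1) and
   assembled into weekly, per-event and opposite-sex (bipartite) graphs.
   Four centrality measures per bird: degree, strength (net association
   quality `S_i = d_i · ΣSRI_i / N(V)`), eigenvector centrality
   (max-normalized), and opposite-sex degree.
3. **Fitness** — from a multi-generational pedigree: *recruits* (offspring
   that themselves produced genetic offspring) per breeding year and over
   a lifetime, and *de-lifed fitness*
   `p_ti = (ξ_t(i) − w_t) / (N_t − 1)` — the change in realized population
   growth when individual *i* and its offspring are removed. In a closed,
   fully censused population with offspring split between parents,
   `Σ_i p_ti = 0` holds each year at machine precision; the package tests
   itself against that identity.
4. **Repeatability** — Gaussian intercept-only mixed models of weekly
   centrality with a bird-identity random effect;
   `R = V_id / (V_id + V_res)` summarized over the posterior.
5. **Selection** — Bayesian GLMMs (Poisson log link with overdispersion
   for recruits, Gaussian for de-lifed fitness) of fitness against each
   mean-centered centrality measure with linear and quadratic terms plus
   sex/age demography; a negative significant quadratic term is the
   stabilizing-selection signature.
6. **Null models** — node permutations that shuffle bird identities across
   observed arrival times (conserving the time and count multisets
   exactly), modal null centralities, and Elo dominance ratings with a
   dominance–centrality correlation check.

A seeded synthetic-data generator (`sim_config()`, `simulate_population()`,
`simulate_visits()`, `simulate_fitness()`) emulates the study system — a
closed island population watched over two multi-week non-breeding events —
with known flock structure, sociality repeatability and sociality–fitness
couplings, so every stage is testable by parameter recovery.

## Worked example

```r
library(flocknet)

cfg <- sim_config(n_individuals = 40, seed = 1)
pop <- simulate_population(cfg)
visits <- simulate_visits(pop$individuals, pop$truth, cfg)

sliced <- slice_windows(visits, cfg$event_windows)
arrivals <- detect_arrivals(sliced, arrival_params(delta_t = 150, delta_i = 300))
counts <- associate_arrivals(dplyr::filter(arrivals, event == "2015/16"))
sri <- compute_sri(counts)
net <- build_network(sri, pop$individuals)
bip <- build_network(sri, pop$individuals, bipartite = TRUE)
compute_centralities(net, bip) |> summarize_event()
#> # A tibble: 4 × 4
#>   measure               mean    sd     n
#>   <chr>                <dbl> <dbl> <int>
#> 1 degree              22.9   0.282    24
#> 2 eigenvector          0.358 0.419    24
#> 3 opposite_sex_degree 11.9   0.282    24
#> 4 strength             1.77  0.859    24
```

24 birds entered the 2015/16 event network (degree ≥ 1 filter), with a
mean of 22.9 associates each and 11.9 opposite-sex associates — a dense
network, as expected after 15 weeks of accumulated co-arrivals.

The whole analysis runs from one configuration:

```r
res <- run_pipeline(list(
  simulation  = list(n_individuals = 40),
  selection   = list(measures = "opposite_sex_degree",
                     responses = "annual_recruits"),
  permutation = list(n_permutations = 50),
  seed = 1))

tidy(res$repeatability)[1:4, 1:6]
#> # A tibble: 4 × 6
#>   event   measure                 R R_mean ci_low ci_high
#>   <chr>   <chr>               <dbl>  <dbl>  <dbl>   <dbl>
#> 1 2015/16 degree              0.156  0.199 0.0764   0.321
#> 2 2015/16 strength            0.647  0.633 0.500    0.772
#> 3 2015/16 eigenvector         0.947  0.943 0.910    0.974
#> 4 2015/16 opposite_sex_degree 0.149  0.187 0.0765   0.309

tidy(res$selection[["annual_recruits.opposite_sex_degree"]], "fixed")[,
  c("term", "mode", "ci_low", "ci_high", "significant")]
#> # A tibble: 7 × 5
#>   term           mode  ci_low ci_high significant
#>   <chr>         <dbl>   <dbl>   <dbl> <lgl>
#> 1 (Intercept) -0.226  -3.10    2.90   FALSE
#> 2 c           -0.0556 -0.380   0.353  FALSE
#> 3 I(c^2)       0.0271 -0.0518  0.0952 FALSE
#> 4 sex         -0.906  -2.89    1.93   FALSE
#> 5 age         -0.207  -2.58    1.49   FALSE
#> 6 I(age^2)     0.0293 -0.255   0.454  FALSE
#> 7 sex:age      0.215  -0.498   0.802  FALSE
```

Weekly centrality is individually repeatable (e.g. degree
R = 0.16, 95% CI 0.08–0.32), while — as this simulation couples nothing to
fitness — every sociality term's credible interval spans zero. A term is
reported `significant` exactly when its 95% credible interval excludes
zero. `autoplot()` methods draw the network, the repeatability estimates
and the coefficient plot; `tidy()`/`glance()` give broom-style summaries.

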