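test_that("invalid configurations are rejected; empty is opt-in", {
  expect_error(sim_config(n_individuals = 1), "invalid config")
  expect_error(sim_config(n_individuals = 0), "invalid config")
  expect_error(sim_config(bout_length_mean = 0), "bout_length_mean")
  expect_error(sim_config(flock_membership_concentration = 1.2), "must be in")
  ew <- tibble::tibble(event = c("a", "b"),
                       start = as.Date(c("2015-11-01", "2015-11-10")),
                       end = as.Date(c("2015-11-20", "2015-11-30")))
  expect_error(sim_config(event_windows = ew), "non-overlapping")

  empty <- simulate_population(sim_config(n_individuals = 0, allow_empty = TRUE))
  expect_equal(nrow(empty$individuals), 0)
  expect_equal(nrow(empty$pedigree), 0)
})

test_that("the same seed reproduces every table byte-identically", {
  cfg <- sim_config(n_individuals = 25, seed = 42, event_windows = short_windows(2, 2))
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a, b)
  va <- simulate_visits(a$individuals, a$truth, cfg)
  vb <- simulate_visits(b$individuals, b$truth, cfg)
  expect_identical(va, vb)
  cpl <- fitness_coupling(beta_linear = 0.3, seed = 9)
  soc <- setNames(a$truth$true_sociality, a$truth$individual_id)
  fa <- simulate_fitness(a$individuals, soc, cpl)
  fb <- simulate_fitness(b$individuals, soc, cpl)
  expect_identical(fa, fb)
})

test_that("population structure satisfies the declared invariants", {
  cfg <- sim_config(n_individuals = 40, seed = 5, event_windows = short_windows())
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop$truth), nrow(pop$individuals)) # one truth row each
  expect_true(all(pop$individuals$sex %in% c(0, 1)))
  expect_gte(dplyr::n_distinct(pop$individuals$cohort), 3)
  # closed pedigree: validate_pedigree (acyclicity + referential) accepted it
  parents <- stats::na.omit(c(pop$pedigree$sire_id, pop$pedigree$dam_id))
  expect_true(all(parents %in% pop$pedigree$individual_id))
})

test_that("a single flock with full concentration shares one flock label", {
  cfg <- sim_config(n_individuals = 12, n_flocks = 1,
                    flock_membership_concentration = 1,
                    seed = 8, event_windows = short_windows(2, 2))
  pop <- simulate_population(cfg)
  expect_equal(dplyr::n_distinct(pop$truth$true_flock), 1)
})

test_that("zero jitter and one flock give identical co-arrival timestamps", {
  ew <- tibble::tibble(event = "e1", start = as.Date("2015-11-02"),
                       end = as.Date("2015-11-03"))
  cfg <- sim_config(n_individuals = 3, n_flocks = 1,
                    flock_membership_concentration = 1,
                    within_flock_arrival_jitter_sd = 0,
                    attendance_prob = 1, arrivals_per_flock_per_day = 1,
                    detection_interval_mean = 0,
                    event_windows = ew, seed = 10)
  pop <- simulate_population(cfg)
  v <- simulate_visits(pop$individuals, pop$truth, cfg)
  present <- pop$individuals$individual_id[
    pop$individuals$cohort <= 2015 &
      dplyr::coalesce(pop$individuals$death_year, Inf) >= 2015]
  arrivals_per_event <- split(v$timestamp, round(v$timestamp))
  # every flock arrival event produced simultaneous detections
  expect_true(all(vapply(arrivals_per_event, function(x) length(unique(x)) == 1,
                         logical(1))))
})

test_that("visit streams stay inside event windows and operating hours", {
  cfg <- sim_config(n_individuals = 15, seed = 6, event_windows = short_windows(2, 2))
  pop <- simulate_population(cfg)
  v <- simulate_visits(pop$individuals, pop$truth, cfg)
  s <- as.numeric(as.POSIXct(as.character(cfg$event_windows$start), tz = "UTC"))
  e <- as.numeric(as.POSIXct(as.character(cfg$event_windows$end), tz = "UTC"))
  in_win <- (v$timestamp >= s[1] & v$timestamp < e[1]) |
    (v$timestamp >= s[2] & v$timestamp < e[2])
  expect_true(all(in_win))
  hour <- (v$timestamp %% 86400) / 3600
  expect_true(all(hour >= 6)) # operating hours 06:00-24:00
})

test_that("truth records with unknown individuals are rejected", {
  cfg <- sim_config(n_individuals = 5, seed = 2, event_windows = short_windows(1, 1))
  pop <- simulate_population(cfg)
  bad_truth <- dplyr::bind_rows(pop$truth,
                                tibble::tibble(individual_id = "ghost",
                                               true_flock = "flock01",
                                               true_sociality = 0, true_icc = 0.3))
  expect_error(simulate_visits(pop$individuals, bad_truth, cfg), "ghost")
})

test_that("with zero concentration flockmates co-arrive no more than strangers", {
  # 200 simulated days, one event; tally co-arrivals within/between flocks
  ew <- tibble::tibble(event = "e1", start = as.Date("2015-11-02"),
                       end = as.Date("2015-11-02") + 200)
  cfg <- sim_config(n_individuals = 16, n_flocks = 4,
                    flock_membership_concentration = 0,
                    arrivals_per_flock_per_day = 2, attendance_prob = 0.5,
                    sociality_sd = 0, event_windows = ew, seed = 13)
  pop <- simulate_population(cfg)
  v <- simulate_visits(pop$individuals, pop$truth, cfg)
  arr <- detect_arrivals(slice_windows(v, cfg$event_windows))
  dc <- associate_arrivals(arr)
  flock <- setNames(pop$truth$true_flock, pop$truth$individual_id)
  same <- flock[dc$dyads$id_a] == flock[dc$dyads$id_b]
  # co-arrival counts split by flock membership: independence test
  ids <- unique(arr$individual_id)
  pairs <- t(utils::combn(ids, 2))
  pair_same <- flock[pairs[, 1]] == flock[pairs[, 2]]
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  x <- setNames(rep(0, nrow(pairs)), key)
  x[paste(dc$dyads$id_a, dc$dyads$id_b)] <- dc$dyads$x
  tab <- rbind(within = c(sum(x[pair_same]), sum(pair_same)),
               between = c(sum(x[!pair_same]), sum(!pair_same)))
  # rate per dyad should be indistinguishable: chi-square on total counts
  exp_within <- sum(x) * sum(pair_same) / nrow(pairs)
  chi <- stats::chisq.test(c(sum(x[pair_same]), sum(x[!pair_same])),
                           p = c(mean(pair_same), mean(!pair_same)))
  expect_gt(chi$p.value, 0.01)
})

test_that("flock structure is recoverable from the arrival-time network", {
  hits <- 0
  n_rep <- 10
  for (seed in seq_len(n_rep)) {
    ew <- tibble::tibble(event = "e1", start = as.Date("2015-11-02"),
                         end = as.Date("2015-11-02") + 14)
    cfg <- sim_config(n_individuals = 20, n_flocks = 4,
                      flock_membership_concentration = 0.9,
                      within_flock_arrival_jitter_sd = 20,
                      arrivals_per_flock_per_day = 3,
                      event_windows = ew, seed = 100 + seed)
    pop <- simulate_population(cfg)
    v <- simulate_visits(pop$individuals, pop$truth, cfg)
    arr <- detect_arrivals(slice_windows(v, cfg$event_windows))
    sri <- compute_sri(associate_arrivals(arr))
    flock <- setNames(pop$truth$true_flock, pop$truth$individual_id)
    # direct tally over ALL dyads of observed individuals (absent pairs = 0)
    ids <- sort(unique(arr$individual_id))
    pairs <- t(utils::combn(ids, 2))
    val <- setNames(rep(0, nrow(pairs)), paste(pairs[, 1], pairs[, 2]))
    val[paste(sri$id_a, sri$id_b)] <- sri$sri
    same <- flock[pairs[, 1]] == flock[pairs[, 2]]
    if (sum(same) > 0 && sum(!same) > 0 &&
        mean(val[same]) > mean(val[!same])) hits <- hits + 1
  }
  expect_gte(hits, ceiling(0.95 * n_rep))
})

test_that("uncoupled fitness recovers the baseline rate (law of large numbers)", {
  n <- 10000
  ind <- tibble::tibble(individual_id = sprintf("i%05d", 1:n),
                        sex = rep(0:1, n / 2), cohort = 2015)
  soc <- tibble::tibble(individual_id = ind$individual_id, sociality = rnorm(n))
  cpl <- fitness_coupling(baseline_log_rate = log(2), seed = 31)
  f <- simulate_fitness(ind, soc, cpl)
  se <- sqrt(2 / n)
  expect_lt(abs(mean(f$recruits) - 2), 3 * se)
})

test_that("a negative quadratic coupling peaks at -b1/(2 b2)", {
  cpl <- fitness_coupling(beta_linear = 0.3, beta_quadratic = -0.15, seed = 1)
  ind <- tibble::tibble(individual_id = c("a", "b", "c"), sex = 0, cohort = 2015)
  grid <- seq(-3, 3, by = 0.01)
  eta <- cpl$baseline_log_rate + cpl$beta_linear * grid + cpl$beta_quadratic * grid^2
  expect_equal(grid[which.max(eta)], -cpl$beta_linear / (2 * cpl$beta_quadratic),
               tolerance = 0.02)
})

test_that("non-finite sociality or predictors name the offending individual", {
  ind <- tibble::tibble(individual_id = c("a", "b"), sex = 0, cohort = 2015)
  soc <- tibble::tibble(individual_id = c("a", "b"), sociality = c(1, NaN))
  expect_error(simulate_fitness(ind, soc, fitness_coupling()), "b")
})

test_that("the weekly-trait generator hits its target ICC", {
  w <- simulate_weekly_centrality(300, 20, icc = 0.3, seed = 3)
  fit <- suppressMessages(lme4::lmer(value ~ 1 + (1 | individual_id), data = w))
  vc <- as.data.frame(lme4::VarCorr(fit))
  icc_hat <- vc$vcov[1] / sum(vc$vcov)
  expect_lt(abs(icc_hat - 0.3), 0.06)
})
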