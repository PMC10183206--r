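# Seeded synthetic data: a closed island passerine population with latent
# flock structure, RFID visit streams over two multi-week non-breeding
# events, a multi-generational pedigree with recruitment, and an optional
# coupling between sociality and expected fitness. Ground truth (flock
# membership, latent sociality, target ICC) is returned alongside so every
# downstream stage can be tested by parameter recovery.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: a closed population monitored at
#' one feeder over two non-breeding events of 15 and 13 weeks
#' (November-February), feeder operating 06:00-24:00 every day, flocks
#' arriving in bursts through the day.
#'
#' @param n_individuals Founding population size.
#' @param n_flocks Number of latent flocks.
#' @param flock_membership_concentration Probability an attending individual
#'   arrives together with its home flock (vs alone at a random time).
#' @param event_windows Tibble (`event`, `start`, `end`): ordered,
#'   non-overlapping calendar intervals (end exclusive).
#' @param arrivals_per_flock_per_day Poisson rate of flock arrival events
#'   per day.
#' @param within_flock_arrival_jitter_sd SD (seconds) of Normal jitter
#'   around the flock's arrival time.
#' @param bout_length_mean Mean feeding-bout length in seconds (exponential).
#' @param revisit_gap_mean Mean gap (seconds) an individual stays away
#'   before it can arrive again (exponential).
#' @param detection_interval_mean Mean gap between antenna detections
#'   within a bout, seconds.
#' @param attendance_prob Baseline probability that a flock member attends
#'   a given arrival event of its flock (1 = always).
#' @param sociality_sd Scale (logit) of the latent sociality effect on
#'   attendance; 0 decouples attendance from sociality.
#' @param target_icc Week-to-week repeatability of the latent
#'   attendance propensity (drives recoverable ICC in weekly centrality).
#' @param sex_ratio Probability an individual is male.
#' @param operating_hours Numeric length-2, feeder recording hours of day.
#' @param fecundity_mean Mean offspring per breeding pair per year.
#' @param juvenile_survival,adult_survival Annual survival probabilities
#'   (first year, and thereafter).
#' @param n_breeding_years Breeding years simulated after the first event.
#' @param allow_empty Permit `n_individuals = 0` (empty tables) instead of
#'   raising an invalid-config error.
#' @param seed Integer seed; fully determines all outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 60,
                       n_flocks = 6,
                       flock_membership_concentration = 0.9,
                       event_windows = default_event_windows(),
                       arrivals_per_flock_per_day = 6,
                       within_flock_arrival_jitter_sd = 15,
                       bout_length_mean = 60,
                       revisit_gap_mean = 600,
                       detection_interval_mean = 20,
                       attendance_prob = 0.6,
                       sociality_sd = 1,
                       target_icc = 0.3,
                       sex_ratio = 0.5,
                       operating_hours = c(6, 24),
                       fecundity_mean = 2,
                       juvenile_survival = 0.5,
                       adult_survival = 0.6,
                       n_breeding_years = 4,
                       allow_empty = FALSE,
                       seed = 1L) {
  cfg <- list(n_individuals = n_individuals, n_flocks = n_flocks,
              flock_membership_concentration = flock_membership_concentration,
              event_windows = tibble::as_tibble(event_windows),
              arrivals_per_flock_per_day = arrivals_per_flock_per_day,
              within_flock_arrival_jitter_sd = within_flock_arrival_jitter_sd,
              bout_length_mean = bout_length_mean,
              revisit_gap_mean = revisit_gap_mean,
              detection_interval_mean = detection_interval_mean,
              attendance_prob = attendance_prob, sociality_sd = sociality_sd,
              target_icc = target_icc, sex_ratio = sex_ratio,
              operating_hours = operating_hours,
              fecundity_mean = fecundity_mean,
              juvenile_survival = juvenile_survival,
              adult_survival = adult_survival,
              n_breeding_years = n_breeding_years,
              allow_empty = allow_empty, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (nm in c("arrivals_per_flock_per_day", "within_flock_arrival_jitter_sd",
               "detection_interval_mean")) {
    check_scalar_number(cfg[[nm]], nm, 0)
  }
  for (nm in c("bout_length_mean", "revisit_gap_mean")) {
    check_scalar_number(cfg[[nm]], nm, 0, strict_min = TRUE)
  }
  for (nm in c("flock_membership_concentration", "sex_ratio", "target_icc")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) abort(glue::glue("`{nm}` must be in [0, 1]"))
  }
  ew <- cfg$event_windows
  if (nrow(ew) > 0) {
    s <- date_seconds(ew$start); e <- date_seconds(ew$end)
    if (any(e <= s)) abort("event windows must have end after start")
    if (is.unsorted(s) || any(utils::head(e, -1) > utils::tail(s, -1))) {
      abort("event windows must be ordered and non-overlapping")
    }
  }
  if (cfg$n_individuals == 0 && !cfg$allow_empty) {
    abort("invalid config: n_individuals = 0 (set allow_empty = TRUE for empty tables)")
  }
  if (cfg$n_individuals %in% 1) abort("invalid config: n_individuals must be >= 2")
  invisible(cfg)
}

#' @rdname sim_config
#' @export
default_event_windows <- function() {
  tibble::tibble(event = c("2015/16", "2016/17"),
                 start = as.Date(c("2015-11-02", "2016-11-07")),
                 end = as.Date(c("2016-02-15", "2017-02-06")))
}

#' Round-trip a simulation configuration through YAML
#'
#' @param config A `sim_config`.
#' @param path YAML file path.
#' @return `read_sim_config()` returns the reconstructed `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$event_windows <- purrr::pmap(x$event_windows, function(event, start, end) {
    list(event = as.character(event), start = as.character(start),
         end = as.character(end))
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$event_windows <- purrr::map_dfr(x$event_windows, function(w) {
    tibble::tibble(event = w$event, start = as.Date(w$start), end = as.Date(w$end))
  })
  do.call(sim_config, x)
}

#' Simulate a closed population with pedigree and ground truth
#'
#' Founders are spread over the four cohorts up to the first event year;
#' subsequent breeding years pair surviving males and females at random,
#' draw Poisson offspring per pair, and apply first-year and adult annual
#' survival, yielding a closed multi-generation pedigree (every named
#' parent is a row) with recruitment. Each individual receives a latent
#' flock, a latent sociality (standard normal), and the target week-to-week
#' ICC of its attendance propensity.
#'
#' @param config A [sim_config()].
#' @return A list with tibbles `individuals`, `pedigree`, `truth`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_individuals == 0) {
    return(list(
      individuals = tibble::tibble(individual_id = character(), tag_id = character(),
                                   sex = numeric(), cohort = numeric(),
                                   death_year = numeric(), first_tagged = as.Date(character())),
      pedigree = tibble::tibble(individual_id = character(), sire_id = character(),
                                dam_id = character(), cohort = numeric(),
                                founder = logical()),
      truth = tibble::tibble(individual_id = character(), true_flock = character(),
                             true_sociality = numeric(), true_icc = numeric())))
  }
  set.seed(config$seed)
  first_year <- as.integer(format(min(as.Date(config$event_windows$start)), "%Y"))
  founder_cohorts <- (first_year - 3):first_year
  breeding_years <- (first_year + 1):(first_year + config$n_breeding_years)
  last_year <- max(breeding_years) + 1

  n <- config$n_individuals
  ids <- sprintf("id%04d", seq_len(n))
  cohort <- sort(sample(founder_cohorts, n, replace = TRUE))
  sex <- rbinom(n, 1, config$sex_ratio)
  rows <- tibble::tibble(individual_id = ids, sire_id = NA_character_,
                         dam_id = NA_character_, cohort = as.numeric(cohort),
                         sex = as.numeric(sex))
  next_id <- n + 1L
  for (year in breeding_years) {
    death_tmp <- draw_death_years(rows, first_year, last_year, config) # provisional == final
    alive <- rows$cohort < year & death_tmp >= year
    males <- rows$individual_id[alive & rows$sex == 1]
    females <- rows$individual_id[alive & rows$sex == 0]
    n_pairs <- min(length(males), length(females))
    if (n_pairs == 0) next
    sires <- sample(males, n_pairs)
    dams <- sample(females, n_pairs)
    n_off <- rpois(n_pairs, config$fecundity_mean)
    if (sum(n_off) == 0) next
    off <- tibble::tibble(
      individual_id = sprintf("id%04d", seq.int(next_id, next_id + sum(n_off) - 1L)),
      sire_id = rep(sires, n_off), dam_id = rep(dams, n_off),
      cohort = as.numeric(year),
      sex = as.numeric(rbinom(sum(n_off), 1, config$sex_ratio)))
    next_id <- next_id + sum(n_off)
    rows <- dplyr::bind_rows(rows, off)
  }
  rows$death_year <- draw_death_years(rows, first_year, last_year, config)

  individuals <- rows |>
    dplyr::transmute(individual_id = .data$individual_id,
                     tag_id = .data$individual_id,
                     sex = .data$sex, cohort = .data$cohort,
                     death_year = .data$death_year,
                     first_tagged = as.Date(sprintf("%d-07-01", .data$cohort))) |>
    validate_individuals()
  pedigree <- rows |>
    dplyr::select("individual_id", "sire_id", "dam_id", "cohort") |>
    validate_pedigree()
  truth <- tibble::tibble(
    individual_id = rows$individual_id,
    true_flock = sprintf("flock%02d", sample.int(config$n_flocks, nrow(rows),
                                                 replace = TRUE)),
    true_sociality = rnorm(nrow(rows)),
    true_icc = config$target_icc)
  list(individuals = individuals, pedigree = pedigree, truth = truth)
}

# Deterministic per-individual death year given the seed stream: survival
# through each April census, first-year then adult annual probability.
# Founders are the standing population at the study start, so their
# survival clock is conditioned on being alive in the first event year.
# Uses each individual's own RNG substream keyed by its index so that death
# years are reproducible regardless of when in the simulation they are
# needed (provisional draws during breeding equal the final draws).
draw_death_years <- function(rows, first_year, last_year, config) {
  founder <- is.na(rows$sire_id) & is.na(rows$dam_id)
  vapply(seq_len(nrow(rows)), function(i) {
    set.seed(config$seed + 7919L * i)
    if (founder[i]) {
      y <- first_year
    } else {
      y <- rows$cohort[i]
      if (runif(1) > config$juvenile_survival) return(y)
      y <- y + 1
    }
    while (y < last_year && runif(1) < config$adult_survival) y <- y + 1
    y
  }, numeric(1))
}

#' Simulate RFID visit streams with latent flock structure
#'
#' Flock arrival events follow a Poisson process through each feeder
#' operating day inside every event window. Attending flock members arrive
#' together (Normal jitter around the flock time) with probability
#' `flock_membership_concentration`, otherwise alone at a random time of
#' day. Attendance probability varies by individual and week through a
#' latent propensity with between-individual share `target_icc`, so weekly
#' centrality is individually repeatable by construction. Each arrival
#' spawns a bout of detections; re-arrival is blocked until an exponential
#' revisit gap has passed.
#'
#' @param individuals,truth From [simulate_population()].
#' @param config The same [sim_config()].
#' @return A visit-log tibble (`timestamp`, `tag_id`, `antenna_id`).
#' @export
simulate_visits <- function(individuals, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  unknown <- setdiff(truth$individual_id, individuals$individual_id)
  if (length(unknown) > 0) {
    abort(glue::glue("truth records for unknown individual(s): {unknown[1]}"))
  }
  if (nrow(config$event_windows) == 0) abort("event_windows must be non-empty")
  set.seed(config$seed + 1L)
  soc <- setNames(truth$true_sociality, truth$individual_id)
  flock <- setNames(truth$true_flock, truth$individual_id)
  icc <- config$target_icc
  hours <- config$operating_hours
  all_arrivals <- list()
  for (k in seq_len(nrow(config$event_windows))) {
    ev <- config$event_windows[k, ]
    ev_year <- as.integer(format(as.Date(ev$end), "%Y"))
    present <- individuals$cohort <= as.integer(format(as.Date(ev$start), "%Y")) &
      dplyr::coalesce(individuals$death_year, Inf) >= ev_year
    members <- individuals$individual_id[present]
    if (length(members) == 0) next
    t0 <- date_seconds(ev$start)
    n_days <- as.integer(as.Date(ev$end) - as.Date(ev$start))
    flocks <- sort(unique(flock[members]))
    # week-specific attendance propensity, between-individual share = icc
    n_weeks <- ceiling(n_days / 7)
    zi <- sqrt(icc) * soc[members]
    zw <- matrix(rnorm(length(members) * n_weeks, 0, sqrt(1 - icc)),
                 nrow = length(members))
    for (day in seq_len(n_days) - 1L) {
      week <- 1L + day %/% 7L
      day0 <- t0 + day * DAY
      for (f in flocks) {
        n_events <- rpois(1, config$arrivals_per_flock_per_day)
        if (n_events == 0) next
        f_members <- members[flock[members] == f]
        t_events <- day0 + runif(n_events, hours[1] * 3600, hours[2] * 3600)
        for (te in t_events) {
          z <- zi[match(f_members, members)] +
            zw[cbind(match(f_members, members), week)]
          p <- if (config$attendance_prob >= 1) rep(1, length(f_members)) else {
            plogis(qlogis(config$attendance_prob) + config$sociality_sd * z)
          }
          going <- f_members[runif(length(f_members)) < p]
          if (length(going) == 0) next
          with_flock <- runif(length(going)) < config$flock_membership_concentration
          t_arr <- numeric(length(going))
          t_arr[with_flock] <- pmin(pmax(
            te + rnorm(sum(with_flock), 0, config$within_flock_arrival_jitter_sd),
            day0 + hours[1] * 3600), day0 + hours[2] * 3600 - 1)
          t_arr[!with_flock] <- day0 + runif(sum(!with_flock), hours[1] * 3600,
                                             hours[2] * 3600)
          all_arrivals[[length(all_arrivals) + 1L]] <-
            tibble::tibble(individual_id = going, t = t_arr)
        }
      }
    }
  }
  if (length(all_arrivals) == 0) {
    return(tibble::tibble(timestamp = numeric(), tag_id = character(),
                          antenna_id = character()))
  }
  arr <- dplyr::arrange(dplyr::bind_rows(all_arrivals), .data$t)
  # enforce revisit gaps and expand arrivals into detection bouts
  detections <- arr |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::group_map(function(d, key) {
      id <- key$individual_id
      keep_t <- numeric(0)
      ends <- numeric(0)
      cur_end <- -Inf
      for (t in d$t) {
        if (t <= cur_end + rexp(1, 1 / config$revisit_gap_mean)) next
        len <- rexp(1, 1 / config$bout_length_mean)
        keep_t <- c(keep_t, t)
        ends <- c(ends, t + len)
        cur_end <- t + len
      }
      if (length(keep_t) == 0) return(NULL)
      purrr::map2_dfr(keep_t, ends, function(t, e) {
        ts <- t
        while (utils::tail(ts, 1) < e) {
          gap <- if (config$detection_interval_mean > 0) {
            rexp(1, 1 / config$detection_interval_mean)
          } else break
          nxt <- utils::tail(ts, 1) + gap
          if (nxt > e) break
          ts <- c(ts, nxt)
        }
        tibble::tibble(timestamp = ts, tag_id = id, antenna_id = "A1")
      })
    }) |>
    dplyr::bind_rows()
  # bouts never extend past the feeder's recording day or the event window
  win_s <- date_seconds(config$event_windows$start)
  win_e <- date_seconds(config$event_windows$end)
  in_window <- Reduce(`|`, lapply(seq_along(win_s), function(k) {
    detections$timestamp >= win_s[k] & detections$timestamp < win_e[k]
  }))
  hod <- (detections$timestamp %% DAY) / 3600
  detections <- detections[in_window & hod >= hours[1] &
                             (hod < hours[2] | hours[2] >= 24), ]
  dplyr::arrange(detections, .data$timestamp, .data$tag_id)
}

#' Fitness-coupling configuration
#'
#' Parameters of the generative sociality-to-fitness link used by
#' [simulate_fitness()]: a log-linear (Poisson recruits) or identity-link
#' (Gaussian de-lifed) model with linear and quadratic sociality terms and
#' sex/age covariates.
#'
#' @param beta_linear,beta_quadratic,beta_sex,beta_age Coefficients.
#' @param baseline_log_rate Intercept (log scale for the Poisson family).
#' @param family `"poisson_recruits"` or `"gaussian_delifed"`.
#' @param sigma Residual SD for the Gaussian family.
#' @param seed Integer seed.
#' @export
fitness_coupling <- function(beta_linear = 0, beta_quadratic = 0, beta_sex = 0,
                             beta_age = 0, baseline_log_rate = log(2),
                             family = c("poisson_recruits", "gaussian_delifed"),
                             sigma = 1, seed = 1L) {
  family <- match.arg(family)
  structure(list(beta_linear = beta_linear, beta_quadratic = beta_quadratic,
                 beta_sex = beta_sex, beta_age = beta_age,
                 baseline_log_rate = baseline_log_rate, family = family,
                 sigma = sigma, seed = as.integer(seed)),
            class = "fitness_coupling")
}

#' Simulate fitness coupled to sociality
#'
#' Draws per-individual fitness from the coupling model
#' `eta = baseline + b1 c + b2 c^2 + b_sex sex + b_age age`:
#' `recruits ~ Poisson(exp(eta))` for the Poisson family, or
#' `value ~ Normal(eta, sigma)` for the Gaussian (de-lifed) family.
#'
#' @param individuals Individual metadata (`individual_id`, `sex`, `cohort`).
#' @param sociality Tibble (`individual_id`, `sociality`) or named numeric
#'   vector of the sociality measure `c`.
#' @param coupling A [fitness_coupling()].
#' @param year Breeding year used to compute age (`year - cohort`);
#'   required when `beta_age != 0`.
#' @return A tibble (`individual_id`, `sociality`, `eta`, and `recruits`
#'   or `delifed`).
#' @export
simulate_fitness <- function(individuals, sociality, coupling, year = NULL) {
  stopifnot(inherits(coupling, "fitness_coupling"))
  if (is.numeric(sociality) && !is.null(names(sociality))) {
    sociality <- tibble::tibble(individual_id = names(sociality),
                                sociality = unname(sociality))
  }
  d <- dplyr::inner_join(
    dplyr::select(individuals, "individual_id", "sex", "cohort"),
    sociality, by = "individual_id")
  if (any(!is.finite(d$sociality))) {
    abort(glue::glue(
      "non-finite sociality for {d$individual_id[which(!is.finite(d$sociality))[1]]}"))
  }
  age <- if (!is.null(year)) year - d$cohort else {
    if (coupling$beta_age != 0) abort("`year` needed when beta_age != 0") else 0
  }
  eta <- coupling$baseline_log_rate + coupling$beta_linear * d$sociality +
    coupling$beta_quadratic * d$sociality^2 + coupling$beta_sex * d$sex +
    coupling$beta_age * age
  if (any(!is.finite(eta))) {
    abort(glue::glue(
      "non-finite linear predictor for {d$individual_id[which(!is.finite(eta))[1]]}"))
  }
  set.seed(coupling$seed)
  out <- tibble::tibble(individual_id = d$individual_id,
                        sociality = d$sociality, eta = eta)
  if (coupling$family == "poisson_recruits") {
    out$recruits <- rpois(nrow(d), exp(eta))
  } else {
    out$delifed <- rnorm(nrow(d), eta, coupling$sigma)
  }
  out
}

#' Simulate weekly centrality with a known ICC
#'
#' Direct Gaussian generator for repeatability-recovery experiments:
#' `y_iw = mean + sd * (sqrt(icc) a_i + sqrt(1 - icc) e_iw)` with
#' `a_i, e_iw ~ N(0, 1)`, so the between-individual variance share is
#' exactly `icc`.
#'
#' @param n_individuals,n_weeks Design size.
#' @param icc Target intraclass correlation in `[0, 1]`.
#' @param mean,sd Affine scale of the trait.
#' @param seed Integer seed.
#' @return A tibble (`individual_id`, `week`, `value`).
#' @export
simulate_weekly_centrality <- function(n_individuals, n_weeks, icc,
                                       mean = 0, sd = 1, seed = 1L) {
  if (icc < 0 || icc > 1) abort("icc must be in [0, 1]")
  set.seed(seed)
  a <- rnorm(n_individuals)
  tidyr::expand_grid(individual_id = sprintf("id%04d", seq_len(n_individuals)),
                     week = seq_len(n_weeks)) |>
    dplyr::mutate(value = mean + sd * (sqrt(icc) * a[match(.data$individual_id,
                                                           sprintf("id%04d", seq_len(n_individuals)))] +
                                         sqrt(1 - icc) * rnorm(dplyr::n())))
}
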