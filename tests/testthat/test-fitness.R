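# Small hand-built population used by several tests: ten adults of cohort
# 2015 that all survive to 2017; one focal bird (f) with two offspring born
# 2016 who both survive, so N_2016 = 10, N_2017 = 12, w = 1.2.
worked_population <- function() {
  ind <- tibble::tibble(
    individual_id = c(sprintf("a%02d", 1:9), "f", "k1", "k2"),
    sex = c(rep(c(0, 1), length.out = 9), 1, 0, 1),
    cohort = c(rep(2015, 10), 2016, 2016),
    death_year = c(rep(2018, 10), 2018, 2018))
  ped <- tibble::tibble(
    individual_id = ind$individual_id,
    sire_id = c(rep(NA, 10), "f", "f"),
    dam_id = c(rep(NA, 10), "a01", "a01"),
    cohort = ind$cohort)
  list(individuals = ind, pedigree = ped)
}

test_that("recruits are parents, applied recursively down a chain", {
  ped <- tibble::tibble(individual_id = c("A", "B", "C"),
                        sire_id = c(NA, "A", "B"), dam_id = NA_character_,
                        cohort = c(2000, 2001, 2002))
  r <- identify_recruits(ped)
  expect_equal(r$recruit, c(TRUE, TRUE, FALSE)) # C has no offspring
  # stable under row order, idempotent
  r2 <- identify_recruits(identify_recruits(ped[3:1, ]))
  expect_equal(r2$recruit[r2$individual_id == "B"], TRUE)
})

test_that("the census counts individuals alive on April 1", {
  ind <- tibble::tibble(individual_id = letters[1:4], sex = 0,
                        cohort = c(2014, 2015, 2016, 2014),
                        death_year = c(2015, 2018, 2018, NA))
  cen <- build_census(ind, 2016)
  # brute-force scan: born before 2016 and death_year >= 2016 (NA = alive)
  expect_equal(cen$n_t, sum(ind$cohort < 2016 &
                              dplyr::coalesce(ind$death_year, Inf) >= 2016))
  expect_equal(cen$n_t, 2)
  expect_equal(cen$w_t, cen$n_t1 / cen$n_t, tolerance = 1e-12)
})

test_that("annual recruits count recruiting offspring and apply exclusions", {
  pop <- worked_population()
  # make k1 itself a parent so it is a recruit; k2 stays childless.
  # g1 (k1's 2017 offspring) gets a 2018 offspring so g1 is also a recruit.
  ped <- dplyr::bind_rows(pop$pedigree,
                          tibble::tibble(individual_id = c("g1", "h1"),
                                         sire_id = NA,
                                         dam_id = c("k1", "g1"),
                                         cohort = c(2017, 2018)))
  ind <- dplyr::bind_rows(pop$individuals,
                          tibble::tibble(individual_id = c("g1", "h1"), sex = 0,
                                         cohort = c(2017, 2018),
                                         death_year = c(2018, 2018)))
  rec <- annual_recruits(ped, ind, 2016)
  expect_equal(rec$annual_recruits[rec$individual_id == "f"], 1L) # k1 only

  # a bird dead before the breeding season is an absent row, not a zero
  ind2 <- dplyr::mutate(ind, death_year = ifelse(individual_id == "a05",
                                                 2015, death_year))
  rec2 <- annual_recruits(ped, ind2, 2016)
  expect_false("a05" %in% rec2$individual_id)

  # yearlings with zero recruits are excluded
  rec3 <- annual_recruits(ped, ind, 2017)
  expect_false("k2" %in% rec3$individual_id) # age 1, no recruits
  expect_true("k1" %in% rec3$individual_id)  # age 1 but recruited g1
})

test_that("de-lifing matches the hand-worked contribution", {
  pop <- worked_population()
  cen <- build_census(pop$individuals, 2016)
  expect_equal(cen$w_t, 1.2)
  p <- delifed_annual(pop$pedigree, cen, pop$individuals, 2016,
                      offspring_share = 0.5)
  # focal: xi = 0.5 * 2 + 1 = 2 -> (2 - 1.2) / 9
  expect_equal(p$p_ti[p$individual_id == "f"], (2 - 1.2) / 9, tolerance = 1e-9)
  expect_equal(round(p$p_ti[p$individual_id == "f"], 4), 0.0889)
  # a bird with xi exactly w_t would contribute zero
  expect_equal(((1.2 - cen$w_t) / 9), 0)
})

test_that("annual contributions sum to zero in a closed censused population", {
  for (seed in 1:10) {
    cfg <- sim_config(n_individuals = 30, seed = seed,
                      event_windows = short_windows())
    pop <- simulate_population(cfg)
    years <- 2016:2019
    cen <- build_census(pop$individuals, years)
    for (y in years[cen$n_t >= 2]) {
      p <- delifed_annual(pop$pedigree, cen, pop$individuals, y,
                          offspring_share = 0.5)
      expect_lt(abs(sum(p$p_ti)), 1e-10)
    }
  }
})

test_that("lifetime de-lifed fitness sums annual values exactly", {
  ann <- tibble::tibble(individual_id = c("a", "a", "b"),
                        p_ti = c(0.1, -0.05, 0.2))
  life <- delifed_lifetime(ann)
  expect_equal(life$p_i[life$individual_id == "a"], 0.05)
  expect_equal(life$p_i[life$individual_id == "b"], 0.2)

  cfg <- sim_config(n_individuals = 30, seed = 4, event_windows = short_windows())
  pop <- simulate_population(cfg)
  years <- 2016:2019
  cen <- build_census(pop$individuals, years)
  ok_years <- years[cen$n_t >= 2]
  ann2 <- purrr::map_dfr(ok_years,
                         ~delifed_annual(pop$pedigree, cen, pop$individuals, .x))
  life2 <- delifed_lifetime(ann2)
  expect_lt(abs(sum(life2$p_i)), 1e-10) # identity extends across years
  expect_equal(sum(life2$p_i), sum(ann2$p_ti), tolerance = 1e-12)
})

test_that("the fitness table reconciles annual and lifetime aggregates", {
  cfg <- sim_config(n_individuals = 30, seed = 2, event_windows = short_windows())
  pop <- simulate_population(cfg)
  years <- 2016:2017
  cen <- build_census(pop$individuals, years)
  ft <- fitness_table(pop$pedigree, pop$individuals, cen, years,
                      apply_exclusions = FALSE)
  # lifetime recruits >= the recruits counted in any single covered year
  expect_true(all(ft$lifetime_recruits >= ft$annual_recruits, na.rm = TRUE))
  expect_true(all(c("sex", "age", "lifespan") %in% names(ft)))

  # the delifed output filter blanks values without changing computation
  ft2 <- fitness_table(pop$pedigree, pop$individuals, cen, years,
                       apply_exclusions = FALSE, delifed_filter = TRUE)
  has <- ft2$lifetime_recruits >= 1 & !is.na(ft2$p_ti)
  expect_equal(ft2$p_ti[has], ft$p_ti[has])
  expect_true(all(is.na(ft2$p_ti[ft2$lifetime_recruits == 0])))
})

test_that("de-lifing errors on degenerate censuses", {
  ind <- tibble::tibble(individual_id = "a", sex = 0, cohort = 2015,
                        death_year = 2018)
  cen <- build_census(ind, 2016)
  ped <- tibble::tibble(individual_id = "a", sire_id = NA_character_,
                        dam_id = NA_character_, cohort = 2015)
  expect_error(delifed_annual(ped, cen, ind, 2016), "N_t")
})
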