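# Pedigree-based fitness: recruits and de-lifed individual contributions to
# population growth. A "recruit" is an offspring that survived and itself
# produced genetic offspring. De-lifing removes an individual and its
# offspring from the pedigree and measures the resulting change in realized
# population growth: p_ti = (xi_t(i) - w_t) / (N_t - 1), where xi_t(i) is
# the individual's performance in year t (its surviving offspring that year,
# plus 1 if it survived itself) and w_t = N_{t+1} / N_t.

#' Flag recruits in a pedigree
#'
#' An individual is a recruit if it appears as sire or dam of at least one
#' pedigree member, i.e. it survived to produce genetic offspring itself.
#' Stable under row order and idempotent.
#'
#' @param pedigree A pedigree tibble ([read_pedigree()] or
#'   [simulate_population()]).
#' @return The pedigree with a logical `recruit` column.
#' @export
identify_recruits <- function(pedigree) {
  parents <- unique(stats::na.omit(c(pedigree$sire_id, pedigree$dam_id)))
  dplyr::mutate(pedigree, recruit = .data$individual_id %in% parents)
}

# Alive at the census (April 1) of year t: born in an earlier year and not
# yet dead. death_year is the last year the bird was alive on April 1.
alive_at <- function(individuals, year) {
  dy <- ifelse(is.na(individuals$death_year), Inf, individuals$death_year)
  individuals$cohort < year & dy >= year
}

#' Build an April-census table
#'
#' `N_t` counts individuals alive at the start of the breeding cycle
#' (April 1) of year `t`: born in an earlier cohort with `death_year >= t`.
#' `w_t = N_{t+1} / N_t` is the realized population growth rate.
#'
#' @param individuals Individual metadata (`cohort`, `death_year`).
#' @param years Integer vector of census years `t`.
#' @return A tibble (`year`, `n_t`, `n_t1`, `w_t`).
#' @export
build_census <- function(individuals, years) {
  purrr::map_dfr(years, function(y) {
    n_t <- sum(alive_at(individuals, y))
    n_t1 <- sum(alive_at(individuals, y + 1))
    tibble::tibble(year = y, n_t = n_t, n_t1 = n_t1,
                   w_t = ifelse(n_t > 0, n_t1 / n_t, NA_real_))
  })
}

#' Annual recruit counts per parent
#'
#' For each parent, counts its offspring born in breeding year `year` that
#' are themselves recruits (produced genetic offspring). Applies the
#' analysis exclusions: birds that did not survive to the breeding season
#' of `year` are excluded (absent rows, not zeros), as are yearlings (age
#' 1 in `year`) with zero recruits.
#'
#' @param pedigree Pedigree tibble.
#' @param individuals Individual metadata.
#' @param year Breeding year.
#' @param apply_exclusions Set `FALSE` to keep all censused parents.
#' @return A tibble (`individual_id`, `year`, `annual_recruits`).
#' @export
annual_recruits <- function(pedigree, individuals, year, apply_exclusions = TRUE) {
  if (year < min(pedigree$cohort) || year > max(pedigree$cohort)) {
    warn(glue::glue("year {year} outside pedigree span"))
    return(tibble::tibble(individual_id = character(), year = integer(),
                          annual_recruits = integer()))
  }
  ped <- identify_recruits(pedigree)
  born <- dplyr::filter(ped, .data$cohort == year, .data$recruit)
  by_parent <- tibble::tibble(parent = c(born$sire_id, born$dam_id)) |>
    dplyr::filter(!is.na(.data$parent)) |>
    dplyr::count(.data$parent, name = "annual_recruits")
  out <- individuals |>
    dplyr::filter(alive_at(individuals, year)) |>
    dplyr::transmute(individual_id = .data$individual_id, year = year,
                     age = year - .data$cohort) |>
    dplyr::left_join(by_parent, by = c(individual_id = "parent")) |>
    dplyr::mutate(annual_recruits = dplyr::coalesce(.data$annual_recruits, 0L))
  if (apply_exclusions) {
    out <- dplyr::filter(out, !(.data$age == 1 & .data$annual_recruits == 0))
  }
  dplyr::select(out, "individual_id", "year", "annual_recruits")
}

#' Annual de-lifed fitness
#'
#' Computes `p_ti = (xi_t(i) - w_t) / (N_t - 1)` for every individual in
#' the April census of year `t`. Individual performance `xi_t(i)` is
#' `offspring_share` times the number of the individual's offspring born in
#' year `t` that survived to the next census, plus 1 if the individual
#' itself survived to `t + 1`. With `offspring_share = 0.5` (each offspring
#' split between its two genetic parents) and a fully censused closed
#' population the contributions satisfy `sum_i p_ti = 0` exactly each year.
#'
#' @param pedigree Pedigree tibble.
#' @param census Census table from [build_census()].
#' @param individuals Individual metadata.
#' @param year Breeding year `t`.
#' @param offspring_share 0.5 (default; split between parents) or 1.0.
#' @return A tibble (`individual_id`, `year`, `xi`, `p_ti`, `survived`).
#' @export
delifed_annual <- function(pedigree, census, individuals, year,
                           offspring_share = 0.5) {
  if (!offspring_share %in% c(0.5, 1.0)) abort("offspring_share must be 0.5 or 1.0")
  row <- dplyr::filter(census, .data$year == !!year)
  if (nrow(row) != 1) abort(glue::glue("census has no row for year {year}"))
  if (row$n_t < 2) abort(glue::glue("N_t = {row$n_t} in {year}: de-lifing needs N_t >= 2"))
  w_t <- row$w_t
  dy <- ifelse(is.na(individuals$death_year), Inf, individuals$death_year)
  surv_lookup <- setNames(dy >= year + 1, individuals$individual_id)
  off <- dplyr::filter(pedigree, .data$cohort == year,
                       surv_lookup[.data$individual_id])
  by_parent <- tibble::tibble(parent = c(off$sire_id, off$dam_id)) |>
    dplyr::filter(!is.na(.data$parent)) |>
    dplyr::count(.data$parent, name = "n_surviving_offspring")
  individuals |>
    dplyr::filter(alive_at(individuals, year)) |>
    dplyr::transmute(individual_id = .data$individual_id, year = year,
                     survived = unname(surv_lookup[.data$individual_id])) |>
    dplyr::left_join(by_parent, by = c(individual_id = "parent")) |>
    dplyr::mutate(
      n_surviving_offspring = dplyr::coalesce(.data$n_surviving_offspring, 0L),
      xi = offspring_share * .data$n_surviving_offspring + as.numeric(.data$survived),
      p_ti = (.data$xi - w_t) / (row$n_t - 1)) |>
    dplyr::select("individual_id", "year", "xi", "p_ti", "survived")
}

#' Lifetime de-lifed fitness
#'
#' Sums annual contributions within individuals: `p_i = sum_t p_ti`.
#'
#' @param annual A tibble of annual rows (`individual_id`, `p_ti`), e.g.
#'   several years of [delifed_annual()] bound together.
#' @return A tibble (`individual_id`, `p_i`, `n_years`).
#' @export
delifed_lifetime <- function(annual) {
  annual |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(p_i = sum(.data$p_ti), n_years = dplyr::n(), .groups = "drop")
}

#' Assemble the annual + lifetime fitness table
#'
#' Runs [annual_recruits()] and [delifed_annual()] over `years`, then
#' aggregates lifetime recruits (summed across all pedigree years up to
#' `censor_year`) and lifetime de-lifed fitness. Following the analysis
#' convention, the de-lifed columns can be restricted to birds that
#' produced at least one recruit (`delifed_filter = TRUE`); this is an
#' output filter only and never changes the computed values.
#'
#' @param pedigree,individuals,census As elsewhere.
#' @param years Breeding years covered by the social events.
#' @param offspring_share Passed to [delifed_annual()].
#' @param apply_exclusions Passed to [annual_recruits()].
#' @param censor_year Final year counted towards lifetime recruits
#'   (default: the last pedigree cohort).
#' @param delifed_filter Restrict de-lifed values to birds with >= 1
#'   lifetime recruit.
#' @return A tibble, one row per individual-year, with `annual_recruits`,
#'   `p_ti`, `lifetime_recruits`, `p_i`, `lifespan`, `sex`, `age`.
#' @export
fitness_table <- function(pedigree, individuals, census, years,
                          offspring_share = 0.5, apply_exclusions = TRUE,
                          censor_year = max(pedigree$cohort),
                          delifed_filter = FALSE) {
  rec <- purrr::map_dfr(years, ~annual_recruits(pedigree, individuals, .x,
                                                apply_exclusions = apply_exclusions))
  del <- purrr::map_dfr(years, ~delifed_annual(pedigree, census, individuals, .x,
                                               offspring_share = offspring_share))
  ped_r <- identify_recruits(pedigree)
  recruits_set <- ped_r$individual_id[ped_r$recruit]
  life_rec <- pedigree |>
    dplyr::filter(.data$cohort <= censor_year,
                  .data$individual_id %in% recruits_set) |>
    (\(born) tibble::tibble(parent = c(born$sire_id, born$dam_id)))() |>
    dplyr::filter(!is.na(.data$parent)) |>
    dplyr::count(.data$parent, name = "lifetime_recruits")
  life_del <- delifed_lifetime(del)
  out <- rec |>
    dplyr::full_join(dplyr::select(del, "individual_id", "year", "p_ti"),
                     by = c("individual_id", "year")) |>
    dplyr::left_join(life_rec, by = c(individual_id = "parent")) |>
    dplyr::left_join(dplyr::select(life_del, "individual_id", "p_i"),
                     by = "individual_id") |>
    dplyr::mutate(lifetime_recruits = dplyr::coalesce(.data$lifetime_recruits, 0L)) |>
    dplyr::left_join(dplyr::select(individuals, "individual_id", "sex", "cohort",
                                   "death_year"),
                     by = "individual_id") |>
    dplyr::mutate(
      age = .data$year - .data$cohort,
      lifespan = pmin(dplyr::coalesce(.data$death_year, Inf), censor_year + 1) -
        .data$cohort) |>
    dplyr::select(-"death_year")
  if (delifed_filter) {
    out <- dplyr::mutate(out, dplyr::across(
      c("p_ti", "p_i"),
      ~ifelse(.data$lifetime_recruits >= 1, .x, NA_real_)))
  }
  tibble::as_tibble(out)
}
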