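# End-to-end orchestration: simulate (or load) -> slice -> arrivals ->
# networks -> fitness -> repeatability -> selection -> null models, driven
# by one configuration list (or YAML file) and one global seed, with a run
# manifest recording config hash, seed, versions and per-stage row counts.

#' Run the full analysis pipeline
#'
#' @param config A list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{simulation}{arguments for [sim_config()] (simulated-input
#'       mode), or}
#'     \item{paths}{list with `visits`, `individuals`, `pedigree` CSV paths
#'       and `event_windows` (tibble or list of event/start/end); exactly
#'       one of `simulation` / `paths` must be present}
#'     \item{arrival}{`delta_t`, `delta_i` (optional)}
#'     \item{mcmc}{arguments for [mcmc_config()] (optional; defaults to
#'       [mcmc_config_short()])}
#'     \item{permutation}{`n_permutations`, `scope` (optional)}
#'     \item{selection}{`measures`, `responses` (optional)}
#'     \item{seed}{global seed (default 1)}
#'   }
#' @param out_dir Optional directory; stage outputs are written as CSVs and
#'   the manifest as JSON.
#' @param run_null Recompute modal null centralities and refit the
#'   selection models on them (`TRUE` by default; the slowest stage).
#' @return A list of stage outputs plus `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, run_null = TRUE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  has_sim <- !is.null(config$simulation)
  has_paths <- !is.null(config$paths)
  if (has_sim == has_paths) {
    abort("config must contain exactly one of `simulation` or `paths`")
  }
  seed <- as.integer(config$seed %||% 1L)
  params <- do.call(arrival_params, config$arrival %||% list())
  mcfg <- if (is.null(config$mcmc)) mcmc_config_short(seed = seed) else {
    do.call(mcmc_config, c(config$mcmc, list(seed = seed)))
  }
  counts <- list()

  if (has_sim) {
    scfg <- do.call(sim_config, c(config$simulation, list(seed = seed)))
    pop <- simulate_population(scfg)
    individuals <- pop$individuals
    pedigree <- pop$pedigree
    truth <- pop$truth
    visits <- simulate_visits(individuals, truth, scfg)
    event_windows <- scfg$event_windows
  } else {
    p <- config$paths
    for (nm in c("visits", "individuals", "pedigree")) {
      if (is.null(p[[nm]]) || !file.exists(p[[nm]])) {
        abort(glue::glue("input path `{nm}` missing or not found"))
      }
    }
    visits <- read_visit_log(p$visits)
    individuals <- read_individuals(p$individuals)
    pedigree <- read_pedigree(p$pedigree)
    truth <- NULL
    ew <- p$event_windows
    event_windows <- if (is.data.frame(ew)) tibble::as_tibble(ew) else {
      purrr::map_dfr(ew, tibble::as_tibble)
    }
    event_windows$start <- as.Date(event_windows$start)
    event_windows$end <- as.Date(event_windows$end)
    # visit logs carry tag ids; translate to individual ids where known
    tag_map <- setNames(individuals$individual_id, individuals$tag_id)
    mapped <- unname(tag_map[visits$tag_id])
    visits$tag_id <- ifelse(is.na(mapped), visits$tag_id, mapped)
  }
  counts$visits <- nrow(visits)

  sliced <- slice_windows(visits, event_windows)
  counts$in_window_detections <- nrow(sliced)

  # weekly networks (repeatability substrate)
  weekly_centrality <- sliced |>
    dplyr::group_by(.data$event, .data$week) |>
    dplyr::group_map(function(d, key) {
      arr <- detect_arrivals(d, params)
      cent <- centrality_from_arrivals(arr, individuals, params)
      if (nrow(cent) == 0) return(NULL)
      dplyr::mutate(cent, event = key$event, week = key$week)
    }) |>
    dplyr::bind_rows()
  counts$weekly_centrality_rows <- nrow(weekly_centrality)

  # event networks + bipartite sub-graphs
  event_year <- setNames(as.integer(format(as.Date(event_windows$end), "%Y")),
                         as.character(event_windows$event))
  arrivals <- detect_arrivals(sliced, params)
  networks <- list()
  event_centrality <- purrr::map_dfr(unique(sliced$event), function(ev) {
    arr <- dplyr::filter(arrivals, .data$event == ev)
    dc <- associate_arrivals(arr, params)
    if (nrow(dc$dyads) == 0) return(NULL)
    sri <- compute_sri(dc)
    net <- build_network(sri, individuals)
    bip <- build_network(sri, individuals, bipartite = TRUE)
    networks[[ev]] <<- net
    compute_centralities(net, bip) |>
      dplyr::mutate(event = ev, year = event_year[[ev]])
  })
  counts$event_centrality_rows <- nrow(event_centrality)
  event_summary <- summarize_event(
    dplyr::select(event_centrality, -"year"), group = "event")

  # fitness
  years <- sort(unique(event_centrality$year))
  census <- build_census(individuals, years)
  fitness <- fitness_table(pedigree, individuals, census, years)
  counts$fitness_rows <- nrow(fitness)

  # repeatability per event
  repeatability <- fit_repeatability(
    weekly_centrality,
    measures = c("degree", "strength", "eigenvector", "opposite_sex_degree"),
    config = mcfg, event_col = "event")

  # selection models on mean-centered measures
  centered <- mean_center_within_year(
    event_centrality,
    measures = c("degree", "strength", "eigenvector", "opposite_sex_degree"))
  sel_cfg <- config$selection %||% list()
  measures <- sel_cfg$measures %||% c("degree", "strength", "eigenvector",
                                      "opposite_sex_degree")
  responses <- sel_cfg$responses %||% "annual_recruits"
  model_frame <- dplyr::inner_join(centered, fitness,
                                   by = c("individual_id", "year"))
  selection <- list()
  for (resp in responses) {
    lifetime <- grepl("^lifetime|^p_i$", resp)
    for (m in measures) {
      d <- dplyr::mutate(model_frame, c = .data[[paste0(m, "_c")]])
      resp_col <- switch(resp, annual_delifed = "p_ti",
                         lifetime_delifed = "p_i", resp)
      d[[resp]] <- d[[resp_col]]
      if (lifetime) d <- dplyr::distinct(d, .data$individual_id, .keep_all = TRUE)
      fit <- fit_selection_model(d, response = resp,
                                 scale = if (lifetime) "lifetime" else "annual",
                                 config = mcfg)
      selection[[paste(resp, m, sep = ".")]] <- fit
    }
  }

  # node-permutation null models
  null <- NULL
  if (run_null) {
    pcfg <- do.call(permutation_config,
                    c(config$permutation %||% list(), list(seed = seed)))
    null <- purrr::map_dfr(unique(arrivals$event), function(ev) {
      arr <- dplyr::filter(arrivals, .data$event == ev)
      null_centrality(arr, individuals, params, pcfg) |>
        dplyr::mutate(event = ev, year = event_year[[ev]])
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("flocknet")),
    r_version = as.character(getRversion()),
    seed = seed,
    config_hash = rlang::hash(config),
    stage_counts = counts,
    output_hashes = list(
      event_centrality = rlang::hash(event_centrality),
      fitness = rlang::hash(fitness),
      weekly_centrality = rlang::hash(weekly_centrality)))

  result <- list(individuals = individuals, pedigree = pedigree, truth = truth,
                 visits = visits, arrivals = arrivals,
                 weekly_centrality = weekly_centrality,
                 event_centrality = event_centrality,
                 event_summary = event_summary,
                 census = census, fitness = fitness,
                 repeatability = repeatability, selection = selection,
                 null_centrality = null, networks = networks,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(individuals, file.path(out_dir, "individuals.csv"))
    readr::write_csv(pedigree, file.path(out_dir, "pedigree.csv"))
    readr::write_csv(event_centrality, file.path(out_dir, "event_centrality.csv"))
    readr::write_csv(weekly_centrality, file.path(out_dir, "weekly_centrality.csv"))
    readr::write_csv(fitness, file.path(out_dir, "fitness.csv"))
    readr::write_csv(census, file.path(out_dir, "census.csv"))
    readr::write_csv(tidy(repeatability), file.path(out_dir, "repeatability.csv"))
    purrr::iwalk(selection, function(fit, nm) {
      write_model_result(fit, file.path(out_dir, paste0("selection_", nm, ".json")))
    })
    if (!is.null(null)) readr::write_csv(null, file.path(out_dir, "null_centrality.csv"))
    purrr::iwalk(networks, function(net, nm) {
      write_network(net, file.path(out_dir, paste0(
        "network_", gsub("[^A-Za-z0-9]", "-", nm), ".graphml")), "graphml")
    })
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
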