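# Node-permutation null models and Elo dominance ratings. The null model
# shuffles individual identities across observed arrival times, exactly
# conserving both the multiset of arrival times and the multiset of
# per-individual arrival counts while breaking any individual-level link
# between sociality and fitness.

#' Permutation configuration
#'
#' @param n_permutations Number of randomized permutations (default 1000).
#' @param scope `"within_event"` (default) or `"within_week"`: identities
#'   are shuffled only among arrivals in the same scope unit.
#' @param seed Integer seed.
#' @export
permutation_config <- function(n_permutations = 1000,
                               scope = c("within_event", "within_week"),
                               seed = 1L) {
  scope <- match.arg(scope)
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  structure(list(n_permutations = n_permutations, scope = scope,
                 seed = as.integer(seed)),
            class = "permutation_config")
}

#' Shuffle individual identities across arrival events
#'
#' Applies a uniform random bijection of identities (a label permutation)
#' within each scope unit: individual a's arrivals are relabelled as some
#' individual b's, so each window's arrival-time multiset and the multiset
#' of per-individual arrival counts are exactly conserved.
#'
#' @param arrivals An arrival-event tibble ([detect_arrivals()]); needs an
#'   `event` column (and `week` for `within_week` scope) unless it is a
#'   single window.
#' @param config A [permutation_config()]; `$seed` is consumed via the
#'   current RNG state, so wrap in [set.seed()] or pass `rng = TRUE`.
#' @param rng If `TRUE` (default) seed the RNG from `config$seed` first.
#' @return The arrivals tibble with identities permuted.
#' @export
permute_identities <- function(arrivals, config = permutation_config(),
                               rng = TRUE) {
  if (nrow(arrivals) == 0) abort("arrivals must be non-empty")
  if (rng) set.seed(config$seed)
  scope_cols <- switch(config$scope,
                       within_event = intersect("event", names(arrivals)),
                       within_week = intersect(c("event", "week"), names(arrivals)))
  key <- if (length(scope_cols) == 0) rep("all", nrow(arrivals)) else {
    do.call(paste, c(arrivals[scope_cols], sep = "\r"))
  }
  out <- arrivals
  for (k in unique(key)) {
    rows <- which(key == k)
    ids <- unique(out$individual_id[rows])
    relabel <- setNames(sample(ids), ids)
    out$individual_id[rows] <- unname(relabel[out$individual_id[rows]])
  }
  out
}

#' Modal null centralities from permuted networks
#'
#' For each permutation, rebuilds the SRI network from the permuted
#' arrivals and recomputes all four centrality measures; per individual
#' and measure, returns the mode across permutations (exact mode for the
#' integer measures, half-sample mode for the continuous ones). These
#' null centralities can be fed back into the selection models: with
#' identities shuffled, sociality terms should show no association with
#' fitness.
#'
#' @param arrivals Arrival-event tibble for one window.
#' @param individuals Individual metadata (for the bipartite sub-graph).
#' @param params [arrival_params()].
#' @param config [permutation_config()]; at least ~100 permutations give
#'   stable modes.
#' @param strength Passed to [compute_centralities()].
#' @return A tibble (`individual_id`, `degree`, `strength`, `eigenvector`,
#'   `opposite_sex_degree`) of modal null values.
#' @export
null_centrality <- function(arrivals, individuals, params = arrival_params(),
                            config = permutation_config(),
                            strength = c("net", "sum")) {
  strength <- match.arg(strength)
  set.seed(config$seed)
  per_perm <- purrr::map_dfr(seq_len(config$n_permutations), function(b) {
    perm <- permute_identities(arrivals, config, rng = FALSE)
    cent <- centrality_from_arrivals(perm, individuals, params, strength)
    dplyr::mutate(cent, .perm = b)
  })
  missing_everywhere <- setdiff(unique(arrivals$individual_id),
                                unique(per_perm$individual_id))
  if (length(missing_everywhere) > 0) {
    inform(glue::glue("{length(missing_everywhere)} individual(s) absent from all permuted networks"))
  }
  per_perm |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(degree = integer_mode(.data$degree),
                     strength = half_sample_mode(.data$strength),
                     eigenvector = half_sample_mode(.data$eigenvector),
                     opposite_sex_degree = integer_mode(.data$opposite_sex_degree),
                     .groups = "drop")
}

# Arrivals -> SRI network -> centralities, the standard chain used by the
# observed and permuted pipelines alike.
centrality_from_arrivals <- function(arrivals, individuals,
                                     params = arrival_params(),
                                     strength = "net") {
  counts <- associate_arrivals(arrivals, params)
  if (nrow(counts$dyads) == 0) {
    return(tibble::tibble(individual_id = character(), degree = integer(),
                          strength = numeric(), eigenvector = numeric(),
                          opposite_sex_degree = integer()))
  }
  sri <- compute_sri(counts)
  net <- build_network(sri, individuals)
  bip <- if (!is.null(individuals)) {
    build_network(sri, individuals, bipartite = TRUE)
  } else NULL
  compute_centralities(net, bip, strength = strength)
}

#' Elo configuration
#'
#' @param start_rating Initial rating for every individual (default 1000).
#' @param k_factor Update step size (default 100).
#' @export
elo_config <- function(start_rating = 1000, k_factor = 100) {
  check_scalar_number(k_factor, "k_factor", 0, strict_min = TRUE)
  structure(list(start_rating = start_rating, k_factor = k_factor),
            class = "elo_config")
}

#' Elo dominance ratings from dyadic interactions
#'
#' Sequential (chronological) update: with winner rating `R_w` and loser
#' rating `R_l`, the expected win probability is
#' `p_w = 1 / (1 + 10^((R_l - R_w) / 400))`; the winner gains
#' `k (1 - p_w)` and the loser loses the same, so the total rating is
#' conserved after every update (zero-sum).
#'
#' @param interactions Tibble (`timestamp`, `winner_id`, `loser_id`).
#' @param config An [elo_config()].
#' @param individuals Optional metadata; individuals without interactions
#'   keep the start rating.
#' @return A tibble (`individual_id`, `rating`, `n_interactions`).
#' @export
elo_ratings <- function(interactions, config = elo_config(),
                        individuals = NULL) {
  if (any(interactions$winner_id == interactions$loser_id)) {
    abort("interaction with winner == loser rejected")
  }
  ids <- unique(c(interactions$winner_id, interactions$loser_id,
                  if (!is.null(individuals)) individuals$individual_id))
  rating <- setNames(rep(config$start_rating, length(ids)), ids)
  n_int <- setNames(rep(0L, length(ids)), ids)
  ord <- order(interactions$timestamp)
  for (r in ord) {
    w <- interactions$winner_id[r]; l <- interactions$loser_id[r]
    p_w <- 1 / (1 + 10^((rating[[l]] - rating[[w]]) / 400))
    delta <- config$k_factor * (1 - p_w)
    rating[[w]] <- rating[[w]] + delta
    rating[[l]] <- rating[[l]] - delta
    n_int[[w]] <- n_int[[w]] + 1L
    n_int[[l]] <- n_int[[l]] + 1L
  }
  tibble::tibble(individual_id = ids, rating = unname(rating),
                 n_interactions = unname(n_int))
}

#' Correlation between dominance and centrality
#'
#' Spearman rank correlation between Elo rating and each observed
#' centrality measure, with a permutation p-value (ratings shuffled across
#' individuals). Null-model (permuted) centralities are excluded by
#' design: pass observed centralities only.
#'
#' @param elo Output of [elo_ratings()].
#' @param centrality Observed centrality tibble.
#' @param n_permutations Label permutations for the p-value.
#' @param seed Integer seed.
#' @return A tibble (`measure`, `rho`, `p_value`, `n`).
#' @export
dominance_centrality_correlation <- function(elo, centrality,
                                             n_permutations = 1000, seed = 1L) {
  joined <- dplyr::inner_join(elo, centrality, by = "individual_id")
  measures <- setdiff(names(centrality)[vapply(centrality, is.numeric, logical(1))],
                      c("week", "year"))
  if (nrow(joined) < 3) {
    warn("fewer than 3 shared individuals: correlation undefined")
    return(tibble::tibble(measure = measures, rho = NA_real_,
                          p_value = NA_real_, n = nrow(joined)))
  }
  set.seed(seed)
  purrr::map_dfr(measures, function(m) {
    obs <- stats::cor(joined$rating, joined[[m]], method = "spearman")
    null <- replicate(n_permutations,
                      stats::cor(sample(joined$rating), joined[[m]],
                                 method = "spearman"))
    p <- (1 + sum(abs(null) >= abs(obs))) / (n_permutations + 1)
    tibble::tibble(measure = m, rho = obs, p_value = p, n = nrow(joined))
  })
}
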