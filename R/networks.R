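#' Simple Ratio Index from dyadic counts
#'
#' For a dyad (a, b), `SRI = x_ab / (x_ab + y_a + y_b)` where `x_ab` is the
#' number of co-arrivals and `y_a = n_a - x_ab`, `y_b = n_b - x_ab` are the
#' arrivals of each individual without the other. The index is the
#' association probability of the dyad, from 0 (never associated) to 1
#' (always associated). The sampling unit is an arrival, so no joint
#' "both observed apart in the same sampling period" term enters the
#' denominator. A dyad with no arrivals at all (0/0) gets SRI 0.
#'
#' @param counts A `dyad_counts` object (any method).
#' @return A tibble (`id_a`, `id_b`, `x`, `n_a`, `n_b`, `sri`) with one row
#'   per dyad with `x > 0`, plus attribute `totals` carrying all
#'   per-individual arrival counts.
#' @examples
#' arr <- tibble::tibble(individual_id = c("a", "b"), arrival_time = c(0, 50),
#'                       bout_end = c(0, 50))
#' compute_sri(associate_arrivals(arr))
#' @export
compute_sri <- function(counts) {
  stopifnot(inherits(counts, "dyad_counts"))
  n_lookup <- setNames(counts$totals$n, counts$totals$individual_id)
  d <- counts$dyads
  d$n_a <- as.integer(n_lookup[d$id_a])
  d$n_b <- as.integer(n_lookup[d$id_b])
  if (nrow(d) > 0 && any(d$x > pmin(d$n_a, d$n_b))) {
    abort("internal consistency error: co-arrival count exceeds arrival total")
  }
  denom <- d$n_a + d$n_b - d$x
  d$sri <- ifelse(denom == 0, 0, d$x / denom)
  out <- tibble::as_tibble(d)
  attr(out, "totals") <- counts$totals
  attr(out, "method") <- counts$method
  out
}

#' Build an SRI-weighted social network
#'
#' Creates a weighted, undirected graph whose vertices are individuals and
#' whose edge weights are dyadic SRIs. Only dyads with `SRI > 0` form
#' edges; isolated vertices (degree 0, i.e. birds that never arrived in a
#' dyad) are removed, so every retained vertex has degree >= 1. Networks
#' are not thresholded beyond this.
#'
#' @param sri Output of [compute_sri()].
#' @param individuals Individual metadata tibble (needs `individual_id`,
#'   `sex`) used to attach a `sex` vertex attribute.
#' @param bipartite If `TRUE`, drop same-sex edges before the degree filter,
#'   leaving the opposite-sex (male-female) sub-graph.
#' @return An `igraph` object (class also `flocknet_network`) with vertex
#'   attribute `sex` and edge attribute `weight` (the SRI).
#' @export
build_network <- function(sri, individuals = NULL, bipartite = FALSE) {
  edges <- dplyr::filter(sri, .data$sri > 0)
  ids <- sort(unique(c(edges$id_a, edges$id_b)))
  sex_lookup <- NULL
  if (!is.null(individuals)) {
    sex_lookup <- setNames(individuals$sex, individuals$individual_id)
  }
  if (bipartite) {
    if (is.null(sex_lookup)) abort("bipartite networks need individual sex metadata")
    missing <- setdiff(ids, names(sex_lookup))
    if (length(missing) > 0) {
      abort(glue::glue("missing sex for vertex {missing[1]} in bipartite mode"))
    }
    edges <- dplyr::filter(edges, sex_lookup[.data$id_a] != sex_lookup[.data$id_b])
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$id_a, to = edges$id_b, weight = edges$sri),
    directed = FALSE)
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  if (!is.null(sex_lookup)) {
    igraph::V(g)$sex <- unname(sex_lookup[igraph::V(g)$name])
  }
  class(g) <- c("flocknet_network", class(g))
  g
}

#' Centrality measures of an SRI network
#'
#' Computes, per individual: `degree` (number of associates), `strength`
#' (net association quality: the degree-weighted sum of the individual's
#' SRIs scaled by network size, `S_i = d_i * sum_j SRI_ij / N(V)`, with the
#' plain SRI sum available via `strength = "sum"`), `eigenvector` (leading
#' eigenvector of the SRI-weighted adjacency, normalized so the maximum
#' score is 1), and `opposite_sex_degree` (degree in the opposite-sex
#' bipartite sub-graph; 0 for individuals absent from it).
#'
#' On a disconnected network the eigenvector score is still taken from the
#' dominant eigenvector of the full weighted adjacency (components other
#' than the dominant one score ~0); this is reported via a message.
#'
#' @param network A `flocknet_network` from [build_network()].
#' @param bipartite_network Optional opposite-sex sub-graph from
#'   [build_network(..., bipartite = TRUE)].
#' @param strength `"net"` (default, degree-and-size scaled) or `"sum"`
#'   (plain sum of SRIs).
#' @return A tibble (`individual_id`, `degree`, `strength`, `eigenvector`,
#'   `opposite_sex_degree`).
#' @export
compute_centralities <- function(network, bipartite_network = NULL,
                                 strength = c("net", "sum")) {
  strength <- match.arg(strength)
  nv <- igraph::vcount(network)
  if (nv == 0) {
    return(tibble::tibble(individual_id = character(), degree = integer(),
                          strength = numeric(), eigenvector = numeric(),
                          opposite_sex_degree = integer()))
  }
  deg <- igraph::degree(network)
  sri_sum <- igraph::strength(network, weights = igraph::E(network)$weight)
  s <- if (strength == "net") deg * sri_sum / nv else sri_sum
  if (igraph::count_components(network) > 1) {
    inform("network is disconnected; eigenvector taken from the dominant eigenvector of the full adjacency")
  }
  eig <- igraph::eigen_centrality(network,
                                  weights = igraph::E(network)$weight)$vector
  out <- tibble::tibble(
    individual_id = igraph::V(network)$name,
    degree = as.integer(deg),
    strength = as.numeric(s),
    eigenvector = as.numeric(eig),
    opposite_sex_degree = 0L)
  if (!is.null(bipartite_network) && igraph::vcount(bipartite_network) > 0) {
    bd <- igraph::degree(bipartite_network)
    hit <- match(names(bd), out$individual_id)
    ok <- !is.na(hit)
    out$opposite_sex_degree[hit[ok]] <- as.integer(bd[ok])
  }
  out
}

#' Per-event summary of centrality measures
#'
#' Mean, sample standard deviation (n - 1 denominator) and sample size per
#' measure, optionally per grouping column (e.g. `event`).
#'
#' @param centrality A centrality tibble; numeric measure columns are
#'   summarised.
#' @param group Optional grouping column name (e.g. `"event"`).
#' @return A tibble (`measure`, `mean`, `sd`, `n`, plus the group column).
#'   With a single observation the SD is reported as `NA`.
#' @export
summarize_event <- function(centrality, group = NULL) {
  if (nrow(centrality) == 0) abort("empty centrality table")
  measures <- setdiff(names(centrality)[vapply(centrality, is.numeric, logical(1))],
                      c("week", "year"))
  long <- tidyr::pivot_longer(centrality, dplyr::all_of(measures),
                              names_to = "measure", values_to = "value")
  grouping <- c(group, "measure")
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) stats::sd(.data$value) else NA_real_,
                     n = dplyr::n(), .groups = "drop")
}
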