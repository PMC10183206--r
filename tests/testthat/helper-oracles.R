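# Independent oracles and fixture builders shared across the suite.

# Arrival-event tibble from parallel vectors.
make_arrivals <- function(ids, times, ends = times) {
  tibble::tibble(individual_id = as.character(ids),
                 arrival_time = as.numeric(times),
                 bout_end = as.numeric(ends))
}

# Brute-force all-pairs greedy matcher: for every unordered dyad, walk a's
# arrivals in time order and give each the earliest unused arrival of b
# within delta_t. O(n^2), written independently of the package's
# two-pointer implementation.
brute_force_dyads <- function(arrivals, delta_t) {
  ids <- sort(unique(arrivals$individual_id))
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      ta <- sort(arrivals$arrival_time[arrivals$individual_id == ids[i]])
      tb <- sort(arrivals$arrival_time[arrivals$individual_id == ids[j]])
      used <- rep(FALSE, length(tb))
      x <- 0L
      for (t in ta) {
        for (k in seq_along(tb)) {
          if (!used[k] && abs(t - tb[k]) <= delta_t) {
            used[k] <- TRUE
            x <- x + 1L
            break
          }
        }
      }
      if (x > 0) out[[length(out) + 1L]] <- tibble::tibble(
        id_a = ids[i], id_b = ids[j], x = x)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(id_a = character(), id_b = character(), x = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), id_a, id_b)
}

# Random arrival stream: clustered bursts plus solo arrivals.
random_stream <- function(n, n_ids = 8, horizon = 50000) {
  ids <- sample(letters[seq_len(n_ids)], n, replace = TRUE)
  base <- sort(runif(n, 0, horizon))
  # push some arrivals into bursts so matches actually occur
  burst <- runif(n) < 0.5
  base[burst] <- base[burst] - (base[burst] %% 400) + runif(sum(burst), 0, 200)
  make_arrivals(ids, base)
}

# Power-iteration leading eigenvector of a symmetric weighted adjacency,
# normalized to max = 1.
power_iteration_centrality <- function(A, tol = 1e-13, max_iter = 100000) {
  # spectral shift keeps bipartite graphs (eigenvalues +/- lambda) convergent
  A <- A + diag(max(rowSums(A)), nrow(A))
  v <- rep(1, nrow(A))
  for (i in seq_len(max_iter)) {
    w <- as.numeric(A %*% v)
    w <- w / sqrt(sum(w^2))
    if (sqrt(sum((w - v)^2)) < tol) break
    v <- w
  }
  w / max(w)
}

# Random connected SRI edge list on n vertices (path backbone + extras).
random_sri_graph <- function(n, p_extra = 0.15) {
  ids <- sprintf("v%02d", seq_len(n))
  edges <- tibble::tibble(id_a = ids[-n], id_b = ids[-1])
  extra <- t(utils::combn(n, 2))
  take <- runif(nrow(extra)) < p_extra
  extra <- extra[take, , drop = FALSE]
  if (nrow(extra) > 0) {
    edges <- dplyr::bind_rows(edges,
                              tibble::tibble(id_a = ids[extra[, 1]],
                                             id_b = ids[extra[, 2]]))
  }
  edges <- dplyr::distinct(edges)
  edges$sri <- runif(nrow(edges), 0.05, 1)
  edges
}

# Adjacency matrix from an SRI edge list, in vertex order `ids`.
sri_adjacency <- function(edges, ids) {
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(edges))) {
    A[edges$id_a[r], edges$id_b[r]] <- edges$sri[r]
    A[edges$id_b[r], edges$id_a[r]] <- edges$sri[r]
  }
  A
}

# Tiny two-event windows for fast simulations.
short_windows <- function(weeks1 = 4, weeks2 = 3) {
  tibble::tibble(event = c("2015/16", "2016/17"),
                 start = as.Date(c("2015-11-02", "2016-11-07")),
                 end = as.Date(c("2015-11-02", "2016-11-07")) + 7 * c(weeks1, weeks2))
}

# Synthetic annual model frame for selection-model recovery: n birds, one
# row each, sociality standard normal, Poisson recruits from the coupling.
selection_frame <- function(n, beta_linear = 0, beta_quadratic = 0,
                            baseline = log(2), seed = 1) {
  set.seed(seed)
  ind <- tibble::tibble(
    individual_id = sprintf("b%04d", seq_len(n)),
    sex = stats::rbinom(n, 1, 0.5),
    cohort = sample(2012:2015, n, replace = TRUE))
  soc <- tibble::tibble(individual_id = ind$individual_id,
                        sociality = stats::rnorm(n))
  cpl <- flocknet::fitness_coupling(beta_linear = beta_linear,
                                    beta_quadratic = beta_quadratic,
                                    baseline_log_rate = baseline,
                                    family = "poisson_recruits",
                                    seed = seed + 1)
  fit <- flocknet::simulate_fitness(ind, soc, cpl)
  dplyr::mutate(
    dplyr::inner_join(ind, fit, by = "individual_id"),
    c = sociality - mean(sociality),
    age = 2016 - cohort,
    annual_recruits = recruits)
}
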