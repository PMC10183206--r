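#' Arrival-inference parameters
#'
#' `delta_t` is the co-arrival window: two individuals arriving within
#' `delta_t` seconds of each other (inclusive) are associated. `delta_i` is
#' the absence gap: a detection starts a new arrival bout only when the gap
#' since the individual's previous detection is strictly greater than
#' `delta_i` seconds. Defaults are 150 s and 300 s, the values used to
#' define flock co-arrival at an open-access feeder.
#'
#' @param delta_t Co-arrival window in seconds (> 0).
#' @param delta_i Absence gap defining a new arrival, in seconds (> 0).
#' @return A list of class `arrival_params`.
#' @export
arrival_params <- function(delta_t = 150, delta_i = 300) {
  check_scalar_number(delta_t, "delta_t", 0, strict_min = TRUE)
  check_scalar_number(delta_i, "delta_i", 0, strict_min = TRUE)
  structure(list(delta_t = delta_t, delta_i = delta_i), class = "arrival_params")
}

#' Partition a visit log into arrival bouts
#'
#' An arrival is the (re)appearance of an individual at the feeder after an
#' absence strictly longer than `delta_i` seconds. Consecutive detections
#' with gaps `<= delta_i` belong to the same bout; `arrival_time` is the
#' bout's first detection and `bout_end` its last.
#'
#' @param visits A visit-log tibble (`timestamp`, `tag_id`, ...), e.g. from
#'   [read_visit_log()] or [simulate_visits()].
#' @param params An [arrival_params()] object.
#' @return A tibble (`individual_id`, `arrival_time`, `bout_end`, plus any
#'   `event` / `week` labels present on the input), sorted by arrival time.
#' @examples
#' v <- tibble::tibble(timestamp = c(0, 100, 600), tag_id = "A")
#' detect_arrivals(v, arrival_params(delta_i = 300))
#' @export
detect_arrivals <- function(visits, params = arrival_params()) {
  stopifnot(inherits(params, "arrival_params"))
  id_col <- if ("individual_id" %in% names(visits)) "individual_id" else "tag_id"
  labels <- intersect(c("event", "week"), names(visits))
  if (nrow(visits) == 0) {
    return(tibble::tibble(individual_id = character(), arrival_time = numeric(),
                          bout_end = numeric()))
  }
  visits |>
    dplyr::transmute(individual_id = as.character(.data[[id_col]]),
                     timestamp = .data$timestamp,
                     dplyr::across(dplyr::all_of(labels))) |>
    dplyr::arrange(.data$individual_id, .data$timestamp) |>
    dplyr::group_by(.data$individual_id, dplyr::across(dplyr::all_of(labels))) |>
    dplyr::mutate(
      gap = .data$timestamp - dplyr::lag(.data$timestamp),
      bout = cumsum(is.na(.data$gap) | .data$gap > params$delta_i)) |>
    dplyr::group_by(.data$bout, .add = TRUE) |>
    dplyr::summarise(arrival_time = min(.data$timestamp),
                     bout_end = max(.data$timestamp), .groups = "drop") |>
    dplyr::select(-"bout") |>
    dplyr::relocate("individual_id", "arrival_time", "bout_end") |>
    dplyr::arrange(.data$arrival_time, .data$individual_id)
}

#' Construct dyadic association counts directly
#'
#' Builds the container used by [compute_sri()] from raw counts, e.g. when
#' association data come from another observation protocol. `x_ab` must be
#' symmetric (stored once per unordered dyad with `id_a < id_b`) and cannot
#' exceed either individual's total.
#'
#' @param dyads Tibble (`id_a`, `id_b`, `x`) of co-occurrence counts.
#' @param totals Tibble (`individual_id`, `n`) of per-individual totals.
#' @param method Label for the association definition used.
#' @return A `dyad_counts` object.
#' @export
dyad_counts <- function(dyads, totals, method = "external") {
  ord <- order_dyad(dyads$id_a, dyads$id_b)
  dyads <- tibble::tibble(id_a = ord$id_a, id_b = ord$id_b,
                          x = as.integer(dyads$x))
  if (any(dyads$x < 0) || any(totals$n < 0)) abort("counts must be >= 0")
  new_dyad_counts(dyads, tibble::as_tibble(totals), method = method)
}

new_dyad_counts <- function(dyads, totals, method, window = NA_character_) {
  stopifnot(all(dyads$id_a < dyads$id_b | nrow(dyads) == 0))
  structure(list(dyads = dyads, totals = totals, method = method,
                 window = window),
            class = "dyad_counts")
}

#' @export
print.dyad_counts <- function(x, ...) {
  cat(glue::glue("<dyad_counts> method={x$method} individuals={nrow(x$totals)} ",
                 "dyads={nrow(x$dyads)}"), "\n")
  print(x$dyads, n = 5)
  invisible(x)
}

#' Dyadic association counts from co-arrivals (arrival-time method)
#'
#' For each unordered dyad, counts pairs of arrivals (one per individual)
#' within `delta_t` seconds of each other (inclusive). Matching is greedy in
#' time order and one-to-one: each arrival can be matched to at most one
#' arrival of the same partner, so a single arrival never counts against
#' several bouts of one individual. Associations are dyadic, not
#' transitive: A-B and B-C co-arrivals do not imply A-C.
#'
#' @param arrivals Output of [detect_arrivals()].
#' @param params An [arrival_params()] object.
#' @param counting `"per_event"` (default; a dyad accumulates one count per
#'   matched co-arrival) or `"binary_per_window"` (a dyad counts at most
#'   once, with per-individual totals collapsed to presence).
#' @return A `dyad_counts` object: `$dyads` (`id_a`, `id_b`, `x`),
#'   `$totals` (`individual_id`, `n` arrivals), `$method`.
#' @export
associate_arrivals <- function(arrivals, params = arrival_params(),
                               counting = c("per_event", "binary_per_window")) {
  counting <- match.arg(counting)
  stopifnot(inherits(params, "arrival_params"))
  empty <- tibble::tibble(id_a = character(), id_b = character(), x = integer())
  if (nrow(arrivals) == 0) {
    return(new_dyad_counts(empty,
                           tibble::tibble(individual_id = character(), n = integer()),
                           method = "arrival_time"))
  }
  arr <- dplyr::arrange(arrivals, .data$arrival_time, .data$individual_id)
  totals <- dplyr::count(arr, individual_id = .data$individual_id, name = "n")
  times_by_id <- split(arr$arrival_time, arr$individual_id)
  cand <- candidate_dyads(arr$arrival_time, arr$individual_id, params$delta_t)
  if (nrow(cand) == 0) {
    return(new_dyad_counts(empty, totals, method = "arrival_time"))
  }
  x <- purrr::map2_int(cand$id_a, cand$id_b, function(a, b) {
    greedy_match_count(times_by_id[[a]], times_by_id[[b]], params$delta_t)
  })
  dyads <- tibble::tibble(id_a = cand$id_a, id_b = cand$id_b, x = x) |>
    dplyr::filter(.data$x > 0)
  if (counting == "binary_per_window") {
    dyads$x <- pmin(dyads$x, 1L)
    totals$n <- pmin(totals$n, 1L)
  }
  new_dyad_counts(dyads, totals, method = "arrival_time")
}

# Unordered dyads with at least one arrival pair within delta_t: sweep the
# time-sorted arrivals, pairing each with the later ones inside the window.
candidate_dyads <- function(times, ids, delta_t) {
  o <- order(times)
  times <- times[o]; ids <- ids[o]
  n <- length(times)
  upper <- findInterval(times + delta_t, times)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    if (upper[i] > i) {
      j <- (i + 1):upper[i]
      from <- c(from, rep.int(i, length(j)))
      to <- c(to, j)
    }
  }
  if (length(from) == 0) {
    return(tibble::tibble(id_a = character(), id_b = character()))
  }
  keep <- ids[from] != ids[to]
  dplyr::distinct(order_dyad(ids[from][keep], ids[to][keep]))
}

# Greedy one-to-one matching of two sorted arrival-time vectors: walk both
# in time order, pair when |ta - tb| <= delta_t, else advance the earlier.
greedy_match_count <- function(ta, tb, delta_t) {
  i <- 1L; j <- 1L; m <- 0L
  na <- length(ta); nb <- length(tb)
  while (i <= na && j <= nb) {
    d <- ta[i] - tb[j]
    if (abs(d) <= delta_t) {
      m <- m + 1L; i <- i + 1L; j <- j + 1L
    } else if (d < 0) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  m
}

#' Dyadic association counts under the gambit of the group
#'
#' Clusters arrivals into discrete groups by single-linkage on arrival time
#' (a new group starts when the gap to the previous arrival exceeds `gap`),
#' then links every within-group dyad equally. With `gap` equal to the
#' co-arrival window this produces a superset of the arrival-time method's
#' edges (single-linkage closure can chain two separate flocks together).
#'
#' @param arrivals Output of [detect_arrivals()].
#' @param gap Single-linkage threshold in seconds (> 0); default 150.
#' @return A `dyad_counts` object; `$totals$n` counts the groups in which
#'   each individual appears.
#' @export
gambit_of_group <- function(arrivals, gap = 150) {
  check_scalar_number(gap, "gap", 0, strict_min = TRUE)
  empty <- tibble::tibble(id_a = character(), id_b = character(), x = integer())
  if (nrow(arrivals) == 0) {
    return(new_dyad_counts(empty,
                           tibble::tibble(individual_id = character(), n = integer()),
                           method = "gambit_of_group"))
  }
  arr <- dplyr::arrange(arrivals, .data$arrival_time)
  grp <- cumsum(c(TRUE, diff(arr$arrival_time) > gap))
  members <- tibble::tibble(group = grp, individual_id = arr$individual_id) |>
    dplyr::distinct()
  totals <- dplyr::count(members, .data$individual_id, name = "n")
  dyads <- members |>
    dplyr::group_by(.data$group) |>
    dplyr::reframe(pair_grid(.data$individual_id)) |>
    dplyr::count(.data$id_a, .data$id_b, name = "x")
  new_dyad_counts(tibble::as_tibble(dyads), totals, method = "gambit_of_group")
}

pair_grid <- function(ids) {
  ids <- sort(unique(ids))
  if (length(ids) < 2) {
    return(tibble::tibble(id_a = character(), id_b = character()))
  }
  idx <- utils::combn(length(ids), 2)
  tibble::tibble(id_a = ids[idx[1, ]], id_b = ids[idx[2, ]])
}

#' Dyadic association counts from time-window overlap
#'
#' Two individuals are associated when their presence intervals intersect,
#' where presence extends from the bout's first detection to `delta_t`
#' seconds after its last (covering birds still present but no longer on
#' the antenna). In a busy stream this yields chained, linear structures:
#' A-B and B-C overlap without A-C.
#'
#' @param visits A visit-log tibble; bouts are computed internally with
#'   `params$delta_i`.
#' @param params An [arrival_params()] object.
#' @return A `dyad_counts` object; `x` counts intersecting bout pairs and
#'   `$totals$n` counts bouts per individual.
#' @export
time_window_overlap <- function(visits, params = arrival_params()) {
  stopifnot(inherits(params, "arrival_params"))
  bouts <- detect_arrivals(visits, params)
  empty <- tibble::tibble(id_a = character(), id_b = character(), x = integer())
  if (nrow(bouts) == 0) {
    return(new_dyad_counts(empty,
                           tibble::tibble(individual_id = character(), n = integer()),
                           method = "time_window_overlap"))
  }
  totals <- dplyr::count(bouts, .data$individual_id, name = "n")
  start <- bouts$arrival_time
  end <- bouts$bout_end + params$delta_t
  o <- order(start)
  start <- start[o]; end <- end[o]; ids <- bouts$individual_id[o]
  n <- length(start)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n && start[j] <= end[i]) {
      if (ids[i] != ids[j]) { from <- c(from, i); to <- c(to, j) }
      j <- j + 1L
    }
  }
  if (length(from) == 0) {
    return(new_dyad_counts(empty, totals, method = "time_window_overlap"))
  }
  dyads <- order_dyad(ids[from], ids[to]) |>
    dplyr::count(.data$id_a, .data$id_b, name = "x")
  new_dyad_counts(tibble::as_tibble(dyads), totals, method = "time_window_overlap")
}

#' Slice a visit log into events and weeks
#'
#' Assigns each detection to the event window containing it and to a 7-day
#' week block anchored at the event start (half-open intervals
#' `[start, start + 7 days)`). Detections outside every window are dropped
#' with a reported count. Bouts never span slice boundaries because bout
#' detection runs within slices.
#'
#' @param visits A visit-log tibble.
#' @param event_windows A tibble with columns `event`, `start`, `end`
#'   (dates; `end` exclusive), ordered and non-overlapping.
#' @param week_length Days per week block (default 7).
#' @return The visit log with `event` and `week` columns (week numbered from
#'   1 within each event); out-of-window rows removed.
#' @export
slice_windows <- function(visits, event_windows, week_length = 7) {
  ew <- dplyr::arrange(event_windows, .data$start)
  starts <- date_seconds(ew$start)
  ends <- date_seconds(ew$end)
  if (any(utils::head(ends, -1) > utils::tail(starts, -1))) {
    abort("event windows must be ordered and non-overlapping")
  }
  idx <- rep(NA_integer_, nrow(visits))
  for (k in seq_along(starts)) {
    hit <- visits$timestamp >= starts[k] & visits$timestamp < ends[k]
    idx[hit] <- k
  }
  dropped <- sum(is.na(idx))
  if (dropped > 0) {
    inform(glue::glue("dropped {dropped} detection(s) outside all event windows"))
  }
  out <- visits[!is.na(idx), , drop = FALSE]
  k <- idx[!is.na(idx)]
  out$event <- as.character(ew$event)[k]
  out$week <- 1L + as.integer((out$timestamp - starts[k]) %/% (week_length * DAY))
  tibble::as_tibble(out)
}

#' Enumerate the weekly slices of sliced visits
#'
#' Returns one row per event-week present in the event windows (including
#' empty weeks, so downstream models see missing weeks as absent rows).
#'
#' @param event_windows As for [slice_windows()].
#' @param week_length Days per week block.
#' @return A tibble (`event`, `week`).
#' @export
enumerate_weeks <- function(event_windows, week_length = 7) {
  purrr::pmap_dfr(event_windows, function(event, start, end, ...) {
    nw <- as.integer(ceiling(as.numeric(as.Date(end) - as.Date(start)) / week_length))
    tibble::tibble(event = as.character(event), week = seq_len(nw))
  })
}
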