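test_that("bout detection follows the strict absence-gap rule", {
  v <- tibble::tibble(timestamp = c(0, 100, 600), tag_id = "A")
  arr <- detect_arrivals(v, arrival_params(delta_i = 300))
  expect_equal(arr$arrival_time, c(0, 600)) # gap 500 > 300 reopens a bout
  expect_equal(arr$bout_end, c(100, 600))

  single <- detect_arrivals(tibble::tibble(timestamp = 42, tag_id = "A"))
  expect_equal(single$arrival_time, single$bout_end)

  # boundary: a gap of exactly delta_i does NOT start a new bout (> rule)
  v2 <- tibble::tibble(timestamp = c(0, 300), tag_id = "A")
  expect_equal(nrow(detect_arrivals(v2, arrival_params(delta_i = 300))), 1)
  v3 <- tibble::tibble(timestamp = c(0, 300.001), tag_id = "A")
  expect_equal(nrow(detect_arrivals(v3, arrival_params(delta_i = 300))), 2)
})

test_that("co-arrival association is dyadic, inclusive at delta_t, and drops loners", {
  arr <- make_arrivals(c("A", "B", "C"), c(0, 100, 200))
  dc <- associate_arrivals(arr, arrival_params(delta_t = 150))
  d <- dc$dyads
  expect_equal(d$x[d$id_a == "A" & d$id_b == "B"], 1L)
  expect_equal(d$x[d$id_a == "B" & d$id_b == "C"], 1L)
  expect_false(any(d$id_a == "A" & d$id_b == "C")) # gap 200 > 150: dyadic, no chain

  # exactly delta_t apart is associated (inclusive window)
  d2 <- associate_arrivals(make_arrivals(c("A", "B"), c(0, 150)))$dyads
  expect_equal(nrow(d2), 1)

  # a lone arrival yields no dyads; degree-0 birds drop out of the network
  lone <- associate_arrivals(make_arrivals("Z", 0))
  expect_equal(nrow(lone$dyads), 0)
  expect_equal(lone$totals$n, 1L)
})

test_that("greedy matching is one-to-one per partner", {
  # one arrival of A against three bouts of B: only one co-arrival counted
  arr <- make_arrivals(c("A", "B", "B", "B"), c(0, 10, 50, 100))
  dc <- associate_arrivals(arr, arrival_params(delta_t = 150))
  expect_equal(dc$dyads$x, 1L)
  expect_equal(dc$totals$n[dc$totals$individual_id == "B"], 3L)
})

test_that("binary counting caps dyads and totals at one", {
  arr <- make_arrivals(rep(c("A", "B"), 3), c(0, 1, 1000, 1001, 2000, 2001))
  per_event <- associate_arrivals(arr)
  binary <- associate_arrivals(arr, counting = "binary_per_window")
  expect_equal(per_event$dyads$x, 3L)
  expect_equal(binary$dyads$x, 1L)
})

test_that("dyad counts match the brute-force matcher on random streams", {
  set.seed(101)
  for (rep in 1:60) {
    arr <- random_stream(sample(5:120, 1))
    dt <- sample(c(50, 150, 400), 1)
    got <- associate_arrivals(arr, arrival_params(delta_t = dt))$dyads |>
      dplyr::arrange(id_a, id_b)
    want <- brute_force_dyads(arr, dt)
    expect_equal(as.data.frame(got[, c("id_a", "id_b", "x")]),
                 as.data.frame(want))
  }
})

test_that("dyad count invariants hold on random streams", {
  set.seed(77)
  for (rep in 1:20) {
    arr <- random_stream(sample(10:100, 1))
    dc <- associate_arrivals(arr)
    n <- setNames(dc$totals$n, dc$totals$individual_id)
    expect_true(all(dc$dyads$x >= 0))
    expect_true(all(dc$dyads$x <= pmin(n[dc$dyads$id_a], n[dc$dyads$id_b])))
    expect_true(all(dc$dyads$id_a < dc$dyads$id_b)) # stored once per unordered dyad
  }
})

test_that("gambit of the group clusters by single linkage", {
  arr <- make_arrivals(c("A", "B", "C"), c(0, 100, 200))
  dc <- gambit_of_group(arr, gap = 150)
  expect_equal(nrow(dc$dyads), 3) # one chained group of 3 -> all dyads
  expect_true(any(dc$dyads$id_a == "A" & dc$dyads$id_b == "C"))

  far <- gambit_of_group(make_arrivals(c("A", "B"), c(0, 1000)), gap = 150)
  expect_equal(nrow(far$dyads), 0)
})

test_that("gambit links dyads the arrival-time method does not", {
  # the overestimation contrast: chained arrivals merge two sub-groups
  arr <- make_arrivals(c("A", "B", "C"), c(0, 100, 200))
  at <- associate_arrivals(arr, arrival_params(delta_t = 150))$dyads
  gg <- gambit_of_group(arr, gap = 150)$dyads
  at_keys <- paste(at$id_a, at$id_b)
  gg_keys <- paste(gg$id_a, gg$id_b)
  expect_true(all(at_keys %in% gg_keys))
  expect_true("A C" %in% setdiff(gg_keys, at_keys))
})

test_that("gambit edge set dominates the arrival-time edge set on random streams", {
  set.seed(303)
  for (rep in 1:25) {
    arr <- random_stream(sample(10:80, 1))
    at <- associate_arrivals(arr, arrival_params(delta_t = 150))$dyads
    gg <- gambit_of_group(arr, gap = 150)$dyads
    expect_true(all(paste(at$id_a, at$id_b) %in% paste(gg$id_a, gg$id_b)))
  }
})

test_that("time-window overlap counts intersecting presence intervals", {
  v <- tibble::tibble(timestamp = c(0, 50, 40, 90), tag_id = c("A", "A", "B", "B"))
  dc <- time_window_overlap(v, arrival_params(delta_t = 150, delta_i = 300))
  expect_equal(dc$dyads$x, 1L)

  # extended interval [0, 200] misses a bout starting at 210
  v2 <- tibble::tibble(timestamp = c(0, 50, 210, 260), tag_id = c("A", "A", "B", "B"))
  expect_equal(nrow(time_window_overlap(v2, arrival_params(150, 300))$dyads), 0)
})

test_that("overlap produces linear chains without transitive closure", {
  v <- tibble::tibble(timestamp = c(0, 100, 150, 260, 310, 420),
                      tag_id = rep(c("A", "B", "C"), each = 2))
  dc <- time_window_overlap(v, arrival_params(delta_t = 60, delta_i = 300))
  keys <- paste(dc$dyads$id_a, dc$dyads$id_b)
  expect_setequal(keys, c("A B", "B C")) # A-B-C chain, no A-C
})

test_that("window slicing assigns events and 7-day weeks", {
  ew <- tibble::tibble(event = "e1", start = as.Date("2015-11-02"),
                       end = as.Date("2015-11-02") + 105)
  t0 <- as.numeric(as.POSIXct("2015-11-02", tz = "UTC"))
  v <- tibble::tibble(timestamp = t0 + c(0, 6.5 * 86400, 7 * 86400, 104 * 86400),
                      tag_id = "A")
  s <- slice_windows(v, ew)
  expect_equal(s$week, c(1L, 1L, 2L, 15L)) # 15-week event spans weeks 1..15
  expect_equal(nrow(enumerate_weeks(ew)), 15)

  # boundary start included (half-open weeks); outside detections dropped
  v2 <- tibble::tibble(timestamp = t0 + c(-1, 0, 106 * 86400), tag_id = "A")
  expect_message(s2 <- slice_windows(v2, ew), "dropped 2")
  expect_equal(s2$week, 1L)
})

test_that("identity shuffling preserves each window's arrival-time multiset", {
  set.seed(5)
  arr <- random_stream(60)
  arr$event <- rep(c("e1", "e2"), 30)
  perm <- permute_identities(arr, permutation_config(seed = 3))
  expect_equal(sort(perm$arrival_time), sort(arr$arrival_time))
  for (ev in c("e1", "e2")) {
    a <- arr[arr$event == ev, ]; p <- perm[perm$event == ev, ]
    expect_equal(sort(p$arrival_time), sort(a$arrival_time))
    expect_setequal(unique(p$individual_id), unique(a$individual_id))
    expect_equal(sort(as.integer(table(p$individual_id))),
                 sort(as.integer(table(a$individual_id))))
  }
})
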