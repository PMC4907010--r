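test_that("the interval grid tiles the period half-open", {
  g <- make_interval_grid("2013-01-01 00:00", "2014-01-01 00:00")
  expect_length(g, 17520L)
  expect_equal(g[1], ts0("2013-01-01 00:00"))
  expect_equal(g[length(g)], ts0("2013-12-31 23:30"))
  expect_length(make_interval_grid("2013-01-01 00:00", "2013-01-01 01:00"), 2L)
  expect_error(make_interval_grid("2013-01-01 00:00", "2013-01-02 00:00",
                                  width_min = 0), "positive")
  expect_error(make_interval_grid("2013-01-01 00:00", "2013-01-02 00:00",
                                  width_min = 7), "divide")
  expect_error(make_interval_grid("2013-01-02 00:00", "2013-01-01 00:00"),
               "precede")
})

test_that("events bin into the interval whose start they fall on", {
  g <- make_interval_grid("2013-01-01 00:00", "2013-01-01 04:00")
  rec <- make_visits("2013-01-01 01:00", "2013-01-01 02:15")
  cnt <- count_events(rec, g)
  expect_equal(cnt$A, c(0, 0, 1, 0, 0, 0, 0, 0))  # boundary -> interval 3
  expect_equal(cnt$D, c(0, 0, 0, 0, 1, 0, 0, 0))
  # arrival and departure in the same interval count in both series
  rec2 <- make_visits("2013-01-01 00:40", "2013-01-01 00:50")
  cnt2 <- count_events(rec2, g)
  expect_equal(cnt2$A[2], 1); expect_equal(cnt2$D[2], 1)
  # events outside the grid spill, not crash
  rec3 <- make_visits("2012-12-31 22:00", "2013-01-01 01:00")
  cnt3 <- count_events(rec3, g)
  expect_equal(sum(cnt3$A), 0)
  expect_equal(unname(attr(cnt3, "spill")["A"]), 1L)
})

test_that("total binned arrivals equal a direct count of in-period records", {
  set.seed(21)
  g <- make_interval_grid("2013-06-01 00:00", "2013-06-11 00:00")
  rec <- random_records(1000, "2013-06-01 00:00", 10 * 1440)
  cnt <- count_events(rec, g)
  expect_equal(sum(cnt$A), nrow(rec))
  expect_equal(sum(cnt$D), nrow(rec))
})

test_that("the queue recursion reproduces hand arithmetic and telescopes", {
  expect_equal(queue_recursion(c(2, 1, 0), c(0, 2, 1)), c(0L, 2L, 1L, 0L))
  expect_equal(queue_recursion(c(3, 3), c(3, 3), q0 = 4L), c(4L, 4L, 4L))
  expect_error(queue_recursion(1:3, 1:2), "equal length")
  set.seed(22)
  A <- rpois(500, 3); D <- rpois(500, 3)
  Q <- suppressWarnings(queue_recursion(A, D, q0 = 10L))
  expect_length(Q, 501L)
  expect_equal(Q[length(Q)], 10L + sum(A) - sum(D))
})

test_that("negative queues warn but are never clamped", {
  expect_warning(Q <- queue_recursion(c(0, 1), c(2, 0)), "negative")
  expect_equal(Q, c(0L, -2L, -1L))
})

test_that("the census oracle counts presence directly", {
  g <- make_interval_grid("2013-01-01 00:00", "2013-01-01 05:00")
  expect_equal(census_oracle(make_visits(character(), character()), g),
               rep(0L, 10))
  # a visit spanning three intervals is present at exactly the three
  # interval starts after its entry
  rec <- make_visits("2013-01-01 00:45", "2013-01-01 02:10")
  expect_equal(census_oracle(rec, g), c(0L, 0L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L))
})

test_that("recursion over counted events equals the census oracle", {
  set.seed(23)
  g <- make_interval_grid("2013-02-01 00:00", "2013-02-08 00:00")
  rec <- random_records(2000, "2013-02-01 00:00", 7 * 1440)
  cnt <- count_events(rec, g)
  Q <- queue_recursion(cnt$A, cnt$D)
  expect_equal(Q[seq_along(g)], census_oracle(rec, g))
})

test_that("aggregate_table computes presence attributes and conserves flow", {
  g <- make_interval_grid("2013-01-01 00:00", "2013-01-01 03:00")
  none <- aggregate_table(make_visits(character(), character()), g,
                          builtin_queues("blackbox"))
  expect_true(all(is.na(none$mean_age)))
  expect_true(all(none$n_red == 0L))

  rec <- make_visits("2013-01-01 00:10", "2013-01-01 01:40",
                     age = 50, triage_score = 1L, trauma = TRUE)
  iv <- aggregate_table(rec, g, builtin_queues("blackbox"))
  # present at 00:30, 01:00, 01:30
  expect_equal(iv$n_red, c(0L, 1L, 1L, 1L, 0L, 0L))
  expect_equal(iv$n_trauma, c(0L, 1L, 1L, 1L, 0L, 0L))
  expect_equal(iv$mean_age[2], 50)
  expect_equal(attr(iv, "final_Q")$blackbox,
               0L + sum(iv$A_blackbox) - sum(iv$D_blackbox))
})

test_that("sub-queues nest inside the black box and sum to it on complete records", {
  set.seed(24)
  n <- 300
  arr <- ts0("2013-04-01 00:00") + floor(runif(n) * 4 * 1440) * 60
  los <- pmax(4, round(rexp(n, 1 / 200)))
  gaps <- matrix(rgamma(n * 4, 1.5), ncol = 4)
  fr <- gaps / rowSums(gaps)
  rec <- make_visits(arr, arr + los * 60,
                     triage = arr + round(fr[, 1] * los) * 60,
                     first_ews = arr + round((fr[, 1] + fr[, 2]) * los) * 60,
                     last_ews = arr + round(rowSums(fr[, 1:3]) * los) * 60)
  g <- make_interval_grid("2013-04-01 00:00", "2013-04-06 00:00")
  iv <- aggregate_table(rec, g)
  for (q in c("Q1", "Q2", "Q3", "Q4"))
    expect_true(all(iv$Q_blackbox >= iv[[paste0("Q_", q)]]))
  expect_equal(iv$Q_Q1 + iv$Q_Q2 + iv$Q_Q3 + iv$Q_Q4, iv$Q_blackbox)
})

test_that("halving the interval width changes no event totals", {
  set.seed(25)
  rec <- random_records(500, "2013-03-01 00:00", 5 * 1440)
  g30 <- make_interval_grid("2013-03-01 00:00", "2013-03-06 00:00", 30)
  g15 <- make_interval_grid("2013-03-01 00:00", "2013-03-06 00:00", 15)
  c30 <- count_events(rec, g30); c15 <- count_events(rec, g15)
  expect_equal(sum(c30$A), sum(c15$A))
  expect_equal(sum(c30$D), sum(c15$D))
})

test_that("order-violating records are excluded only from the violated queue", {
  rec <- make_visits("2013-01-01 00:10", "2013-01-01 02:40",
                     triage = "2013-01-01 01:30",
                     first_ews = "2013-01-01 01:00")  # triage after first EWS
  g <- make_interval_grid("2013-01-01 00:00", "2013-01-01 03:00")
  expect_equal(sum(count_events(rec, g, builtin_queues("Q2")[[1]])$A), 0L)
  expect_equal(sum(count_events(rec, g, builtin_queues("blackbox")[[1]])$A), 1L)
  expect_equal(sum(count_events(rec, g, builtin_queues("Q1")[[1]])$A), 1L)
})

test_that("flow completeness assigns each record exactly one category", {
  rec <- make_visits(
    arrival = rep("2013-01-01 10:00", 5),
    departure = rep("2013-01-01 12:00", 5),
    triage = c("2013-01-01 10:05", "2013-01-01 10:05", NA, NA,
               "2013-01-01 10:05"),
    first_ews = c("2013-01-01 10:30", NA, "2013-01-01 10:30", NA,
                  "2013-01-01 10:30"),
    last_ews = c("2013-01-01 11:30", NA, NA, NA, NA))
  fc <- classify_flow(rec)
  expect_equal(unname(fc$counts),
               c(1L, 2L, 1L, 1L))  # complete, triage_only, ews_no_triage, blackbox_only
  expect_equal(sum(fc$counts), fc$total)
  expect_equal(queue_definition("x", "arrival", "departure")$name, "x")
  expect_error(queue_definition("bad", "departure", "arrival"), "precede")
})
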