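test_that("the same spec yields byte-identical output", {
  spec <- simulation_spec("2013-01-01 00:00", "2013-01-08 00:00", seed = 9)
  a <- simulate_ed(spec)
  b <- simulate_ed(spec)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_patients(a, f1); write_patients(b, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("a zero arrival rate yields an empty record set with full schema", {
  spec <- simulation_spec("2013-01-01 00:00", "2013-01-03 00:00", seed = 1,
                          daily_mean = c(weekday = 0, weekend = 0))
  rec <- simulate_ed(spec)
  expect_equal(nrow(rec), 0L)
  expect_true(all(c("visit_id", "arrival", "departure", "triage_time") %in%
                    names(rec)))
})

test_that("flat-profile Poisson arrivals hit the configured interval mean", {
  spec <- simulation_spec("2013-04-01 00:00", "2013-05-01 00:00", seed = 13,
                          daily_mean = c(weekday = 96, weekend = 96),
                          profile = rep(1, 48), count_model = "poisson",
                          miss_prob = c(triage = 0, first_ews = 0,
                                        last_ews = 0))
  rec <- simulate_ed(spec)
  g <- make_interval_grid("2013-04-01 00:00", "2013-05-01 00:00")
  cnt <- count_events(rec, g)
  # mean 2.0 per interval; LOS can push exits past the grid but arrivals not
  se <- sqrt(2 / length(g))
  expect_lt(abs(mean(cnt$A) - 2), 3 * se)
})

test_that("simulated records satisfy every record invariant before missingness", {
  spec <- simulation_spec("2013-02-01 00:00", "2013-02-08 00:00", seed = 3,
                          miss_prob = c(triage = 0, first_ews = 0,
                                        last_ews = 0))
  rec <- simulate_ed(spec)
  expect_gt(nrow(rec), 0)
  expect_true(all(rec$arrival <= rec$departure))
  expect_true(all(rec$arrival <= rec$triage_time &
                    rec$triage_time <= rec$first_ews_time &
                    rec$first_ews_time <= rec$last_ews_time &
                    rec$last_ews_time <= rec$departure))
  expect_true(all(as.numeric(rec$arrival) %% 60 == 0))  # minute precision
  expect_true(all(rec$age >= 0 & rec$age < 95))
  expect_true(all(rec$triage_score %in% 1:5))
  # validation accepts all of them unchanged
  out <- validate_patients(rec)
  expect_equal(out$report$n_dropped, 0L)
  # length of stay respects the truncation bounds
  los_min <- as.numeric(rec$departure - rec$arrival, units = "mins")
  expect_true(all(los_min >= 1 & los_min <= spec$los_range[2]))
})

test_that("missingness injection matches its configured probabilities", {
  spec0 <- simulation_spec("2013-03-01 00:00", "2013-03-06 00:00", seed = 5,
                           miss_prob = c(triage = 0, first_ews = 0,
                                         last_ews = 0))
  rec <- simulate_ed(spec0)
  same <- inject_missingness(rec, c(triage = 0, first_ews = 0, last_ews = 0),
                             seed = 99)
  expect_identical(same, rec)
  all_gone <- inject_missingness(rec, c(triage = 1, first_ews = 1,
                                        last_ews = 1), seed = 99)
  fc <- classify_flow(all_gone)
  expect_equal(unname(fc$counts["blackbox_only"]), nrow(rec))
  # joint neither-share within 3 binomial SEs of p_triage * p_first
  set.seed(61)
  big <- rec[sample(nrow(rec), 10000, replace = TRUE), ]
  p <- c(triage = 0.71, first_ews = 0.8, last_ews = 0.5)
  miss <- inject_missingness(big, p, seed = 7)
  p_joint <- p[["triage"]] * p[["first_ews"]]
  share <- unname(classify_flow(miss)$counts["blackbox_only"]) / nrow(big)
  expect_lt(abs(share - p_joint), 3 * sqrt(p_joint * (1 - p_joint) / 10000))
  expect_error(inject_missingness(rec, c(triage = 1.2), seed = 1), "\\[0, 1\\]")
})

test_that("substreams are independent: missingness does not perturb arrivals", {
  s1 <- simulation_spec("2013-03-01 00:00", "2013-03-04 00:00", seed = 17,
                        miss_prob = c(triage = 0, first_ews = 0, last_ews = 0))
  s2 <- simulation_spec("2013-03-01 00:00", "2013-03-04 00:00", seed = 17,
                        miss_prob = c(triage = 0.9, first_ews = 0.5,
                                      last_ews = 0.5))
  r1 <- simulate_ed(s1); r2 <- simulate_ed(s2)
  expect_identical(r1$arrival, r2$arrival)
  expect_identical(r1$departure, r2$departure)
})

test_that("invalid specs fail before any draw", {
  expect_error(simulation_spec("2013-01-01 00:00", "2013-01-02 00:00",
                               daily_mean = c(weekday = -1, weekend = 10)),
               "non-negative")
  expect_error(simulation_spec("2013-01-01 00:00", "2013-01-02 00:00",
                               dispersion_k = 0), "dispersion_k")
  expect_error(simulation_spec("2013-01-02 00:00", "2013-01-01 00:00"),
               "period")
  expect_error(simulation_spec("2013-01-01 00:00", "2013-01-02 00:00",
                               miss_prob = c(triage = 2, first_ews = 0,
                                             last_ews = 0)), "\\[0, 1\\]")
  expect_error(simulation_spec("2013-01-01 00:00", "2013-01-02 00:00",
                               profile = rep(1, 10)), "48")
})

test_that("over-dispersed and Poisson specs are recovered by the dispersion index", {
  spec_nb <- simulation_spec("2013-01-07 00:00", "2013-02-18 00:00", seed = 29,
                             daily_mean = c(weekday = 96, weekend = 96),
                             profile = rep(1, 48),
                             count_model = "negative_binomial",
                             dispersion_k = 2)  # mu = 2, var/mean = 2
  rec <- simulate_ed(spec_nb)
  g <- make_interval_grid("2013-01-07 00:00", "2013-02-18 00:00")
  idx <- fisher_dispersion(count_events(rec, g)$A)
  expect_gt(idx$index, 1.5)
  expect_equal(idx$verdict, "over")
})

test_that("the YAML spec round-trips through the generator deterministically", {
  path <- system.file("extdata", "demo_sim_spec.yaml", package = "edcrowd")
  spec <- read_sim_spec(path)
  expect_s3_class(spec, "ed_sim_spec")
  expect_equal(spec$seed, 42L)
  expect_equal(spec$count_model, "negative_binomial")
  short <- simulation_spec("2013-01-01 00:00", "2013-01-03 00:00",
                           seed = spec$seed)
  expect_identical(simulate_ed(short), simulate_ed(short))
})
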