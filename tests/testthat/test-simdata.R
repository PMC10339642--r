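test_that("hazard_from_median implements h = log(2)/median", {
  expect_equal(hazard_from_median(log(2)), 1.0)
  expect_equal(hazard_from_median(20), log(2) / 20)
  expect_equal(hazard_from_median(10) / hazard_from_median(20), 2.0)
  # strictly decreasing in the median
  m <- c(0.5, 1, 2, 5, 10, 40)
  expect_true(all(diff(hazard_from_median(m)) < 0))
  expect_error(hazard_from_median(0), "positive")
  expect_error(hazard_from_median(-3), "positive")
})

test_that("condition validates its parameters and derives hazards", {
  cond <- condition(10, 5)
  expect_equal(cond$h_ae_verum, log(2) / 10)
  expect_equal(cond$h_death_verum, log(2) / 20)
  expect_equal(cond$censor_time, 30)
  expect_error(condition(0, 5), "median_ae_verum")
  expect_error(condition(10, 5, censor_time = -1), "censor_time")
  expect_error(condition(10, 5, censor_time = Inf), "finite")
})

test_that("true cause-specific HR is the inverse ratio of AE medians", {
  expect_equal(true_cs_hr(condition(10, 10)), 1.0)
  expect_equal(true_cs_hr(condition(20, 1)), 0.05)
  # fixed death medians 20 / 10 give a death HR of exactly 0.5
  cond <- condition(10, 10)
  expect_equal(cond$h_death_verum / cond$h_death_control, 0.5)
})

test_that("the 20x20 design grid partitions into 47.5/47.5/5 percent by truth", {
  grid <- condition_grid(1:20)
  expect_length(grid, 400)
  hr <- vapply(grid, true_cs_hr, numeric(1))
  expect_equal(sum(hr < 1), 190)
  expect_equal(sum(hr > 1), 190)
  expect_equal(sum(hr == 1), 20)
})

test_that("simulated trials satisfy the construction invariants", {
  cond <- condition(8, 3)
  d <- simulate_trial(cond, n_per_arm = 250, seed = 11)
  expect_equal(nrow(d), 500)
  expect_equal(as.vector(table(d$group)), c(250, 250))
  expect_true(all(d$event %in% 0:2))
  expect_true(all(d$time > 0 & d$time <= cond$censor_time))
  expect_true(all(d$time[d$event == 0L] == cond$censor_time))
  expect_true(all(d$time[d$event != 0L] < cond$censor_time))
  # identical seed reproduces bit-identically; different seed does not
  expect_identical(simulate_trial(cond, 250, seed = 11)$time, d$time)
  expect_false(identical(simulate_trial(cond, 250, seed = 12)$time, d$time))
})

test_that("a rate-zero (infinite-median) cause never fires", {
  cond <- condition(Inf, Inf)
  d <- simulate_trial(cond, n_per_arm = 200, seed = 3)
  expect_true(all(d$event %in% c(0L, 2L)))
  # and with also no deaths, everyone is administratively censored
  cond2 <- condition(Inf, Inf, median_death_verum = Inf,
                     median_death_control = Inf)
  d2 <- simulate_trial(cond2, n_per_arm = 50, seed = 3)
  expect_true(all(d2$event == 0L))
  expect_true(all(d2$time == 30))
})

test_that("empirical event-type frequencies match the analytic CIF", {
  cond <- condition(10, 10)
  n <- 40000
  d <- simulate_trial(cond, n_per_arm = n, seed = 29)
  for (arm in c(0L, 1L)) {
    for (cause in c(1L, 2L)) {
      p <- true_cif(cond, arm, cause, cond$censor_time)
      phat <- mean(d$event[d$group == arm] == cause)
      expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n))
    }
  }
})

test_that("analytic CIF obeys its boundary and conservation identities", {
  cond <- condition(7, 13)
  expect_equal(true_cif(cond, "verum", 1, 0), 0)
  # equal hazards split incidence equally in the limit
  sym <- condition(20, 5, median_death_verum = 20, median_death_control = 5)
  expect_equal(true_cif(sym, 1, 1, 1e9), 0.5, tolerance = 1e-12)
  expect_equal(true_cif(sym, 1, 2, 1e9), 0.5, tolerance = 1e-12)
  # two causes sum to the all-cause distribution function
  t <- c(0.5, 3, 12, 30)
  tot <- cond$h_ae_verum + cond$h_death_verum
  expect_equal(true_cif(cond, 1, 1, t) + true_cif(cond, 1, 2, t),
               1 - exp(-tot * t))
  expect_error(true_cif(cond, 1, 3, 5), "cause")
})

test_that("summarize_condition averages per-replicate medians", {
  # three replicates engineered so the control-arm AE medians are 4, 5, 6
  reps <- lapply(c(4, 5, 6), function(m) {
    toy_trial(time = c(m - 1, m, m + 1, 2), event = c(1, 1, 1, 2),
              group = c(0, 0, 0, 1))
  })
  s <- suppressWarnings(summarize_condition(reps))
  row <- s[s$group == 0 & s$event == 1, ]
  expect_equal(row$mean_median, 5)
  expect_equal(row$sd_median, 1)
  expect_equal(row$n_replicates, 3)
  # identical replicates have zero spread
  s2 <- suppressWarnings(summarize_condition(reps[c(1, 1, 1)]))
  expect_equal(s2[s2$group == 0 & s2$event == 1, "sd_median"], 0)
  # a replicate with no events of a cell is excluded with a warning
  w <- capture_warnings(s3 <- summarize_condition(reps))
  expect_match(w, "no events", all = FALSE)
  expect_equal(s3[s3$group == 1 & s3$event == 1, "n_replicates"], 0)
})

test_that("at large n without competing risk the median recovers the target", {
  cond <- condition(10, 10, median_death_verum = Inf,
                    median_death_control = Inf, censor_time = 1000)
  d <- simulate_trial(cond, n_per_arm = 50000, seed = 41)
  expect_equal(median(d$time[d$event == 1L]), 10, tolerance = 0.05)
})

test_that("trial CSV round-trips and malformed input is rejected", {
  d <- simulate_trial(condition(6, 9), n_per_arm = 40, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(d, path)
  back <- read_trial(path)
  expect_equal(back$time, d$time)
  expect_equal(back$event, d$event)
  expect_equal(back$group, d$group)
  bad <- d
  bad$event[3] <- 7L
  expect_error(validate_trial(bad), "event")
  bad2 <- d
  bad2$time[2] <- -1
  expect_error(validate_trial(bad2), "time")
  expect_error(validate_trial(d[0, ]), "empty")
  expect_error(read_trial(withr::local_tempfile(fileext = ".csv")), "not found")
})
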