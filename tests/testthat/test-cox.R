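test_that("symmetric arms force a null fit", {
  # identical multisets of (time, event) in both arms: score vanishes at 0
  t <- c(1, 2, 3, 4, 30)
  ev <- c(1, 1, 2, 1, 0)
  d <- toy_trial(time = c(t, t), event = c(ev, ev),
                 group = rep(c(0, 1), each = 5))
  f <- fit_cox_cause_specific(d)
  expect_equal(f$log_hr, 0, tolerance = 1e-10)
  expect_equal(f$hr, 1, tolerance = 1e-10)
  expect_equal(f$p_value, 1, tolerance = 1e-10)
})

test_that("the fit maximises the partial likelihood (brute-force oracle)", {
  # 4-subject toy with interleaved events so the maximum is interior
  # (fully separated arms give a monotone likelihood, tested elsewhere)
  d <- toy_trial(time = 1:4, event = rep(1L, 4), group = c(0, 1, 0, 1))
  f <- fit_cox_cause_specific(d)
  oracle <- brute_maximize(function(b)
    brute_partial_loglik(d$time, d$event, d$group, b))
  expect_equal(f$log_hr, oracle, tolerance = 1e-6)
  expect_true(f$converged)

  # richer 8-subject fixture with censoring and a competing event
  d8 <- toy_trial(time = c(0.5, 1.2, 2.0, 3.5, 0.8, 1.9, 2.7, 4.1),
                  event = c(1, 1, 2, 0, 1, 1, 1, 0),
                  group = c(0, 0, 0, 0, 1, 1, 1, 1))
  st <- as.integer(d8$event == 1L)
  f8 <- fit_cox_cause_specific(d8)
  oracle8 <- brute_maximize(function(b)
    brute_partial_loglik(d8$time, st, d8$group, b))
  expect_equal(f8$log_hr, oracle8, tolerance = 1e-6)
})

test_that("cox_partial_loglik matches the definition and is maximised at the fit", {
  # 2 events with risk sets of sizes 4 and 3 at beta = 0: -log4 - log3
  d <- toy_trial(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0),
                 group = c(1, 0, 1, 0))
  expect_equal(cox_partial_loglik(d, beta = 0), -log(4) - log(3))
  # agreement with the independent brute-force likelihood at arbitrary beta
  d8 <- toy_trial(time = c(0.5, 1.2, 2.0, 3.5, 0.8, 1.9, 2.7, 4.1),
                  event = c(1, 1, 2, 0, 1, 1, 1, 0),
                  group = c(0, 0, 0, 0, 1, 1, 1, 1))
  st <- as.integer(d8$event == 1L)
  for (b in c(-2, -0.3, 0, 0.7, 1.5)) {
    expect_equal(cox_partial_loglik(d8, beta = b),
                 brute_partial_loglik(d8$time, st, d8$group, b),
                 tolerance = 1e-10)
  }
  # first-order optimality and global dominance at the fitted value
  f8 <- fit_cox_cause_specific(d8)
  eps <- 1e-5
  deriv <- (cox_partial_loglik(d8, beta = f8$log_hr + eps) -
            cox_partial_loglik(d8, beta = f8$log_hr - eps)) / (2 * eps)
  expect_lt(abs(deriv), 1e-6)
  ll_hat <- cox_partial_loglik(d8, beta = f8$log_hr)
  expect_true(all(cox_partial_loglik(d8, beta = seq(-5, 5, by = 0.1)) <=
                    ll_hat + 1e-12))
})

test_that("the estimate depends on ranks only (time-scale invariance)", {
  d <- simulate_trial(condition(6, 12), n_per_arm = 80, seed = 13)
  f1 <- fit_cox_cause_specific(d)
  d2 <- d
  d2$time <- d$time * 37.5
  f2 <- fit_cox_cause_specific(d2)
  expect_equal(f1$log_hr, f2$log_hr, tolerance = 1e-9)
  expect_equal(f1$se, f2$se, tolerance = 1e-9)
})

test_that("fit agrees with survival::coxph (Efron ties) on simulated data", {
  skip_if_not_installed("survival")
  d <- simulate_trial(condition(9, 4), n_per_arm = 200, seed = 17)
  # introduce ties by coarse rounding to exercise the Efron correction
  d$time <- pmax(round(d$time * 2) / 2, 0.5)
  d$time[d$event == 0L] <- 30
  f <- fit_cox_cause_specific(d)
  ref <- survival::coxph(survival::Surv(time, event == 1) ~ group, data = d,
                         ties = "efron")
  expect_equal(f$log_hr, unname(coef(ref)), tolerance = 1e-7)
  expect_equal(f$se, sqrt(vcov(ref)[1, 1]), tolerance = 1e-7)
  expect_equal(f$p_value, summary(ref)$coefficients[1, "Pr(>|z|)"],
               tolerance = 1e-6)
})

test_that("large-sample fit recovers the design hazard ratio", {
  # verum median 5, control 10, no deaths: true HR = 2
  cond <- condition(5, 10, median_death_verum = Inf,
                    median_death_control = Inf)
  d <- simulate_trial(cond, n_per_arm = 50000, seed = 23)
  f <- fit_cox_cause_specific(d)
  expect_lt(abs(f$log_hr - log(2)), 3 * f$se)
})

test_that("degenerate inputs are handled as contracted", {
  # no events of the requested cause
  d <- toy_trial(time = c(1, 2, 30, 30), event = c(2, 2, 0, 0),
                 group = c(0, 1, 0, 1))
  expect_error(fit_cox_cause_specific(d, cause = 1), "no events")
  # monotone likelihood: all events in one arm -> capped, flagged
  dm <- toy_trial(time = c(1, 2, 3, 30, 30, 30), event = c(1, 1, 1, 0, 0, 0),
                  group = c(1, 1, 1, 0, 0, 0))
  fm <- fit_cox_cause_specific(dm)
  expect_false(fm$converged)
  expect_equal(abs(fm$log_hr), 15)
})

test_that("FitResult invariants hold and the flat export is faithful", {
  d <- simulate_trial(condition(7, 7), n_per_arm = 100, seed = 31)
  f <- fit_cox_cause_specific(d)
  expect_equal(f$hr, exp(f$log_hr))
  expect_true(f$ci_low < f$hr && f$hr < f$ci_high)
  expect_true(f$p_value >= 0 && f$p_value <= 1)
  expect_equal(f$n_events, sum(d$event == 1L))
  row <- as.data.frame(f)
  expect_equal(row$log_hr, f$log_hr)
  expect_equal(row$setting, "cs")
  expect_equal(nrow(row), 1L)
})
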