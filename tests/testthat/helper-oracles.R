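# Independent brute-force oracles, written directly from the definitions and
# deliberately naive: explicit loops over risk sets, grid/golden-section
# maximisation. They share no code with the package's fitters.

# Breslow-form log partial likelihood by explicit risk-set enumeration.
# `at_risk` gives, for subject i and event time t, whether i is in the risk
# set; the default is the ordinary (cause-specific) rule. Fixtures used with
# this oracle have no tied event times, so Breslow = Efron.
brute_partial_loglik <- function(time, status, x, beta,
                                 at_risk = function(ti, t) ti >= t) {
  ll <- 0
  for (i in which(status == 1L)) {
    rs <- which(vapply(time, at_risk, logical(1), t = time[i]))
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[rs])))
  }
  ll
}

# maximise a unimodal function on [-10, 10] by fine grid + optimize polish
brute_maximize <- function(f, lower = -10, upper = 10) {
  grid <- seq(lower, upper, by = 0.01)
  vals <- vapply(grid, f, numeric(1))
  b0 <- grid[which.max(vals)]
  stats::optimize(f, c(max(lower, b0 - 0.02), min(upper, b0 + 0.02)),
                  maximum = TRUE, tol = 1e-9)$maximum
}

# extended risk set rule of the censoring-complete subdistribution model:
# a subject with the competing event stays at risk until censor_time
fg_at_risk <- function(time, event, censor_time) {
  function(i, t) time[i] >= t || (event[i] == 2L && censor_time >= t)
}

brute_fg_loglik <- function(time, event, x, beta, censor_time) {
  ll <- 0
  for (i in which(event == 1L)) {
    rs <- which(vapply(seq_along(time), fg_at_risk(time, event, censor_time),
                       logical(1), t = time[i]))
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[rs])))
  }
  ll
}

# assemble a small trial data.frame from parallel vectors
toy_trial <- function(time, event, group) {
  data.frame(id = seq_along(time), time = time, event = as.integer(event),
             group = as.integer(group))
}

# condition used by several large-sample checks: equal AE medians of 10,
# death medians 20/10, censoring 30
null_condition <- function() condition(10, 10)
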