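# Non-parametric one-sample estimators used to contrast naive ("as if
# nothing else could happen") incidence with incidence that accounts for the
# competing event: Kaplan-Meier, Nelson-Aalen, and the Aalen-Johansen
# cumulative incidence function.

new_stepcurve <- function(times, values, variance = NULL, type, estimator,
                          group = NA_integer_, cause = NA_integer_) {
  structure(list(times = times, values = values, variance = variance,
                 type = type, estimator = estimator,
                 group = group, cause = cause),
            class = "cr_stepcurve")
}

#' @export
print.cr_stepcurve <- function(x, ...) {
  cat(sprintf("%s step curve (%s), %d steps, group %s, cause %s\n",
              x$estimator, x$type, length(x$times),
              as.character(x$group), as.character(x$cause)))
  if (length(x$times)) {
    cat(sprintf("  last step: t = %g, value = %.5f\n",
                x$times[length(x$times)], x$values[length(x$values)]))
  }
  invisible(x)
}

#' Evaluate a step curve at arbitrary times
#'
#' Right-continuous step interpolation; before the first jump a survival
#' curve is 1 and an incidence or cumulative-hazard curve is 0.
#'
#' @param curve A `"cr_stepcurve"` from [kaplan_meier()], [nelson_aalen()]
#'   or [aalen_johansen_cif()].
#' @param t Time(s) at which to evaluate.
#' @return Numeric vector of curve values.
#' @export
stepcurve_at <- function(curve, t) {
  stopifnot(inherits(curve, "cr_stepcurve"))
  start <- if (curve$type == "survival") 1 else 0
  idx <- findInterval(t, curve$times)
  c(start, curve$values)[idx + 1]
}

#' Tidy export of a step curve
#'
#' @param x A `"cr_stepcurve"` object.
#' @param row.names,optional,... Standard [as.data.frame()] arguments, unused.
#' @return Columns `time`, `estimate`, `variance`, `group`, `cause`,
#'   `estimator` — one row per step.
#' @export
as.data.frame.cr_stepcurve <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  data.frame(time = x$times, estimate = x$values,
             variance = if (is.null(x$variance)) NA_real_ else x$variance,
             group = x$group, cause = x$cause, estimator = x$estimator)
}

# shared tabulation: at each distinct time with >= 1 event (any cause),
# number at risk, events of each cause, with censorings at an event time
# ordered after the events (they leave the risk set at the next time)
risk_table <- function(time, event) {
  et <- sort(unique(time[event != 0L]))
  st <- sort(time)
  n_risk <- length(st) - findInterval(et, st, left.open = TRUE)
  d1 <- as.vector(table(factor(time[event == 1L], levels = et)))
  d2 <- as.vector(table(factor(time[event == 2L], levels = et)))
  list(times = et, n_risk = n_risk, d1 = d1, d2 = d2)
}

subset_group <- function(data, group) {
  validate_trial(data)
  if (!is.null(group)) {
    g <- normalize_arm(group)
    data <- data[data$group == g, , drop = FALSE]
    if (nrow(data) == 0L) stop("no subjects in the requested group",
                               call. = FALSE)
  }
  data
}

#' Kaplan-Meier survival curve for one cause
#'
#' The product-limit estimator for the event of interest, treating competing
#' events as censored at their occurrence time. Its complement 1 - KM is the
#' naive incidence of the cause, interpreted as the absolute risk "as if
#' nothing else could happen first"; with competing events present it
#' systematically exceeds the Aalen-Johansen cumulative incidence.
#'
#' @param data A trial data.frame (columns `time`, `event`, `group`).
#' @param cause Event code treated as the event; all other nonzero codes are
#'   censored.
#' @param group Restrict to one arm (0/1 or "control"/"verum"); `NULL` pools
#'   both arms.
#' @return A `"cr_stepcurve"` of type `"survival"` with Greenwood pointwise
#'   variance.
#' @export
kaplan_meier <- function(data, cause = 1L, group = NULL) {
  data <- subset_group(data, group)
  ev <- as.integer(data$event == cause)
  rt <- risk_table(data$time, ev)
  surv <- cumprod(1 - rt$d1 / rt$n_risk)
  greenwood <- surv^2 * cumsum(rt$d1 / (rt$n_risk * pmax(rt$n_risk - rt$d1, 1)))
  new_stepcurve(rt$times, surv, greenwood, type = "survival",
                estimator = "kaplan-meier",
                group = if (is.null(group)) NA_integer_ else normalize_arm(group),
                cause = as.integer(cause))
}

#' Nelson-Aalen cumulative hazard for one cause
#'
#' The cumulative sum of `d_i / n_i` over event times, competing events
#' censored. `exp(-NA)` dominates the Kaplan-Meier curve pointwise and
#' converges to it as increments shrink.
#'
#' @inheritParams kaplan_meier
#' @return A `"cr_stepcurve"` of type `"cumhaz"` with Poisson-type variance
#'   `cumsum(d_i / n_i^2)`.
#' @export
nelson_aalen <- function(data, cause = 1L, group = NULL) {
  data <- subset_group(data, group)
  ev <- as.integer(data$event == cause)
  rt <- risk_table(data$time, ev)
  na <- cumsum(rt$d1 / rt$n_risk)
  v <- cumsum(rt$d1 / rt$n_risk^2)
  new_stepcurve(rt$times, na, v, type = "cumhaz", estimator = "nelson-aalen",
                group = if (is.null(group)) NA_integer_ else normalize_arm(group),
                cause = as.integer(cause))
}

#' Aalen-Johansen cumulative incidence function
#'
#' The non-parametric cumulative incidence of one cause in the presence of
#' the other: \eqn{F_k(t) = \sum_{t_i \le t} S(t_i^-)\, d_{k,i}/n_i}, where
#' \eqn{S} is the all-cause Kaplan-Meier survival. At every event time the
#' cause-specific CIFs and the all-cause survival sum to 1, and with zero
#' competing events the estimator reduces exactly to 1 - KM.
#'
#' @inheritParams kaplan_meier
#' @param cause Cause whose incidence is estimated (1 = AE, 2 = death).
#' @return A `"cr_stepcurve"` of type `"incidence"` (no pointwise variance).
#' @export
aalen_johansen_cif <- function(data, cause = 1L, group = NULL) {
  data <- subset_group(data, group)
  rt <- risk_table(data$time, data$event)
  d_all <- rt$d1 + rt$d2
  s_all <- cumprod(1 - d_all / rt$n_risk)
  s_minus <- c(1, s_all[-length(s_all)])
  dk <- if (cause == 1L) rt$d1 else if (cause == 2L) rt$d2 else
    stop("unknown cause code: ", cause, call. = FALSE)
  cif <- cumsum(s_minus * dk / rt$n_risk)
  new_stepcurve(rt$times, cif, NULL, type = "incidence",
                estimator = "aalen-johansen",
                group = if (is.null(group)) NA_integer_ else normalize_arm(group),
                cause = as.integer(cause))
}
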