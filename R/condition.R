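#' Convert a target median event time into an exponential hazard rate
#'
#' For an exponential event-time distribution the median \eqn{t_{0.5}} and the
#' constant hazard \eqn{h} are linked by \eqn{h = \log(2)/t_{0.5}}. The trial
#' simulator parameterises every cause in every arm through this formula.
#'
#' @param median Target median time to event, in months. Must be strictly
#'   positive. `Inf` is allowed and yields a rate of 0 (a cause that never
#'   fires), which is useful for degenerate designs without a competing risk.
#' @return Hazard rate per month.
#' @examples
#' hazard_from_median(20)           # 0.0347 per month
#' hazard_from_median(10) / hazard_from_median(20)  # exactly 2
#' @export
hazard_from_median <- function(median) {
  if (!is.numeric(median) || any(is.na(median)) || any(median <= 0)) {
    stop("`median` must be strictly positive (months)", call. = FALSE)
  }
  log(2) / median
}

#' Define one simulated trial condition
#'
#' A condition is one cell of the simulation design: the median time to the
#' first adverse event (AE) in each arm, the median survival (death medians)
#' in each arm, and the administrative censoring horizon. Defaults reproduce
#' the fixed parts of the study design: death medians of 20 (verum) and 10
#' (control) months, i.e. a death hazard ratio of 0.5 in favour of verum, and
#' censoring at 30 months.
#'
#' @param median_ae_verum,median_ae_control Median time to first AE per arm
#'   (months, > 0; `Inf` allowed for a never-firing cause).
#' @param median_death_verum,median_death_control Median survival per arm.
#' @param censor_time Administrative censoring time (months, > 0).
#' @return An object of class `"cr_condition"`: a list of the five parameters
#'   plus the derived per-cause, per-arm hazard rates.
#' @seealso [condition_grid()], [simulate_trial()], [true_cs_hr()]
#' @export
condition <- function(median_ae_verum, median_ae_control,
                      median_death_verum = 20, median_death_control = 10,
                      censor_time = 30) {
  for (nm in c("median_ae_verum", "median_ae_control",
               "median_death_verum", "median_death_control", "censor_time")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop(sprintf("`%s` must be a single strictly positive number", nm),
           call. = FALSE)
    }
  }
  if (!is.finite(censor_time)) {
    stop("`censor_time` must be finite", call. = FALSE)
  }
  structure(
    list(
      median_ae_verum = median_ae_verum,
      median_ae_control = median_ae_control,
      median_death_verum = median_death_verum,
      median_death_control = median_death_control,
      censor_time = censor_time,
      # hazards: rows = cause (1 AE, 2 death), cols = arm (control, verum)
      h_ae_verum = log(2) / median_ae_verum,
      h_ae_control = log(2) / median_ae_control,
      h_death_verum = log(2) / median_death_verum,
      h_death_control = log(2) / median_death_control
    ),
    class = "cr_condition"
  )
}

#' @export
print.cr_condition <- function(x, ...) {
  cat("Trial condition (months):\n")
  cat(sprintf("  median time to AE   : verum %g, control %g (true cause-specific HR %.4g)\n",
              x$median_ae_verum, x$median_ae_control, true_cs_hr(x)))
  cat(sprintf("  median survival     : verum %g, control %g\n",
              x$median_death_verum, x$median_death_control))
  cat(sprintf("  administrative censoring at %g\n", x$censor_time))
  invisible(x)
}

#' Enumerate the grid of simulated conditions
#'
#' Builds the full factorial design over median times to first adverse event,
#' one condition per (verum, control) pair. The default 1--20 month range in
#' 1-month steps gives the 400 "conditions of interest" of the study design.
#'
#' @param ae_medians Vector of AE medians used for both arms (months).
#' @param ... Passed to [condition()] (death medians, censoring time).
#' @return A list of `"cr_condition"` objects, in column-major order
#'   (control median varying slowest), each carrying `verum` / `control`
#'   attributes with its grid coordinates.
#' @export
condition_grid <- function(ae_medians = 1:20, ...) {
  cells <- expand.grid(verum = ae_medians, control = ae_medians)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cond <- condition(median_ae_verum = cells$verum[i],
                      median_ae_control = cells$control[i], ...)
    attr(cond, "verum") <- cells$verum[i]
    attr(cond, "control") <- cells$control[i]
    out[[i]] <- cond
  }
  out
}

#' True cause-specific hazard ratio of a condition
#'
#' The design truth: the ratio of the AE hazard in the verum arm to that in
#' the control arm, i.e. `median_ae_control / median_ae_verum`. Values below 1
#' mean verum is the safer arm.
#'
#' @param cond A [condition()] object.
#' @return Dimensionless hazard ratio.
#' @export
true_cs_hr <- function(cond) {
  stopifnot(inherits(cond, "cr_condition"))
  cond$h_ae_verum / cond$h_ae_control
}

#' Analytic cumulative incidence under the exponential latent-time model
#'
#' With constant cause-specific hazards \eqn{h_1} (AE) and \eqn{h_2} (death),
#' the cumulative incidence of cause \eqn{k} at time \eqn{t} is
#' \deqn{F_k(t) = \frac{h_k}{h_1 + h_2}\left(1 - e^{-(h_1+h_2)t}\right).}
#' This is the uncensored truth used as the analytic oracle for the
#' non-parametric and model-based incidence estimators.
#'
#' @param cond A [condition()] object.
#' @param arm `"verum"` or `"control"` (or codes 1 / 0).
#' @param cause Event code: 1 = adverse event of interest, 2 = death.
#' @param t Time(s) in months, >= 0.
#' @return Probability in \[0, 1\] (vectorised over `t`).
#' @export
true_cif <- function(cond, arm, cause, t) {
  stopifnot(inherits(cond, "cr_condition"), all(t >= 0))
  arm <- normalize_arm(arm)
  h1 <- if (arm == 1L) cond$h_ae_verum else cond$h_ae_control
  h2 <- if (arm == 1L) cond$h_death_verum else cond$h_death_control
  hk <- switch(as.character(cause), "1" = h1, "2" = h2,
               stop("unknown cause code: ", cause, call. = FALSE))
  tot <- h1 + h2
  if (tot == 0) return(rep(0, length(t)))
  hk / tot * (1 - exp(-tot * t))
}

normalize_arm <- function(arm) {
  if (is.character(arm)) {
    arm <- match.arg(arm, c("control", "verum"))
    return(if (arm == "verum") 1L else 0L)
  }
  if (!arm %in% c(0, 1)) stop("`arm` must be 0/1 or 'control'/'verum'",
                              call. = FALSE)
  as.integer(arm)
}
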