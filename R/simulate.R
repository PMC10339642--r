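#' Simulate one two-arm competing-risks trial
#'
#' Draws, for every patient, independent latent exponential times for the
#' adverse event of interest and for death, with arm- and cause-specific
#' hazards taken from the condition. The observed record is the minimum of the
#' two latent times and the administrative censoring horizon:
#' event code 1 (AE) or 2 (death) if a latent time wins, 0 if the patient is
#' still event-free at the censoring time. Allocation is 1:1, `n_per_arm`
#' patients per arm.
#'
#' A latent time exactly equal to the censoring time (a measure-zero event,
#' possible only through floating-point rounding) is treated as censored.
#'
#' @param cond A [condition()] object.
#' @param n_per_arm Patients per arm (default 300, i.e. a 600-patient trial).
#' @param seed Optional integer seed applied via [set.seed()] before drawing;
#'   `NULL` uses the current RNG state.
#' @return A `data.frame` of class `"cr_trial"` with columns `id`, `time`
#'   (months), `event` (0 censored / 1 AE / 2 death) and `group` (0 control /
#'   1 verum), plus the condition and seed stored as attributes.
#' @examples
#' d <- simulate_trial(condition(10, 5), n_per_arm = 100, seed = 1)
#' table(d$event, d$group)
#' @export
simulate_trial <- function(cond, n_per_arm = 300, seed = NULL) {
  stopifnot(inherits(cond, "cr_condition"))
  if (!is.numeric(n_per_arm) || n_per_arm < 1) {
    stop("`n_per_arm` must be >= 1", call. = FALSE)
  }
  n_per_arm <- as.integer(n_per_arm)
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * n_per_arm
  group <- rep(c(0L, 1L), each = n_per_arm)

  # rexp() with rate 0 returns Inf, which is exactly the never-firing cause
  rate_ae <- ifelse(group == 1L, cond$h_ae_verum, cond$h_ae_control)
  rate_d <- ifelse(group == 1L, cond$h_death_verum, cond$h_death_control)
  t_ae <- rexp_safe(n, rate_ae)
  t_death <- rexp_safe(n, rate_d)

  time <- pmin(t_ae, t_death, cond$censor_time)
  event <- integer(n)
  event[t_ae < cond$censor_time & t_ae <= t_death] <- 1L
  event[t_death < cond$censor_time & t_death < t_ae] <- 2L

  out <- data.frame(id = seq_len(n), time = time, event = event, group = group)
  attr(out, "condition") <- cond
  attr(out, "seed") <- seed
  class(out) <- c("cr_trial", "data.frame")
  out
}

rexp_safe <- function(n, rate) {
  out <- rep(Inf, n)
  pos <- rate > 0
  # draw in original subject order so the stream is reproducible
  if (any(pos)) out[pos] <- stats::rexp(sum(pos), rate[pos])
  out
}

#' Validate a long-format event table
#'
#' Checks the column contract shared by the simulator and the fitters:
#' `time` positive, `event` in \{0, 1, 2\}, `group` in \{0, 1\}. Used on
#' user-supplied tables before fitting.
#'
#' @param data A data.frame with columns `time`, `event`, `group` (an `id`
#'   column is tolerated and ignored).
#' @return The validated data.frame, invisibly.
#' @export
validate_trial <- function(data) {
  need <- c("time", "event", "group")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  bad <- which(!is.finite(data$time) | data$time <= 0)
  if (length(bad)) {
    stop("non-positive or missing `time` in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!data$event %in% c(0L, 1L, 2L))
  if (length(bad)) {
    stop("`event` must be 0 (censored), 1 (AE) or 2 (death); bad row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!data$group %in% c(0L, 1L))
  if (length(bad)) {
    stop("`group` must be 0 (control) or 1 (verum); bad row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(data)
}

#' Write / read a trial in the long CSV dialect
#'
#' One row per subject with columns `id,time,event,group`. This is both the
#' export format of the simulator and the ingestion format for user data.
#'
#' @param data A trial data.frame (see [simulate_trial()]).
#' @param path File path.
#' @return `write_trial()`: the path, invisibly. `read_trial()`: the
#'   validated data.frame.
#' @export
write_trial <- function(data, path) {
  validate_trial(data)
  utils::write.csv(data[, c("id", "time", "event", "group")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- tryCatch(
    utils::read.csv(path, colClasses = c(NA, "numeric", "integer", "integer")),
    error = function(e) stop("malformed CSV (", conditionMessage(e), ")",
                             call. = FALSE)
  )
  validate_trial(data)
  data
}

#' Descriptive medians across replicate trials
#'
#' For each arm and cause, takes the per-replicate sample median of the
#' observed event times among subjects who experienced that cause, then
#' reports the across-replicate mean of those medians and their
#' across-replicate standard deviation. A replicate with no events of a cause
#' in an arm contributes a missing value and is dropped from that cell, with
#' a warning recording how many were dropped.
#'
#' @param replicates A list of trial data.frames from [simulate_trial()].
#' @return A data.frame with columns `group`, `event`, `mean_median`,
#'   `sd_median`, `n_replicates` (contributing replicates).
#' @export
summarize_condition <- function(replicates) {
  if (!length(replicates)) stop("need at least one replicate", call. = FALSE)
  cells <- expand.grid(group = c(0L, 1L), event = c(1L, 2L))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    g <- cells$group[i]; ev <- cells$event[i]
    meds <- vapply(replicates, function(d) {
      tt <- d$time[d$group == g & d$event == ev]
      if (length(tt)) stats::median(tt) else NA_real_
    }, numeric(1))
    ok <- !is.na(meds)
    if (any(!ok)) {
      warning(sprintf(
        "group %d, event %d: %d replicate(s) had no events and were excluded",
        g, ev, sum(!ok)), call. = FALSE)
    }
    data.frame(group = g, event = ev,
               mean_median = if (any(ok)) mean(meds[ok]) else NA_real_,
               sd_median = if (sum(ok) > 1) stats::sd(meds[ok]) else NA_real_,
               n_replicates = sum(ok))
  })
  do.call(rbind, rows)
}
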