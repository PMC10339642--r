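#' Default configuration of the grid experiment
#'
#' The defaults are the study design itself: a 20 x 20 grid of median times
#' to first adverse event (1-20 months per arm), 600 patients per trial
#' (1:1), death medians fixed at 20 (verum) / 10 (control) months,
#' administrative censoring at 30 months, 1 000 replications per condition,
#' alpha 0.05. Reduce `reps` and/or the grid for desk-scale runs; that
#' changes only Monte-Carlo precision, never the code path.
#'
#' @param ... Named overrides of any default field.
#' @return A named list of class `"cr_config"`.
#' @export
default_config <- function(...) {
  cfg <- list(
    grid_min = 1,
    grid_max = 20,
    grid_step = 1,
    n_per_arm = 300,
    reps = 1000,
    median_death_verum = 20,
    median_death_control = 10,
    censor_time = 30,
    alpha = 0.05,
    seed = 1,
    settings = c("cs", "sd")
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  class(cfg) <- "cr_config"
  validate_config(cfg)
}

#' Read an experiment configuration from YAML or JSON
#'
#' Fields omitted from the file keep their [default_config()] values.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `"cr_config"` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(default_config, raw)
}

validate_config <- function(cfg) {
  chk <- function(field, ok, what) {
    if (!ok) stop(sprintf("config field `%s`: %s", field, what),
                  call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk("grid_min", num1(cfg$grid_min) && cfg$grid_min > 0,
      "must be a positive number (months)")
  chk("grid_max", num1(cfg$grid_max) && cfg$grid_max >= cfg$grid_min,
      "must be a number >= grid_min")
  chk("grid_step", num1(cfg$grid_step) && cfg$grid_step > 0,
      "must be a positive step (months)")
  chk("n_per_arm", num1(cfg$n_per_arm) && cfg$n_per_arm >= 1,
      "must be a count >= 1")
  chk("reps", num1(cfg$reps) && cfg$reps >= 2,
      "must be a count >= 2 (pooling needs at least 2 replicates)")
  chk("median_death_verum", num1(cfg$median_death_verum) &&
        cfg$median_death_verum > 0, "must be positive (months)")
  chk("median_death_control", num1(cfg$median_death_control) &&
        cfg$median_death_control > 0, "must be positive (months)")
  chk("censor_time", num1(cfg$censor_time) && cfg$censor_time > 0,
      "must be positive (months)")
  chk("alpha", num1(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1,
      "must be in (0, 1)")
  chk("seed", num1(cfg$seed) && cfg$seed == round(cfg$seed),
      "must be an integer")
  chk("settings", is.character(cfg$settings) &&
        all(cfg$settings %in% c("cs", "sd")) && length(cfg$settings) >= 1,
      "must be a subset of c('cs', 'sd')")
  cfg
}

#' Deterministic per-replicate seed table
#'
#' One master seed is expanded into one substream seed per
#' (condition, replicate) cell, so that any single replicate can be re-run
#' in isolation from the manifest.
#'
#' @param master Master seed (integer).
#' @param n_conditions,reps Grid size and replications.
#' @return An integer matrix, `n_conditions` x `reps`.
#' @export
replicate_seeds <- function(master, n_conditions, reps) {
  set.seed(master)
  matrix(sample.int(.Machine$integer.max - 1L, n_conditions * reps,
                    replace = n_conditions * reps > 1e7),
         nrow = n_conditions, ncol = reps)
}

#' Run the full grid experiment
#'
#' For every condition of the grid: simulate `reps` independent trials, fit
#' the cause-specific and/or subdistribution model to each, pool the
#' replicate log-HRs by Rubin's rules, and classify. The per-condition
#' pooled rows are then cross-classified into the nine switching categories
#' and summarised by [grid_report()].
#'
#' @param config A `"cr_config"` from [default_config()] / [load_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `manifest.json`, `conditions.csv`, the three `map_*.csv` tables and
#'   `summary.json` via [write_report()].
#' @param progress Emit a [message()] every `progress` conditions (0 = quiet).
#' @return A list of class `"cr_experiment"`: `report` (a `"cr_report"`),
#'   `results` (the long per-(condition, setting) pooled table), `config`,
#'   and `manifest`.
#' @examples
#' \donttest{
#' ex <- run_experiment(default_config(grid_max = 3, reps = 5, seed = 42),
#'                      progress = 0)
#' ex$report$outcome_margins
#' }
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL,
                           progress = 50) {
  config <- validate_config(config)
  medians <- seq(config$grid_min, config$grid_max, by = config$grid_step)
  grid <- condition_grid(medians,
                         median_death_verum = config$median_death_verum,
                         median_death_control = config$median_death_control,
                         censor_time = config$censor_time)
  n_cond <- length(grid)
  seeds <- replicate_seeds(config$seed, n_cond, config$reps)

  rows <- vector("list", n_cond * length(config$settings))
  descr <- vector("list", n_cond)
  excl_total <- integer(0)
  for (ci in seq_len(n_cond)) {
    cond <- grid[[ci]]
    fits <- replicate_fits(cond, config, seeds[ci, ])
    descr[[ci]] <- cbind(verum = attr(cond, "verum"),
                         control = attr(cond, "control"),
                         fits$medians)
    for (s in config$settings) {
      f <- fits[[s]]
      ok <- f$converged
      n_excl <- sum(!ok)
      excl_total <- c(excl_total, n_excl)
      pooled <- tryCatch(pool_rubin(f[ok, , drop = FALSE],
                                    alpha = config$alpha),
                         error = function(e) NULL)
      row <- data.frame(
        verum = attr(cond, "verum"), control = attr(cond, "control"),
        hr_true = true_cs_hr(cond), setting = s,
        m = sum(ok), n_excluded = n_excl,
        hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        p_value = NA_real_, qbar = NA_real_, W = NA_real_, B = NA_real_,
        T = NA_real_)
      if (!is.null(pooled)) {
        row[c("hr", "ci_low", "ci_high", "p_value", "qbar", "W", "B", "T")] <-
          pooled[c("hr", "ci_low", "ci_high", "p_value", "qbar", "W", "B", "T")]
      }
      rows[[(ci - 1L) * length(config$settings) + match(s, config$settings)]] <- row
    }
    if (progress > 0 && ci %% progress == 0) {
      message(sprintf("condition %d/%d done (%d exclusions so far)",
                      ci, n_cond, sum(excl_total)))
    }
  }
  results <- do.call(rbind, rows)
  bad <- is.na(results$hr)
  if (any(bad)) {
    warning(sprintf("%d (condition, setting) cell(s) were unanalyzable",
                    sum(bad)), call. = FALSE)
    results <- results[!bad, , drop = FALSE]
  }
  report <- grid_report(results, alpha = config$alpha)
  manifest <- list(
    config = unclass(config),
    n_conditions = n_cond,
    seed_table_digest = sum(as.double(seeds)),
    n_excluded_total = sum(excl_total),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("crsafety")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  out <- structure(list(report = report, results = results,
                        descriptives = do.call(rbind, descr),
                        config = config, manifest = manifest),
                   class = "cr_experiment")
  if (!is.null(out_dir)) {
    write_report(report, out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(out$descriptives,
                     file.path(out_dir, "descriptive_medians.csv"),
                     row.names = FALSE)
  }
  out
}

# simulate and fit all replicates of one condition; returns per-setting
# data.frames (log_hr, se, converged) plus pooled descriptive medians
replicate_fits <- function(cond, config, seeds) {
  reps <- config$reps
  res <- list()
  for (s in config$settings) {
    res[[s]] <- data.frame(log_hr = numeric(reps), se = numeric(reps),
                           converged = logical(reps))
  }
  med <- matrix(NA_real_, nrow = reps, ncol = 4)  # ae0, ae1, death0, death1
  for (r in seq_len(reps)) {
    d <- simulate_trial(cond, n_per_arm = config$n_per_arm, seed = seeds[r])
    med[r, ] <- c(
      stats::median(d$time[d$group == 0L & d$event == 1L]),
      stats::median(d$time[d$group == 1L & d$event == 1L]),
      stats::median(d$time[d$group == 0L & d$event == 2L]),
      stats::median(d$time[d$group == 1L & d$event == 2L]))
    for (s in config$settings) {
      f <- tryCatch(
        if (s == "cs") fit_cox_cause_specific(d, alpha = config$alpha)
        else fit_fine_gray(d, alpha = config$alpha),
        error = function(e) NULL)
      if (is.null(f)) {
        res[[s]][r, ] <- list(NA_real_, NA_real_, FALSE)
      } else {
        res[[s]][r, ] <- list(f$log_hr, f$se, f$converged)
      }
    }
  }
  res$medians <- data.frame(
    mean_median_ae_control = mean(med[, 1], na.rm = TRUE),
    sd_median_ae_control = stats::sd(med[, 1][!is.na(med[, 1])]),
    mean_median_ae_verum = mean(med[, 2], na.rm = TRUE),
    sd_median_ae_verum = stats::sd(med[, 2][!is.na(med[, 2])]),
    mean_median_death_control = mean(med[, 3], na.rm = TRUE),
    sd_median_death_control = stats::sd(med[, 3][!is.na(med[, 3])]),
    mean_median_death_verum = mean(med[, 4], na.rm = TRUE),
    sd_median_death_verum = stats::sd(med[, 4][!is.na(med[, 4])]))
  res
}

#' @export
print.cr_experiment <- function(x, ...) {
  cat(sprintf("Grid experiment: %d conditions x %d replications, n = %d/trial\n",
              x$manifest$n_conditions, x$config$reps, 2 * x$config$n_per_arm))
  print(x$report)
  invisible(x)
}

#' Fit a single delimited-text dataset
#'
#' Single-dataset entry point for user data in the long CSV dialect
#' (`id,time,event,group`).
#'
#' @param path CSV path.
#' @param setting `"cs"` (cause-specific Cox) or `"sd"` (Fine-Gray).
#' @param cause Event code of interest.
#' @param censor_time Required for `"sd"` when the administrative horizon is
#'   not the maximum observed time.
#' @param alpha Two-sided level.
#' @return A `"cr_fit"` object.
#' @export
fit_file <- function(path, setting = c("cs", "sd"), cause = 1L,
                     censor_time = NULL, alpha = 0.05) {
  setting <- match.arg(setting)
  data <- read_trial(path)
  if (setting == "cs") {
    fit_cox_cause_specific(data, cause = cause, alpha = alpha)
  } else {
    fit_fine_gray(data, cause = cause, censor_time = censor_time,
                  alpha = alpha)
  }
}
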