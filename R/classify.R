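#' Classify a pooled result into superiority / inferiority / equivalence
#'
#' The three-way decision rule applied to each condition and setting:
#' superiority of verum if the pooled HR is below 1 with two-sided
#' p <= alpha, inferiority if the pooled HR is above 1 with p <= alpha, and
#' equivalence whenever p > alpha. A pooled HR of exactly 1 cannot be
#' significant under Wald-type inference (log-HR 0 gives p = 1), so the rule
#' is exhaustive.
#'
#' @param pooled A `"cr_pooled"` object (or any list with `hr` and
#'   `p_value`).
#' @param alpha Significance boundary; p equal to `alpha` counts as
#'   significant.
#' @return One of `"superiority"`, `"inferiority"`, `"equivalence"`.
#' @export
classify_outcome <- function(pooled, alpha = 0.05) {
  stopifnot(is.numeric(pooled$hr), is.numeric(pooled$p_value))
  if (pooled$p_value > alpha) return("equivalence")
  if (pooled$hr < 1) "superiority" else "inferiority"
}

#' Nine-category cross-classification of outcome switching
#'
#' Maps the pair (cause-specific outcome, subdistribution outcome) to the
#' category code 1-9:
#'
#' | cs \ sd       | superiority | equivalence | inferiority |
#' |---------------|:-----------:|:-----------:|:-----------:|
#' | superiority   | 1           | 2           | 3           |
#' | equivalence   | 4           | 5           | 6           |
#' | inferiority   | 7           | 8           | 9           |
#'
#' @param cs,sd Outcome labels from [classify_outcome()].
#' @return Integer category in 1..9.
#' @export
cross_classify <- function(cs, sd) {
  lv <- c("superiority", "equivalence", "inferiority")
  i <- match(cs, lv); j <- match(sd, lv)
  if (is.na(i) || is.na(j)) stop("outcome labels must be one of: ",
                                 paste(lv, collapse = ", "), call. = FALSE)
  as.integer((i - 1L) * 3L + j)
}

#' Grid-level report: condition table, marginals and heat-map tables
#'
#' Takes the per-condition pooled results of both settings and produces the
#' full reporting substrate: one wide row per condition with both pooled
#' fits, both outcomes and the switching category; the marginal outcome
#' percentages per setting; the category shares within each cause-specific
#' outcome; and three tidy map tables over the grid (design-truth HR, the
#' ratio pooled-cs-HR / true HR, and the switching category).
#'
#' @param results A data.frame with one row per (condition, setting) as
#'   produced by [run_experiment()]'s fitting stage: columns `verum`,
#'   `control` (grid medians), `hr_true`, `setting` ("cs"/"sd"), `hr`,
#'   `p_value`, and optionally `ci_low`, `ci_high`, `m`, `n_excluded`.
#' @param alpha Significance boundary for [classify_outcome()].
#' @return A list of class `"cr_report"`:
#'   `conditions` (wide per-condition table with outcomes and category),
#'   `outcome_margins` (percent per outcome per setting),
#'   `switching` (category shares within each cause-specific outcome),
#'   `category_counts` (count and percent of all conditions per category),
#'   `maps` (list of tidy tables `hr_true`, `ratio_cs_true`, `category`),
#'   `n_conditions`, `n_missing`.
#' @export
grid_report <- function(results, alpha = 0.05) {
  need <- c("verum", "control", "hr_true", "setting", "hr", "p_value")
  missing_cols <- setdiff(need, names(results))
  if (length(missing_cols)) {
    stop("results table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cs <- results[results$setting == "cs", ]
  sd_ <- results[results$setting == "sd", ]
  wide <- merge(cs, sd_, by = c("verum", "control", "hr_true"),
                suffixes = c("_cs", "_sd"))
  expected <- length(unique(results$verum)) * length(unique(results$control))
  n_missing <- expected - nrow(wide)
  if (n_missing > 0) {
    warning(sprintf(
      "%d grid cell(s) lack results in one or both settings; proportions use %d analyzable cells",
      n_missing, nrow(wide)), call. = FALSE)
  }
  wide$outcome_cs <- mapply(function(hr, p)
    classify_outcome(list(hr = hr, p_value = p), alpha),
    wide$hr_cs, wide$p_value_cs)
  wide$outcome_sd <- mapply(function(hr, p)
    classify_outcome(list(hr = hr, p_value = p), alpha),
    wide$hr_sd, wide$p_value_sd)
  wide$category <- mapply(cross_classify, wide$outcome_cs, wide$outcome_sd)
  wide <- wide[order(wide$control, wide$verum), ]
  rownames(wide) <- NULL

  lv <- c("superiority", "equivalence", "inferiority")
  margins <- do.call(rbind, lapply(c("cs", "sd"), function(s) {
    oc <- factor(wide[[paste0("outcome_", s)]], levels = lv)
    data.frame(setting = s, outcome = lv,
               n = as.vector(table(oc)),
               percent = 100 * as.vector(table(oc)) / nrow(wide))
  }))

  # category shares within each cause-specific outcome row
  switching <- do.call(rbind, lapply(seq_along(lv), function(i) {
    sub <- wide[wide$outcome_cs == lv[i], ]
    cats <- (i - 1L) * 3L + 1:3
    n <- vapply(cats, function(k) sum(sub$category == k), numeric(1))
    data.frame(outcome_cs = lv[i], category = cats, outcome_sd = lv, n = n,
               percent = if (nrow(sub)) 100 * n / nrow(sub) else NA_real_)
  }))

  category_counts <- data.frame(
    category = 1:9,
    n = vapply(1:9, function(k) sum(wide$category == k), numeric(1)))
  category_counts$percent <- 100 * category_counts$n / nrow(wide)

  maps <- list(
    hr_true = wide[, c("control", "verum", "hr_true")],
    ratio_cs_true = data.frame(control = wide$control, verum = wide$verum,
                               ratio = wide$hr_cs / wide$hr_true),
    category = wide[, c("control", "verum", "category")]
  )

  structure(list(conditions = wide, outcome_margins = margins,
                 switching = switching, category_counts = category_counts,
                 maps = maps, n_conditions = nrow(wide),
                 n_missing = n_missing, alpha = alpha),
            class = "cr_report")
}

#' @export
print.cr_report <- function(x, ...) {
  cat(sprintf("Grid report over %d conditions (alpha = %g)\n",
              x$n_conditions, x$alpha))
  if (x$n_missing > 0) cat(sprintf("  %d cell(s) missing\n", x$n_missing))
  cat("\nOutcome margins (% of conditions):\n")
  print(x$outcome_margins, row.names = FALSE, digits = 4)
  cat("\nSwitching categories (cause-specific -> subdistribution):\n")
  print(x$switching, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write the report tables of a grid experiment
#'
#' Exports the wide condition table, the three tidy map tables and a JSON
#' summary of all marginal percentages.
#'
#' @param report A `"cr_report"` from [grid_report()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cr_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$conditions, file.path(dir, "conditions.csv"),
                   row.names = FALSE)
  for (nm in names(report$maps)) {
    utils::write.csv(report$maps[[nm]],
                     file.path(dir, paste0("map_", nm, ".csv")),
                     row.names = FALSE)
  }
  summary <- list(
    n_conditions = report$n_conditions,
    n_missing = report$n_missing,
    alpha = report$alpha,
    outcome_margins = report$outcome_margins,
    switching = report$switching,
    category_counts = report$category_counts
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Optional ggplot2 heat maps of the three grid tables
#'
#' Convenience rendering of the map tables; the CSV tables written by
#' [write_report()] are the canonical artifact and nothing downstream
#' depends on these figures.
#'
#' @param report A `"cr_report"`.
#' @return A named list of ggplot objects (`hr_true`, `ratio_cs_true`,
#'   `category`).
#' @export
plot_heatmaps <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  gg <- ggplot2::ggplot
  aes <- ggplot2::aes
  base <- function(d, fill, trans = "identity") {
    gg(d, aes(x = .data$control, y = .data$verum, fill = .data[[fill]])) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "gold",
                                    high = "firebrick", midpoint = 0,
                                    trans = trans) +
      ggplot2::labs(x = "median time to AE, control (months)",
                    y = "median time to AE, verum (months)") +
      ggplot2::theme_minimal()
  }
  m <- report$maps
  list(
    hr_true = base(transform(m$hr_true, log_hr = log(m$hr_true$hr_true)),
                   "log_hr"),
    ratio_cs_true = base(transform(m$ratio_cs_true,
                                   log_ratio = log(m$ratio_cs_true$ratio)),
                         "log_ratio"),
    category = gg(m$category, aes(x = .data$control, y = .data$verum,
                                  fill = factor(.data$category))) +
      ggplot2::geom_tile() +
      ggplot2::labs(x = "median time to AE, control (months)",
                    y = "median time to AE, verum (months)",
                    fill = "category") +
      ggplot2::theme_minimal()
  )
}
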