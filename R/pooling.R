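#' Pool replicated hazard-ratio fits by Rubin's rules
#'
#' Combines the log-HR estimates and model-based standard errors of
#' independently replicated fits into a single estimate, confidence interval
#' and two-sided p-value. With `m` replicates, point estimates `Q_i` and
#' squared standard errors `U_i`:
#' \deqn{\bar Q = m^{-1}\sum Q_i,\quad W = m^{-1}\sum U_i,\quad
#'       B = (m-1)^{-1}\sum (Q_i-\bar Q)^2,\quad T = W + (1+1/m)B,}
#' with the classical Rubin degrees of freedom
#' \eqn{\nu = (m-1)\,[1 + W/((1+1/m)B)]^2} and a Student-t reference for
#' \eqn{\bar Q/\sqrt{T}}. When `B = 0` (all replicates identical) the normal
#' reference is used. Pooling is done on the log-HR scale and results are
#' exponentiated for reporting.
#'
#' @param fits A list of `"cr_fit"` objects (or a data.frame with columns
#'   `log_hr` and `se`), all from the same setting.
#' @param alpha Two-sided level for the pooled confidence interval.
#' @return An object of class `"cr_pooled"`: `m`, `qbar`, `W`, `B`, `T`,
#'   `df`, `hr`, `ci_low`, `ci_high`, `p_value`, `n_excluded` (0 here; see
#'   [pool_condition()]).
#' @examples
#' f <- data.frame(log_hr = c(0.1, 0.2, 0.3), se = 0.1)
#' pool_rubin(f)
#' @export
pool_rubin <- function(fits, alpha = 0.05) {
  if (is.data.frame(fits)) {
    q <- fits$log_hr; u <- fits$se^2
  } else {
    q <- vapply(fits, `[[`, numeric(1), "log_hr")
    u <- vapply(fits, `[[`, numeric(1), "se")^2
  }
  m <- length(q)
  if (m < 2L) stop("need at least 2 fits to pool", call. = FALSE)
  if (any(!is.finite(q)) || any(!is.finite(u))) {
    stop("non-finite estimates or variances cannot be pooled", call. = FALSE)
  }
  qbar <- mean(q)
  W <- mean(u)
  B <- stats::var(q)
  Tv <- W + (1 + 1 / m) * B
  if (B > 0) {
    df <- (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
    tq <- stats::qt(1 - alpha / 2, df)
    p <- 2 * stats::pt(-abs(qbar / sqrt(Tv)), df)
  } else {
    df <- Inf
    tq <- stats::qnorm(1 - alpha / 2)
    p <- 2 * stats::pnorm(-abs(qbar / sqrt(Tv)))
  }
  structure(list(m = m, qbar = qbar, W = W, B = B, T = Tv, df = df,
                 hr = exp(qbar),
                 ci_low = exp(qbar - tq * sqrt(Tv)),
                 ci_high = exp(qbar + tq * sqrt(Tv)),
                 p_value = p, n_excluded = 0L),
            class = "cr_pooled")
}

#' @export
print.cr_pooled <- function(x, ...) {
  cat(sprintf("Rubin-pooled estimate over %d replicates (%d excluded)\n",
              x$m, x$n_excluded))
  cat(sprintf("  HR %.4f (95%% CI %.4f-%.4f), p = %.4g\n",
              x$hr, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  log-HR %.4f; W %.5f, B %.5f, T %.5f, df %.1f\n",
              x$qbar, x$W, x$B, x$T, x$df))
  invisible(x)
}

#' Pool all replicate fits of one condition and setting
#'
#' Filters out non-converged replicates (capped monotone-likelihood fits),
#' records how many were excluded, and delegates to [pool_rubin()].
#'
#' @param fits List of `"cr_fit"` objects for one condition and setting.
#' @param alpha Two-sided level.
#' @return A `"cr_pooled"` object with `n_excluded` set; errors if fewer
#'   than 2 converged replicates remain (condition unanalyzable).
#' @export
pool_condition <- function(fits, alpha = 0.05) {
  ok <- vapply(fits, `[[`, logical(1), "converged")
  n_excl <- sum(!ok)
  if (n_excl > 0) {
    message(sprintf("excluding %d non-converged replicate(s) from pooling",
                    n_excl))
  }
  if (sum(ok) < 2L) {
    stop("fewer than 2 converged replicates: condition unanalyzable",
         call. = FALSE)
  }
  pooled <- pool_rubin(fits[ok], alpha = alpha)
  pooled$n_excluded <- n_excl
  pooled
}
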