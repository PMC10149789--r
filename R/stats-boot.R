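# Bias-corrected and accelerated (BCa) bootstrap confidence intervals and
# CI-inversion p-values. Resampling is by cases (rows); for two-group
# statistics an optional strata argument resamples within groups. The
# p-value and the interval at any level are computed from one fixed
# bootstrap resample set, so "p <= alpha" and "the (1-alpha) interval
# excludes the null" agree by construction.

resample_rows <- function(data, idx) {
  if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
}

# One bootstrap run: point estimate, B case-resampled statistics and the
# leave-one-out jackknife statistics (for the acceleration constant).
boot_stats <- function(stat_fn, data, B, strata = NULL) {
  n <- NROW(data)
  stopifnot(n >= 3L, B >= 1L)
  theta_hat <- stat_fn(data)
  idx_all <- seq_len(n)
  draw_idx <- if (is.null(strata)) {
    function() sample.int(n, n, replace = TRUE)
  } else {
    stopifnot(length(strata) == n)
    groups <- split(idx_all, strata)
    function() unlist(lapply(groups, function(g)
      g[sample.int(length(g), length(g), replace = TRUE)]),
      use.names = FALSE)
  }
  t_boot <- vapply(seq_len(B), function(b) stat_fn(resample_rows(data, draw_idx())),
                   numeric(1L))
  jack <- vapply(idx_all, function(i) stat_fn(resample_rows(data, idx_all[-i])),
                 numeric(1L))
  # resamples where the statistic is undefined (e.g. a degenerate
  # correlation) are dropped; the effective B shrinks accordingly
  t_boot <- t_boot[is.finite(t_boot)]
  jack <- jack[is.finite(jack)]
  if (length(t_boot) < 2L || length(jack) < 2L) {
    stop("statistic undefined on nearly all resamples", call. = FALSE)
  }
  list(theta_hat = theta_hat, t_boot = t_boot, jack = jack,
       B = length(t_boot))
}

# BCa interval endpoints from a completed bootstrap run.
bca_from_boot <- function(bs, level, quiet = FALSE) {
  t_boot <- bs$t_boot
  theta <- bs$theta_hat
  B <- bs$B
  if (max(t_boot) - min(t_boot) < .Machine$double.eps^0.5 * (1 + abs(theta))) {
    if (!quiet) {
      warning("degenerate bootstrap distribution (all resampled statistics ",
              "equal); returning a point interval", call. = FALSE)
    }
    return(c(lower = t_boot[1L], upper = t_boot[1L]))
  }
  prop <- (sum(t_boot < theta) + 0.5 * sum(t_boot == theta)) / B
  prop <- min(max(prop, 0.5 / B), 1 - 0.5 / B)
  z0 <- stats::qnorm(prop)
  jm <- mean(bs$jack)
  d <- jm - bs$jack
  denom <- sum(d^2)^1.5
  a <- if (denom < .Machine$double.eps) 0 else sum(d^3) / (6 * denom)
  alpha <- (1 - level) / 2
  zq <- stats::qnorm(c(alpha, 1 - alpha))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  ci <- stats::quantile(t_boot, probs = adj, type = 6, names = FALSE)
  c(lower = ci[1L], upper = ci[2L])
}

#' BCa bootstrap confidence interval
#'
#' Case-resampling bootstrap interval with bias correction (z0, from the
#' fraction of the bootstrap distribution below the point estimate) and
#' acceleration (a, from the skewness of the leave-one-out jackknife),
#' applied as adjusted percentile endpoints. Deterministic under `seed`.
#'
#' @param stat_fn Function of the (resampled) data returning one number.
#'   Rows are the resampling unit: a data frame is resampled by rows, a
#'   vector by elements.
#' @param data Vector or data frame, at least 3 rows.
#' @param B Bootstrap resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed.
#' @param strata Optional factor of length `NROW(data)`; resampling is done
#'   within strata (used for two-group mean differences).
#' @return Numeric `c(lower, upper)`, with attributes `theta_hat` and `B`.
#' @examples
#' ci <- bca_ci(mean, rnorm(20), B = 500, seed = 1)
#' @export
bca_ci <- function(stat_fn, data, B = 2000L, level = 0.95, seed = NULL,
                   strata = NULL) {
  with_seed(seed, {
    bs <- boot_stats(stat_fn, data, B, strata)
    ci <- bca_from_boot(bs, level)
    attr(ci, "theta_hat") <- bs$theta_hat
    attr(ci, "B") <- bs$B
    ci
  })
}

#' p-value by inversion of BCa confidence intervals
#'
#' The p-value for `H0: statistic = null_value` is the smallest alpha for
#' which the (1 - alpha) BCa interval excludes the null, located by
#' bisection (tolerance `tol`) over one fixed bootstrap resample set reused
#' across levels. When even the widest achievable interval excludes the
#' null the p-value is bounded below by `2/B` (with a warning); when no
#' interval excludes it the p-value is 1.
#'
#' @inheritParams bca_ci
#' @param null_value Null value of the statistic (default 0).
#' @param tol Bisection tolerance on alpha (default 1e-4).
#' @return The p-value.
#' @export
p_from_ci_inversion <- function(stat_fn, data, null_value = 0, B = 2000L,
                                seed = NULL, strata = NULL, tol = 1e-4) {
  with_seed(seed, {
    bs <- boot_stats(stat_fn, data, B, strata)
    p_from_boot(bs, null_value, tol)
  })
}

p_from_boot <- function(bs, null_value, tol = 1e-4) {
  excludes <- function(alpha) {
    ci <- bca_from_boot(bs, 1 - alpha, quiet = TRUE)
    null_value < ci[1L] || null_value > ci[2L]
  }
  alpha_min <- 2 / bs$B
  alpha_max <- 1 - tol
  if (excludes(alpha_min)) {
    warning("null value lies outside the widest achievable interval; ",
            "p-value bounded below by 2/B = ", format(alpha_min),
            call. = FALSE)
    return(alpha_min)
  }
  if (!excludes(alpha_max)) return(1)
  lo <- alpha_min
  hi <- alpha_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (excludes(mid)) hi <- mid else lo <- mid
  }
  hi
}
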