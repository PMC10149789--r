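# Elementary inference pieces: pooled t, Hedges' g, Pearson r, BH step-up
# adjustment and Cohen's f-squared.

#' Pooled-variance two-sample t statistic
#'
#' Student's independent-samples t with the pooled variance estimate and
#' `df = n1 + n2 - 2`.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return List with `t`, `df`, `mean_diff` (`mean(x) - mean(y)`),
#'   `n1`, `n2`.
#' @examples
#' student_t(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4
#' @export
student_t <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  stopifnot(n1 >= 2L, n2 >= 2L)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  md <- mean(x) - mean(y)
  list(t = md / sqrt(sp2 * (1 / n1 + 1 / n2)), df = n1 + n2 - 2L,
       mean_diff = md, n1 = n1, n2 = n2)
}

#' Hedges' g from a pooled t statistic
#'
#' Small-sample-corrected standardized mean difference, reported as a
#' magnitude: `g = J * |t| * sqrt(1/n1 + 1/n2)` with
#' `J = 1 - 3 / (4 (n1 + n2) - 9)`. The sign of the effect lives in the
#' mean difference, not in g.
#'
#' @param t Pooled t statistic.
#' @param n1,n2 Group sizes (>= 2).
#' @return g (non-negative).
#' @examples
#' hedges_g(-0.229, 9, 10)
#' @export
hedges_g <- function(t, n1, n2) {
  stopifnot(n1 >= 2L, n2 >= 2L)
  j <- 1 - 3 / (4 * (n1 + n2) - 9)
  j * abs(t) * sqrt(1 / n1 + 1 / n2)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Sample correlation in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Controls the false discovery rate: with the m p-values sorted
#' ascending, `p_adj[(i)] = min_{j >= i} min(1, m * p[(j)] / j)`; results
#' are returned in the input order. Idempotent and order-preserving.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || any(is.na(pvals)) ||
      any(pvals < 0 | pvals > 1)) {
    stop("pvals must be numeric in [0, 1] without NAs", call. = FALSE)
  }
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  o <- order(pvals)
  scaled <- m * pvals[o] / seq_len(m)
  adj_sorted <- pmin(1, rev(cummin(rev(scaled))))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

#' Cohen's f-squared from R-squared
#'
#' `f2 = R2 / (1 - R2)`; with a reduced model,
#' `f2 = (R2 - R2_reduced) / (1 - R2)` measures the incremental effect.
#' Computed from the unadjusted (robust) R-squared.
#'
#' @param r2 Full-model R-squared in [0, 1).
#' @param r2_reduced Optional reduced-model R-squared.
#' @return f-squared.
#' @examples
#' cohens_f2(0.30)  # 0.4286
#' @export
cohens_f2 <- function(r2, r2_reduced = NULL) {
  if (!is.numeric(r2) || r2 < 0 || r2 >= 1) {
    stop("r2 must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(r2_reduced)) r2 / (1 - r2) else (r2 - r2_reduced) / (1 - r2)
}
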