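# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. `seed = NULL` uses (and advances) the
# current stream, so nested calls inside a seeded block stay deterministic.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Running logical AND, used for suffix checks of the threshold rule.
cumall <- function(x) as.logical(cumprod(as.logical(x)))

assert_chroma <- function(x, what = "chroma") {
  if (!is.numeric(x) || anyNA(match(x[!is.na(x)], 0:11))) {
    stop(what, " must be integer pitch-class indices in 0..11", call. = FALSE)
  }
  invisible(x)
}

assert_proportion <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(what, " must be a single proportion in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

# Normal draw clamped to [lower, upper]; used for covariates and per-subject
# observer parameters where only a mean and SD are specified.
rnorm_clamped <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lower), upper)
}
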