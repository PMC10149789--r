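# Parametric simulated observers: a wrapped-Gaussian-plus-guessing pitch
# namer and guess/lapse logistic detectors for the gap-detection and
# backward-masking tasks. These make every downstream stage testable with
# known ground-truth psychometric parameters.

#' Guess/lapse logistic psychometric function
#'
#' Detection probability at stimulus magnitude `x`:
#' `p = guess + (1 - guess - lapse) / (1 + exp(-(x - x50) / slope))`.
#' `guess` is the lower asymptote, `1 - lapse` the upper, `x50` the
#' midpoint of the underlying logistic and `slope` its scale in stimulus
#' units (smaller = steeper).
#'
#' @param x Stimulus magnitudes (>= 0), vectorized.
#' @param params List with `x50`, `slope` (> 0) and optional `guess`,
#'   `lapse` (proportions, `guess + lapse <= 1`).
#' @return Detection probabilities.
#' @examples
#' psychometric_p(5, list(x50 = 5, slope = 1))  # 0.5
#' @export
psychometric_p <- function(x, params) {
  stopifnot(is.numeric(x), all(x >= 0))
  guess <- params$guess %||% 0
  lapse <- params$lapse %||% 0
  assert_proportion(guess, "guess")
  assert_proportion(lapse, "lapse")
  if (guess + lapse > 1) stop("guess + lapse must be <= 1", call. = FALSE)
  if (is.null(params$x50) || is.null(params$slope) || params$slope <= 0) {
    stop("params must supply x50 and a positive slope", call. = FALSE)
  }
  guess + (1 - guess - lapse) * stats::plogis((x - params$x50) / params$slope)
}

#' Simulate a pitch-naming observer on a protocol
#'
#' On each trial the observer guesses uniformly over the 12 chroma labels
#' with probability `guess_rate`; otherwise it responds the target chroma
#' plus a rounded Gaussian naming error (SD `sigma` semitones), wrapped
#' onto the chroma circle. `sigma = 0, guess_rate = 0` is a perfect namer.
#'
#' @param params List with `sigma` (>= 0, semitones) and `guess_rate`
#'   (proportion).
#' @param protocol A [build_pitch_id_protocol()] object, or any data frame
#'   with a `chroma` column.
#' @param seed Optional seed.
#' @return A trial log data frame (`target_chroma`, `response_chroma`)
#'   suitable for [score_pitch_id()].
#' @export
simulate_pitch_observer <- function(params, protocol, seed = NULL) {
  sigma <- params$sigma
  lambda <- params$guess_rate %||% 0
  stopifnot(is.numeric(sigma), sigma >= 0)
  assert_proportion(lambda, "guess_rate")
  trials <- if (inherits(protocol, "pitch_id_protocol")) protocol$trials
            else protocol
  tgt <- trials$chroma
  n <- length(tgt)
  with_seed(seed, {
    guess <- stats::runif(n) < lambda
    err <- round(stats::rnorm(n, 0, sigma))
    rsp <- (tgt + err) %% 12L
    rsp[guess] <- sample.int(12L, sum(guess), replace = TRUE) - 1L
    data.frame(target_chroma = as.integer(tgt),
               response_chroma = as.integer(rsp))
  })
}

#' Simulate a gap-detection observer on a Gaps-in-Noise track
#'
#' Each gap is detected independently with probability
#' [psychometric_p()] of its duration; spurious taps arise per segment as
#' Poisson with mean `params$false_alarm`.
#'
#' @param params Psychometric parameters (see [psychometric_p()]) plus
#'   optional `false_alarm` (expected spurious taps per segment).
#' @param track A [build_gin_track()] object.
#' @param seed Optional seed.
#' @return A [gin_response_log()].
#' @export
simulate_gin_observer <- function(params, track, seed = NULL) {
  stopifnot(inherits(track, "gin_track"))
  fa <- params$false_alarm %||% 0
  stopifnot(fa >= 0)
  with_seed(seed, {
    p <- psychometric_p(track$gaps$duration_ms, params)
    detected <- stats::runif(nrow(track$gaps)) < p
    false_alarms <- sum(stats::rpois(track$n_segments, fa))
    gin_response_log(detected, false_alarms)
  })
}

#' Simulate a backward-masking observer on a session
#'
#' Tone trials are answered with probability [psychometric_p()] of the
#' tone-to-masker interval; catch trials are answered with probability
#' `params$false_alarm`.
#'
#' @param params Psychometric parameters plus optional `false_alarm`
#'   (press probability on masker-only trials).
#' @param session A [build_bmt_session()] object.
#' @param seed Optional seed.
#' @return A [bmt_response_log()].
#' @export
simulate_bmt_observer <- function(params, session, seed = NULL) {
  stopifnot(inherits(session, "bmt_session"))
  fa <- params$false_alarm %||% 0
  assert_proportion(fa, "false_alarm")
  trials <- session$trials
  with_seed(seed, {
    pressed <- logical(nrow(trials))
    tone <- !trials$catch
    pressed[tone] <- stats::runif(sum(tone)) <
      psychometric_p(trials$isi_ms[tone], params)
    pressed[!tone] <- stats::runif(sum(!tone)) < fa
    bmt_response_log(pressed)
  })
}
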