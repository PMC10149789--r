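# Scoring of trial-level response logs into the standard performance
# measures: CRR/MAD (pitch identification), GDP/GDT (Gaps-in-Noise),
# BMTP/BMTT (backward masking), plus two-ear averaging.
#
# Thresholds that no tested level satisfies are censored: represented as
# NA_real_ alongside an explicit `censored` flag, and serialized as the
# token "NA_censored". They are never imputed with a number.

#' Circular distance between two pitch classes
#'
#' Distance on the 12-chroma circle, in semitones: `min(d, 12 - d)` with
#' `d = |a - b| mod 12`. Symmetric, ranges 0..6 (6 = tritone, the antipode).
#' Responses carry chroma only, so deviation is necessarily circular.
#'
#' @param a,b Integer pitch-class indices in 0..11 (vectorized, recycled).
#' @return Integer distances in semitones, 0..6.
#' @examples
#' chroma_distance(11, 0)  # 1
#' chroma_distance(3, 9)   # 6
#' @export
chroma_distance <- function(a, b) {
  assert_chroma(a, "a")
  assert_chroma(b, "b")
  d <- abs(a - b) %% 12
  pmin(d, 12 - d)
}

#' Score a pitch-identification trial log
#'
#' CRR (correct response rate) counts only responses with zero chroma
#' deviation; MAD is the mean circular chroma distance in semitones.
#' Missing responses (`NA`) are handled per `none_policy`: `"worst"`
#' (default) scores them incorrect with the maximal deviation of 6
#' semitones; `"exclude"` drops them from both measures.
#'
#' @param log Data frame with columns `target_chroma` and `response_chroma`
#'   (integers 0..11; `response_chroma` may be `NA`).
#' @param none_policy `"worst"` or `"exclude"`.
#' @return Object of class `"pitch_scores"`: list with `crr` (percent),
#'   `mad` (semitones), `n_trials`, `n_none`.
#' @examples
#' log <- data.frame(target_chroma = c(0, 4, 7), response_chroma = c(0, 5, 7))
#' score_pitch_id(log)  # CRR 66.7%, MAD 1/3
#' @export
score_pitch_id <- function(log, none_policy = c("worst", "exclude")) {
  none_policy <- match.arg(none_policy)
  if (!is.data.frame(log) || nrow(log) == 0L) {
    stop("log must be a non-empty data frame", call. = FALSE)
  }
  if (!all(c("target_chroma", "response_chroma") %in% names(log))) {
    stop("log needs columns target_chroma and response_chroma", call. = FALSE)
  }
  tgt <- log$target_chroma
  rsp <- log$response_chroma
  assert_chroma(tgt, "target_chroma")
  assert_chroma(rsp, "response_chroma")
  none <- is.na(rsp)
  if (none_policy == "exclude") {
    tgt <- tgt[!none]
    rsp <- rsp[!none]
    if (length(tgt) == 0L) {
      stop("all responses missing; nothing to score under policy 'exclude'",
           call. = FALSE)
    }
    dist <- chroma_distance(tgt, rsp)
  } else {
    dist <- numeric(length(tgt))
    dist[!none] <- chroma_distance(tgt[!none], rsp[!none])
    dist[none] <- 6
  }
  structure(
    list(crr = 100 * mean(dist == 0), mad = mean(dist),
         n_trials = nrow(log), n_none = sum(none)),
    class = "pitch_scores"
  )
}

#' Construct a Gaps-in-Noise response log
#'
#' @param detected Logical vector, one detection outcome per gap of the
#'   track (60 per ear).
#' @param false_alarms Count of taps not matched to any gap.
#' @return Object of class `"gin_response_log"`.
#' @export
gin_response_log <- function(detected, false_alarms = 0L) {
  stopifnot(is.logical(detected), !anyNA(detected),
            is.numeric(false_alarms), false_alarms >= 0)
  structure(list(detected = detected, false_alarms = as.integer(false_alarms)),
            class = "gin_response_log")
}

#' Construct a backward-masking response log
#'
#' @param pressed Logical vector, one button-press outcome per trial (60).
#' @return Object of class `"bmt_response_log"`.
#' @export
bmt_response_log <- function(pressed) {
  stopifnot(is.logical(pressed), !anyNA(pressed))
  structure(list(pressed = pressed), class = "bmt_response_log")
}

#' Tally detections per gap duration
#'
#' @param track A [build_gin_track()] object.
#' @param log A [gin_response_log()] matching the track.
#' @return Named integer vector: detected count (0..6) per duration, named
#'   by duration in ms, ascending.
#' @export
detection_counts <- function(track, log) {
  stopifnot(inherits(track, "gin_track"), inherits(log, "gin_response_log"))
  if (length(log$detected) != nrow(track$gaps)) {
    stop("response log length (", length(log$detected),
         ") does not match track gap count (", nrow(track$gaps), ")",
         call. = FALSE)
  }
  f <- factor(track$gaps$duration_ms, levels = GIN_GAP_DURATIONS_MS)
  counts <- tapply(log$detected, f, sum, default = 0L)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Threshold from per-level detection counts (4-of-6 rule)
#'
#' Levels are ordered by increasing detectability (ascending gap duration,
#' or ascending tone-to-masker interval). Under the default policy
#' `"maintained_criterion"` the threshold is the smallest level whose count
#' meets the criterion (>= 4 of 6) with every easier (higher) level also
#' meeting the criterion — the standard clinical reading. Under
#' `"maintained_rate"` (the literal "equal or higher detection rate"
#' reading) every easier level must have a count at least equal to the
#' candidate's own count. When no level qualifies the threshold is censored
#' (`NA_real_`): performance lies beyond the tested range.
#'
#' @param counts Named numeric vector of detected counts, names are the
#'   stimulus levels; sorted internally by ascending level.
#' @param criterion Required detections per level (default 4).
#' @param n_per_level Presentations per level (default 6).
#' @param policy `"maintained_criterion"` or `"maintained_rate"`.
#' @return The threshold level as a number, or `NA_real_` when censored.
#' @examples
#' counts <- c(`2` = 0, `3` = 1, `4` = 4, `5` = 5, `6` = 6, `8` = 6,
#'             `10` = 6, `12` = 6, `15` = 6, `20` = 6)
#' threshold_from_counts(counts)  # 4
#' @export
threshold_from_counts <- function(counts, criterion = 4, n_per_level = 6,
                                  policy = c("maintained_criterion",
                                             "maintained_rate")) {
  policy <- match.arg(policy)
  if (is.null(names(counts)) || anyNA(suppressWarnings(as.numeric(names(counts))))) {
    stop("counts must be named by numeric stimulus levels", call. = FALSE)
  }
  if (any(counts < 0 | counts > n_per_level)) {
    stop("counts must lie in 0..", n_per_level, call. = FALSE)
  }
  lev <- as.numeric(names(counts))
  o <- order(lev)
  lev <- lev[o]
  cnt <- as.numeric(counts[o])
  k <- length(cnt)
  if (policy == "maintained_criterion") {
    ok <- cnt >= criterion
    maintained <- rev(cumall(rev(ok)))
    idx <- which(maintained)
  } else {
    idx <- which(vapply(seq_len(k), function(i) {
      cnt[i] >= criterion && all(cnt[seq_len(k) >= i] >= cnt[i])
    }, logical(1L)))
  }
  if (length(idx) == 0L) NA_real_ else lev[min(idx)]
}

#' Score one ear of the Gaps-in-Noise test
#'
#' GDP is the percentage of the 60 gaps detected; GDT is the
#' [threshold_from_counts()] threshold over the ten durations.
#'
#' @param track A [build_gin_track()] object.
#' @param log A matching [gin_response_log()].
#' @param policy Threshold policy, see [threshold_from_counts()].
#' @return Object of class `"gin_scores"`: `gdp` (percent), `gdt` (ms or
#'   `NA_real_` when censored), `censored`, `counts`, `false_alarms`.
#' @export
score_gin_ear <- function(track, log,
                          policy = c("maintained_criterion",
                                     "maintained_rate")) {
  policy <- match.arg(policy)
  counts <- detection_counts(track, log)
  gdt <- threshold_from_counts(counts, policy = policy)
  structure(
    list(gdp = 100 * sum(log$detected) / length(log$detected),
         gdt = gdt, censored = is.na(gdt), counts = counts,
         false_alarms = log$false_alarms),
    class = "gin_scores"
  )
}

#' Score one ear of the backward-masking test
#'
#' BMTP is the percentage of the 48 tone trials answered with a press; BMTT
#' is the [threshold_from_counts()] threshold over the eight tone-to-masker
#' intervals. Presses on the 12 catch trials give the false-alarm rate,
#' which is reported but does not enter BMTP.
#'
#' @param session A [build_bmt_session()] object.
#' @param log A matching [bmt_response_log()].
#' @param policy Threshold policy, see [threshold_from_counts()].
#' @return Object of class `"bmt_scores"`: `bmtp` (percent), `bmtt` (ms or
#'   `NA_real_`), `censored`, `counts`, `false_alarm_rate`.
#' @export
score_bmt_ear <- function(session, log,
                          policy = c("maintained_criterion",
                                     "maintained_rate")) {
  policy <- match.arg(policy)
  stopifnot(inherits(session, "bmt_session"), inherits(log, "bmt_response_log"))
  trials <- session$trials
  if (length(log$pressed) != nrow(trials)) {
    stop("response log length does not match session trial count",
         call. = FALSE)
  }
  tone <- !trials$catch
  f <- factor(trials$isi_ms[tone], levels = BMT_ISI_MS)
  counts <- tapply(log$pressed[tone], f, sum, default = 0L)
  cnt <- as.integer(counts)
  names(cnt) <- names(counts)
  bmtt <- threshold_from_counts(cnt, policy = policy)
  structure(
    list(bmtp = 100 * sum(log$pressed[tone]) / sum(tone),
         bmtt = bmtt, censored = is.na(bmtt), counts = cnt,
         false_alarm_rate = mean(log$pressed[trials$catch])),
    class = "bmt_scores"
  )
}

#' Average the two ears' scores
#'
#' Percent measures (GDP/BMTP) are averaged arithmetically. Thresholds
#' (GDT/BMTT) are averaged only when both ears have an uncensored
#' threshold; if either ear is censored the averaged threshold is censored
#' and flagged, never imputed.
#'
#' @param left,right Two `"gin_scores"` or two `"bmt_scores"` objects.
#' @return A list with the averaged percent measure, the averaged threshold
#'   (`NA_real_` if censored) and `censored`.
#' @examples
#' # GDT 4 ms and 6 ms average to 5 ms
#' @export
average_ears <- function(left, right) {
  if (!identical(class(left), class(right))) {
    stop("left and right must be scores of the same test", call. = FALSE)
  }
  if (inherits(left, "gin_scores")) {
    pct <- mean(c(left$gdp, right$gdp))
    thr <- c(left$gdt, right$gdt)
    censored <- anyNA(thr)
    list(gdp = pct, gdt = if (censored) NA_real_ else mean(thr),
         censored = censored)
  } else if (inherits(left, "bmt_scores")) {
    pct <- mean(c(left$bmtp, right$bmtp))
    thr <- c(left$bmtt, right$bmtt)
    censored <- anyNA(thr)
    list(bmtp = pct, bmtt = if (censored) NA_real_ else mean(thr),
         censored = censored)
  } else {
    stop("average_ears expects gin_scores or bmt_scores", call. = FALSE)
  }
}

#' @export
print.pitch_scores <- function(x, ...) {
  cat(sprintf("Pitch identification: CRR %.2f%%, MAD %.3f semitones (%d trials, %d without response)\n",
              x$crr, x$mad, x$n_trials, x$n_none))
  invisible(x)
}

#' @export
print.gin_scores <- function(x, ...) {
  cat(sprintf("GIN ear scores: GDP %.1f%%, GDT %s, %d false alarm(s)\n",
              x$gdp, if (x$censored) "censored (> 20 ms)" else
                paste0(x$gdt, " ms"), x$false_alarms))
  invisible(x)
}

#' @export
print.bmt_scores <- function(x, ...) {
  cat(sprintf("BMT ear scores: BMTP %.1f%%, BMTT %s, false-alarm rate %.2f\n",
              x$bmtp, if (x$censored) "censored (> 400 ms)" else
                paste0(x$bmtt, " ms"), x$false_alarm_rate))
  invisible(x)
}
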