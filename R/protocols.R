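# Protocol generators for the four psychoacoustic tests.
#
# All generators are pure functions of (parameters, seed): identical inputs
# give byte-identical objects, and the caller's RNG state is left untouched.

#' Gap durations (ms) tested by the Gaps-in-Noise task
#'
#' Ten durations, each embedded six times per ear (60 gaps in total).
#' @export
GIN_GAP_DURATIONS_MS <- c(2, 3, 4, 5, 6, 8, 10, 12, 15, 20)

#' Inter-stimulus intervals (ms) tested by the backward-masking task
#'
#' Eight tone-to-masker intervals, each presented six times per ear
#' (48 tone trials), plus 12 masker-only catch trials.
#' @export
BMT_ISI_MS <- c(0, 10, 20, 30, 50, 100, 200, 400)

#' Pitch-class labels, C = 0 through B = 11
#' @export
PITCH_CLASS_NAMES <- c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#",
                       "A", "A#", "B")

#' Build a pitch-identification protocol
#'
#' Two variants are supported. `exp1_sine52`: 13 sine tones spanning F#3-F#4
#' (MIDI 54-66), each presented four times (52 trials, 2 s inter-tone
#' interval), ordered so that a stimulus recurs only after all 12 other
#' stimuli have been presented since its last occurrence. That rule is
#' strict: a counting argument shows the only 52-trial sequences satisfying
#' it are a single permutation of the 13 stimuli repeated four times, which
#' is the construction used here. `exp2_piano72`: 36 synthetic piano tones
#' spanning C3-B5 (MIDI 48-83), each presented twice in six blocks of 12
#' (72 trials, 4.25 s inter-tone interval), with every consecutive pair of
#' tones more than one octave apart (|MIDI difference| >= 13, enforced
#' across block boundaries as well).
#'
#' @param variant `"exp1_sine52"` or `"exp2_piano72"`.
#' @param seed Optional non-negative integer seed; identical seeds give
#'   identical protocols.
#' @param max_restarts Restart cap for the randomized constructor of the
#'   piano variant; exceeding it raises an error rather than relaxing the
#'   ordering constraint.
#' @return An object of class `"pitch_id_protocol"`: a list with `variant`,
#'   a `trials` data frame (`trial`, `block`, `midi`, `chroma`,
#'   `pitch_class`), `iti_s`, `level_db_sl`, `timbre` and `seed`.
#' @examples
#' p <- build_pitch_id_protocol("exp1_sine52", seed = 1)
#' nrow(p$trials)  # 52
#' @export
build_pitch_id_protocol <- function(variant = c("exp1_sine52", "exp2_piano72"),
                                    seed = NULL, max_restarts = 1000L) {
  variant <- match.arg(variant)
  with_seed(seed, {
    if (variant == "exp1_sine52") {
      midi <- rep(sample(54:66), times = 4L)
      iti_s <- 2
      timbre <- "sine"
      block_size <- 13L
    } else {
      midi <- octave_spaced_sequence(48:83, n_rep = 2L, min_interval = 13L,
                                     max_restarts = max_restarts)
      iti_s <- 4.25
      timbre <- "synthetic_piano"
      block_size <- 12L
    }
    n <- length(midi)
    trials <- data.frame(
      trial = seq_len(n),
      block = as.integer(ceiling(seq_len(n) / block_size)),
      midi = as.integer(midi),
      chroma = as.integer(midi %% 12L),
      pitch_class = PITCH_CLASS_NAMES[midi %% 12L + 1L],
      stringsAsFactors = FALSE
    )
    structure(
      list(variant = variant, trials = trials, iti_s = iti_s,
           level_db_sl = 50, timbre = timbre, seed = seed),
      class = "pitch_id_protocol"
    )
  })
}

# Randomized sequencer with restarts: each note appears `n_rep` times and
# consecutive notes differ by at least `min_interval` semitones. Among the
# notes compatible with the previous tone, the pick is a most-constrained
# candidate (fewest compatible partners left in the pool, so hard-to-place
# mid-range tones are not stranded), with uniformly random tie-breaking.
# A dead end triggers a restart; exhausting `max_restarts` is an explicit
# generation error — the spacing constraint is never silently relaxed.
octave_spaced_sequence <- function(notes, n_rep, min_interval, max_restarts) {
  total <- length(notes) * n_rep
  for (attempt in seq_len(max_restarts)) {
    remaining <- rep(notes, times = n_rep)
    out <- integer(total)
    prev <- NA_integer_
    ok <- TRUE
    for (i in seq_len(total)) {
      cand <- if (is.na(prev)) remaining else
        remaining[abs(remaining - prev) >= min_interval]
      if (length(cand) == 0L) {
        ok <- FALSE
        break
      }
      ucand <- unique(cand)
      n_partners <- vapply(ucand, function(v) {
        pool <- remaining[-match(v, remaining)]
        sum(abs(pool - v) >= min_interval)
      }, numeric(1L))
      tied <- ucand[n_partners == min(n_partners)]
      pick <- tied[sample.int(length(tied), 1L)]
      out[i] <- pick
      remaining <- remaining[-match(pick, remaining)]
      prev <- pick
    }
    if (ok) return(out)
  }
  stop("protocol generation failed: no tone ordering satisfying the ",
       "> one octave spacing constraint was found within ", max_restarts,
       " restarts", call. = FALSE)
}

#' Build a Gaps-in-Noise track
#'
#' A track is a list of 6-second white-noise segments (35 for track 1,
#' 29 for track 3, 5 s between segments), each carrying 0-3 silent gaps.
#' Sixty gaps in total are divided evenly over the ten durations in
#' [GIN_GAP_DURATIONS_MS] (six gaps per duration). The commercial test uses
#' fixed recorded tracks; this generator reproduces their statistical
#' structure (segment counts, per-segment gap caps, duration histogram) with
#' randomized gap-to-segment assignment and onsets.
#'
#' @param track_id `"track1"` (35 segments) or `"track3"` (29 segments).
#' @param seed Optional seed.
#' @param min_gap_separation_ms Minimum silence-free interval between the
#'   offset of one gap and the onset of the next within a segment (default
#'   500 ms, keeping gaps perceptually separable).
#' @param edge_margin_ms Minimum distance of a gap from either segment edge
#'   (default 300 ms).
#' @param max_attempts Rejection-sampling cap for placing the gaps of one
#'   segment; exceeding it raises a generation error.
#' @return Object of class `"gin_track"`: `track_id`, `n_segments`,
#'   `segment_ms` (6000), `isi_s` (5), a `gaps` data frame
#'   (`gap`, `segment`, `onset_ms`, `duration_ms`) and `seed`.
#' @examples
#' tr <- build_gin_track("track1", seed = 1)
#' table(tr$gaps$duration_ms)  # six gaps of each duration
#' @export
build_gin_track <- function(track_id = c("track1", "track3"), seed = NULL,
                            min_gap_separation_ms = 500,
                            edge_margin_ms = 300, max_attempts = 1000L) {
  track_id <- match.arg(track_id)
  n_segments <- if (track_id == "track1") 35L else 29L
  n_gaps <- 60L
  if (3L * n_segments < n_gaps) {
    stop("infeasible track: ", n_segments,
         " segments cannot hold 60 gaps at 3 per segment", call. = FALSE)
  }
  with_seed(seed, {
    durations <- sample(rep(GIN_GAP_DURATIONS_MS, each = 6L))
    seg_of <- integer(n_gaps)
    load <- integer(n_segments)
    for (g in seq_len(n_gaps)) {
      open <- which(load < 3L)
      s <- open[sample.int(length(open), 1L)]
      seg_of[g] <- s
      load[s] <- load[s] + 1L
    }
    rows <- lapply(sort(unique(seg_of)), function(s) {
      durs <- durations[seg_of == s]
      ons <- place_gaps(durs, segment_ms = 6000,
                        edge_margin_ms = edge_margin_ms,
                        min_sep_ms = min_gap_separation_ms,
                        max_attempts = max_attempts)
      o <- order(ons)
      data.frame(segment = s, onset_ms = ons[o], duration_ms = durs[o])
    })
    gaps <- do.call(rbind, rows)
    gaps <- data.frame(gap = seq_len(nrow(gaps)), gaps)
    rownames(gaps) <- NULL
    structure(
      list(track_id = track_id, n_segments = n_segments, segment_ms = 6000,
           isi_s = 5, gaps = gaps, seed = seed),
      class = "gin_track"
    )
  })
}

# Uniform random onsets for `durs` gaps in one segment, rejected until the
# gaps are inside the edge margins, non-overlapping and separated.
place_gaps <- function(durs, segment_ms, edge_margin_ms, min_sep_ms,
                       max_attempts) {
  k <- length(durs)
  hi <- segment_ms - edge_margin_ms - durs
  if (any(hi <= edge_margin_ms)) {
    stop("infeasible gap placement: segment too short for requested margins",
         call. = FALSE)
  }
  for (attempt in seq_len(max_attempts)) {
    ons <- stats::runif(k, min = edge_margin_ms, max = hi)
    o <- order(ons)
    so <- ons[o]
    sd_ <- durs[o]
    if (k == 1L || all(so[-1L] >= so[-k] + sd_[-k] + min_sep_ms)) {
      return(ons)
    }
  }
  stop("gap placement failed after ", max_attempts, " attempts", call. = FALSE)
}

#' Build a backward-masking test session for one ear
#'
#' Sixty trials in randomized order: six presentations of a 25 ms tone at
#' each of the eight tone-to-masker intervals in [BMT_ISI_MS] (48 tone
#' trials) plus 12 masker-only catch trials. Tone level 20 dB SL, 200 ms
#' narrow-band masker, signal-to-noise ratio -20 dB.
#'
#' @param seed Optional seed.
#' @return Object of class `"bmt_session"`: a `trials` data frame (`trial`,
#'   `isi_ms` with `NA` on catch trials, `catch`), the stimulus constants
#'   and `seed`.
#' @examples
#' s <- build_bmt_session(seed = 1)
#' sum(s$trials$catch)  # 12
#' @export
build_bmt_session <- function(seed = NULL) {
  with_seed(seed, {
    isi <- c(rep(BMT_ISI_MS, each = 6L), rep(NA_real_, 12L))
    isi <- sample(isi)
    trials <- data.frame(trial = seq_along(isi), isi_ms = isi,
                         catch = is.na(isi))
    structure(
      list(trials = trials, tone_ms = 25, masker_ms = 200,
           tone_level_db_sl = 20, snr_db = -20, seed = seed),
      class = "bmt_session"
    )
  })
}

#' @export
print.pitch_id_protocol <- function(x, ...) {
  cat("Pitch identification protocol (", x$variant, ")\n", sep = "")
  cat("  ", nrow(x$trials), " trials, ", length(unique(x$trials$midi)),
      " stimuli (MIDI ", min(x$trials$midi), "-", max(x$trials$midi),
      "), timbre ", x$timbre, "\n", sep = "")
  cat("  inter-tone interval ", x$iti_s, " s at ", x$level_db_sl,
      " dB SL\n", sep = "")
  invisible(x)
}

#' @export
print.gin_track <- function(x, ...) {
  cat("Gaps-in-Noise ", x$track_id, ": ", x$n_segments,
      " noise segments of ", x$segment_ms / 1000, " s, ",
      nrow(x$gaps), " gaps (6 per duration)\n", sep = "")
  invisible(x)
}

#' @export
print.bmt_session <- function(x, ...) {
  cat("Backward-masking session: ", sum(!x$trials$catch), " tone trials + ",
      sum(x$trials$catch), " catch trials, tone ", x$tone_ms,
      " ms at ", x$tone_level_db_sl, " dB SL, SNR ", x$snr_db, " dB\n",
      sep = "")
  invisible(x)
}
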