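# Independent oracles used across tests. These re-state the rules literally
# and naively (explicit loops, no shared code with the implementation).

# Literal re-check of the 4-of-6 threshold rule: walk every candidate level
# in ascending order and re-verify the maintenance condition from scratch.
oracle_threshold <- function(counts, criterion = 4,
                             policy = "maintained_criterion") {
  lev <- as.numeric(names(counts))
  o <- order(lev)
  lev <- lev[o]
  cnt <- as.numeric(counts[o])
  for (i in seq_along(lev)) {
    ok <- if (policy == "maintained_criterion") {
      all(cnt[i:length(cnt)] >= criterion)
    } else {
      cnt[i] >= criterion && all(cnt[i:length(cnt)] >= cnt[i])
    }
    if (ok) return(lev[i])
  }
  NA_real_
}

# Exhaustive check that between consecutive occurrences of every stimulus
# all other stimuli occur.
oracle_separation_ok <- function(seq_vals) {
  items <- unique(seq_vals)
  for (s in items) {
    pos <- which(seq_vals == s)
    if (length(pos) < 2L) next
    for (j in seq_len(length(pos) - 1L)) {
      between <- seq_vals[(pos[j] + 1L):(pos[j + 1L] - 1L)]
      if (!all(setdiff(items, s) %in% between)) return(FALSE)
    }
  }
  TRUE
}

# Small pitch trial log fixture.
make_pitch_log <- function(targets, responses) {
  data.frame(target_chroma = targets, response_chroma = responses)
}

# A response log detecting exactly the gaps whose duration passes `rule`.
gin_log_by_rule <- function(track, rule) {
  gin_response_log(rule(track$gaps$duration_ms))
}
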