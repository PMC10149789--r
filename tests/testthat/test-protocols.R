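test_that("sine-tone protocol has 52 trials, 4 of each of 13 stimuli, and obeys the recurrence rule", {
  p <- build_pitch_id_protocol("exp1_sine52", seed = 7)
  expect_s3_class(p, "pitch_id_protocol")
  expect_equal(nrow(p$trials), 52L)
  expect_equal(sort(unique(p$trials$midi)), 54:66)
  expect_true(all(table(p$trials$midi) == 4L))
  expect_equal(p$trials$chroma, p$trials$midi %% 12L)
  expect_equal(p$iti_s, 2)
  # between consecutive occurrences of any stimulus all 12 others occur
  expect_true(oracle_separation_ok(p$trials$midi))
})

test_that("piano-tone protocol has 36 stimuli twice with > one octave between consecutive tones", {
  for (seed in 1:3) {
    p <- build_pitch_id_protocol("exp2_piano72", seed = seed)
    expect_equal(nrow(p$trials), 72L)
    expect_equal(sort(unique(p$trials$midi)), 48:83)
    expect_true(all(table(p$trials$midi) == 2L))
    # all 71 consecutive pairs, including across block boundaries
    expect_true(all(abs(diff(p$trials$midi)) >= 13L))
    expect_equal(max(p$trials$block), 6L)
    expect_true(all(table(p$trials$block) == 12L))
  }
})

test_that("protocol generators are deterministic under a seed and vary across seeds", {
  expect_identical(build_pitch_id_protocol("exp1_sine52", seed = 3),
                   build_pitch_id_protocol("exp1_sine52", seed = 3))
  expect_identical(build_gin_track("track1", seed = 3),
                   build_gin_track("track1", seed = 3))
  a <- build_bmt_session(seed = 1)
  b <- build_bmt_session(seed = 2)
  expect_identical(a, build_bmt_session(seed = 1))
  expect_false(identical(a$trials$isi_ms, b$trials$isi_ms))
  # different order, same multiset of trials
  expect_identical(sort(a$trials$isi_ms, na.last = TRUE),
                   sort(b$trials$isi_ms, na.last = TRUE))
})

test_that("GIN tracks carry 60 gaps, 6 per duration, 0-3 per segment, inside placement bounds", {
  for (spec in list(list(id = "track1", n = 35L), list(id = "track3", n = 29L))) {
    tr <- build_gin_track(spec$id, seed = 11)
    expect_equal(tr$n_segments, spec$n)
    expect_equal(nrow(tr$gaps), 60L)
    expect_equal(unname(table(tr$gaps$duration_ms)),
                 rep(6L, 10L), ignore_attr = TRUE)
    expect_true(all(table(tr$gaps$segment) <= 3L))
    expect_true(all(tr$gaps$segment >= 1 & tr$gaps$segment <= spec$n))
    expect_true(all(tr$gaps$onset_ms >= 300))
    expect_true(all(tr$gaps$onset_ms + tr$gaps$duration_ms <= 6000 - 300))
    # within-segment separation
    by_seg <- split(tr$gaps, tr$gaps$segment)
    for (sg in by_seg) {
      if (nrow(sg) > 1L) {
        off <- sg$onset_ms[-nrow(sg)] + sg$duration_ms[-nrow(sg)]
        expect_true(all(sg$onset_ms[-1L] >= off + 500))
      }
    }
  }
})

test_that("BMT sessions hold 48 tone trials (6 per ISI) plus 12 catch trials", {
  s <- build_bmt_session(seed = 5)
  expect_equal(nrow(s$trials), 60L)
  expect_equal(sum(s$trials$catch), 12L)
  counts <- table(s$trials$isi_ms)
  expect_equal(sort(as.numeric(names(counts))), BMT_ISI_MS)
  expect_true(all(counts == 6L))
  expect_equal(s$snr_db, -20)
  expect_equal(s$tone_ms, 25)
})

test_that("protocols round-trip losslessly through CSV", {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  for (x in list(build_pitch_id_protocol("exp1_sine52", seed = 2),
                 build_gin_track("track3", seed = 2),
                 build_bmt_session(seed = 2))) {
    write_protocol_csv(x, tmp)
    y <- read_protocol_csv(tmp)
    expect_equal(y, x)
  }
})
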