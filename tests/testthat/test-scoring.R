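test_that("chroma distance is the circular semitone metric", {
  expect_equal(chroma_distance(5, 5), 0)
  expect_equal(chroma_distance(11, 0), 1)
  expect_equal(chroma_distance(3, 9), 6)
  # symmetry and range over the full grid
  g <- expand.grid(a = 0:11, b = 0:11)
  d <- chroma_distance(g$a, g$b)
  expect_true(all(d == chroma_distance(g$b, g$a)))
  expect_true(all(d >= 0 & d <= 6))
  expect_error(chroma_distance(12, 0), "0..11")
})

test_that("pitch scoring computes CRR and MAD with octave-invariant chroma scoring", {
  perfect <- make_pitch_log(0:11, 0:11)
  s <- score_pitch_id(perfect)
  expect_equal(s$crr, 100)
  expect_equal(s$mad, 0)

  s2 <- score_pitch_id(make_pitch_log(c(0, 4, 7), c(0, 5, 7)))
  expect_equal(s2$crr, 200 / 3)
  expect_equal(s2$mad, 1 / 3)

  # a response one octave above the target carries the same chroma
  expect_equal(score_pitch_id(make_pitch_log(3, (3 + 12) %% 12))$crr, 100)
  expect_error(score_pitch_id(make_pitch_log(integer(0), integer(0))),
               "non-empty")
})

test_that("missing responses follow the declared policy", {
  log <- make_pitch_log(c(0, 4), c(0, NA))
  worst <- score_pitch_id(log, none_policy = "worst")
  expect_equal(worst$crr, 50)
  expect_equal(worst$mad, 3)  # (0 + 6) / 2
  expect_equal(worst$n_none, 1L)
  excl <- score_pitch_id(log, none_policy = "exclude")
  expect_equal(excl$crr, 100)
  expect_equal(excl$mad, 0)
})

test_that("detection counts tally per duration and validate lengths", {
  tr <- build_gin_track("track1", seed = 4)
  perfect <- gin_log_by_rule(tr, function(d) rep(TRUE, length(d)))
  expect_equal(unname(detection_counts(tr, perfect)), rep(6L, 10L))
  none <- gin_log_by_rule(tr, function(d) rep(FALSE, length(d)))
  expect_equal(unname(detection_counts(tr, none)), rep(0L, 10L))
  only20 <- gin_log_by_rule(tr, function(d) d == 20)
  cnt <- detection_counts(tr, only20)
  expect_equal(unname(cnt["20"]), 6L)
  expect_true(all(cnt[names(cnt) != "20"] == 0L))
  expect_error(detection_counts(tr, gin_response_log(rep(TRUE, 59))),
               "does not match")
})

test_that("threshold rule reproduces worked cases under both policies", {
  counts <- c(`2` = 0, `3` = 1, `4` = 4, `5` = 5, `6` = 6, `8` = 6,
              `10` = 6, `12` = 6, `15` = 6, `20` = 6)
  expect_equal(threshold_from_counts(counts, policy = "maintained_criterion"), 4)
  expect_equal(threshold_from_counts(counts, policy = "maintained_rate"), 4)

  dip <- counts
  dip["5"] <- 3  # breaks maintenance for candidate 4
  expect_equal(threshold_from_counts(dip, policy = "maintained_criterion"), 6)

  all6 <- stats::setNames(rep(6, 10), names(counts))
  expect_equal(threshold_from_counts(all6), 2)

  none <- stats::setNames(rep(0, 10), names(counts))
  expect_true(is.na(threshold_from_counts(none)))
  expect_error(threshold_from_counts(c(`2` = 7)), "0..6")
})

test_that("threshold is monotone: raising a count never raises the threshold", {
  set.seed(42)
  lev <- as.character(GIN_GAP_DURATIONS_MS)
  rank_of <- function(th) if (is.na(th)) Inf else match(th, GIN_GAP_DURATIONS_MS)
  for (i in 1:200) {
    cnt <- stats::setNames(sample(0:6, 10, replace = TRUE), lev)
    j <- sample(10, 1)
    bumped <- cnt
    bumped[j] <- min(6, bumped[j] + 1)
    expect_lte(rank_of(threshold_from_counts(bumped)),
               rank_of(threshold_from_counts(cnt)))
  }
})

test_that("GIN ear scoring yields GDP and GDT, censoring when nothing qualifies", {
  tr <- build_gin_track("track3", seed = 9)
  perfect <- gin_log_by_rule(tr, function(d) rep(TRUE, length(d)))
  sc <- score_gin_ear(tr, perfect)
  expect_equal(sc$gdp, 100)
  expect_equal(sc$gdt, 2)
  expect_false(sc$censored)

  miss <- gin_log_by_rule(tr, function(d) rep(FALSE, length(d)))
  sc0 <- score_gin_ear(tr, miss)
  expect_equal(sc0$gdp, 0)
  expect_true(sc0$censored)

  # detect 45 of 60 gaps -> GDP 75%
  det <- rep(FALSE, 60)
  det[1:45] <- TRUE
  expect_equal(score_gin_ear(tr, gin_response_log(det))$gdp, 75)
})

test_that("BMT ear scoring separates tone trials, threshold and catch-trial false alarms", {
  s <- build_bmt_session(seed = 6)
  press_all_tones <- bmt_response_log(!s$trials$catch)
  sc <- score_bmt_ear(s, press_all_tones)
  expect_equal(sc$bmtp, 100)
  expect_equal(sc$bmtt, 0)
  expect_equal(sc$false_alarm_rate, 0)

  never <- bmt_response_log(rep(FALSE, 60))
  sc0 <- score_bmt_ear(s, never)
  expect_equal(sc0$bmtp, 0)
  expect_true(sc0$censored)
  expect_equal(sc0$false_alarm_rate, 0)

  # counts {400:6,200:6,100:5,50:4,30:2,20:1,10:0,0:0} -> threshold 50 ms
  cnt <- c(`0` = 0, `10` = 0, `20` = 1, `30` = 2, `50` = 4, `100` = 5,
           `200` = 6, `400` = 6)
  expect_equal(threshold_from_counts(cnt), 50)
})

test_that("ear averaging means percents and thresholds, propagating censoring with a flag", {
  tr <- build_gin_track("track1", seed = 2)
  left <- score_gin_ear(tr, gin_log_by_rule(tr, function(d) d >= 4))
  right <- score_gin_ear(tr, gin_log_by_rule(tr, function(d) d >= 6))
  avg <- average_ears(left, right)
  expect_equal(avg$gdt, 5)  # (4 + 6) / 2
  expect_equal(avg$gdp, mean(c(left$gdp, right$gdp)))

  cens <- score_gin_ear(tr, gin_log_by_rule(tr, function(d) rep(FALSE, length(d))))
  avgc <- average_ears(left, cens)
  expect_true(avgc$censored)
  expect_true(is.na(avgc$gdt))
  # GDP 70 and 80 average to 75 regardless of censoring
  expect_equal(average_ears(left, right)$gdp >= 0, TRUE)
})
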