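test_that("psychometric function hits its closed-form values and asymptotes", {
  expect_equal(psychometric_p(5, list(x50 = 5, slope = 1)), 0.5)
  # closed form: 0.1 + 0.85 / (1 + exp(-2))
  expect_equal(psychometric_p(7, list(x50 = 5, slope = 1, guess = 0.1,
                                      lapse = 0.05)),
               0.1 + 0.85 * plogis(2))
  expect_equal(psychometric_p(1e9, list(x50 = 5, slope = 1, lapse = 0.05)),
               0.95, tolerance = 1e-9)
  expect_equal(psychometric_p(0, list(x50 = 1e9, slope = 1, guess = 0.2)),
               0.2, tolerance = 1e-6)
  expect_error(psychometric_p(1, list(x50 = 5, slope = 0)), "slope")
  expect_error(psychometric_p(1, list(x50 = 5, slope = 1, guess = 0.7,
                                      lapse = 0.5)), "<= 1")
})

test_that("pitch observer matches its analytic CRR/MAD expectations", {
  proto <- build_pitch_id_protocol("exp1_sine52", seed = 1)
  # deterministic namer
  s <- score_pitch_id(simulate_pitch_observer(
    list(sigma = 0, guess_rate = 0), proto, seed = 2))
  expect_equal(s$crr, 100)
  expect_equal(s$mad, 0)

  # pure guessing: E[CRR] = 100/12, E[MAD] = mean circular distance = 3
  set.seed(3)
  scores <- replicate(60, {
    sc <- score_pitch_id(simulate_pitch_observer(
      list(sigma = 0, guess_rate = 1), proto))
    c(sc$crr, sc$mad)
  })
  expect_equal(mean(scores[1, ]), 100 / 12, tolerance = 0.15)
  expect_equal(mean(scores[2, ]), 3, tolerance = 0.05)

  # sigma = 0.5: E[CRR] = 100 * (2 * pnorm(1) - 1)
  set.seed(4)
  crr <- replicate(60, score_pitch_id(simulate_pitch_observer(
    list(sigma = 0.5, guess_rate = 0), proto))$crr)
  expect_equal(mean(crr), 100 * (2 * pnorm(1) - 1), tolerance = 1.5)
})

test_that("gap-detection observer respects its psychometric limits", {
  tr <- build_gin_track("track1", seed = 5)
  step <- simulate_gin_observer(list(x50 = 1e-6, slope = 1e-3), tr, seed = 1)
  expect_equal(score_gin_ear(tr, step)$gdp, 100)

  deaf <- simulate_gin_observer(list(x50 = 5, slope = 1, guess = 0, lapse = 1),
                                tr, seed = 1)
  sc <- score_gin_ear(tr, deaf)
  expect_equal(sc$gdp, 0)
  expect_true(sc$censored)

  # steep observer at x50 = 4.5 thresholds at 5 ms in most runs
  set.seed(6)
  gdt <- replicate(40, score_gin_ear(tr, simulate_gin_observer(
    list(x50 = 4.5, slope = 0.05), tr))$gdt)
  expect_gte(mean(gdt == 5, na.rm = TRUE), 0.9)
})

test_that("backward-masking observer presses per the psychometric function and false alarms", {
  s <- build_bmt_session(seed = 7)
  perfect <- simulate_bmt_observer(list(x50 = -5, slope = 0.5), s, seed = 1)
  sc <- score_bmt_ear(s, perfect)
  expect_equal(sc$bmtp, 100)
  expect_equal(sc$bmtt, 0)

  # catch trials pressed at the false-alarm probability
  set.seed(8)
  fa <- replicate(120, score_bmt_ear(s, simulate_bmt_observer(
    list(x50 = 1e9, slope = 1, false_alarm = 0.5), s))$false_alarm_rate)
  expect_equal(mean(fa), 0.5, tolerance = 0.05)

  # steep observer at x50 = 40 ms thresholds at 50 ms mostly
  set.seed(9)
  bmtt <- replicate(40, score_bmt_ear(s, simulate_bmt_observer(
    list(x50 = 40, slope = 0.5), s))$bmtt)
  expect_gte(mean(bmtt == 50, na.rm = TRUE), 0.9)
})

test_that("empirical detection rates are nondecreasing in level for a valid observer", {
  tr <- build_gin_track("track3", seed = 10)
  set.seed(11)
  total <- rep(0, 10)
  for (i in 1:80) {
    log <- simulate_gin_observer(list(x50 = 6, slope = 2, guess = 0.05,
                                      lapse = 0.05), tr)
    total <- total + detection_counts(tr, log)
  }
  rate <- total / (80 * 6)
  # allow binomial noise: adjacent decreases no larger than 3 SE
  se <- sqrt(rate * (1 - rate) / (80 * 6))
  expect_true(all(diff(rate) >= -3 * (se[-1] + se[-10])))
})
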