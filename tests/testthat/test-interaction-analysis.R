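test_that("call ratio is call onsets per second of song", {
  bouts <- data.frame(onset_s = c(0, 10), offset_s = c(2, 12))
  expect_equal(callRatio(bouts, call_table(c(0.5, 10.5), c(0.6, 10.6)))$call_ratio,
               0.5)
  expect_equal(callRatio(bouts, call_table(numeric(0), numeric(0)))$call_ratio, 0)
  # no song: undefined
  none <- callRatio(data.frame(onset_s = numeric(), offset_s = numeric()),
                    call_table(1, 1.1))
  expect_true(is.na(none$call_ratio))
})

test_that("call ratio is concatenation-invariant and linear in calls", {
  b1 <- data.frame(onset_s = 0, offset_s = 4)
  calls2 <- call_table(c(1, 2), c(1.05, 2.05))
  calls4 <- call_table(c(1, 2, 2.5, 3.5), c(1.05, 2.05, 2.55, 3.55))
  r2 <- callRatio(b1, calls2)$call_ratio
  r4 <- callRatio(b1, calls4)$call_ratio
  expect_equal(r4, 2 * r2)
  # two sessions with equal ratios concatenate to the same ratio
  b_cat <- data.frame(onset_s = c(0, 100), offset_s = c(4, 104))
  calls_cat <- call_table(c(1, 2, 101, 102), c(1.05, 2.05, 101.05, 102.05))
  expect_equal(callRatio(b_cat, calls_cat)$call_ratio, r2)
})

test_that("development trend reproduces noiseless and degenerate fits", {
  ages <- seq(50, 80, by = 5)
  lin <- data.frame(age_dph = ages, call_ratio = 0.1 + 0.01 * ages)
  tr <- suppressWarnings(developmentTrend(lin))  # perfect-fit warning
  expect_equal(tr$slope, 0.01, tolerance = 1e-10)
  expect_equal(tr$r_squared, 1, tolerance = 1e-9)

  const <- data.frame(age_dph = ages, call_ratio = rep(0.4, length(ages)))
  tc <- suppressWarnings(developmentTrend(const))
  expect_equal(tc$slope, 0, tolerance = 1e-12)
  expect_lt(abs(tc$r_squared), 1e-9)

  sing <- data.frame(age_dph = rep(60, 5), call_ratio = rnorm(5))
  expect_true(developmentTrend(sing)$singular)
})

test_that("learner threshold is the 1.96 SE upper bound to one decimal", {
  expect_equal(learnerThreshold(32.023, 4.44), 40.7)
  expect_equal(learnerThreshold(0, 0), 0)
  expect_equal(learnerThreshold(10, 1), 12.0)
  expect_error(learnerThreshold(10, -1))
})

test_that("learner classification uses a strict threshold", {
  thr <- learnerThreshold(32.023, 4.44)
  expect_identical(classifyLearner(42.33, thr), "good")
  expect_identical(classifyLearner(29.11, thr), "poor")
  expect_identical(classifyLearner(thr, thr), "poor")
  # the published similarity ranges partition into good and poor learners
  expect_true(all(classifyLearner(c(42.33, 55, 73.1), thr) == "good"))
  expect_true(all(classifyLearner(c(19.44, 25, 29.11), thr) == "poor"))
})

test_that("post-call snippets are 300 ms, clipped and paired with controls", {
  # bout A [1, 3), call in it ending at 1.5; bout B [10, 12) unperturbed
  syls <- syl_table(c(1, 1.6, 2.4, 10, 10.8, 11.6), c(1.5, 2.2, 3.0, 10.6, 11.4, 12.0))
  calls <- call_table(1.45, 1.5)
  sn <- extractPostCallSnippets(syls, calls)
  expect_identical(nrow(sn), 1L)
  expect_equal(sn$snippet_on_s, 1.5)
  expect_equal(sn$snippet_off_s, 1.8)
  expect_false(sn$short)
  expect_false(sn$no_next_syllable)
  # control lives in the unperturbed bout at the same within-bout offsets
  expect_identical(sn$control_bout, 2L)
  expect_equal(sn$control_on_s - 10, sn$snippet_on_s - 1)

  # call close to the bout end: clipped and flagged short
  calls2 <- call_table(2.8, 2.85)
  sn2 <- extractPostCallSnippets(syls, calls2)
  expect_true(sn2$short)
  expect_equal(sn2$snippet_off_s, 3.0)
})

test_that("snippet counts match the generator's in-song call placements", {
  s <- simulateSessionEvents(sessionSimConfig(callBaseRateHz = 0.8,
                                              callRateOutSongHz = 0,
                                              sessionDur_s = 120, seed = 21))
  sn <- extractPostCallSnippets(s$events, s$events)
  bouts <- assembleSongBouts(s$events)
  att <- attributeCallsToSong(bouts, s$events)
  expect_identical(nrow(sn), sum(att$flagged))
  expect_true(all(sn$snippet_off_s > sn$snippet_on_s))
})

test_that("session summaries assemble counts, ratio and rate", {
  s <- simulateSessionEvents(sessionSimConfig(callBaseRateHz = 0.5, seed = 8))
  sm <- sessionSummary(s$events, s$events)
  expect_identical(sm$n_bouts, nrow(s$bouts))
  expect_gt(sm$syllable_rate, 0)
  expect_equal(sm$call_ratio,
               callRatio(assembleSongBouts(s$events), s$events)$call_ratio)
})
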