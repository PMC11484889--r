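test_that("envelope is a moving RMS with the expected properties", {
  z <- audioClip(numeric(4000), 8000)
  expect_true(all(computeEnvelope(z) == 0))

  # constant-amplitude sinusoid: envelope ~ a / sqrt(2) away from edges
  a <- 0.6
  sr <- 8000
  clip <- audioClip(a * sin(2 * pi * 1000 * (0:7999) / sr), sr)
  env <- computeEnvelope(clip, smoothing_s = 0.004)
  mid <- env[200:7800]
  expect_equal(mean(mid), a / sqrt(2), tolerance = 0.01)

  # homogeneity: scaling samples scales the envelope
  clip2 <- audioClip(3 * samples(clip), sr)
  expect_equal(computeEnvelope(clip2, 0.004), 3 * env, tolerance = 1e-12)

  expect_error(computeEnvelope(audioClip(numeric(10), 8000), 1), "longer")
})

test_that("syllable segmentation matches the tutor ground truth", {
  sil <- audioClip(numeric(8000), 8000)
  expect_identical(nEvents(segmentSyllables(sil)), 0L)

  tut <- renderTutorAudio(40000)
  seg <- segmentSyllables(tut$clip)
  expect_identical(nEvents(seg), 4L)
  durs <- events(seg)$offset_s - events(seg)$onset_s
  expect_true(all(abs(durs - c(0.185, 0.155, 0.185, 0.155)) <= 0.005))
})

test_that("sub-threshold gaps below the merge limit are bridged", {
  sr <- 10000
  burst <- rep(0.5, round(0.050 * sr))
  gap <- numeric(round(0.005 * sr))
  x <- c(numeric(500), burst, gap, burst, numeric(500))
  clip <- audioClip(x, sr)
  seg <- segmentSyllables(clip, segmentationParams(smoothing_s = 0.001,
                                                   minGap_s = 0.010,
                                                   threshold = 0.1))
  expect_identical(nEvents(seg), 1L)
  seg2 <- segmentSyllables(clip, segmentationParams(smoothing_s = 0.001,
                                                    minGap_s = 0.002,
                                                    threshold = 0.1))
  expect_identical(nEvents(seg2), 2L)
})

test_that("song bouts follow the 400 ms span and 350 ms break rules", {
  # two syllables, 0.1 s gap, 0.5 s span: one bout
  b1 <- assembleSongBouts(syl_table(c(0, 0.3), c(0.2, 0.5)))
  expect_identical(nrow(b1), 1L)
  expect_equal(c(b1$onset_s, b1$offset_s), c(0, 0.5))
  expect_identical(b1$n_syllables, 2L)

  # single 0.3 s syllable: span below 400 ms, no bout
  expect_identical(nrow(assembleSongBouts(syl_table(0, 0.3))), 0L)

  # span of exactly 400 ms is kept
  expect_identical(nrow(assembleSongBouts(syl_table(c(0, 0.3), c(0.2, 0.4)))), 1L)

  # gap of exactly 350 ms breaks the chain
  b2 <- assembleSongBouts(syl_table(c(0, 0.55), c(0.2, 1.0)))
  expect_identical(nrow(b2), 1L)  # only the second span (0.45 s) survives
  expect_equal(b2$onset_s, 0.55)
  # gap just under 350 ms chains
  b3 <- assembleSongBouts(syl_table(c(0, 0.549), c(0.2, 1.0)))
  expect_identical(nrow(b3), 1L)
  expect_equal(b3$offset_s - b3$onset_s, 1.0)
})

test_that("bout assembly is idempotent and order-independent", {
  set.seed(42)
  on <- sort(runif(20, 0, 30))
  off <- on + runif(20, 0.05, 0.25)
  off <- pmin(off, c(on[-1] - 0.01, Inf))  # keep non-overlapping
  tab <- syl_table(on, off)
  b <- assembleSongBouts(tab)
  perm <- sample(20)
  tab2 <- syl_table(on[perm], off[perm])  # eventTable sorts internally
  b2 <- assembleSongBouts(tab2)
  expect_equal(b$onset_s, b2$onset_s)
  expect_equal(b$offset_s, b2$offset_s)
})

test_that("calls are attributed by the onset-in-window rule", {
  bouts <- assembleSongBouts(syl_table(c(1.0, 1.4), c(1.3, 1.8)))
  # onset 1 ms before the bout: not counted
  att <- attributeCallsToSong(bouts, call_table(0.999, 1.05))
  expect_identical(sum(att$perBout), 0L)
  # onset inside, offset past bout end: counted
  att2 <- attributeCallsToSong(bouts, call_table(1.75, 1.95))
  expect_identical(sum(att2$perBout), 1L)
  # onset exactly at the bout offset: outside the half-open window
  att3 <- attributeCallsToSong(bouts, call_table(1.8, 1.9))
  expect_identical(sum(att3$perBout), 0L)
})

test_that("syllable rate excludes gaps and scales as expected", {
  expect_equal(syllableRate(syl_table(0, 1)), 1)
  tut <- renderTutorAudio(40000)
  expect_equal(syllableRate(tut$events), 4 / 0.680, tolerance = 1e-12)
  # gap invariance: 10 x 100 ms syllables at any spacing
  on <- seq(0, by = 0.7, length.out = 10)
  expect_equal(syllableRate(syl_table(on, on + 0.1)), 10)
  on2 <- seq(0, by = 0.2, length.out = 10)
  expect_equal(syllableRate(syl_table(on2, on2 + 0.1)), 10)
})

test_that("tutor template statistics match the published values", {
  tut <- renderTutorAudio(40000)
  st <- syllableGapStats(tut$events)
  expect_equal(st$syllable_mean_s * 1000, 170)
  expect_equal(st$gap_mean_s * 1000, mean(c(119, 124, 119)), tolerance = 1e-9)
  expect_equal(round(st$gap_mean_s * 1000), 121)
  expect_identical(st$n_gaps, 3L)
  # single syllable: gap statistics are absent
  st1 <- syllableGapStats(syl_table(0, 0.5))
  expect_true(is.na(st1$gap_mean_s))
})

test_that("segmentation scoring counts greedy one-to-one onset matches", {
  truth <- syl_table(seq(0, 9), seq(0, 9) + 0.2)
  expect_equal(evaluateSegmentation(truth, truth)$precision, 1)
  expect_equal(evaluateSegmentation(truth, truth)$recall, 1)

  empty <- eventTable()
  ev0 <- evaluateSegmentation(empty, truth)
  expect_equal(ev0$precision, 0)
  expect_equal(ev0$recall, 0)

  # 8 of 10 matched plus 2 false positives: precision = recall = 0.8
  pred <- syl_table(c(seq(0, 7) + 0.004, 20, 21),
                    c(seq(0, 7) + 0.204, 20.2, 21.2))
  ev <- evaluateSegmentation(pred, truth, tolerance_s = 0.010)
  expect_equal(ev$precision, 0.8)
  expect_equal(ev$recall, 0.8)
  expect_identical(ev$n_matched, 8L)
})
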