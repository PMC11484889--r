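test_that("tutor playback has the published ABAB timing", {
  tut <- renderTutorAudio(40000, pad_s = 0.05)
  ev <- events(tut$events)
  expect_identical(nrow(ev), 4L)
  expect_equal(ev$offset_s - ev$onset_s, c(0.185, 0.155, 0.185, 0.155))
  # motif span: 0.185+0.119+0.155+0.124+0.185+0.119+0.155
  expect_equal(max(ev$offset_s) - min(ev$onset_s), 1.042)
  # internal gaps
  expect_equal(ev$onset_s[-1] - ev$offset_s[-4], c(0.119, 0.124, 0.119))
})

test_that("tutor rendering is deterministic and rate-respecting", {
  a <- renderTutorAudio(16000)
  b <- renderTutorAudio(16000)
  expect_identical(samples(a$clip), samples(b$clip))
  expect_equal(sampleRate(a$clip), 16000)
  expect_error(renderTutorAudio(4000))
})

test_that("session generator honours degenerate rate settings", {
  cfg0 <- sessionSimConfig(callBaseRateHz = 0, callRateOutSongHz = 0,
                           seed = 3)
  s <- simulateSessionEvents(cfg0)
  expect_identical(sum(events(s$events)$kind == "call"), 0L)
  expect_gt(sum(events(s$events)$kind == "syllable"), 0L)

  cfgB <- sessionSimConfig(boutRatePerMin = 0, callRateOutSongHz = 0.2,
                           seed = 3)
  sb <- simulateSessionEvents(cfgB)
  expect_identical(sum(events(sb$events)$kind == "syllable"), 0L)
  expect_identical(nrow(sb$bouts), 0L)
})

test_that("generated sessions satisfy event-table invariants and bout rules", {
  for (seed in 1:5) {
    s <- simulateSessionEvents(sessionSimConfig(callBaseRateHz = 0.6,
                                                seed = seed))
    expect_true(validObject(s$events))
    bouts <- assembleSongBouts(s$events)
    # assembled bouts reproduce the generator's bout windows
    expect_equal(nrow(bouts), nrow(s$bouts))
    expect_equal(bouts$onset_s, s$bouts$onset_s, tolerance = 1e-9)
  }
})

test_that("within-song call counts are Poisson at the configured rate", {
  ratios <- vapply(1:60, function(i) {
    s <- simulateSessionEvents(sessionSimConfig(callBaseRateHz = 0.5,
                                                sessionDur_s = 60, seed = i))
    callRatio(s$bouts, s$events)$call_ratio
  }, numeric(1))
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 0.5), 3 * se)
})

test_that("developmental series follows the configured linear trend", {
  # slope 0: all true rates equal
  dev0 <- simulateDevelopment(sessionSimConfig(callAgeSlope = 0, seed = 2),
                              ages = seq(50, 80, by = 5))
  expect_true(all(dev0$summaries$true_rate_hz == dev0$summaries$true_rate_hz[1]))

  # noiseless limit: OLS on the true rates recovers the slope exactly
  dev <- simulateDevelopment(
    sessionSimConfig(callAgeSlope = 0.012, callBaseRateHz = 0.3, age0 = 50,
                     seed = 2), ages = seq(50, 88, by = 2))
  fit <- stats::lm(true_rate_hz ~ age_dph, data = dev$summaries)
  expect_equal(unname(stats::coef(fit)["age_dph"]), 0.012, tolerance = 1e-12)
})

test_that("intracellular generator honours its degenerate settings", {
  # rho = 1, no private noise: identical subthreshold traces inside window
  sim1 <- simulateIntracellularTrialSet(
    trialSimConfig(nTrials = 4, rho = 1, seed = 5))
  sr <- 10000
  win <- (floor(0.4 * sr) + 1):ceiling(0.6 * sr)
  base <- sim1$subthreshold[[1]][win]
  # shared component is identical across trials; private noise enters with
  # weight sqrt(1 - rho) = 0
  centered <- lapply(sim1$subthreshold, function(v) v[win] - mean(v[win]))
  for (k in 2:4)
    expect_equal(centered[[k]], centered[[1]], tolerance = 1e-9)

  # no locked or background spikes: zero spikes
  sim0 <- simulateIntracellularTrialSet(
    trialSimConfig(lambdaLocked = 0, bgRateHz = 0, seed = 5))
  expect_identical(sum(lengths(sim0$spikeTimes)), 0L)

  # determinism
  a <- simulateIntracellularTrialSet(trialSimConfig(nTrials = 3, seed = 9,
                                                    lambdaLocked = 2))
  b <- simulateIntracellularTrialSet(trialSimConfig(nTrials = 3, seed = 9,
                                                    lambdaLocked = 2))
  expect_identical(a$trials@traces, b$trials@traces)
  expect_identical(a$spikeTimes, b$spikeTimes)
})

test_that("singing-perturbation generator injects the configured effect", {
  # deflection recovered by the subthreshold pipeline across replicates
  deltas <- vapply(1:30, function(i) {
    sim <- simulateSingingPerturbation(
      nRenditions = 8, perturbedIdx = c(2, 6), deflectionMv = 8,
      extraSpikes = 0L, noiseSdMv = 1, seed = i)
    e <- sim$epoch
    m <- function(v) mean(v[(floor(e[1] * 1e4) + 1):ceiling(e[2] * 1e4)])
    mean(vapply(sim$subthreshold[c(2, 6)], m, numeric(1))) -
      mean(vapply(sim$subthreshold[setdiff(1:8, c(2, 6))], m, numeric(1)))
  }, numeric(1))
  se <- stats::sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas) - 8), 3 * se)

  # exactly 2 extra spikes at zero background: delta = 2 per rendition
  sim <- simulateSingingPerturbation(nRenditions = 6, perturbedIdx = 3L,
                                     extraSpikes = 2L, seed = 4)
  n_extra <- length(sim$spikeTimes[[3]]) - length(sim$spikeTimes[[1]])
  expect_identical(n_extra, 2L)
})

test_that("population generator respects class rates and schedule", {
  pop <- simulatePopulationUnits(nUnits = 10, propProjection = 1,
                                 projRateRange = c(0.5, 1), nStimuli = 60,
                                 period_s = 1.5, seed = 6)
  # schedule: 60 onsets spanning 88.5 s
  on <- events(pop$schedule)$onset_s
  expect_identical(length(on), 60L)
  expect_equal(max(on) - min(on), 88.5)
  # projection-class spontaneous rates at or below 2 Hz
  for (u in pop$units) {
    r <- spontaneousRate(spikeTimes(u), pop$schedule, pop$totalDur_s)
    expect_lte(r, 2)
  }
  # determinism
  pop2 <- simulatePopulationUnits(nUnits = 10, propProjection = 1,
                                  projRateRange = c(0.5, 1), nStimuli = 60,
                                  period_s = 1.5, seed = 6)
  expect_identical(lapply(pop$units, spikeTimes),
                   lapply(pop2$units, spikeTimes))
})
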