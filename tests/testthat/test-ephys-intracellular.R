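test_that("spike detection finds threshold crossings and nothing else", {
  sr <- 10000
  flat <- rep(-70, sr)
  expect_identical(length(detectSpikes(flat, sr, -70)), 0L)

  # one 35 mV transient: exactly one spike at its crossing time
  v <- flat
  v[5001:5015] <- -70 + 35
  s <- detectSpikes(v, sr, -70)
  expect_identical(length(s), 1L)
  expect_equal(s, 5000 / sr, tolerance = 1 / sr)

  # refractory merge: two crossings 0.5 ms apart collapse to one
  v2 <- flat
  v2[5001:5003] <- -40
  v2[5008:5010] <- -40
  expect_identical(length(detectSpikes(v2, sr, -70)), 1L)
  v3 <- flat
  v3[5001:5003] <- -40
  v3[5031:5033] <- -40
  expect_identical(length(detectSpikes(v3, sr, -70)), 2L)
})

test_that("generator ground-truth spikes are recovered exactly", {
  sim <- simulateIntracellularTrialSet(
    trialSimConfig(nTrials = 10, lambdaLocked = 3, bgRateHz = 2,
                   noiseSdMv = 2, seed = 3))
  st <- subthresholdTraces(sim$trials)
  for (k in 1:10) {
    expect_identical(length(st$spikeTimes[[k]]),
                     length(sim$spikeTimes[[k]]))
    if (length(sim$spikeTimes[[k]]))
      expect_lt(max(abs(st$spikeTimes[[k]] - sim$spikeTimes[[k]])), 0.002)
  }
})

test_that("analysis and silence windows follow the 50 ms pad rules", {
  w <- stimulusWindows(1.00, 1.15)
  expect_equal(w$analysis, c(1.00, 1.20))
  expect_equal(w$silence, c(0.75, 0.95))
  w2 <- stimulusWindows(0.30, 0.40)
  expect_equal(w2$analysis, c(0.30, 0.45))
  expect_equal(w2$silence, c(0.10, 0.25))
  expect_error(stimulusWindows(0.05, 0.15), "before trace start")
})

test_that("firing rate is count over duration, unbiased on Poisson input", {
  expect_equal(firingRate(numeric(0), c(0, 1)), 0)
  expect_equal(firingRate(c(0.45, 0.5), c(0.4, 0.6)), 10)
  set.seed(11)
  trains <- poisson_trains(1000, 5, 1)
  rates <- vapply(trains, firingRate, numeric(1), window = c(0, 1))
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 5), 3 * se)
})

test_that("spiking precision flags perfect locking and refuses sparse input", {
  trains <- replicate(8, c(0.05, 0.12), simplify = FALSE)
  r <- spikingPrecision(trains, c(0, 0.2), nPerm = 200, seed = 1)
  # identical spike times in every trial: mean cross-trial latency
  # difference only reflects the two fixed latencies; strongly responsive
  expect_true(r$responsive)
  expect_gt(r$score, 2)

  one <- spikingPrecision(list(c(0.1), numeric(0)), c(0, 0.2),
                          nPerm = 50, seed = 1)
  expect_true(is.na(one$D_obs))
  expect_true(is.na(one$responsive))

  # single common latency: D_obs is 0 exactly
  same <- spikingPrecision(replicate(5, 0.1, simplify = FALSE), c(0, 0.2),
                           nPerm = 100, seed = 2)
  expect_equal(same$D_obs, 0)
  expect_true(same$responsive)
})

test_that("spiking precision is calibrated against the Poisson null", {
  set.seed(31)
  resp <- vapply(1:80, function(i) {
    trains <- poisson_trains(15, 5, 0.2)
    r <- spikingPrecision(trains, c(0, 0.2), nPerm = 300, seed = 4000 + i)
    isTRUE(r$responsive)
  }, logical(1))
  expect_gte(mean(resp), 0.0)
  expect_lte(mean(resp), 0.15)  # wide gate at this replicate count
})

test_that("spike clipping reconstructs the subthreshold trace", {
  sr <- 10000
  sim <- simulateIntracellularTrialSet(
    trialSimConfig(nTrials = 6, lambdaLocked = 3, bgRateHz = 2,
                   noiseSdMv = 2, seed = 3))
  for (k in 1:6) {
    v <- traces(sim$trials)[[k]]
    s <- detectSpikes(v, sr, -70)
    ex <- extractSubthreshold(v, sr, s, -70)
    if (!length(s)) {
      expect_identical(ex$vm, v)
      next
    }
    mask <- rep(TRUE, length(v))
    for (r in seq_len(nrow(ex$cutSegments))) {
      a <- max(1, ex$cutSegments[r, 1] - 20)  # 2 ms guard
      b <- min(length(v), ex$cutSegments[r, 2] + 20)
      mask[a:b] <- FALSE
    }
    rmse <- sqrt(mean((ex$vm[mask] - sim$subthreshold[[k]][mask])^2))
    expect_lt(rmse, 0.5)
    # clipped trace never exceeds the detection level
    if (!ex$boundaryFlagged)
      expect_lt(max(ex$vm), -70 + 15 + 1e-9)
  }
})

test_that("no-spike traces pass through clipping unchanged; cuts merge", {
  sr <- 10000
  v <- -70 + sin(seq(0, 10, length.out = sr))
  expect_identical(extractSubthreshold(v, sr, numeric(0), -70)$vm, v)

  # two distinct crossings sharing one sub-level sample: cuts merge
  v2 <- rep(-70, 1000)
  v2[500:520] <- -40
  v2[521] <- -60            # single dip below the -55 mV level
  v2[522:540] <- -40
  s <- detectSpikes(v2, sr, -70)
  expect_identical(length(s), 2L)
  ex <- extractSubthreshold(v2, sr, s, -70)
  expect_identical(nrow(ex$cutSegments), 1L)
  expect_lt(max(ex$vm), -54.9)
})

test_that("subthreshold correlation handles identity, orthogonality, gain", {
  sr <- 1000
  t <- (0:999) / sr
  a <- sin(2 * pi * 5 * t)
  expect_equal(subthresholdCorrelation(list(a, a, a), sr, c(0, 1))$mean_r, 1)

  b <- cos(2 * pi * 5 * t)
  r <- subthresholdCorrelation(list(a, b), sr, c(0, 1))$mean_r
  expect_lt(abs(r), 0.01)

  # invariant to a common positive affine rescaling
  set.seed(5)
  x <- lapply(1:4, function(i) rnorm(1000))
  r1 <- subthresholdCorrelation(x, sr, c(0, 1))$mean_r
  x2 <- lapply(x, function(v) 3.7 * v - 12)
  expect_equal(subthresholdCorrelation(x2, sr, c(0, 1))$mean_r, r1)

  # zero-variance trace: pair skipped and counted
  z <- rep(0, 1000)
  rz <- subthresholdCorrelation(list(a, z, b), sr, c(0, 1))
  expect_identical(rz$n_skipped, 2L)
})

test_that("delta subthreshold measures the injected window offset", {
  sr <- 1000
  base <- rep(-70, 2000)
  expect_equal(deltaSubthreshold(list(base, base), sr,
                                 c(1, 1.5), c(0.2, 0.7))$delta_mV, 0)
  v <- base
  v[1001:1500] <- -67  # +3 mV boxcar in the analysis window
  expect_equal(deltaSubthreshold(list(v), sr, c(1, 1.5), c(0.2, 0.7))$delta_mV,
               3)
})

test_that("perturbation spike deltas and the 1.96 SD flag behave", {
  # instance delta: 3 spikes vs unperturbed mean 1
  pd <- perturbationSpikeDelta(
    list(c(0.42, 0.45, 0.5)),
    list(c(0.43), c(0.47), numeric(0), c(0.41), c(0.44), c(0.46)),
    epoch = c(0.4, 0.6))
  expect_equal(pd$delta, 3 - 5 / 6)

  # stereotyped renditions: delta 0 +/- 0, nothing flagged
  same <- replicate(6, c(0.45, 0.52), simplify = FALSE)
  pd0 <- perturbationSpikeDelta(same[1:2], same[3:6], c(0.4, 0.6))
  expect_equal(pd0$delta, c(0, 0))
  expect_equal(pd0$ci, c(0, 0))
  expect_false(any(pd0$flagged))

  # constructed +2-spike perturbations at zero background: all flagged
  sim <- simulateSingingPerturbation(nRenditions = 10,
                                     perturbedIdx = c(2, 5, 9),
                                     extraSpikes = 2L, noiseSdMv = 1,
                                     seed = 4)
  st <- subthresholdTraces(sim$trials)
  pd2 <- perturbationSpikeDelta(st$spikeTimes[c(2, 5, 9)],
                                st$spikeTimes[setdiff(1:10, c(2, 5, 9))],
                                sim$epoch)
  expect_equal(pd2$delta, c(2, 2, 2))
  expect_true(all(pd2$flagged))
})

test_that("subthreshold perturbation flag needs and uses the adult bound", {
  expect_error(perturbationSubthresholdFlag(c(0, 1)), "adult")
  expect_identical(perturbationSubthresholdFlag(0, 2), FALSE)
  expect_identical(perturbationSubthresholdFlag(2, 2), FALSE)   # tie: not out
  expect_identical(perturbationSubthresholdFlag(-2.1, 2), TRUE)
  # deflection at twice the bound with mild noise flags essentially always
  set.seed(9)
  d <- 4 + rnorm(40, 0, 0.2)
  expect_gte(mean(perturbationSubthresholdFlag(d, 2)), 0.95)
})

test_that("per-cell intracellular summary recovers the simulated regime", {
  cfg <- trialSimConfig(nTrials = 12, rho = 0.6, lambdaLocked = 3,
                        bgRateHz = 1, noiseSdMv = 2, seed = 13)
  sim <- simulateIntracellularTrialSet(cfg)
  sm <- summarizeIntracellular(sim$trials,
                               runConfig(n_permutations = 300L, seed = 2L))
  expect_identical(sm$n_trials, 12L)
  # locked spikes inside the analysis window raise the call rate
  expect_gt(sm$firing_rate_call_hz, sm$firing_rate_silence_hz)
  expect_true(sm$responsive_call)
  expect_gt(sm$subthreshold_corr, 0.3)
})
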