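## Synthetic inputs with known ground truth. Every generator is
## deterministic under a fixed seed and emits objects that satisfy the
## package invariants (sorted event tables, spikes >= 30 mV above baseline).

#' Session simulation settings
#'
#' Describes one juvenile recording session: song bouts of consecutive
#' syllables on the cage ("box") microphone and female calls captured on the
#' backpack microphone, with the within-song call rate following a linear
#' age trend (floored at zero): \code{rate(age) = callBaseRateHz +
#' callAgeSlope * (age - age0)}.
#'
#' @param ageDph juvenile age in days post-hatch.
#' @param sessionDur_s session length in seconds.
#' @param boutRatePerMin expected song bouts per minute.
#' @param boutDurMean_s,boutDurSd_s target bout span distribution (s).
#' @param sylDurMean_s,sylDurSd_s syllable duration distribution (s).
#' @param gapMean_s,gapSd_s intra-bout gap distribution (s); kept well below
#'   the 350 ms bout-break rule.
#' @param callBaseRateHz within-song call rate at \code{age0} (Hz).
#' @param callAgeSlope change in within-song call rate per day (Hz/dph).
#' @param age0 reference age for the trend.
#' @param callRateOutSongHz call rate outside song windows (Hz).
#' @param callDur_s female call duration (s).
#' @param noiseFloor background noise amplitude on the rendered audio.
#' @param seed RNG seed.
#' @return list of class "SessionSimConfig".
#' @export
sessionSimConfig <- function(ageDph = 60L, sessionDur_s = 60,
                             boutRatePerMin = 4, boutDurMean_s = 1.2,
                             boutDurSd_s = 0.3, sylDurMean_s = 0.120,
                             sylDurSd_s = 0.020, gapMean_s = 0.080,
                             gapSd_s = 0.015, callBaseRateHz = 0.3,
                             callAgeSlope = 0, age0 = 60,
                             callRateOutSongHz = 0.05, callDur_s = 0.080,
                             noiseFloor = 0.005, seed = 1L) {
  stopifnot(sessionDur_s > 0, boutRatePerMin >= 0, callBaseRateHz >= 0,
            callRateOutSongHz >= 0, callDur_s > 0)
  structure(as.list(environment()), class = "SessionSimConfig")
}

#' Within-song call rate implied by a session config at its age
#' @param cfg a [sessionSimConfig()].
#' @param ageDph age to evaluate at (defaults to the config's age).
#' @return rate in Hz, floored at 0.
#' @export
callRateInSongHz <- function(cfg, ageDph = cfg$ageDph) {
  max(0, cfg$callBaseRateHz + cfg$callAgeSlope * (ageDph - cfg$age0))
}

## 5 ms raised-cosine on/off ramps; avoids clicks so the envelope
## segmenter sees the intended interval
.apply_ramps <- function(x, sr, ramp_s = 0.005) {
  n <- length(x)
  nr <- min(round(ramp_s * sr), n %/% 2L)
  if (nr > 0L) {
    r <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    x[seq_len(nr)] <- x[seq_len(nr)] * r
    x[n - nr + seq_len(nr)] <- x[n - nr + seq_len(nr)] * rev(r)
  }
  x
}

.tone_complex <- function(dur_s, f0, sr, amp = 0.7, nHarm = 3L) {
  t <- seq_len(round(dur_s * sr)) / sr
  x <- rowSums(sapply(seq_len(nHarm), function(h) sin(2 * pi * h * f0 * t) / h))
  .apply_ramps(amp * x / max(abs(x)), sr)
}

.noise_burst <- function(dur_s, sr, amp = 0.3) {
  n <- round(dur_s * sr)
  x <- stats::rnorm(n)
  # crude band-limit: 3-point moving average knocks down the top octave
  x <- stats::filter(x, rep(1 / 3, 3), sides = 2)
  x[is.na(x)] <- 0
  .apply_ramps(amp * x / max(abs(x)), sr)
}

.call_stack <- function(dur_s, sr, amp = 0.5, f0 = 600) {
  .tone_complex(dur_s, f0, sr, amp = amp, nHarm = 5L)
}

#' Render the synthetic ABAB tutor-song playback
#'
#' Two synthesized zebra finch syllables repeated twice: syllable A (185 ms
#' tone complex near 2456.6 Hz) and syllable B (155 ms near 1165.4 Hz), with
#' internal silent gaps of 119 ms after each A and 124 ms after each B.
#' The motif A-gap-B-gap-A-gap-B spans 1.042 s.
#'
#' @param sampleRate output rate in Hz (>= 8000).
#' @param pad_s leading/trailing silence around the motif.
#' @return list with \code{clip} (an [AudioClip-class], channel "playback")
#'   and \code{events} (ground-truth [EventTable-class] of the 4 syllables).
#' @examples
#' tut <- renderTutorAudio(40000)
#' nEvents(tut$events)  # 4 syllables
#' @export
renderTutorAudio <- function(sampleRate = 40000, pad_s = 0.050) {
  stopifnot(sampleRate >= 8000)
  sr <- sampleRate
  sylA <- .tone_complex(0.185, 2456.6, sr)
  sylB <- .tone_complex(0.155, 1165.4, sr)
  gapA <- numeric(round(0.119 * sr))
  gapB <- numeric(round(0.124 * sr))
  pad <- numeric(round(pad_s * sr))
  x <- c(pad, sylA, gapA, sylB, gapB, sylA, gapA, sylB, pad)
  durs <- c(0.185, 0.155, 0.185, 0.155)
  gaps <- c(0.119, 0.124, 0.119)
  onsets <- pad_s + cumsum(c(0, durs[-4] + gaps))
  ev <- data.frame(kind = "syllable", onset_s = onsets,
                   offset_s = onsets + durs, channel = "playback",
                   label = c("A", "B", "A", "B"), stringsAsFactors = FALSE)
  list(clip = audioClip(x, sr, "playback"),
       events = eventTable(ev, birdId = "tutor", recordingId = "tutor_abab"))
}

#' Simulate the vocal events of one session (no audio)
#'
#' Song bouts are placed by a Poisson process at \code{boutRatePerMin}; each
#' bout is a chain of at least three syllables whose durations and gaps are
#' drawn from the configured (truncated normal) distributions until the
#' target span is reached. Female call onsets follow an inhomogeneous
#' Poisson process: rate \code{callRateInSongHz(cfg)} inside bout windows
#' and \code{callRateOutSongHz} outside. Syllables are tagged channel "box",
#' calls channel "backpack".
#'
#' @param cfg a [sessionSimConfig()].
#' @return list with \code{events} (ground-truth [EventTable-class]),
#'   \code{bouts} (data.frame of true bout windows) and \code{callRate}
#'   (the in-song rate used).
#' @export
simulateSessionEvents <- function(cfg) {
  stopifnot(inherits(cfg, "SessionSimConfig"))
  set.seed(cfg$seed)
  rate_in <- callRateInSongHz(cfg)

  rtrunc <- function(n, mean, sd, lo, hi)
    pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)

  ## --- bouts and their syllables
  syl_on <- numeric(0); syl_off <- numeric(0)
  bout_on <- numeric(0); bout_off <- numeric(0)
  t <- 0
  mean_ibi <- if (cfg$boutRatePerMin > 0) 60 / cfg$boutRatePerMin else Inf
  repeat {
    if (!is.finite(mean_ibi)) break
    t <- t + stats::rexp(1, 1 / mean_ibi)
    target <- max(0.5, rtrunc(1, cfg$boutDurMean_s, cfg$boutDurSd_s, 0.5, 5))
    if (t + target > cfg$sessionDur_s) break
    pos <- t
    b_on <- numeric(0); b_off <- numeric(0)
    while ((pos - t) < target || length(b_on) < 3L) {
      d <- rtrunc(1, cfg$sylDurMean_s, cfg$sylDurSd_s, 0.03, 0.3)
      b_on <- c(b_on, pos); b_off <- c(b_off, pos + d)
      pos <- pos + d
      if ((pos - t) >= target && length(b_on) >= 3L) break
      g <- rtrunc(1, cfg$gapMean_s, cfg$gapSd_s, 0.02, 0.3)
      pos <- pos + g
    }
    syl_on <- c(syl_on, b_on); syl_off <- c(syl_off, b_off)
    bout_on <- c(bout_on, b_on[1]); bout_off <- c(bout_off, b_off[length(b_off)])
    # at least the bout-break silence before the next bout can start
    t <- b_off[length(b_off)] + 0.4
  }

  ## --- calls: inhomogeneous Poisson over song / non-song intervals
  call_on <- numeric(0)
  if (rate_in > 0 && length(bout_on)) {
    for (i in seq_along(bout_on)) {
      L <- bout_off[i] - bout_on[i]
      k <- stats::rpois(1, rate_in * L)
      if (k) call_on <- c(call_on, sort(stats::runif(k, bout_on[i], bout_off[i])))
    }
  }
  if (cfg$callRateOutSongHz > 0) {
    edges <- sort(c(0, bout_on, bout_off, cfg$sessionDur_s))
    for (i in seq_len(length(edges) - 1L)) {
      lo <- edges[i]; hi <- edges[i + 1L]
      mid <- (lo + hi) / 2
      in_song <- length(bout_on) &&
        any(mid >= bout_on & mid < bout_off)
      if (!in_song && hi > lo) {
        k <- stats::rpois(1, cfg$callRateOutSongHz * (hi - lo))
        if (k) call_on <- c(call_on, sort(stats::runif(k, lo, hi)))
      }
    }
  }
  call_on <- sort(call_on)
  call_off <- pmin(call_on + cfg$callDur_s, cfg$sessionDur_s)
  keep <- call_off > call_on
  call_on <- call_on[keep]; call_off <- call_off[keep]

  ev <- rbind(
    if (length(syl_on))
      data.frame(kind = "syllable", onset_s = syl_on, offset_s = syl_off,
                 channel = "box", label = "", stringsAsFactors = FALSE),
    if (length(call_on))
      data.frame(kind = "call", onset_s = call_on, offset_s = call_off,
                 channel = "backpack", label = "", stringsAsFactors = FALSE))
  if (is.null(ev)) ev <- data.frame()
  bouts <- data.frame(onset_s = bout_on, offset_s = bout_off,
                      duration_s = bout_off - bout_on)
  list(events = eventTable(ev, ageDph = cfg$ageDph,
                           recordingId = sprintf("sim_age%03d", cfg$ageDph)),
       bouts = bouts, callRate = rate_in)
}

#' Simulate one session and render both microphone channels
#'
#' Renders the events from [simulateSessionEvents()] as audio: juvenile
#' syllables as band-limited noise bursts, female calls as harmonic stacks,
#' 5 ms cosine ramps on every element. The box channel carries the
#' syllables at full level plus the calls; the backpack channel carries the
#' calls at full level and the juvenile sounds 20 dB down (the backpack
#' microphone predominantly captures the female). Gaussian noise at
#' \code{noiseFloor} is added to both channels.
#'
#' @param cfg a [sessionSimConfig()].
#' @param sampleRate audio rate in Hz.
#' @return list with \code{box} and \code{backpack} [AudioClip-class]s plus
#'   the \code{events}/\code{bouts}/\code{callRate} ground truth.
#' @export
simulateSession <- function(cfg, sampleRate = 40000) {
  sim <- simulateSessionEvents(cfg)
  sr <- sampleRate
  n <- ceiling(cfg$sessionDur_s * sr)
  ev <- sim$events@events
  juv <- numeric(n); fem <- numeric(n)
  set.seed(cfg$seed + 1L)
  place <- function(buf, snd, onset) {
    i0 <- floor(onset * sr) + 1L
    i1 <- min(i0 + length(snd) - 1L, n)
    len <- i1 - i0 + 1L
    if (len > 0L) buf[i0:i1] <- buf[i0:i1] + snd[seq_len(len)]
    buf
  }
  for (i in which(ev$kind == "syllable"))
    juv <- place(juv, .noise_burst(ev$offset_s[i] - ev$onset_s[i], sr),
                 ev$onset_s[i])
  for (i in which(ev$kind == "call"))
    fem <- place(fem, .call_stack(ev$offset_s[i] - ev$onset_s[i], sr),
                 ev$onset_s[i])
  bleed <- 10^(-20 / 20)   # -20 dB
  box <- juv + 0.7 * fem + stats::rnorm(n, 0, cfg$noiseFloor)
  bp <- fem + bleed * juv + stats::rnorm(n, 0, cfg$noiseFloor)
  c(list(box = audioClip(box, sr, "box"),
         backpack = audioClip(bp, sr, "backpack")), sim)
}

#' Simulate a developmental series of sessions
#'
#' One session per age, with the within-song call rate following the
#' template's linear trend \code{callBaseRateHz + callAgeSlope * (age -
#' age0)}. Session seeds are derived from the template seed so the series is
#' reproducible as a whole.
#'
#' @param cfg template [sessionSimConfig()]; its \code{callAgeSlope} is the
#'   true slope of the series.
#' @param ages strictly increasing integer vector of ages (dph).
#' @return list with \code{sessions} (per-age output of
#'   [simulateSessionEvents()]), \code{summaries} (data.frame of age, true
#'   rate, realized call ratio and counts) and \code{trueSlope}.
#' @export
simulateDevelopment <- function(cfg, ages) {
  stopifnot(inherits(cfg, "SessionSimConfig"), !is.unsorted(ages, strictly = TRUE))
  sessions <- vector("list", length(ages))
  sm <- vector("list", length(ages))
  for (i in seq_along(ages)) {
    ci <- cfg
    ci$ageDph <- as.integer(ages[i])
    ci$seed <- cfg$seed + 1000L * i
    sessions[[i]] <- simulateSessionEvents(ci)
    s <- sessions[[i]]
    ev <- s$events@events
    n_calls_in <- 0L
    if (nrow(s$bouts)) {
      con <- ev$onset_s[ev$kind == "call"]
      for (b in seq_len(nrow(s$bouts)))
        n_calls_in <- n_calls_in +
          sum(con >= s$bouts$onset_s[b] & con < s$bouts$offset_s[b])
    }
    tot <- sum(s$bouts$duration_s)
    sm[[i]] <- data.frame(
      age_dph = ages[i], true_rate_hz = s$callRate,
      n_bouts = nrow(s$bouts), total_song_dur_s = tot,
      n_calls_in_song = n_calls_in,
      call_ratio = if (tot > 0) n_calls_in / tot else NA_real_)
  }
  list(sessions = sessions, summaries = do.call(rbind, sm),
       trueSlope = cfg$callAgeSlope)
}

## ---- intracellular --------------------------------------------------------

#' Trial simulation settings for intracellular playback experiments
#'
#' Each trial is baseline + a stimulus-locked subthreshold component shared
#' across trials (the same realization every trial, carrying fraction
#' \code{rho} of the within-window subthreshold variance) + private
#' exponentially-correlated (Ornstein-Uhlenbeck) noise + spikes. Locked
#' spikes are drawn per trial as Poisson(\code{lambdaLocked}) at template
#' latencies with Gaussian jitter; background spikes are homogeneous
#' Poisson. Spike height is at least 30 mV so the 15 mV detector finds
#' every one.
#'
#' @param nTrials number of stimulus presentations.
#' @param trialDur_s trial length (s).
#' @param stimOnset_s,stimOffset_s stimulus window (s).
#' @param baselineMv resting potential (mV).
#' @param noiseSdMv marginal SD of the subthreshold fluctuations (mV).
#' @param noiseTau_s correlation time of the private noise (default 10 ms).
#' @param rho shared-variance fraction inside the stimulus window, in [0,1].
#' @param lambdaLocked expected locked spikes per trial.
#' @param nTemplateLatencies number of distinct locked latencies (default 1:
#'   one stimulus-evoked response event per presentation, as in call-evoked
#'   responses; more latencies spread the locked spikes over the window).
#' @param jitterSd_s SD of spike-time jitter around template latencies (s).
#' @param bgRateHz background Poisson spike rate (Hz).
#' @param spikeHeightMv spike peak above baseline (>= 30 mV).
#' @param spikeWidth_s spike width at base (s).
#' @param sampleRate_hz sampling rate (Hz).
#' @param seed RNG seed; also fixes the shared waveform and template
#'   latencies.
#' @return list of class "TrialSimConfig".
#' @export
trialSimConfig <- function(nTrials = 15L, trialDur_s = 1.0,
                           stimOnset_s = 0.4, stimOffset_s = 0.6,
                           baselineMv = -70, noiseSdMv = 2,
                           noiseTau_s = 0.010, rho = 0.3,
                           lambdaLocked = 0, nTemplateLatencies = 1L,
                           jitterSd_s = 0.002,
                           bgRateHz = 0, spikeHeightMv = 45,
                           spikeWidth_s = 0.0015, sampleRate_hz = 10000,
                           seed = 1L) {
  stopifnot(rho >= 0, rho <= 1, spikeHeightMv >= 30,
            stimOffset_s > stimOnset_s, stimOffset_s <= trialDur_s)
  structure(as.list(environment()), class = "TrialSimConfig")
}

## Ornstein-Uhlenbeck process with unit marginal SD (stationary AR(1))
.ou_noise <- function(n, dt, tau) {
  a <- exp(-dt / tau)
  innov <- c(stats::rnorm(1), sqrt(1 - a^2) * stats::rnorm(n - 1L))
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

## Gaussian-bump spike waveform, height h, base width w (s)
.spike_shape <- function(h, w, sr) {
  half <- max(2L, round(w * sr / 2))
  t <- (-half):half
  h * exp(-(t / (half / 2.5))^2 / 2)
}

#' Simulate an intracellular trial set with ground truth
#'
#' See [trialSimConfig()] for the generative model. The shared waveform is
#' standardized to zero mean and unit SD inside the stimulus window (and
#' tapered at its edges), so the expected zero-lag pairwise correlation of
#' the subthreshold traces inside the window equals \code{rho}.
#'
#' @param cfg a [trialSimConfig()].
#' @return list with \code{trials} (an [IntracellularTrialSet-class]),
#'   \code{spikeTimes} (list of true spike times per trial),
#'   \code{subthreshold} (list of spike-free traces) and
#'   \code{templateLatencies}.
#' @export
simulateIntracellularTrialSet <- function(cfg) {
  stopifnot(inherits(cfg, "TrialSimConfig"))
  set.seed(cfg$seed)
  sr <- cfg$sampleRate_hz
  n <- round(cfg$trialDur_s * sr)
  dt <- 1 / sr
  w0 <- floor(cfg$stimOnset_s * sr) + 1L
  w1 <- ceiling(cfg$stimOffset_s * sr)
  win <- w0:w1

  # shared stimulus-locked waveform: one fixed smooth realization,
  # standardized within the window, cosine-tapered at the edges
  shared <- numeric(n)
  s_raw <- .ou_noise(length(win), dt, cfg$noiseTau_s)
  s_std <- (s_raw - mean(s_raw)) / stats::sd(s_raw)
  taper_n <- min(round(0.005 * sr), length(win) %/% 4L)
  if (taper_n > 0L) {
    r <- 0.5 * (1 - cos(pi * seq_len(taper_n) / taper_n))
    s_std[seq_len(taper_n)] <- s_std[seq_len(taper_n)] * r
    s_std[length(s_std) - taper_n + seq_len(taper_n)] <-
      s_std[length(s_std) - taper_n + seq_len(taper_n)] * rev(r)
  }
  shared[win] <- s_std

  m_template <- max(1L, as.integer(cfg$nTemplateLatencies))
  templ <- sort(stats::runif(m_template, cfg$stimOnset_s + 0.005,
                             cfg$stimOffset_s - 0.005))

  spike_wave <- .spike_shape(cfg$spikeHeightMv, cfg$spikeWidth_s, sr)
  half <- (length(spike_wave) - 1L) %/% 2L

  tr <- vector("list", cfg$nTrials)
  sub <- vector("list", cfg$nTrials)
  spk <- vector("list", cfg$nTrials)
  for (k in seq_len(cfg$nTrials)) {
    eta <- .ou_noise(n, dt, cfg$noiseTau_s)
    v <- cfg$baselineMv + cfg$noiseSdMv *
      (sqrt(cfg$rho) * shared + sqrt(1 - cfg$rho) * eta)
    # locked spikes
    times <- numeric(0)
    if (cfg$lambdaLocked > 0) {
      kk <- stats::rpois(1, cfg$lambdaLocked)
      if (kk) {
        lat <- sample(templ, kk, replace = TRUE) +
          stats::rnorm(kk, 0, cfg$jitterSd_s)
        times <- c(times, pmin(pmax(lat, cfg$stimOnset_s),
                               cfg$stimOffset_s - dt))
      }
    }
    if (cfg$bgRateHz > 0) {
      nb <- stats::rpois(1, cfg$bgRateHz * cfg$trialDur_s)
      if (nb) times <- c(times, stats::runif(nb, 0.01, cfg$trialDur_s - 0.01))
    }
    times <- sort(times)
    # enforce a 2 ms minimum separation so spikes are individually countable
    if (length(times) > 1L)
      times <- times[c(TRUE, diff(times) > 0.002)]
    sub[[k]] <- v
    if (length(times)) {
      for (tt in times) {
        c0 <- round(tt * sr) + 1L
        idx <- (c0 - half):(c0 + half)
        ok <- idx >= 1L & idx <= n
        v[idx[ok]] <- v[idx[ok]] + spike_wave[ok]
      }
    }
    tr[[k]] <- v
    spk[[k]] <- times
  }
  list(
    trials = intracellularTrialSet(
      tr, sr, cfg$stimOnset_s, cfg$stimOffset_s,
      stimKind = "playback_call", baselineMv = cfg$baselineMv),
    spikeTimes = spk, subthreshold = sub, templateLatencies = templ)
}

#' Simulate stereotyped singing renditions with call perturbations
#'
#' Unperturbed renditions share a stereotyped motif membrane-potential
#' pattern (a fixed smooth waveform plus optional template spikes) with
#' private noise; perturbed renditions additionally receive a configured
#' subthreshold deflection and/or extra locked spikes inside the call
#' window plus the 50 ms response pad.
#'
#' @param nRenditions total motif renditions.
#' @param perturbedIdx indices of the perturbed renditions.
#' @param callOnset_s,callOffset_s female-call window within the motif (s).
#' @param motifDur_s motif duration (s).
#' @param deflectionMv subthreshold deflection added in the call epoch (mV).
#' @param extraSpikes integer count of extra locked spikes per perturbed
#'   rendition.
#' @param templateSpikes_s stereotyped spike latencies present in every
#'   rendition.
#' @param noiseSdMv private noise SD (mV).
#' @param responsePad_s pad after call offset included in the epoch (s).
#' @param baselineMv,spikeHeightMv,sampleRate_hz,seed as in
#'   [trialSimConfig()].
#' @return list with \code{trials} ([IntracellularTrialSet-class], condition
#'   "singing", stimulus window = call epoch incl. pad), \code{perturbedIdx},
#'   \code{spikeTimes} and \code{subthreshold} ground truth.
#' @export
simulateSingingPerturbation <- function(nRenditions = 10L,
                                        perturbedIdx = integer(0),
                                        callOnset_s = 0.4, callOffset_s = 0.5,
                                        motifDur_s = 1.0, deflectionMv = 0,
                                        extraSpikes = 0L,
                                        templateSpikes_s = c(0.15, 0.7),
                                        noiseSdMv = 1, responsePad_s = 0.050,
                                        baselineMv = -70, spikeHeightMv = 45,
                                        sampleRate_hz = 10000, seed = 1L) {
  stopifnot(all(perturbedIdx %in% seq_len(nRenditions)))
  set.seed(seed)
  sr <- sampleRate_hz
  n <- round(motifDur_s * sr)
  dt <- 1 / sr
  epoch_on <- callOnset_s
  epoch_off <- min(callOffset_s + responsePad_s, motifDur_s)

  motif <- 4 * .ou_noise(n, dt, 0.030)        # stereotyped Vm pattern, ~4 mV SD
  spike_wave <- .spike_shape(spikeHeightMv, 0.0015, sr)
  half <- (length(spike_wave) - 1L) %/% 2L
  e0 <- floor(epoch_on * sr) + 1L
  e1 <- ceiling(epoch_off * sr)
  defl <- numeric(n)
  defl[e0:e1] <- deflectionMv
  extra_lat <- if (extraSpikes > 0L)
    seq(epoch_on + 0.01, epoch_off - 0.01, length.out = extraSpikes) else numeric(0)

  tr <- vector("list", nRenditions)
  sub <- vector("list", nRenditions)
  spk <- vector("list", nRenditions)
  for (k in seq_len(nRenditions)) {
    perturbed <- k %in% perturbedIdx
    v <- baselineMv + motif + noiseSdMv * .ou_noise(n, dt, 0.010)
    if (perturbed) v <- v + defl
    times <- templateSpikes_s
    if (perturbed && length(extra_lat)) times <- sort(c(times, extra_lat))
    sub[[k]] <- v
    for (tt in times) {
      c0 <- round(tt * sr) + 1L
      idx <- (c0 - half):(c0 + half)
      ok <- idx >= 1L & idx <= n
      v[idx[ok]] <- v[idx[ok]] + spike_wave[ok]
    }
    tr[[k]] <- v
    spk[[k]] <- times
  }
  list(
    trials = intracellularTrialSet(
      tr, sr, epoch_on, epoch_off, stimKind = "playback_call",
      baselineMv = baselineMv, condition = "singing"),
    perturbedIdx = perturbedIdx, spikeTimes = spk, subthreshold = sub,
    epoch = c(epoch_on, epoch_off))
}

## ---- extracellular population --------------------------------------------

#' Simulate a sorted extracellular population with a playback schedule
#'
#' Stimuli are presented every \code{period_s} for \code{nStimuli} trials
#' (the default schedule: every 1.5 s for 60 trials). Projection-class units
#' get spontaneous rates at or below 2 Hz, interneuron-class units above
#' 2 Hz. During each analysis window (stimulus + 50 ms) the rate is
#' multiplied by \code{responseGain}. Quality metrics are drawn in the
#' passing range except for units listed in \code{failUnits}, which fail the
#' named metric.
#'
#' @param nUnits number of units.
#' @param propProjection fraction of projection-class units.
#' @param projRateRange,interRateRange spontaneous-rate ranges (Hz) for the
#'   two classes.
#' @param responseGain multiplicative rate increase inside analysis windows.
#' @param nStimuli,period_s,stimDur_s playback schedule.
#' @param responsePad_s pad after stimulus offset (s).
#' @param failUnits named character vector, e.g. \code{c(u3 = "isi")}, of
#'   units that must fail one QC metric ("isi", "amplitude", "presence").
#' @param seed RNG seed.
#' @return list with \code{units} (list of [UnitRecord-class]),
#'   \code{schedule} ([EventTable-class] of playback_call events),
#'   \code{classes} (true class per unit) and \code{totalDur_s}.
#' @export
simulatePopulationUnits <- function(nUnits = 20L, propProjection = 0.7,
                                    projRateRange = c(0.2, 2),
                                    interRateRange = c(2.5, 12),
                                    responseGain = 1, nStimuli = 60L,
                                    period_s = 1.5, stimDur_s = 0.15,
                                    responsePad_s = 0.050,
                                    failUnits = character(0), seed = 1L) {
  stopifnot(propProjection >= 0, propProjection <= 1, nStimuli >= 1)
  set.seed(seed)
  stim_on <- 1 + period_s * (seq_len(nStimuli) - 1L)
  stim_off <- stim_on + stimDur_s
  total <- stim_off[nStimuli] + 1
  an_on <- stim_on
  an_off <- stim_off + responsePad_s

  n_proj <- round(propProjection * nUnits)
  classes <- c(rep("projection", n_proj),
               rep("interneuron", nUnits - n_proj))
  units <- vector("list", nUnits)
  for (u in seq_len(nUnits)) {
    uid <- sprintf("u%d", u)
    base <- if (classes[u] == "projection")
      stats::runif(1, projRateRange[1], projRateRange[2])
    else stats::runif(1, interRateRange[1], interRateRange[2])
    # thinning from the peak rate gives the inhomogeneous Poisson train
    peak <- base * max(1, responseGain)
    n_cand <- stats::rpois(1, peak * total)
    cand <- sort(stats::runif(n_cand, 0, total))
    in_win <- vapply(cand, function(s) any(s >= an_on & s < an_off), logical(1))
    rate <- ifelse(in_win, base * responseGain, base)
    spikes <- cand[stats::runif(n_cand) < rate / peak]

    qc <- list(isi = stats::runif(1, 0, 0.2),
               amplitude = stats::runif(1, 0, 0.25),
               presence = stats::runif(1, 0.92, 1))
    if (uid %in% names(failUnits)) {
      fail <- failUnits[[uid]]
      if (fail == "isi") qc$isi <- stats::runif(1, 0.3, 0.6)
      else if (fail == "amplitude") qc$amplitude <- stats::runif(1, 0.35, 0.6)
      else if (fail == "presence") qc$presence <- stats::runif(1, 0.5, 0.85)
      else stop("unknown QC metric in failUnits: ", fail)
    }
    units[[u]] <- unitRecord(uid, spikes, birdId = "simbird",
                             isiViolation = qc$isi,
                             amplitudeCutoff = qc$amplitude,
                             presenceRatio = qc$presence)
  }
  sched <- eventTable(data.frame(
    kind = "playback_call", onset_s = stim_on, offset_s = stim_off,
    channel = "playback", label = "", stringsAsFactors = FALSE),
    recordingId = "sim_playback")
  list(units = units, schedule = sched, classes = classes,
       totalDur_s = total)
}
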