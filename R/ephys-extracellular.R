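## Extracellular unit QC, projection/interneuron classification and
## population playback-response summaries.

#' Quality-control filter for sorted units
#'
#' A unit is kept when its inter-spike-interval violation index is at most
#' \code{qc_isi_max} (0.25), its amplitude-cutoff estimate is below
#' \code{qc_amp_cutoff_max} (0.3) and its presence ratio is above
#' \code{qc_presence_min} (0.90). Excluding high-ISI-violation units is the
#' standard reading of the criterion and the default; setting
#' \code{literalIsi = TRUE} instead keeps units with an index above the
#' cutoff (the reverse direction), with a warning.
#'
#' Units missing any metric are excluded with reason "missing_metric".
#' Filtering is a pure function of the metrics: the kept set never depends
#' on unit order.
#'
#' @param units list of [UnitRecord-class] objects.
#' @param cfg a [runConfig()].
#' @param literalIsi reverse the ISI-violation direction (see above).
#' @return list with \code{kept} and \code{excluded} (lists of UnitRecord)
#'   and \code{reasons} (named character: failing metrics per excluded
#'   unit).
#' @export
applyUnitQc <- function(units, cfg = runConfig(), literalIsi = FALSE) {
  if (literalIsi)
    warning("literal ISI-violation reading selected: keeping units with ",
            "violation index > ", cfg$qc_isi_max)
  reasons <- character(0)
  keep <- logical(length(units))
  for (i in seq_along(units)) {
    u <- units[[i]]
    m <- c(isi = u@isiViolation, amplitude = u@amplitudeCutoff,
           presence = u@presenceRatio)
    if (anyNA(m)) {
      reasons[u@unitId] <- "missing_metric"
      next
    }
    fail <- character(0)
    isi_ok <- if (literalIsi) m["isi"] > cfg$qc_isi_max
              else m["isi"] <= cfg$qc_isi_max
    if (!isi_ok) fail <- c(fail, "isi")
    if (!(m["amplitude"] < cfg$qc_amp_cutoff_max)) fail <- c(fail, "amplitude")
    if (!(m["presence"] > cfg$qc_presence_min)) fail <- c(fail, "presence")
    if (length(fail)) reasons[u@unitId] <- paste(fail, collapse = ",")
    else keep[i] <- TRUE
  }
  list(kept = units[keep], excluded = units[!keep], reasons = reasons)
}

#' Classify a unit as projection neuron or interneuron
#'
#' Spontaneous firing rate at or below 2 Hz marks an HVC projection cell;
#' above 2 Hz an interneuron.
#'
#' @param spontaneousRateHz non-negative spontaneous rate (Hz).
#' @param boundaryHz class boundary (default 2 Hz).
#' @return character vector, "projection" or "interneuron".
#' @export
classifyUnitType <- function(spontaneousRateHz, boundaryHz = 2.0) {
  stopifnot(all(spontaneousRateHz >= 0))
  ifelse(spontaneousRateHz <= boundaryHz, "projection", "interneuron")
}

#' Spontaneous rate over inter-stimulus silence
#'
#' Firing rate computed with all analysis windows (stimulus + pad) excised
#' from both the spike train and the elapsed time.
#'
#' @param spikes spike times (s).
#' @param schedule [EventTable-class] of stimulus events.
#' @param totalDur_s total recording duration (s).
#' @param responsePad_s pad after each stimulus offset (s).
#' @return rate in Hz.
#' @export
spontaneousRate <- function(spikes, schedule, totalDur_s,
                            responsePad_s = 0.050) {
  ev <- schedule@events
  on <- ev$onset_s; off <- ev$offset_s + responsePad_s
  in_stim <- rep(FALSE, length(spikes))
  for (i in seq_along(on))
    in_stim <- in_stim | (spikes >= on[i] & spikes < off[i])
  silent_time <- totalDur_s - sum(off - on)
  if (silent_time <= 0) return(NA_real_)
  sum(!in_stim) / silent_time
}

#' Peri-stimulus time histogram
#'
#' Bins spike latencies relative to each stimulus onset over the window.
#' Total counts are conserved exactly: the bin counts sum to the number of
#' in-window spikes. Rates are counts / (trials x bin width).
#'
#' @param spikeTrains list of per-trial spike times, already aligned so
#'   that 0 is the stimulus onset (use [alignToStimuli()] for raw trains).
#' @param window \code{c(start, end)} relative to stimulus onset (s).
#' @param bin_s bin width (s).
#' @return list with \code{breaks}, \code{counts}, \code{rate_hz},
#'   \code{n_trials}.
#' @export
psth <- function(spikeTrains, window, bin_s = 0.010) {
  stopifnot(bin_s > 0, length(window) == 2L, window[2] > window[1])
  nb <- ceiling((window[2] - window[1]) / bin_s - 1e-9)
  breaks <- window[1] + bin_s * (0:nb)
  all_s <- unlist(spikeTrains, use.names = FALSE)
  all_s <- all_s[all_s >= window[1] & all_s < window[2]]
  bin <- pmin(floor((all_s - window[1]) / bin_s) + 1L, nb)
  counts <- tabulate(bin, nbins = nb)
  n_tr <- length(spikeTrains)
  list(breaks = breaks, counts = counts,
       rate_hz = counts / (n_tr * bin_s), n_trials = n_tr)
}

#' Slice a continuous spike train into stimulus-aligned trials
#'
#' @param spikes spike times (s) on the recording clock.
#' @param schedule [EventTable-class] of stimulus events.
#' @param pre_s,post_s window before onset / after onset per trial (s).
#' @return list of per-trial spike-time vectors relative to stimulus onset.
#' @export
alignToStimuli <- function(spikes, schedule, pre_s = 0.5, post_s = 0.5) {
  ev <- schedule@events
  lapply(seq_len(nrow(ev)), function(i) {
    on <- ev$onset_s[i]
    s <- spikes[spikes >= on - pre_s & spikes < on + post_s]
    s - on
  })
}

#' Population playback-response summary
#'
#' Applies QC, classifies every kept unit by spontaneous rate, and computes
#' per-unit paired statistics across the stimulus schedule: mean firing
#' rate in the analysis window (stimulus + 50 ms) vs the matched preceding
#' silence window, and the spiking precision in both. Precision is absent
#' (NA) for units with spikes in fewer than two trials.
#'
#' @param units list of [UnitRecord-class].
#' @param schedule [EventTable-class] of stimulus presentations.
#' @param totalDur_s recording duration (s).
#' @param cfg a [runConfig()].
#' @param precisionPerm permutations for the precision test (default from
#'   cfg).
#' @return data.frame, one row per QC-passing unit: class, spontaneous
#'   rate, rates and precision scores in call vs silence.
#' @export
populationResponseSummary <- function(units, schedule, totalDur_s,
                                      cfg = runConfig(),
                                      precisionPerm = cfg$n_permutations) {
  qc <- applyUnitQc(units, cfg)
  ev <- schedule@events
  if (!nrow(ev)) stop("empty stimulus schedule")
  stim_dur <- ev$offset_s[1] - ev$onset_s[1]
  rows <- vector("list", length(qc$kept))
  for (i in seq_along(qc$kept)) {
    u <- qc$kept[[i]]
    spont <- spontaneousRate(u@spikeTimes, schedule, totalDur_s,
                             cfg$response_pad_s)
    klass <- classifyUnitType(spont, cfg$projection_rate_hz)
    fr_an <- numeric(nrow(ev)); fr_si <- numeric(nrow(ev))
    an_trains <- vector("list", nrow(ev))
    si_trains <- vector("list", nrow(ev))
    for (t in seq_len(nrow(ev))) {
      win <- stimulusWindows(ev$onset_s[t], ev$offset_s[t],
                             cfg$response_pad_s, cfg$silence_gap_s)
      fr_an[t] <- firingRate(u@spikeTimes, win$analysis)
      fr_si[t] <- firingRate(u@spikeTimes, win$silence)
      an_trains[[t]] <- u@spikeTimes[u@spikeTimes >= win$analysis[1] &
                                     u@spikeTimes < win$analysis[2]] -
                        win$analysis[1]
      si_trains[[t]] <- u@spikeTimes[u@spikeTimes >= win$silence[1] &
                                     u@spikeTimes < win$silence[2]] -
                        win$silence[1]
    }
    wlen <- stim_dur + cfg$response_pad_s
    pr_an <- spikingPrecision(an_trains, c(0, wlen), nPerm = precisionPerm,
                              alpha = cfg$alpha, seed = cfg$seed + i)
    pr_si <- spikingPrecision(si_trains, c(0, wlen), nPerm = precisionPerm,
                              alpha = cfg$alpha, seed = cfg$seed + 10000L + i)
    rows[[i]] <- data.frame(
      unit_id = u@unitId, bird_id = u@birdId, unit_class = klass,
      spontaneous_rate_hz = spont,
      firing_rate_call_hz = mean(fr_an),
      firing_rate_silence_hz = mean(fr_si),
      precision_call = pr_an$score, precision_silence = pr_si$score,
      responsive_call = pr_an$responsive,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  out
}
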