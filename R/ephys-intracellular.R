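## Intracellular statistics: spike detection at baseline + 15 mV, analysis /
## silence windows around a call, firing rate, permutation spiking
## precision, spike clipping, zero-lag subthreshold correlation, delta
## subthreshold, and perturbation responsiveness.

#' Detect spikes by threshold crossing
#'
#' One spike per upward crossing of \code{baseline + threshold} (15 mV by
#' default), timestamped at the crossing sample. Crossings closer than the
#' refractory merge window are collapsed into the first.
#'
#' @param vm numeric membrane-potential trace (mV).
#' @param sampleRate sampling rate (Hz).
#' @param baselineMv baseline membrane potential (mV).
#' @param thresholdMv detection threshold above baseline (mV).
#' @param refractory_s crossings closer than this are merged (default 1 ms).
#' @return numeric vector of spike times in seconds (0-based sample
#'   convention: a crossing at sample i has time (i-1)/rate).
#' @export
detectSpikes <- function(vm, sampleRate, baselineMv, thresholdMv = 15,
                         refractory_s = 0.001) {
  stopifnot(all(is.finite(vm)), sampleRate > 0)
  level <- baselineMv + thresholdMv
  above <- vm >= level
  cross <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(cross)) return(numeric(0))
  t <- (cross - 1L) / sampleRate
  keep <- c(TRUE, diff(t) >= refractory_s)
  t[keep]
}

#' Analysis and silence windows around a call stimulus
#'
#' The analysis window runs from call onset to call offset plus the 50 ms
#' response pad. The silence window has the same length and ends 50 ms
#' before call onset, so the two never overlap.
#'
#' @param callOnset_s,callOffset_s the call event \code{[on, off)} (s).
#' @param responsePad_s pad after the call offset (s).
#' @param silenceGap_s gap between silence-window end and call onset (s).
#' @param traceStart_s earliest admissible time; the silence window must not
#'   start before it.
#' @return list with \code{analysis} and \code{silence}, each
#'   \code{c(onset, offset)} in seconds.
#' @examples
#' stimulusWindows(1.00, 1.15)  # analysis [1.00, 1.20), silence [0.75, 0.95)
#' @export
stimulusWindows <- function(callOnset_s, callOffset_s,
                            responsePad_s = 0.050, silenceGap_s = 0.050,
                            traceStart_s = 0) {
  stopifnot(callOffset_s > callOnset_s)
  L <- callOffset_s - callOnset_s + responsePad_s
  analysis <- c(callOnset_s, callOffset_s + responsePad_s)
  silence <- c(callOnset_s - silenceGap_s - L, callOnset_s - silenceGap_s)
  if (silence[1] < traceStart_s - 1e-12)
    stop(sprintf("silence window [%g, %g) starts before trace start %g",
                 silence[1], silence[2], traceStart_s))
  list(analysis = analysis, silence = silence)
}

#' Firing rate in a window
#'
#' Spike count inside the half-open window divided by the window duration.
#'
#' @param spikes numeric spike times (s).
#' @param window \code{c(onset, offset)} in seconds.
#' @return rate in Hz.
#' @export
firingRate <- function(spikes, window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  sum(spikes >= window[1] & spikes < window[2]) / (window[2] - window[1])
}

#' Mean firing rate over trials
#'
#' Per-cell value: the mean over trials of the per-trial [firingRate()].
#'
#' @param spikeTrains list of spike-time vectors, one per trial.
#' @param window \code{c(onset, offset)} in seconds (shared), or a 2-column
#'   matrix of per-trial windows.
#' @return mean rate in Hz.
#' @export
meanFiringRate <- function(spikeTrains, window) {
  if (is.matrix(window)) {
    mean(vapply(seq_along(spikeTrains),
                function(i) firingRate(spikeTrains[[i]], window[i, ]),
                numeric(1)))
  } else {
    mean(vapply(spikeTrains, firingRate, numeric(1), window = window))
  }
}

#' Spiking precision: permutation test for stimulus-locked timing
#'
#' The observed statistic is the mean absolute latency difference between
#' all pairs of spikes from distinct trials within the window. The null
#' distribution is built by shuffling spikes across trials
#' \code{nPerm} times while preserving the statistical distribution of
#' their occurrence: each trial's spike train gets an independent uniform
#' circular shift within the window (per-trial counts and inter-spike
#' structure are preserved; alignment to the stimulus is destroyed). An
#' alternative null that resamples each trial's inter-spike intervals is
#' available via \code{nullMethod = "isi"}.
#'
#' The precision score is reported as a z-score of the null mean against
#' the observed value, \code{(mean(null) - D_obs) / sd(null)}: around 0
#' under the null and positive for precisely locked spiking. A cell is
#' responsive when the observed mean latency difference falls outside 95\%
#' of the shuffled distribution; the default criterion is one-sided (below
#' the alpha quantile of the null, i.e. more precise than chance).
#'
#' At least two trials containing spikes are required; otherwise the result
#' is absent (all NA, not zero).
#'
#' @param spikeTrains list of spike-time vectors, one per trial (s).
#' @param window \code{c(onset, offset)} (s); only spikes inside it enter.
#' @param nPerm number of shuffles (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed for the shuffles.
#' @param nullMethod "shift" (circular shifts, default) or "isi".
#' @param twoSided use a two-sided criterion (alpha split across tails).
#' @return list with \code{D_obs}, \code{null} (vector of shuffled means),
#'   \code{score}, \code{responsive}, \code{n_spikes},
#'   \code{n_trials_with_spikes}.
#' @export
spikingPrecision <- function(spikeTrains, window, nPerm = 1000L,
                             alpha = 0.05, seed = NULL,
                             nullMethod = c("shift", "isi"),
                             twoSided = FALSE) {
  nullMethod <- match.arg(nullMethod)
  stopifnot(length(window) == 2L, window[2] > window[1])
  if (!is.null(seed)) set.seed(seed)
  absent <- list(D_obs = NA_real_, null = numeric(0), score = NA_real_,
                 responsive = NA, n_spikes = 0L, n_trials_with_spikes = 0L)

  w0 <- window[1]; L <- window[2] - window[1]
  trains <- lapply(spikeTrains, function(s) s[s >= window[1] & s < window[2]])
  nper <- lengths(trains)
  if (sum(nper > 0L) < 2L) return(absent)

  times <- unlist(trains, use.names = FALSE)
  trial <- rep(seq_along(trains), nper)
  ut <- upper.tri(matrix(0, length(times), length(times)))
  cross <- ut & outer(trial, trial, "!=")
  if (!any(cross)) return(absent)
  pair_i <- row(cross)[cross]
  pair_j <- col(cross)[cross]
  D_obs <- mean(abs(times[pair_i] - times[pair_j]))

  # vectorized null: one (n_spikes x nPerm) matrix of shuffled times
  rel <- times - w0
  if (nullMethod == "shift") {
    shifts <- matrix(stats::runif(length(trains) * nPerm, 0, L),
                     nrow = length(trains))
    shifted <- (rel + shifts[trial, , drop = FALSE]) %% L
  } else {
    shifted <- matrix(0, length(times), nPerm)
    for (p in seq_len(nPerm)) {
      col_p <- numeric(length(times))
      for (tr in unique(trial)) {
        idx <- which(trial == tr)
        k <- length(idx)
        # resample the gap structure: permute intervals incl. the leading gap
        s <- sort(rel[idx])
        iv <- diff(c(0, s, L))
        iv <- sample(iv)
        col_p[idx] <- cumsum(iv[-length(iv)])
      }
      shifted[, p] <- col_p
    }
  }
  null <- colMeans(abs(shifted[pair_i, , drop = FALSE] -
                       shifted[pair_j, , drop = FALSE]))
  score <- (mean(null) - D_obs) / stats::sd(null)
  if (twoSided) {
    lo <- stats::quantile(null, alpha / 2, names = FALSE)
    hi <- stats::quantile(null, 1 - alpha / 2, names = FALSE)
    responsive <- D_obs < lo || D_obs > hi
  } else {
    responsive <- D_obs < stats::quantile(null, alpha, names = FALSE)
  }
  list(D_obs = D_obs, null = null, score = score, responsive = responsive,
       n_spikes = length(times), n_trials_with_spikes = sum(nper > 0L))
}

#' Remove spikes from a membrane-potential trace
#'
#' For each detected spike the samples from the last sub-threshold-level
#' sample before the upward crossing to the first sub-threshold-level sample
#' after it are replaced by linear interpolation between those two anchor
#' samples. Overlapping cut segments are merged. A spike cut reaching a
#' trace boundary is interpolated flat from the available anchor and
#' flagged.
#'
#' @param vm numeric Vm trace (mV).
#' @param sampleRate sampling rate (Hz).
#' @param spikes spike times from [detectSpikes()] on the same trace.
#' @param baselineMv,thresholdMv the detection level \code{baseline +
#'   threshold}.
#' @return list with \code{vm} (spike-free trace) and
#'   \code{boundaryFlagged} (TRUE when a cut touched a trace edge) and
#'   \code{cutSegments} (2-column matrix of sample index ranges replaced).
#' @export
extractSubthreshold <- function(vm, sampleRate, spikes, baselineMv,
                                thresholdMv = 15) {
  if (!length(spikes))
    return(list(vm = vm, boundaryFlagged = FALSE,
                cutSegments = matrix(numeric(0), ncol = 2)))
  level <- baselineMv + thresholdMv
  n <- length(vm)
  below <- vm < level
  seg <- matrix(NA_integer_, nrow = length(spikes), ncol = 2)
  flagged <- FALSE
  for (k in seq_along(spikes)) {
    ci <- round(spikes[k] * sampleRate) + 1L   # crossing sample
    ci <- min(max(ci, 1L), n)
    lo <- ci - 1L
    while (lo >= 1L && !below[lo]) lo <- lo - 1L
    hi <- ci
    while (hi <= n && !below[hi]) hi <- hi + 1L
    if (lo < 1L || hi > n) flagged <- TRUE
    seg[k, ] <- c(max(lo, 1L), min(hi, n))
  }
  # merge overlapping segments
  seg <- seg[order(seg[, 1]), , drop = FALSE]
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1L) {
    for (k in 2:nrow(seg)) {
      if (seg[k, 1] <= merged[nrow(merged), 2]) {
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], seg[k, 2])
      } else merged <- rbind(merged, seg[k, ])
    }
  }
  out <- vm
  for (k in seq_len(nrow(merged))) {
    a <- merged[k, 1]; b <- merged[k, 2]
    va <- if (below[a]) vm[a] else if (below[b]) vm[b] else baselineMv
    vb <- if (below[b]) vm[b] else va
    idx <- a:b
    out[idx] <- va + (vb - va) * (idx - a) / max(b - a, 1L)
  }
  list(vm = out, boundaryFlagged = flagged, cutSegments = merged)
}

#' Spike-free traces for every trial of a set
#'
#' Convenience wrapper: detect spikes at baseline + 15 mV on each trial and
#' clip them out with [extractSubthreshold()].
#'
#' @param set an [IntracellularTrialSet-class].
#' @param thresholdMv detection threshold above baseline (mV).
#' @return list with \code{subthreshold} (list of traces) and
#'   \code{spikeTimes} (list of per-trial spike times).
#' @export
subthresholdTraces <- function(set, thresholdMv = 15) {
  stopifnot(is(set, "IntracellularTrialSet"))
  sub <- vector("list", nTrials(set))
  spk <- vector("list", nTrials(set))
  for (k in seq_len(nTrials(set))) {
    v <- set@traces[[k]]
    s <- detectSpikes(v, set@sampleRate, set@baselineMv, thresholdMv)
    sub[[k]] <- extractSubthreshold(v, set@sampleRate, s, set@baselineMv,
                                    thresholdMv)$vm
    spk[[k]] <- s
  }
  list(subthreshold = sub, spikeTimes = spk)
}

#' Mean pairwise zero-lag correlation of subthreshold traces
#'
#' Pearson correlation at lag 0 within the window for every unordered pair
#' of trials; the per-cell value is the mean over pairs. Pairs containing a
#' zero-variance trace inside the window are skipped and counted in
#' \code{n_skipped}. Also applicable across song-motif renditions.
#'
#' @param subTraces list of spike-free Vm traces (equal sampling).
#' @param sampleRate sampling rate (Hz).
#' @param window \code{c(onset, offset)} in seconds.
#' @return list with \code{mean_r}, \code{pair_r} (per-pair values) and
#'   \code{n_skipped}.
#' @export
subthresholdCorrelation <- function(subTraces, sampleRate, window) {
  stopifnot(length(subTraces) >= 2L, length(window) == 2L)
  i0 <- floor(window[1] * sampleRate) + 1L
  i1 <- ceiling(window[2] * sampleRate)
  seg <- vapply(subTraces, function(v) v[i0:i1], numeric(i1 - i0 + 1L))
  sds <- apply(seg, 2, stats::sd)
  ok <- which(sds > 0)
  n_skip <- 0L
  r <- numeric(0)
  if (length(ok) >= 2L) {
    cm <- stats::cor(seg[, ok, drop = FALSE])
    r <- cm[upper.tri(cm)]
  }
  n_tot_pairs <- choose(length(subTraces), 2)
  n_skip <- n_tot_pairs - choose(length(ok), 2)
  list(mean_r = if (length(r)) mean(r) else NA_real_, pair_r = r,
       n_skipped = as.integer(n_skip))
}

#' Delta subthreshold: analysis minus silence mean Vm
#'
#' Per trial, the mean subthreshold membrane potential in the analysis
#' window minus the mean in the silence window; the per-cell value is the
#' mean over trials.
#'
#' @param subTraces list of spike-free Vm traces.
#' @param sampleRate sampling rate (Hz).
#' @param analysisWindow,silenceWindow \code{c(onset, offset)} pairs from
#'   [stimulusWindows()].
#' @return list with \code{delta_mV} (per-cell mean) and \code{per_trial}.
#' @export
deltaSubthreshold <- function(subTraces, sampleRate, analysisWindow,
                              silenceWindow) {
  win_mean <- function(v, w) {
    i0 <- floor(w[1] * sampleRate) + 1L
    i1 <- ceiling(w[2] * sampleRate)
    mean(v[i0:i1])
  }
  per <- vapply(subTraces, function(v)
    win_mean(v, analysisWindow) - win_mean(v, silenceWindow), numeric(1))
  list(delta_mV = mean(per), per_trial = per)
}

#' Spike-count responsiveness to call perturbations during singing
#'
#' For each perturbed rendition, the instance delta is the spike count in
#' the call epoch (call window + 50 ms pad) minus the mean count in the
#' same epoch across unperturbed renditions. The control distribution is
#' built leave-one-out over the unperturbed renditions (each one compared
#' with the mean of the others), and the confidence interval is control
#' mean +/- 1.96 control SD. Instances outside the interval are flagged.
#'
#' @param perturbedTrains list of spike-time vectors for perturbed
#'   renditions.
#' @param unperturbedTrains list of spike-time vectors for unperturbed
#'   renditions (at least 2).
#' @param epoch \code{c(onset, offset)} of the call epoch incl. pad (s).
#' @param ciZ CI half-width in control SDs (default 1.96).
#' @return list with \code{delta} (per perturbed instance),
#'   \code{controlDelta}, \code{ci} \code{c(lo, hi)} and \code{flagged}.
#' @export
perturbationSpikeDelta <- function(perturbedTrains, unperturbedTrains,
                                   epoch, ciZ = 1.96) {
  stopifnot(length(unperturbedTrains) >= 2L, length(epoch) == 2L,
            epoch[2] > epoch[1])
  count <- function(s) sum(s >= epoch[1] & s < epoch[2])
  u <- vapply(unperturbedTrains, count, numeric(1))
  p <- vapply(perturbedTrains, count, numeric(1))
  delta <- p - mean(u)
  nU <- length(u)
  controlDelta <- vapply(seq_len(nU),
                         function(k) u[k] - mean(u[-k]), numeric(1))
  m <- mean(controlDelta)
  s <- stats::sd(controlDelta)
  ci <- c(m - ciZ * s, m + ciZ * s)
  flagged <- delta < ci[1] | delta > ci[2]
  list(delta = delta, controlDelta = controlDelta, ci = ci,
       flagged = flagged)
}

#' Flag subthreshold perturbation responses against an adult reference
#'
#' An instance is flagged when the absolute subthreshold change exceeds the
#' maximum absolute delta subthreshold observed in adults during female
#' calls while singing (a reference value that must be supplied from the
#' adult dataset; equality is not flagged).
#'
#' @param deltaMv numeric per-instance delta subthreshold values (mV).
#' @param adultMaxAbsMv positive reference threshold (mV); required.
#' @return logical vector of flags.
#' @export
perturbationSubthresholdFlag <- function(deltaMv, adultMaxAbsMv) {
  if (missing(adultMaxAbsMv) || is.null(adultMaxAbsMv) ||
      !is.finite(adultMaxAbsMv) || adultMaxAbsMv <= 0)
    stop("adultMaxAbsMv must be supplied as a positive reference value ",
         "(maximum |delta subthreshold| from the adult dataset)")
  abs(deltaMv) > adultMaxAbsMv
}

#' Per-cell intracellular summary
#'
#' Runs the full intracellular pipeline on a trial set: spike detection,
#' analysis/silence windows from the per-trial stimulus annotations, firing
#' rates, spiking precision (analysis window and silence baseline),
#' subthreshold correlation and delta subthreshold.
#'
#' @param set an [IntracellularTrialSet-class].
#' @param cfg a [runConfig()].
#' @return one-row data.frame of per-cell statistics.
#' @export
summarizeIntracellular <- function(set, cfg = runConfig()) {
  stopifnot(is(set, "IntracellularTrialSet"))
  st <- subthresholdTraces(set, cfg$spike_threshold_mV)
  win <- stimulusWindows(set@stimOnset[1], set@stimOffset[1],
                         cfg$response_pad_s, cfg$silence_gap_s)
  fr_an <- meanFiringRate(st$spikeTimes, win$analysis)
  fr_si <- meanFiringRate(st$spikeTimes, win$silence)
  prec_an <- spikingPrecision(st$spikeTimes, win$analysis,
                              nPerm = cfg$n_permutations, alpha = cfg$alpha,
                              seed = cfg$seed)
  prec_si <- spikingPrecision(st$spikeTimes, win$silence,
                              nPerm = cfg$n_permutations, alpha = cfg$alpha,
                              seed = cfg$seed + 1L)
  sc <- subthresholdCorrelation(st$subthreshold, set@sampleRate,
                                win$analysis)
  ds <- deltaSubthreshold(st$subthreshold, set@sampleRate,
                          win$analysis, win$silence)
  data.frame(
    cell_id = set@cellId, bird_id = set@birdId, age_dph = set@ageDph,
    n_trials = nTrials(set),
    firing_rate_call_hz = fr_an, firing_rate_silence_hz = fr_si,
    precision_call = prec_an$score, precision_silence = prec_si$score,
    responsive_call = prec_an$responsive,
    subthreshold_corr = sc$mean_r, delta_subthreshold_mV = ds$delta_mV,
    stringsAsFactors = FALSE)
}
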