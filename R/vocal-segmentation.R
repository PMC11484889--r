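#' Segmentation parameters
#'
#' Constants for envelope-based syllable segmentation. The envelope is a
#' moving RMS of the waveform; syllables are maximal runs where the envelope
#' stays at or above the threshold, merged across sub-threshold gaps shorter
#' than \code{minGap_s} and discarded below \code{minDur_s}.
#'
#' The default threshold is adaptive: 6 times the 5th percentile of the
#' envelope (a noise-floor proxy), but never below 5\% of the envelope peak
#' so that noiseless clips still segment sensibly. An absolute threshold can
#' be supplied instead.
#'
#' @param smoothing_s RMS window length in seconds (default 5 ms).
#' @param threshold absolute envelope threshold, or NULL for adaptive.
#' @param noiseFloorMult multiplier on the 5th-percentile envelope for the
#'   adaptive threshold.
#' @param peakFrac lower bound on the adaptive threshold as a fraction of
#'   the envelope maximum.
#' @param minDur_s minimum syllable duration (s).
#' @param minGap_s sub-threshold gaps shorter than this are merged (s).
#' @return list of class "SegmentationParams".
#' @export
segmentationParams <- function(smoothing_s = 0.005, threshold = NULL,
                               noiseFloorMult = 6, peakFrac = 0.05,
                               minDur_s = 0.010, minGap_s = 0.005) {
  stopifnot(smoothing_s > 0, noiseFloorMult > 0, peakFrac > 0,
            minDur_s > 0, minGap_s > 0)
  structure(list(smoothing_s = smoothing_s, threshold = threshold,
                 noiseFloorMult = noiseFloorMult, peakFrac = peakFrac,
                 minDur_s = minDur_s, minGap_s = minGap_s),
            class = "SegmentationParams")
}

#' Amplitude envelope of an audio clip
#'
#' Moving root-mean-square of the samples over a centred window, returned at
#' the same length as the input. Scaling the samples by a constant scales
#' the envelope by the same constant; an all-zero clip has an all-zero
#' envelope.
#'
#' @param clip an [AudioClip-class].
#' @param smoothing_s RMS window in seconds; must not exceed the clip
#'   duration.
#' @return numeric envelope, same length as \code{samples(clip)}.
#' @export
computeEnvelope <- function(clip, smoothing_s = 0.005) {
  stopifnot(is(clip, "AudioClip"), smoothing_s > 0)
  x <- clip@samples
  win <- max(1L, round(smoothing_s * clip@sampleRate))
  if (win > length(x))
    stop("smoothing window longer than clip")
  # centred moving mean of x^2 via cumulative sums (edges use the window
  # part that fits, keeping the envelope length equal to the signal length)
  cs <- c(0, cumsum(x^2))
  n <- length(x)
  half <- win %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(lo + win - 1L, n)
  lo <- pmax(hi - win + 1L, 1L)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Segment syllables by envelope thresholding
#'
#' Implements amplitude-threshold segmentation of the sound envelope:
#' maximal runs with envelope at or above threshold become candidate
#' syllables, runs separated by gaps shorter than \code{minGap_s} are merged,
#' and candidates shorter than \code{minDur_s} are dropped. Event intervals
#' are half-open in seconds.
#'
#' @param clip an [AudioClip-class]; must be non-empty.
#' @param params a [segmentationParams()] list.
#' @param kind event kind for the output rows ("syllable" or "call").
#' @param durationBounds_s optional \code{c(min, max)} duration filter
#'   applied after merging, e.g. \code{c(0.020, 0.300)} when detecting female
#'   calls on the backpack channel.
#' @return An [EventTable-class] of detected events on the clip's channel.
#' @export
segmentSyllables <- function(clip, params = segmentationParams(),
                             kind = "syllable", durationBounds_s = NULL) {
  stopifnot(is(clip, "AudioClip"))
  if (!length(clip@samples)) stop("empty clip")
  env <- computeEnvelope(clip, params$smoothing_s)
  thr <- params$threshold
  if (is.null(thr)) {
    thr <- max(params$noiseFloorMult * stats::quantile(env, 0.05, names = FALSE),
               params$peakFrac * max(env))
  }
  if (max(env) < thr || thr <= 0)
    return(eventTable(data.frame(), recordingId = "segmented"))

  above <- env >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_idx <- starts[r$values]
  off_idx <- ends[r$values] + 1L   # exclusive
  sr <- clip@sampleRate
  onset <- (on_idx - 1L) / sr
  offset <- (off_idx - 1L) / sr
  if (!length(onset)) return(eventTable(data.frame(), recordingId = "segmented"))

  # merge across short gaps
  m_on <- numeric(0); m_off <- numeric(0)
  cur_on <- onset[1]; cur_off <- offset[1]
  for (i in seq_along(onset)[-1]) {
    if (onset[i] - cur_off < params$minGap_s) {
      cur_off <- offset[i]
    } else {
      m_on <- c(m_on, cur_on); m_off <- c(m_off, cur_off)
      cur_on <- onset[i]; cur_off <- offset[i]
    }
  }
  m_on <- c(m_on, cur_on); m_off <- c(m_off, cur_off)

  dur <- m_off - m_on
  keep <- dur >= params$minDur_s
  if (!is.null(durationBounds_s))
    keep <- keep & dur >= durationBounds_s[1] & dur <= durationBounds_s[2]
  if (!any(keep)) return(eventTable(data.frame(), recordingId = "segmented"))
  eventTable(data.frame(kind = kind, onset_s = m_on[keep],
                        offset_s = m_off[keep],
                        channel = clip@channelTag, label = "",
                        stringsAsFactors = FALSE),
             recordingId = "segmented")
}

#' Assemble song bouts from segmented syllables
#'
#' A song bout is a run of consecutive syllables in which every internal
#' silent gap is shorter than 350 ms; a gap of 350 ms or more ends the bout.
#' Only chains whose span — first-syllable onset to last-syllable offset —
#' is at least 400 ms are kept as song.
#'
#' @param syllables an [EventTable-class] of syllables (any other kinds are
#'   ignored), sorted by onset.
#' @param boutBreak_s silence ending a bout (default 0.350 s).
#' @param boutMinDur_s minimum bout span (default 0.400 s).
#' @param dropIntroNotes optionally drop up to \code{maxIntroNotes} leading
#'   syllables of each chain that are shorter than 100 ms and under 0.6 times
#'   the median syllable duration of the chain (introductory-note heuristic;
#'   off by default).
#' @param maxIntroNotes cap on dropped leading notes per chain.
#' @return data.frame with one row per bout: \code{onset_s}, \code{offset_s},
#'   \code{n_syllables}, \code{duration_s}, and a list column
#'   \code{syllable_idx} of row indices into the syllable table.
#' @export
assembleSongBouts <- function(syllables, boutBreak_s = 0.350,
                              boutMinDur_s = 0.400,
                              dropIntroNotes = FALSE, maxIntroNotes = 3L) {
  stopifnot(is(syllables, "EventTable"))
  ev <- syllables@events
  ev_idx <- which(ev$kind == "syllable")
  empty <- data.frame(onset_s = numeric(), offset_s = numeric(),
                      n_syllables = integer(), duration_s = numeric())
  empty$syllable_idx <- list()
  if (!length(ev_idx)) return(empty)
  on <- ev$onset_s[ev_idx]; off <- ev$offset_s[ev_idx]
  o <- order(on); on <- on[o]; off <- off[o]; ev_idx <- ev_idx[o]

  gaps <- on[-1] - off[-length(off)]
  breakpts <- which(gaps >= boutBreak_s)
  chain_id <- cumsum(c(1L, as.integer(seq_along(gaps) %in% breakpts)))

  rows <- lapply(split(seq_along(on), chain_id), function(ii) {
    if (dropIntroNotes && length(ii) > 1L) {
      dur <- off[ii] - on[ii]
      med <- stats::median(dur)
      drop <- 0L
      while (drop < min(maxIntroNotes, length(ii) - 1L)) {
        d <- dur[drop + 1L]
        if (d < 0.100 && d < 0.6 * med) drop <- drop + 1L else break
      }
      if (drop > 0L) ii <- ii[-seq_len(drop)]
    }
    span_on <- on[ii[1]]; span_off <- off[ii[length(ii)]]
    if (span_off - span_on < boutMinDur_s) return(NULL)
    data.frame(onset_s = span_on, offset_s = span_off,
               n_syllables = length(ii), duration_s = span_off - span_on)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) return(empty)
  out <- do.call(rbind, rows[keep])
  idx_lists <- lapply(split(seq_along(on), chain_id)[keep],
                      function(ii) ev_idx[ii])
  out$syllable_idx <- unname(idx_lists)
  rownames(out) <- NULL
  out
}

#' Attribute female calls to song bouts
#'
#' A call is song-practice-related when its onset falls inside a bout window
#' \code{[onset_s, offset_s)}; the call's own offset may extend past the
#' bout. Each call is attributed to at most one bout.
#'
#' @param bouts data.frame from [assembleSongBouts()].
#' @param calls an [EventTable-class]; rows with kind "call" are used.
#' @return list with \code{perBout} (integer call count per bout row),
#'   \code{flagged} (logical per call: inside a bout?) and
#'   \code{callBout} (bout row index per call, NA when outside song).
#' @export
attributeCallsToSong <- function(bouts, calls) {
  stopifnot(is(calls, "EventTable"))
  ev <- calls@events
  call_on <- ev$onset_s[ev$kind == "call"]
  n_b <- nrow(bouts)
  perBout <- integer(n_b)
  callBout <- rep(NA_integer_, length(call_on))
  if (n_b && length(call_on)) {
    for (i in seq_along(call_on)) {
      hit <- which(call_on[i] >= bouts$onset_s & call_on[i] < bouts$offset_s)
      if (length(hit)) {
        callBout[i] <- hit[1]
        perBout[hit[1]] <- perBout[hit[1]] + 1L
      }
    }
  }
  list(perBout = perBout, flagged = !is.na(callBout), callBout = callBout)
}

#' Syllable rate: syllables per second of vocalisation
#'
#' Number of syllables divided by the summed syllable durations, i.e. silent
#' gaps are excluded. Invariant to gap lengths; multiplying every duration
#' by c divides the rate by c.
#'
#' @param syllables an [EventTable-class] with at least one syllable row.
#' @return rate in syllables per second.
#' @export
syllableRate <- function(syllables) {
  stopifnot(is(syllables, "EventTable"))
  ev <- syllables@events
  ev <- ev[ev$kind == "syllable", , drop = FALSE]
  if (!nrow(ev)) stop("syllableRate needs at least one syllable")
  nrow(ev) / sum(ev$offset_s - ev$onset_s)
}

#' Syllable and gap duration statistics
#'
#' Mean and SD of syllable durations, and of within-bout inter-syllable
#' gaps. Gaps are only measured between consecutive syllables of the same
#' bout; with fewer than two syllables in any bout the gap statistics are
#' returned as NA.
#'
#' @param syllables an [EventTable-class] of syllables.
#' @param bouts optional bout table from [assembleSongBouts()]; when NULL,
#'   bouts are assembled with default rules first.
#' @return list with \code{syllable_mean_s}, \code{syllable_sd_s},
#'   \code{gap_mean_s}, \code{gap_sd_s}, \code{n_syllables}, \code{n_gaps}.
#' @export
syllableGapStats <- function(syllables, bouts = NULL) {
  stopifnot(is(syllables, "EventTable"))
  ev <- syllables@events
  syl <- ev[ev$kind == "syllable", , drop = FALSE]
  if (!nrow(syl)) stop("syllableGapStats needs at least one syllable")
  dur <- syl$offset_s - syl$onset_s
  if (is.null(bouts)) bouts <- assembleSongBouts(syllables)
  gaps <- numeric(0)
  if (nrow(bouts)) {
    for (ii in bouts$syllable_idx) {
      on <- ev$onset_s[ii]; off <- ev$offset_s[ii]
      o <- order(on)
      if (length(ii) > 1L) gaps <- c(gaps, on[o][-1] - off[o][-length(o)])
    }
  }
  list(syllable_mean_s = mean(dur),
       syllable_sd_s = if (length(dur) > 1L) stats::sd(dur) else NA_real_,
       gap_mean_s = if (length(gaps)) mean(gaps) else NA_real_,
       gap_sd_s = if (length(gaps) > 1L) stats::sd(gaps) else NA_real_,
       n_syllables = nrow(syl), n_gaps = length(gaps))
}

#' Precision/recall of a segmentation against ground truth
#'
#' Greedy one-to-one matching by onset proximity: predicted and true events
#' are paired in order of increasing onset distance, each event used at most
#' once, pairs farther apart than \code{tolerance_s} are not matched.
#' Precision = matched / predicted, recall = matched / truth; an empty
#' prediction set yields precision 0 by convention.
#'
#' @param predicted,truth [EventTable-class] objects (all rows used).
#' @param tolerance_s maximum onset distance for a match (default 10 ms).
#' @return list with \code{precision}, \code{recall}, \code{n_matched},
#'   \code{n_predicted}, \code{n_truth}.
#' @export
evaluateSegmentation <- function(predicted, truth, tolerance_s = 0.010) {
  stopifnot(is(predicted, "EventTable"), is(truth, "EventTable"),
            tolerance_s > 0)
  p_on <- predicted@events$onset_s
  t_on <- truth@events$onset_s
  n_p <- length(p_on); n_t <- length(t_on)
  if (!n_p || !n_t) {
    return(list(precision = 0, recall = 0, n_matched = 0L,
                n_predicted = n_p, n_truth = n_t))
  }
  d <- abs(outer(p_on, t_on, "-"))
  cand <- which(d <= tolerance_s, arr.ind = TRUE)
  matched <- 0L
  if (nrow(cand)) {
    cand <- cand[order(d[cand]), , drop = FALSE]
    used_p <- logical(n_p); used_t <- logical(n_t)
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!used_p[i] && !used_t[j]) {
        used_p[i] <- TRUE; used_t[j] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  list(precision = matched / n_p, recall = matched / n_t,
       n_matched = matched, n_predicted = n_p, n_truth = n_t)
}
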