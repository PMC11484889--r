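# Shared fixture builders; everything is generated in code, nothing on disk.

# event table of syllables from onset/offset vectors
syl_table <- function(onsets, offsets, channel = "box") {
  eventTable(data.frame(kind = "syllable", onset_s = onsets,
                        offset_s = offsets, channel = channel, label = "",
                        stringsAsFactors = FALSE))
}

call_table <- function(onsets, offsets) {
  if (!length(onsets)) return(eventTable())
  eventTable(data.frame(kind = "call", onset_s = onsets, offset_s = offsets,
                        channel = "backpack", label = "",
                        stringsAsFactors = FALSE))
}

# homogeneous-Poisson spike trains in a window, one per trial
poisson_trains <- function(n_trials, rate_hz, window_s) {
  lapply(seq_len(n_trials), function(k) {
    n <- stats::rpois(1, rate_hz * window_s)
    sort(stats::runif(n, 0, window_s))
  })
}

# independent two-sided Fisher oracle: enumerate all tables with the
# observed margins, sum hypergeometric probabilities <= observed
fisher_enum_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(ks, r1, r2, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
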