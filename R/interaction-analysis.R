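## Call-ratio statistic, developmental trends, learner classification and
## post-call snippet bookkeeping.

#' Call ratio: female call onsets per second of song
#'
#' Number of call onsets falling inside song-bout windows divided by the
#' summed bout-window durations (the "window of interest" runs from the
#' onset of a song's first syllable to the offset of its last). Undefined
#' when no song was produced.
#'
#' @param bouts data.frame from [assembleSongBouts()] (or any frame with
#'   \code{onset_s}, \code{offset_s}).
#' @param calls an [EventTable-class]; rows with kind "call" are counted.
#' @return list with \code{call_ratio} (calls/s, NA when song duration is
#'   0), \code{n_calls_in_song}, \code{total_song_dur_s}.
#' @export
callRatio <- function(bouts, calls) {
  att <- attributeCallsToSong(bouts, calls)
  tot <- if (nrow(bouts)) sum(bouts$offset_s - bouts$onset_s) else 0
  list(call_ratio = if (tot > 0) sum(att$perBout) / tot else NA_real_,
       n_calls_in_song = sum(att$perBout), total_song_dur_s = tot)
}

#' Per-session summary of song practice and female calling
#'
#' @param syllables [EventTable-class] of segmented syllables (box channel).
#' @param calls [EventTable-class] of female calls (backpack channel).
#' @param cfg a [runConfig()].
#' @return one-row data.frame: bird_id, age_dph, n_bouts, n_songs_produced,
#'   total_song_dur_s, n_calls_in_song, call_ratio, syllable_rate.
#' @export
sessionSummary <- function(syllables, calls, cfg = runConfig()) {
  bouts <- assembleSongBouts(syllables, cfg$bout_break_s, cfg$bout_min_dur_s)
  cr <- callRatio(bouts, calls)
  sr <- tryCatch(syllableRate(syllables), error = function(e) NA_real_)
  data.frame(
    bird_id = syllables@birdId, age_dph = syllables@ageDph,
    n_bouts = nrow(bouts), n_songs_produced = nrow(bouts),
    total_song_dur_s = cr$total_song_dur_s,
    n_calls_in_song = cr$n_calls_in_song,
    call_ratio = cr$call_ratio, syllable_rate = sr,
    stringsAsFactors = FALSE)
}

#' Developmental trend of the call ratio
#'
#' Ordinary least squares of call ratio on age (days post-hatch), with R
#' squared, the regression F statistic and the two-sided p value for the
#' slope.
#'
#' @param summaries data.frame with columns \code{age_dph} and
#'   \code{call_ratio} (rows with NA ratio are dropped); needs at least 3
#'   sessions at distinct ages.
#' @return list with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{f_statistic}, \code{p_value}, \code{n}, \code{ci} (95\% CI for
#'   the slope) and \code{singular} (TRUE for a constant-age fit, where the
#'   other fields are NA).
#' @export
developmentTrend <- function(summaries) {
  d <- summaries[!is.na(summaries$call_ratio), , drop = FALSE]
  if (nrow(d) < 3L || length(unique(d$age_dph)) < 3L) {
    if (length(unique(d$age_dph)) <= 1L)
      return(list(slope = NA_real_, intercept = NA_real_,
                  r_squared = NA_real_, f_statistic = NA_real_,
                  p_value = NA_real_, n = nrow(d), ci = c(NA_real_, NA_real_),
                  singular = TRUE))
    stop("developmentTrend needs >= 3 sessions at distinct ages")
  }
  fit <- stats::lm(call_ratio ~ age_dph, data = d)
  sm <- summary(fit)
  fstat <- unname(sm$fstatistic[1])
  ci <- stats::confint(fit)["age_dph", ]
  list(slope = unname(stats::coef(fit)["age_dph"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = sm$r.squared,
       f_statistic = if (is.null(fstat)) NA_real_ else fstat,
       p_value = sm$coefficients["age_dph", "Pr(>|t|)"],
       n = nrow(d), ci = unname(ci), singular = FALSE)
}

#' Learner threshold from the untutored-bird similarity distribution
#'
#' Upper bound of the 95\% confidence interval of the untutored birds' mean
#' similarity to the tutor song: \code{mean + 1.96 * SE}, reported to one
#' decimal.
#'
#' @param meanPct mean similarity of untutored birds (percent).
#' @param sePct standard error of that mean (percent, >= 0).
#' @param ciZ CI z multiplier (default 1.96).
#' @return threshold in percent, rounded to one decimal.
#' @examples
#' learnerThreshold(32.023, 4.44)  # 40.7
#' @export
learnerThreshold <- function(meanPct, sePct, ciZ = 1.96) {
  stopifnot(sePct >= 0)
  round(meanPct + ciZ * sePct, 1)
}

#' Classify a bird as a good or poor learner
#'
#' Good when the bird's similarity to the tutor song strictly exceeds the
#' threshold (the threshold is an upper confidence bound on "no learning",
#' so a tie stays poor).
#'
#' @param similarityPct per-bird mean similarity (percent).
#' @param thresholdPct threshold from [learnerThreshold()].
#' @return character vector, "good" or "poor".
#' @export
classifyLearner <- function(similarityPct, thresholdPct) {
  ifelse(similarityPct > thresholdPct, "good", "poor")
}

#' Post-call song snippets and matched controls
#'
#' For every song-practice-related call, extracts the 300 ms interval of
#' song directly after the call (anchored at the call offset by default)
#' clipped to its bout, and pairs it with a control interval at the same
#' within-bout offsets in an unperturbed bout of the same session (the
#' nearest-in-time bout long enough to contain the interval; ties broken by
#' seedable random choice). Snippets shorter than the nominal duration
#' (call too close to the bout end) and snippets without a following
#' syllable are flagged.
#'
#' @param syllables [EventTable-class] of syllables.
#' @param calls [EventTable-class] of calls.
#' @param cfg a [runConfig()] (uses \code{snippet_dur_s} and \code{seed}).
#' @param anchor snippet origin: "offset" (default) or "onset" of the call.
#' @return data.frame with one row per in-song call: snippet and control
#'   interval bounds, \code{bout} and \code{control_bout} indices,
#'   \code{short} and \code{no_next_syllable} flags. Zero rows when no call
#'   falls inside song.
#' @export
extractPostCallSnippets <- function(syllables, calls, cfg = runConfig(),
                                    anchor = c("offset", "onset")) {
  anchor <- match.arg(anchor)
  bouts <- assembleSongBouts(syllables, cfg$bout_break_s, cfg$bout_min_dur_s)
  att <- attributeCallsToSong(bouts, calls)
  ev <- calls@events
  cl <- ev[ev$kind == "call", , drop = FALSE]
  syl <- syllables@events
  idx <- which(att$flagged)
  out <- data.frame(call_onset_s = numeric(), snippet_on_s = numeric(),
                    snippet_off_s = numeric(), bout = integer(),
                    control_on_s = numeric(), control_off_s = numeric(),
                    control_bout = integer(), short = logical(),
                    no_next_syllable = logical())
  if (!length(idx)) return(out)
  set.seed(cfg$seed)
  rows <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    b <- att$callBout[i]
    t0 <- if (anchor == "offset") cl$offset_s[i] else cl$onset_s[i]
    t0 <- max(t0, bouts$onset_s[b])
    t1 <- min(t0 + cfg$snippet_dur_s, bouts$offset_s[b])
    short <- (t1 - t0) < cfg$snippet_dur_s - 1e-9
    nxt <- any(syl$kind == "syllable" & syl$onset_s >= t0 & syl$onset_s < t1)
    rel_on <- t0 - bouts$onset_s[b]
    rel_off <- t1 - bouts$onset_s[b]
    # control: unperturbed bout of the same session, long enough
    unpert <- setdiff(which(bouts$offset_s - bouts$onset_s >= rel_off),
                      unique(att$callBout[att$flagged]))
    ctrl <- NA_integer_; c_on <- NA_real_; c_off <- NA_real_
    if (length(unpert)) {
      dist <- abs(bouts$onset_s[unpert] - bouts$onset_s[b])
      best <- unpert[dist == min(dist)]
      ctrl <- if (length(best) > 1L) sample(best, 1L) else best
      c_on <- bouts$onset_s[ctrl] + rel_on
      c_off <- bouts$onset_s[ctrl] + rel_off
    }
    rows[[j]] <- data.frame(
      call_onset_s = cl$onset_s[i], snippet_on_s = t0, snippet_off_s = t1,
      bout = b, control_on_s = c_on, control_off_s = c_off,
      control_bout = ctrl, short = short, no_next_syllable = !nxt)
  }
  do.call(rbind, rows)
}
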