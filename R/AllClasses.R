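#' @import methods
NULL

#' AudioClip: a sampled sound-pressure sequence
#'
#' Carrier object for segmentation. Samples are in arbitrary pressure units
#' (integer PCM is rescaled to \[-1, 1\] on read); times within a clip are
#' seconds from the first sample, sample indices are 0-based and intervals
#' half-open.
#'
#' @slot samples numeric vector of finite sample values.
#' @slot sampleRate sampling rate in Hz (positive).
#' @slot channelTag one of \code{"box"}, \code{"backpack"}, \code{"playback"}.
#'
#' @seealso [audioClip()], [readWav()], [computeEnvelope()]
#' @export
setClass("AudioClip",
  representation(
    samples = "numeric",
    sampleRate = "numeric",
    channelTag = "character"
  )
)

.valid_channel_tags <- c("box", "backpack", "playback")

setValidity("AudioClip", function(object) {
  msg <- character()
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (length(object@samples) && !all(is.finite(object@samples)))
    msg <- c(msg, "all samples must be finite")
  if (length(object@channelTag) != 1L ||
      !object@channelTag %in% .valid_channel_tags)
    msg <- c(msg, sprintf("channelTag must be one of: %s",
                          paste(.valid_channel_tags, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an AudioClip
#'
#' @param samples numeric vector of samples.
#' @param sampleRate sampling rate in Hz.
#' @param channelTag channel label: "box" (cage microphone), "backpack"
#'   (female-borne microphone) or "playback".
#' @return An [AudioClip-class] object.
#' @examples
#' clip <- audioClip(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), 8000)
#' duration(clip)
#' @export
audioClip <- function(samples, sampleRate, channelTag = "box") {
  new("AudioClip", samples = as.numeric(samples),
      sampleRate = as.numeric(sampleRate), channelTag = channelTag)
}

#' VocalEvent kinds recognised throughout the package
#' @keywords internal
.valid_event_kinds <- c("syllable", "call", "song_bout",
                        "playback_call", "playback_bos")

#' EventTable: timestamped vocal events for one recording
#'
#' The lingua franca between vocal-analysis stages. Each row is one event
#' (syllable, call, song bout or playback) with half-open interval
#' \code{[onset_s, offset_s)} in seconds from recording start.
#'
#' @slot events data.frame with columns \code{kind}, \code{onset_s},
#'   \code{offset_s}, \code{channel}, \code{label}; sorted by onset within a
#'   channel.
#' @slot birdId,femaleId,recordingId identifier strings.
#' @slot ageDph age of the juvenile in days post-hatch (non-negative integer).
#'
#' @seealso [eventTable()], [readEventTable()], [segmentSyllables()]
#' @export
setClass("EventTable",
  representation(
    events = "data.frame",
    birdId = "character",
    femaleId = "character",
    ageDph = "integer",
    recordingId = "character"
  )
)

setValidity("EventTable", function(object) {
  ev <- object@events
  msg <- character()
  need <- c("kind", "onset_s", "offset_s", "channel", "label")
  if (!all(need %in% names(ev)))
    return(sprintf("events must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(ev)) {
    if (!all(ev$kind %in% .valid_event_kinds))
      msg <- c(msg, sprintf("event kind must be one of: %s",
                            paste(.valid_event_kinds, collapse = ", ")))
    bad <- which(!(ev$onset_s >= 0 & ev$offset_s > ev$onset_s))
    if (length(bad))
      msg <- c(msg, sprintf("row %d: need 0 <= onset_s < offset_s", bad[1]))
    for (ch in unique(ev$channel)) {
      on <- ev$onset_s[ev$channel == ch]
      if (is.unsorted(on))
        msg <- c(msg, sprintf("events not sorted by onset within channel '%s'", ch))
    }
  }
  if (length(object@ageDph) != 1L || is.na(object@ageDph) || object@ageDph < 0L)
    msg <- c(msg, "ageDph must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Construct an EventTable
#'
#' @param events data.frame with columns \code{kind, onset_s, offset_s,
#'   channel, label} (missing \code{channel}/\code{label} are filled with
#'   defaults). Rows are sorted by channel then onset.
#' @param birdId,femaleId,recordingId identifier strings.
#' @param ageDph age in days post-hatch.
#' @return An [EventTable-class] object.
#' @examples
#' et <- eventTable(data.frame(kind = "syllable", onset_s = 0.1, offset_s = 0.3))
#' nEvents(et)
#' @export
eventTable <- function(events = data.frame(), birdId = "unknown",
                       femaleId = "unknown", ageDph = 0L,
                       recordingId = "unknown") {
  if (!nrow(events)) {
    events <- data.frame(kind = character(), onset_s = numeric(),
                         offset_s = numeric(), channel = character(),
                         label = character(), stringsAsFactors = FALSE)
  } else {
    if (is.null(events$channel)) events$channel <- "box"
    if (is.null(events$label)) events$label <- ""
    events <- events[order(events$channel, events$onset_s, events$offset_s),
                     c("kind", "onset_s", "offset_s", "channel", "label"),
                     drop = FALSE]
    rownames(events) <- NULL
  }
  new("EventTable", events = events, birdId = as.character(birdId),
      femaleId = as.character(femaleId), ageDph = as.integer(ageDph),
      recordingId = as.character(recordingId))
}

#' IntracellularTrialSet: membrane-potential sweeps aligned to a stimulus
#'
#' Holds repeated membrane-potential (Vm, mV) traces from one cell, each with
#' a stimulus window. All trials share the sampling rate and the stimulus
#' kind; spike threshold for detection is \code{baseline + 15 mV} by
#' convention.
#'
#' @slot traces list of numeric Vm vectors (mV), one per trial.
#' @slot sampleRate sampling rate in Hz, shared across trials.
#' @slot stimOnset,stimOffset per-trial stimulus window \code{[on, off)}
#'   in seconds from trial start.
#' @slot stimKind stimulus kind, \code{"playback_call"} or
#'   \code{"playback_bos"}.
#' @slot baselineMv resting membrane potential (mV).
#' @slot cellId,birdId identifiers; \code{ageDph} age; \code{condition}
#'   \code{"listening"} or \code{"singing"}.
#' @export
setClass("IntracellularTrialSet",
  representation(
    traces = "list",
    sampleRate = "numeric",
    stimOnset = "numeric",
    stimOffset = "numeric",
    stimKind = "character",
    baselineMv = "numeric",
    cellId = "character",
    birdId = "character",
    ageDph = "integer",
    condition = "character"
  )
)

setValidity("IntracellularTrialSet", function(object) {
  msg <- character()
  n <- length(object@traces)
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (length(object@stimOnset) != n || length(object@stimOffset) != n)
    msg <- c(msg, "stimOnset/stimOffset must have one entry per trial")
  if (n) {
    if (!all(vapply(object@traces, function(v) all(is.finite(v)), logical(1))))
      msg <- c(msg, "all traces must be finite")
    dur <- vapply(object@traces, length, integer(1)) / object@sampleRate
    if (any(object@stimOnset < 0 | object@stimOffset > dur + 1e-9 |
            object@stimOffset <= object@stimOnset))
      msg <- c(msg, "stimulus windows must lie within trial duration")
  }
  if (length(object@stimKind) != 1L ||
      !object@stimKind %in% c("playback_call", "playback_bos"))
    msg <- c(msg, "stimKind must be 'playback_call' or 'playback_bos'")
  if (length(object@condition) != 1L ||
      !object@condition %in% c("listening", "singing"))
    msg <- c(msg, "condition must be 'listening' or 'singing'")
  if (length(msg)) msg else TRUE
})

#' Construct an IntracellularTrialSet
#'
#' @param traces list of numeric Vm vectors (mV).
#' @param sampleRate sampling rate in Hz.
#' @param stimOnset,stimOffset stimulus window bounds in seconds; recycled to
#'   the number of trials.
#' @param stimKind "playback_call" or "playback_bos".
#' @param baselineMv resting potential in mV.
#' @param cellId,birdId,ageDph,condition metadata.
#' @return An [IntracellularTrialSet-class] object.
#' @export
intracellularTrialSet <- function(traces, sampleRate, stimOnset, stimOffset,
                                  stimKind = "playback_call",
                                  baselineMv = -70, cellId = "cell1",
                                  birdId = "bird1", ageDph = 60L,
                                  condition = "listening") {
  n <- length(traces)
  new("IntracellularTrialSet", traces = traces,
      sampleRate = as.numeric(sampleRate),
      stimOnset = rep_len(as.numeric(stimOnset), n),
      stimOffset = rep_len(as.numeric(stimOffset), n),
      stimKind = stimKind, baselineMv = as.numeric(baselineMv),
      cellId = as.character(cellId), birdId = as.character(birdId),
      ageDph = as.integer(ageDph), condition = condition)
}

#' UnitRecord: one sorted extracellular unit
#'
#' @slot unitId,birdId identifiers.
#' @slot spikeTimes numeric spike times in seconds, sorted.
#' @slot isiViolation,amplitudeCutoff,presenceRatio sorter quality metrics
#'   (NA when a metric is missing).
#' @slot spontaneousRateHz spontaneous firing rate over inter-stimulus
#'   silence (Hz).
#' @slot unitClass "projection", "interneuron" or "excluded".
#' @export
setClass("UnitRecord",
  representation(
    unitId = "character",
    birdId = "character",
    spikeTimes = "numeric",
    isiViolation = "numeric",
    amplitudeCutoff = "numeric",
    presenceRatio = "numeric",
    spontaneousRateHz = "numeric",
    unitClass = "character"
  )
)

setValidity("UnitRecord", function(object) {
  msg <- character()
  if (is.unsorted(object@spikeTimes))
    msg <- c(msg, "spikeTimes must be sorted")
  pr <- object@presenceRatio
  if (length(pr) == 1L && !is.na(pr) && (pr < 0 || pr > 1))
    msg <- c(msg, "presenceRatio must lie in [0, 1]")
  if (!object@unitClass %in% c("projection", "interneuron", "excluded", "unclassified"))
    msg <- c(msg, "unitClass must be projection/interneuron/excluded/unclassified")
  if (length(msg)) msg else TRUE
})

#' Construct a UnitRecord
#'
#' @param unitId,birdId identifiers.
#' @param spikeTimes numeric spike times (s).
#' @param isiViolation,amplitudeCutoff,presenceRatio quality metrics; NA when
#'   unavailable.
#' @param spontaneousRateHz spontaneous rate (Hz); NA to compute later.
#' @param unitClass initial class label.
#' @return A [UnitRecord-class] object.
#' @export
unitRecord <- function(unitId, spikeTimes, birdId = "bird1",
                       isiViolation = NA_real_, amplitudeCutoff = NA_real_,
                       presenceRatio = NA_real_,
                       spontaneousRateHz = NA_real_,
                       unitClass = "unclassified") {
  new("UnitRecord", unitId = as.character(unitId),
      birdId = as.character(birdId),
      spikeTimes = sort(as.numeric(spikeTimes)),
      isiViolation = as.numeric(isiViolation),
      amplitudeCutoff = as.numeric(amplitudeCutoff),
      presenceRatio = as.numeric(presenceRatio),
      spontaneousRateHz = as.numeric(spontaneousRateHz),
      unitClass = unitClass)
}
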