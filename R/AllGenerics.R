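#' Accessors for finchvocal classes
#'
#' \code{samples}, \code{sampleRate}, \code{channelTag} and \code{duration}
#' access [AudioClip-class] slots; \code{events} and \code{nEvents} access
#' [EventTable-class]; \code{traces} and \code{nTrials} access
#' [IntracellularTrialSet-class]; \code{spikeTimes} and \code{unitClass}
#' access [UnitRecord-class].
#'
#' @param object a finchvocal object.
#' @return The slot value (or derived quantity, e.g. duration in seconds).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("channelTag", function(object) standardGeneric("channelTag"))
#' @rdname accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))
#' @rdname accessors
#' @export
setGeneric("events", function(object) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))
#' @rdname accessors
#' @export
setGeneric("traces", function(object) standardGeneric("traces"))
#' @rdname accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("unitClass", function(object) standardGeneric("unitClass"))

#' @rdname accessors
#' @export
setMethod("samples", "AudioClip", function(object) object@samples)
#' @rdname accessors
#' @export
setMethod("sampleRate", "AudioClip", function(object) object@sampleRate)
#' @rdname accessors
#' @export
setMethod("channelTag", "AudioClip", function(object) object@channelTag)
#' @rdname accessors
#' @export
setMethod("duration", "AudioClip",
          function(object) length(object@samples) / object@sampleRate)

#' @rdname accessors
#' @export
setMethod("events", "EventTable", function(object) object@events)
#' @rdname accessors
#' @export
setMethod("nEvents", "EventTable", function(object) nrow(object@events))

#' @rdname accessors
#' @export
setMethod("traces", "IntracellularTrialSet", function(object) object@traces)
#' @rdname accessors
#' @export
setMethod("nTrials", "IntracellularTrialSet",
          function(object) length(object@traces))
#' @rdname accessors
#' @export
setMethod("sampleRate", "IntracellularTrialSet",
          function(object) object@sampleRate)

#' @rdname accessors
#' @export
setMethod("spikeTimes", "UnitRecord", function(object) object@spikeTimes)
#' @rdname accessors
#' @export
setMethod("unitClass", "UnitRecord", function(object) object@unitClass)

setMethod("show", "AudioClip", function(object) {
  cat(sprintf("AudioClip: %.3f s at %g Hz (%s channel), %d samples\n",
              duration(object), object@sampleRate, object@channelTag,
              length(object@samples)))
})

setMethod("show", "EventTable", function(object) {
  ev <- object@events
  cat(sprintf("EventTable: %d events | bird %s, female %s, %d dph, rec %s\n",
              nrow(ev), object@birdId, object@femaleId, object@ageDph,
              object@recordingId))
  if (nrow(ev)) {
    tab <- table(ev$kind)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "IntracellularTrialSet", function(object) {
  cat(sprintf(
    "IntracellularTrialSet: %d trials at %g Hz | cell %s, bird %s, %d dph\n",
    length(object@traces), object@sampleRate, object@cellId, object@birdId,
    object@ageDph))
  cat(sprintf("  stimulus: %s, condition: %s, baseline %.1f mV\n",
              object@stimKind, object@condition, object@baselineMv))
})

setMethod("show", "UnitRecord", function(object) {
  cat(sprintf("UnitRecord %s (bird %s): %d spikes, class %s\n",
              object@unitId, object@birdId, length(object@spikeTimes),
              object@unitClass))
})

#' Convert an EventTable to a data.frame
#'
#' Returns the event rows together with the recording metadata as columns,
#' i.e. the on-disk CSV layout.
#'
#' @param x an [EventTable-class].
#' @param ... unused.
#' @return data.frame with columns \code{recording_id, bird_id, female_id,
#'   age_dph, channel, kind, onset_s, offset_s, label}.
#' @export
as.data.frame.EventTable <- function(x, ...) {
  ev <- x@events
  data.frame(
    recording_id = rep(x@recordingId, nrow(ev)),
    bird_id = rep(x@birdId, nrow(ev)),
    female_id = rep(x@femaleId, nrow(ev)),
    age_dph = rep(x@ageDph, nrow(ev)),
    channel = ev$channel, kind = ev$kind,
    onset_s = ev$onset_s, offset_s = ev$offset_s, label = ev$label,
    stringsAsFactors = FALSE)
}
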