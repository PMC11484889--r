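#' Analysis constants with study defaults
#'
#' Collects every numeric constant of the pipeline in one list so a whole run
#' is reproducible from a single YAML file. Defaults are the values used
#' throughout: 15 mV spike threshold above baseline, 50 ms response pad after
#' stimulus offset, 400 ms minimum song-bout span, 350 ms silence ending a
#' bout, 300 ms post-call snippets, 1000 permutations, 1.96-sigma confidence
#' bounds, a 2 Hz spontaneous-rate boundary between projection neurons and
#' interneurons, and the unit quality-control cutoffs.
#'
#' @param ... named overrides of any default.
#' @return A list of class \code{"RunConfig"}.
#' @examples
#' cfg <- runConfig(n_permutations = 500)
#' cfg$bout_min_dur_s
#' @export
runConfig <- function(...) {
  cfg <- list(
    spike_threshold_mV = 15,
    response_pad_s = 0.050,
    silence_gap_s = 0.050,
    bout_min_dur_s = 0.400,
    bout_break_s = 0.350,
    snippet_dur_s = 0.300,
    n_permutations = 1000L,
    alpha = 0.05,
    ci_z = 1.96,
    projection_rate_hz = 2.0,
    qc_isi_max = 0.25,
    qc_amp_cutoff_max = 0.3,
    qc_presence_min = 0.90,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown RunConfig fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  .validate_run_config(cfg)
  class(cfg) <- "RunConfig"
  cfg
}

.validate_run_config <- function(cfg) {
  pos <- c("spike_threshold_mV", "response_pad_s", "silence_gap_s",
           "bout_min_dur_s", "bout_break_s", "snippet_dur_s",
           "n_permutations", "ci_z", "projection_rate_hz",
           "qc_isi_max", "qc_amp_cutoff_max", "qc_presence_min")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop(sprintf("RunConfig field '%s' must be a single positive number", f))
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("RunConfig alpha must lie in (0, 1)")
  invisible(cfg)
}

#' Read or write a RunConfig as YAML
#'
#' @param path file path.
#' @param cfg a RunConfig list from [runConfig()].
#' @return \code{readRunConfig} returns a RunConfig; \code{writeRunConfig}
#'   returns \code{path} invisibly.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(runConfig, vals)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

## ---- WAV ------------------------------------------------------------------

#' Read a WAV file into an AudioClip
#'
#' Supports the two encodings used by the recording rigs: 16-bit integer PCM
#' and 32-bit IEEE float. Integer samples are rescaled to \[-1, 1\] by
#' division with 32768. Multi-channel files yield the requested channel
#' (default: first).
#'
#' @param path path to a WAV file.
#' @param channelTag channel label to attach ("box", "backpack", "playback").
#' @param channel 1-based channel index for multi-channel files.
#' @return An [AudioClip-class].
#' @seealso [writeWav()]
#' @export
readWav <- function(path, channelTag = "box", channel = 1L) {
  if (!file.exists(path)) stop("audio file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a WAV (RIFF) file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAV (WAVE) payload: ", path)

  fmt <- NULL
  dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        n_channels = readBin(raw_fmt[3:4], "integer", 1, 2,
                             signed = FALSE, endian = "little"),
        sample_rate = readBin(raw_fmt[5:8], "integer", 1, 4,
                              endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1, 2,
                       signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      dat <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stop("malformed WAV: missing chunk in ", path)
  nch <- fmt$n_channels
  if (channel < 1L || channel > nch)
    stop(sprintf("channel %d requested but file has %d channel(s)", channel, nch))
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(dat, "integer", length(dat) %/% 2L, 2, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(dat, "numeric", length(dat) %/% 4L, 4, endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bit)",
                 fmt$audio_format, fmt$bits))
  }
  if (!length(x)) stop("zero-length audio in ", path)
  if (nch > 1L) x <- x[seq(channel, length(x), by = nch)]
  audioClip(x, fmt$sample_rate, channelTag)
}

#' Write an AudioClip as WAV
#'
#' @param clip an [AudioClip-class].
#' @param path output path.
#' @param bits 16 (integer PCM, samples clipped to \[-1, 1\]) or 32
#'   (IEEE float).
#' @return \code{path}, invisibly.
#' @export
writeWav <- function(clip, path, bits = 32L) {
  stopifnot(is(clip, "AudioClip"), bits %in% c(16L, 32L))
  x <- clip@samples
  sr <- as.integer(round(clip@sampleRate))
  if (bits == 16L) {
    pcm <- as.integer(round(pmax(pmin(x, 32767 / 32768), -1) * 32768))
    payload <- writeBin(pcm, raw(), 2, endian = "little")
    fmt_code <- 1L
  } else {
    payload <- writeBin(as.numeric(x), raw(), 4, endian = "little")
    fmt_code <- 3L
  }
  bytes_per <- bits %/% 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + length(payload)), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")        # audio format
  writeBin(1L, con, 2, endian = "little")              # mono
  writeBin(sr, con, 4, endian = "little")
  writeBin(sr * bytes_per, con, 4, endian = "little")  # byte rate
  writeBin(bytes_per, con, 2, endian = "little")       # block align
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(payload)), con, 4, endian = "little")
  writeBin(payload, con)
  invisible(path)
}

## ---- event tables ---------------------------------------------------------

.event_csv_cols <- c("recording_id", "bird_id", "female_id", "age_dph",
                     "channel", "kind", "onset_s", "offset_s", "label")

#' Write an EventTable to CSV
#'
#' Times are written with 6 decimals (1 microsecond), well below one sample
#' at any recording rate used, so a write/read round-trip is lossless.
#'
#' @param table an [EventTable-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @seealso [readEventTable()]
#' @export
writeEventTable <- function(table, path) {
  stopifnot(is(table, "EventTable"))
  df <- as.data.frame(table)
  df$onset_s <- sprintf("%.6f", df$onset_s)
  df$offset_s <- sprintf("%.6f", df$offset_s)
  chr_cols <- which(vapply(df, is.character, logical(1)) &
                    !names(df) %in% c("onset_s", "offset_s"))
  utils::write.csv(df, path, row.names = FALSE, quote = chr_cols)
  invisible(path)
}

#' Read an EventTable from CSV
#'
#' Validates that every row has \code{onset_s < offset_s} and that events are
#' sorted within each channel; violations are reported with their row number.
#'
#' @param path CSV path with the columns written by [writeEventTable()].
#' @return An [EventTable-class].
#' @export
readEventTable <- function(path) {
  if (!file.exists(path)) stop("event table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(onset_s = "numeric",
                                       offset_s = "numeric"))
  miss <- setdiff(.event_csv_cols, names(df))
  if (length(miss))
    stop("event CSV missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    bad <- which(df$offset_s <= df$onset_s | df$onset_s < 0)
    if (length(bad))
      stop(sprintf("invalid event interval at row %d: [%g, %g)",
                   bad[1], df$onset_s[bad[1]], df$offset_s[bad[1]]))
    for (ch in unique(df$channel)) {
      idx <- which(df$channel == ch)
      if (is.unsorted(df$onset_s[idx]))
        stop(sprintf("events not sorted by onset in channel '%s' (first at row %d)",
                     ch, idx[which(diff(df$onset_s[idx]) < 0)[1] + 1L]))
    }
  }
  meta <- if (nrow(df)) df[1, ] else
    list(bird_id = "unknown", female_id = "unknown", age_dph = 0L,
         recording_id = "unknown")
  eventTable(df[, c("kind", "onset_s", "offset_s", "channel", "label")],
             birdId = meta$bird_id, femaleId = meta$female_id,
             ageDph = meta$age_dph, recordingId = meta$recording_id)
}

## ---- sweep archive --------------------------------------------------------

#' Write an IntracellularTrialSet to a sweep archive
#'
#' The archive is a directory of plain-text files: \code{meta.json} (sample
#' rate, baseline, identifiers, per-trial stimulus windows) and one
#' \code{sweepNNN.csv} per trial holding the Vm trace in mV, written with
#' \%.4f precision (0.1 microvolt). Stimulus windows outside the trace
#' duration are rejected.
#'
#' @param store an [IntracellularTrialSet-class].
#' @param path directory to create (overwritten if it exists).
#' @return \code{path}, invisibly.
#' @seealso [readSweepStore()]
#' @export
writeSweepStore <- function(store, path) {
  stopifnot(is(store, "IntracellularTrialSet"))
  validObject(store)
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  dir.create(path, recursive = TRUE)
  n <- length(store@traces)
  meta <- list(
    sample_rate_hz = store@sampleRate, baseline_mV = store@baselineMv,
    bird_id = store@birdId, cell_id = store@cellId,
    age_dph = store@ageDph, condition = store@condition,
    stim_kind = store@stimKind,
    stim_onset_s = store@stimOnset, stim_offset_s = store@stimOffset,
    n_sweeps = n)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_len(n)) {
    f <- file.path(path, sprintf("sweep%03d.csv", i))
    writeLines(c("vm_mV", sprintf("%.4f", store@traces[[i]])), f)
  }
  invisible(path)
}

#' Read a sweep archive
#'
#' @param path directory written by [writeSweepStore()].
#' @return An [IntracellularTrialSet-class].
#' @export
readSweepStore <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("not a sweep archive (no meta.json): ", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  n <- meta$n_sweeps
  tr <- vector("list", n)
  for (i in seq_len(n)) {
    f <- file.path(path, sprintf("sweep%03d.csv", i))
    if (!file.exists(f)) stop("sweep archive missing ", basename(f))
    tr[[i]] <- as.numeric(readLines(f)[-1])
  }
  intracellularTrialSet(
    tr, meta$sample_rate_hz,
    stimOnset = as.numeric(meta$stim_onset_s),
    stimOffset = as.numeric(meta$stim_offset_s),
    stimKind = meta$stim_kind, baselineMv = meta$baseline_mV,
    cellId = meta$cell_id, birdId = meta$bird_id,
    ageDph = meta$age_dph, condition = meta$condition)
}

## ---- shared helpers -------------------------------------------------------

#' Convert a half-open time interval to 0-based sample indices
#'
#' Onsets use floor, offsets use ceiling, so a segment is never off by more
#' than one sample from the true interval.
#'
#' @param onset_s,offset_s interval bounds in seconds.
#' @param rate sampling rate in Hz.
#' @return integer vector \code{c(first, lastExclusive)} of 0-based indices.
#' @keywords internal
secondsToSamples <- function(onset_s, offset_s, rate) {
  c(floor(onset_s * rate), ceiling(offset_s * rate))
}
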