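#' Write a recording to the package's text container
#'
#' The container is a directory holding \code{header.json} (rates, channel
#' names, metadata), \code{signal.tsv} (samples x channels), \code{markers.tsv}
#' and, when ground truth is known, \code{truth.json}. All files are plain
#' text; numbers round-trip at full double precision up to decimal
#' formatting.
#'
#' @param rec an \linkS4class{EegRecording}
#' @param path container directory to create (overwritten if present)
#' @return \code{path}, invisibly
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "EegRecording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  header <- list(format = "ssvepDepth-recording", version = 1L,
                 sample_rate = rec@sampleRate,
                 channel_names = rec@channelNames,
                 n_samples = ncol(rec@signal),
                 units = "uV",
                 metadata = rec@metadata)
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sig <- as.data.frame(t(rec@signal))
  names(sig) <- rec@channelNames
  utils::write.table(sig, file.path(path, "signal.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(rec@markers, file.path(path, "markers.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (nrow(rec@groundTruth)) {
    jsonlite::write_json(rec@groundTruth, file.path(path, "truth.json"),
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a recording from the package's text container
#'
#' Channels are mapped to (and ordered by) the requested canonical montage;
#' missing channels or a missing marker table are errors. The ground-truth
#' sidecar, when present, is attached to the markers.
#'
#' @param path container directory written by \code{\link{writeRecording}}
#' @param requiredChannels channels that must be present, in canonical
#'   order (default \code{\link{standardChannels}()}); NULL keeps the
#'   stored order without checks
#' @return an \linkS4class{EegRecording}
#' @export
readRecording <- function(path, requiredChannels = standardChannels()) {
  hfile <- file.path(path, "header.json")
  if (!file.exists(hfile)) stop("not a recording container: ", path)
  header <- jsonlite::read_json(hfile, simplifyVector = TRUE)
  mfile <- file.path(path, "markers.tsv")
  if (!file.exists(mfile)) {
    stop("container lacks the marker table (markers.tsv)")
  }
  sig <- utils::read.table(file.path(path, "signal.tsv"), header = TRUE,
                           sep = "\t", check.names = FALSE)
  stored <- names(sig)
  if (!is.null(requiredChannels)) {
    missing <- setdiff(requiredChannels, stored)
    if (length(missing)) {
      stop("recording lacks required channel(s): ",
           paste(missing, collapse = ", "))
    }
    sig <- sig[, requiredChannels, drop = FALSE]
    stored <- requiredChannels
  }
  markers <- utils::read.table(mfile, header = TRUE, sep = "\t")
  tfile <- file.path(path, "truth.json")
  truth <- if (file.exists(tfile)) {
    as.data.frame(jsonlite::read_json(tfile, simplifyVector = TRUE))
  } else {
    data.frame(trial_index = integer(), environment = character(),
               depth = numeric(), frequency = numeric())
  }
  signal <- t(as.matrix(sig))
  rownames(signal) <- stored
  new("EegRecording", signal = signal,
      sampleRate = header$sample_rate,
      channelNames = stored,
      markers = markers,
      groundTruth = truth,
      metadata = if (is.null(header$metadata)) list()
                 else as.list(header$metadata))
}

#' Write a trial schedule as an events table (TSV)
#'
#' One row per trial in a BIDS-events-like layout: onset (stimulus onset,
#' seconds), duration, trial_type, frequency, depth, environment, round.
#'
#' @param schedule a \linkS4class{TrialSchedule}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeScheduleTsv <- function(schedule, path) {
  tr <- trialInfo(schedule)
  events <- data.frame(onset = tr$stim_onset,
                       duration = schedule@stimDuration,
                       trial_type = "flicker",
                       frequency = tr$frequency,
                       depth = tr$depth,
                       environment = tr$environment,
                       round = tr$round)
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a trial schedule as JSON
#'
#' One object per trial with the full event timing plus the per-trial
#' segment durations.
#'
#' @param schedule a \linkS4class{TrialSchedule}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeScheduleJson <- function(schedule, path) {
  jsonlite::write_json(
    list(cue_duration = schedule@cueDuration,
         stim_duration = schedule@stimDuration,
         rest_duration = schedule@restDuration,
         trials = trialInfo(schedule)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
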