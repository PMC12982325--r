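#' @include AllClasses.R
NULL

#' Sampling rate accessor
#' @param x an object with a sampling rate
#' @return sampling rate in Hz
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' Channel-name accessor
#' @param x an object carrying channel labels
#' @return character vector of channel labels
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Number of trials
#' @param x a schedule, recording or epoch set
#' @return integer trial count
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Per-trial condition labels
#' @param x a schedule, recording or epoch set
#' @return data.frame with one row per trial
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))

#' Kept-trial mask accessor
#' @param x an \linkS4class{EpochSet}
#' @return logical vector, TRUE for trials that survived rejection
#' @export
setGeneric("keptMask", function(x) standardGeneric("keptMask"))

#' Total session duration
#' @param x a \linkS4class{TrialSchedule}
#' @return duration in seconds
#' @export
setGeneric("totalDuration", function(x) standardGeneric("totalDuration"))

#' @rdname sampleRate
#' @export
setMethod("sampleRate", "EegRecording", function(x) x@sampleRate)
#' @rdname sampleRate
#' @export
setMethod("sampleRate", "EpochSet", function(x) x@sampleRate)
#' @rdname sampleRate
#' @export
setMethod("sampleRate", "FlickerWaveform", function(x) x@sampleRate)
#' @rdname sampleRate
#' @export
setMethod("sampleRate", "GeneratorConfig", function(x) x@sampleRate)
#' @rdname sampleRate
#' @export
setMethod("sampleRate", "ReferenceSet", function(x) x@sampleRate)

#' @rdname channelNames
#' @export
setMethod("channelNames", "EegRecording", function(x) x@channelNames)
#' @rdname channelNames
#' @export
setMethod("channelNames", "EpochSet", function(x) x@channelNames)
#' @rdname channelNames
#' @export
setMethod("channelNames", "GeneratorConfig", function(x) x@channelNames)
#' @rdname channelNames
#' @export
setMethod("channelNames", "TrcaModel", function(x) x@channelNames)

#' @rdname nTrials
#' @export
setMethod("nTrials", "TrialSchedule", function(x) nrow(x@trials))
#' @rdname nTrials
#' @export
setMethod("nTrials", "EegRecording", function(x) nrow(x@markers))
#' @rdname nTrials
#' @export
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[1])

#' @rdname trialInfo
#' @export
setMethod("trialInfo", "TrialSchedule", function(x) x@trials)
#' @rdname trialInfo
#' @export
setMethod("trialInfo", "EegRecording", function(x) x@groundTruth)
#' @rdname trialInfo
#' @export
setMethod("trialInfo", "EpochSet", function(x) x@labels)

#' @rdname keptMask
#' @export
setMethod("keptMask", "EpochSet", function(x) x@keptMask)

#' @rdname totalDuration
#' @export
setMethod("totalDuration", "TrialSchedule", function(x) {
  nrow(x@trials) * (x@cueDuration + x@stimDuration + x@restDuration)
})

setMethod("show", "StimulusSpec", function(object) {
  cat(sprintf(
    "StimulusSpec: %.4g Hz (%d frames/cycle @ %g Hz refresh), duty %.2f\n",
    object@frequency, object@framesPerCycle, object@refreshRate,
    object@dutyCycle))
  cat(sprintf("  depth %.2f m, visual angle %.2f deg, diameter %.2f cm\n",
              object@depth, object@visualAngle, 100 * object@diameter))
})

setMethod("show", "TrialSchedule", function(object) {
  tr <- object@trials
  cat(sprintf("TrialSchedule: %d trials, %.1f s total (%g + %g + %g s each)\n",
              nrow(tr), totalDuration(object), object@cueDuration,
              object@stimDuration, object@restDuration))
  if (nrow(tr)) {
    cat("  environments:", paste(unique(tr$environment), collapse = ", "),
        "| depths:", paste(unique(tr$depth), collapse = ", "), "m",
        "| frequencies:", paste(unique(tr$frequency), collapse = ", "), "Hz\n")
  }
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf("GeneratorConfig: %d channels @ %g Hz, seed %d\n",
              length(object@channelNames), object@sampleRate, object@seed))
  amp <- if (length(object@fundamentalAmplitude)) {
    sprintf("fixed %.3g uV", object@fundamentalAmplitude)
  } else {
    sprintf("calibrated to %d SNR targets", nrow(object@targetSnrDb))
  }
  cat(sprintf("  evoked: %s, harmonic ratio %.2f, latency %.3f s\n",
              amp, object@harmonicRatio, object@responseLatency))
})

setMethod("show", "EegRecording", function(object) {
  cat(sprintf("EegRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@signal), ncol(object@signal), object@sampleRate,
              ncol(object@signal) / object@sampleRate))
  cat(sprintf("  %d markers, ground truth for %d trials\n",
              nrow(object@markers), nrow(object@groundTruth)))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EpochSet: %d trials x %d channels x %d samples @ %g Hz, window [%g, %g) s\n",
    d[1], d[2], d[3], object@sampleRate, object@window[1], object@window[2]))
  cat(sprintf("  kept %d / %d trials\n", sum(object@keptMask), d[1]))
})

setMethod("show", "ReferenceSet", function(object) {
  cat(sprintf(
    "ReferenceSet: %d frequencies (%s Hz), %d harmonics, %d samples @ %g Hz\n",
    length(object@frequencies),
    paste(object@frequencies, collapse = ", "),
    object@nHarmonics, object@nSamples, object@sampleRate))
})

setMethod("show", "FilterBankSpec", function(object) {
  cat(sprintf("FilterBankSpec: %d subbands (order %d)\n",
              length(object@bands), object@order))
  for (i in seq_along(object@bands)) {
    cat(sprintf("  band %d: %.1f-%.1f Hz, weight %.4f\n", i,
                object@bands[[i]][1], object@bands[[i]][2],
                object@weights[i]))
  }
})

setMethod("show", "TrcaModel", function(object) {
  cat(sprintf("TrcaModel: %d channels, class %s Hz, top eigenvalue %.4g\n",
              nrow(object@filters),
              ifelse(is.na(object@frequency), "<none>",
                     format(object@frequency)),
              object@eigenvalues[1]))
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf(
    "PipelineConfig: %s x %d depths x %d frequencies x %d reps, seed %d\n",
    paste(object@environments, collapse = "/"),
    length(object@depths), length(object@frequencies),
    object@repsPerCell, object@seed))
})
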