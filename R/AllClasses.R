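#' @import methods
NULL

#' Canonical occipito-parietal montage
#'
#' The nine posterior electrodes used for SSVEP recording and simulation.
#'
#' @return Character vector of channel labels.
#' @export
standardChannels <- function() {
  c("Oz", "O1", "O2", "PO3", "PO4", "PO5", "PO6", "POz", "Pz")
}

#' StimulusSpec: one frame-locked flicker source
#'
#' Describes a single circular flicker stimulus: its frequency (locked to the
#' display refresh rate through an integer number of frames per cycle), duty
#' cycle, viewing depth and angular size. The physical diameter is derived
#' from depth and visual angle.
#'
#' @slot frequency flicker frequency in Hz
#' @slot refreshRate display refresh rate in Hz
#' @slot framesPerCycle integer number of display frames per flicker cycle
#' @slot dutyCycle on-fraction of each cycle, in (0, 1)
#' @slot depth viewing distance in metres
#' @slot visualAngle angular size in degrees
#' @slot diameter physical diameter in metres
#' @slot peakIntensity normalised on-intensity (1 = on, 0 = off)
#' @exportClass StimulusSpec
setClass("StimulusSpec",
  representation(
    frequency = "numeric",
    refreshRate = "numeric",
    framesPerCycle = "integer",
    dutyCycle = "numeric",
    depth = "numeric",
    visualAngle = "numeric",
    diameter = "numeric",
    peakIntensity = "numeric"
  )
)

setValidity("StimulusSpec", function(object) {
  msg <- character()
  if (abs(object@frequency * object@framesPerCycle - object@refreshRate) >
      1e-9 * object@refreshRate) {
    msg <- c(msg, "frequency * framesPerCycle must equal refreshRate exactly")
  }
  if (object@dutyCycle <= 0 || object@dutyCycle >= 1) {
    msg <- c(msg, "dutyCycle must lie in (0, 1)")
  }
  onFrames <- object@dutyCycle * object@framesPerCycle
  if (abs(onFrames - round(onFrames)) > 1e-9) {
    msg <- c(msg, "dutyCycle * framesPerCycle must be a whole number of frames")
  }
  if (object@depth < 0 || !is.finite(object@depth)) {
    msg <- c(msg, "depth must be finite and non-negative")
  }
  expected <- 2 * object@depth * tan(object@visualAngle * pi / 360)
  if (abs(object@diameter - expected) > 1e-9) {
    msg <- c(msg, "diameter inconsistent with depth and visualAngle")
  }
  if (length(msg)) msg else TRUE
})

#' FlickerWaveform: a sampled on/off luminance sequence
#'
#' @slot samples numeric vector taking values 0 or the peak intensity
#' @slot sampleRate sampling rate in Hz
#' @slot period flicker period in seconds (1 / frequency)
#' @slot dutyCycle on-fraction of each cycle
#' @slot peakIntensity normalised on-intensity
#' @exportClass FlickerWaveform
setClass("FlickerWaveform",
  representation(
    samples = "numeric",
    sampleRate = "numeric",
    period = "numeric",
    dutyCycle = "numeric",
    peakIntensity = "numeric"
  )
)

setValidity("FlickerWaveform", function(object) {
  ok <- object@samples %in% c(0, object@peakIntensity)
  if (!all(ok)) {
    return("samples must take only the values 0 and peakIntensity")
  }
  TRUE
})

#' TrialSchedule: ordered, timed flicker trials
#'
#' One row per trial with condition labels and the four event times (cue
#' onset, stimulus onset/offset, end of rest), all in seconds from the start
#' of the session.
#'
#' @slot trials data.frame with columns index, environment, depth, frequency,
#'   round, cue_onset, stim_onset, stim_offset, rest_end
#' @slot cueDuration cue length in seconds
#' @slot stimDuration flicker length in seconds
#' @slot restDuration rest length in seconds
#' @exportClass TrialSchedule
setClass("TrialSchedule",
  representation(
    trials = "data.frame",
    cueDuration = "numeric",
    stimDuration = "numeric",
    restDuration = "numeric"
  )
)

setValidity("TrialSchedule", function(object) {
  tr <- object@trials
  need <- c("index", "environment", "depth", "frequency", "round",
            "cue_onset", "stim_onset", "stim_offset", "rest_end")
  if (!all(need %in% names(tr))) {
    return(paste("trials must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(tr) > 1) {
    if (any(diff(tr$cue_onset) <= 0)) {
      return("trials must be strictly increasing in time")
    }
    if (any(tr$cue_onset[-1] < tr$rest_end[-nrow(tr)] - 1e-9)) {
      return("trials must not overlap")
    }
  }
  per <- object@cueDuration + object@stimDuration + object@restDuration
  if (nrow(tr) && abs(max(tr$rest_end) - nrow(tr) * per) > 1e-6) {
    return("total duration must equal n_trials * (cue + stim + rest)")
  }
  TRUE
})

#' GeneratorConfig: synthetic EEG session parameters
#'
#' Parameters of the synthetic multi-channel EEG generator: montage, sampling
#' rate, evoked-component model (fundamental + second harmonic with an
#' occipitally weighted topography) and background-noise model (1/f "pink"
#' noise, white sensor noise and a narrow-band alpha oscillation).
#' The evoked amplitude is either fixed (\code{fundamentalAmplitude}) or
#' calibrated per condition so the spectral SNR of generated trials matches
#' \code{targetSnrDb} in expectation.
#'
#' @slot channelNames electrode labels (default the 9 posterior channels)
#' @slot sampleRate acquisition rate in Hz (default 1000)
#' @slot fundamentalAmplitude fixed evoked amplitude in microvolts; length 0
#'   means "calibrate from targetSnrDb"
#' @slot harmonicRatio second-harmonic amplitude as a fraction of the
#'   fundamental
#' @slot topography per-channel gain applied to the evoked component
#' @slot targetSnrDb data.frame (environment, depth, snr_db) giving the
#'   desired narrow-band SNR per condition
#' @slot noise list with elements pink_exponent, pink_sigma, white_sigma,
#'   alpha_center, alpha_amplitude (microvolts / Hz as appropriate)
#' @slot responseLatency evoked-response onset delay after stimulus onset (s)
#' @slot phaseJitterSd SD (radians) of the per-trial jitter around each
#'   class's stimulus-locked base phase
#' @slot seed integer RNG seed for the session
#' @exportClass GeneratorConfig
setClass("GeneratorConfig",
  representation(
    channelNames = "character",
    sampleRate = "numeric",
    fundamentalAmplitude = "numeric",
    harmonicRatio = "numeric",
    topography = "numeric",
    targetSnrDb = "data.frame",
    noise = "list",
    responseLatency = "numeric",
    phaseJitterSd = "numeric",
    seed = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (length(object@topography) != length(object@channelNames)) {
    msg <- c(msg, "topography must have one gain per channel")
  }
  if (!all(is.finite(object@topography)) || !any(object@topography > 0)) {
    msg <- c(msg, "topography gains must be finite with at least one positive")
  }
  if (object@harmonicRatio < 0) {
    msg <- c(msg, "harmonicRatio must be >= 0")
  }
  need <- c("pink_exponent", "pink_sigma", "white_sigma",
            "alpha_center", "alpha_amplitude")
  if (!all(need %in% names(object@noise))) {
    msg <- c(msg, paste("noise must contain:", paste(need, collapse = ", ")))
  }
  if (nrow(object@targetSnrDb) &&
      !all(c("environment", "depth", "snr_db") %in%
           names(object@targetSnrDb))) {
    msg <- c(msg, "targetSnrDb needs columns environment, depth, snr_db")
  }
  if (length(msg)) msg else TRUE
})

#' EegRecording: continuous multi-channel EEG with event markers
#'
#' @slot signal channels x samples matrix, microvolts
#' @slot sampleRate sampling rate in Hz
#' @slot channelNames unique electrode labels, one per signal row
#' @slot markers data.frame (sample_index, trial_index), stimulus onsets
#' @slot groundTruth data.frame (trial_index, environment, depth, frequency)
#'   or 0-row when truth is unknown
#' @slot metadata free-form list (units, provenance, environment labels, ...)
#' @exportClass EegRecording
setClass("EegRecording",
  representation(
    signal = "matrix",
    sampleRate = "numeric",
    channelNames = "character",
    markers = "data.frame",
    groundTruth = "data.frame",
    metadata = "list"
  )
)

setValidity("EegRecording", function(object) {
  msg <- character()
  if (nrow(object@signal) != length(object@channelNames)) {
    msg <- c(msg, "one channel name per signal row required")
  }
  if (anyDuplicated(object@channelNames)) {
    msg <- c(msg, "channel names must be unique")
  }
  if (nrow(object@markers)) {
    if (!all(c("sample_index", "trial_index") %in% names(object@markers))) {
      msg <- c(msg, "markers need columns sample_index, trial_index")
    } else if (any(object@markers$sample_index < 1) ||
               any(object@markers$sample_index > ncol(object@signal))) {
      msg <- c(msg, "markers must lie within the recording")
    }
  }
  if (length(msg)) msg else TRUE
})

#' EpochSet: trial-segmented multi-channel EEG
#'
#' Epochs are stored as a trials x channels x samples array cut around the
#' stimulus onset; the default window is (-1, +5) s, i.e. a 1-s pre-stimulus
#' baseline followed by the 5-s flicker. Rejected trials stay in the array
#' but are flagged in \code{keptMask}.
#'
#' @slot data numeric array, trials x channels x samples, microvolts
#' @slot sampleRate working sampling rate in Hz
#' @slot window c(start, end) in seconds relative to stimulus onset;
#'   samples are the half-open interval [start, end)
#' @slot labels data.frame (trial_index, environment, depth, frequency)
#' @slot keptMask logical, one flag per trial
#' @slot channelNames labels of the channel dimension
#' @slot provenance list of processing parameters applied so far
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    data = "array",
    sampleRate = "numeric",
    window = "numeric",
    labels = "data.frame",
    keptMask = "logical",
    channelNames = "character",
    provenance = "list"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3) {
    msg <- c(msg, "data must be a trials x channels x samples array")
  } else {
    if (nrow(object@labels) != d[1]) {
      msg <- c(msg, "labels must have one row per trial")
    }
    if (length(object@keptMask) != d[1]) {
      msg <- c(msg, "keptMask must have one entry per trial")
    }
    if (length(object@channelNames) != d[2]) {
      msg <- c(msg, "channelNames must match the channel dimension")
    }
    nExp <- round((object@window[2] - object@window[1]) * object@sampleRate)
    if (d[3] != nExp) {
      msg <- c(msg, "sample count must equal (end - start) * sampleRate")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ReferenceSet: sinusoidal reference templates for CCA decoding
#'
#' For each candidate stimulus frequency f, a matrix of unit-amplitude
#' sine/cosine rows at the harmonics h * f, h = 1..nHarmonics.
#'
#' @slot frequencies candidate stimulus frequencies in Hz
#' @slot nHarmonics number of harmonics per frequency
#' @slot sampleRate sampling rate in Hz
#' @slot nSamples template length in samples
#' @slot refs named list of (2 * nHarmonics) x nSamples matrices
#' @exportClass ReferenceSet
setClass("ReferenceSet",
  representation(
    frequencies = "numeric",
    nHarmonics = "integer",
    sampleRate = "numeric",
    nSamples = "integer",
    refs = "list"
  )
)

setValidity("ReferenceSet", function(object) {
  if (length(object@refs) != length(object@frequencies)) {
    return("one reference matrix per frequency required")
  }
  for (m in object@refs) {
    if (nrow(m) != 2L * object@nHarmonics || ncol(m) != object@nSamples) {
      return("each reference matrix must be (2 * nHarmonics) x nSamples")
    }
  }
  TRUE
})

#' FilterBankSpec: subband decomposition for filter-bank CCA
#'
#' @slot bands list of c(low, high) band edges in Hz
#' @slot order Butterworth design order used for each subband filter
#' @slot weights subband fusion weights w(n) = n^(-1.25) + 0.25
#' @exportClass FilterBankSpec
setClass("FilterBankSpec",
  representation(
    bands = "list",
    order = "integer",
    weights = "numeric"
  )
)

setValidity("FilterBankSpec", function(object) {
  if (length(object@weights) != length(object@bands)) {
    return("one weight per band required")
  }
  if (any(object@weights <= 0)) {
    return("weights must be strictly positive")
  }
  if (length(object@weights) > 1 && any(diff(object@weights) >= 0)) {
    return("weights must be strictly decreasing in the band index")
  }
  TRUE
})

#' TrcaModel: task-related component analysis spatial filters for one class
#'
#' Solves the generalized eigenproblem S_t w = lambda S_n w, where S_t sums
#' the cross-trial covariances (inter-trial consistency) and S_n is the
#' normalisation constraint (total covariance over trials, or the identity).
#' Filters are the generalized eigenvectors, sorted by decreasing
#' eigenvalue and normalised so that w' S_n w = 1.
#'
#' @slot filters channels x channels matrix of spatial filters (columns)
#' @slot eigenvalues generalized eigenvalues, descending
#' @slot st inter-trial covariance matrix S_t
#' @slot sn normalisation matrix S_n
#' @slot template channels x samples mean of the training trials
#' @slot channelNames channel labels the model was trained on
#' @slot frequency class label (stimulus frequency in Hz) or NA
#' @slot nComponents number of components retained by default
#' @exportClass TrcaModel
setClass("TrcaModel",
  representation(
    filters = "matrix",
    eigenvalues = "numeric",
    st = "matrix",
    sn = "matrix",
    template = "matrix",
    channelNames = "character",
    frequency = "numeric",
    nComponents = "integer"
  )
)

setValidity("TrcaModel", function(object) {
  if (length(object@eigenvalues) != ncol(object@filters)) {
    return("one eigenvalue per filter column required")
  }
  if (length(object@eigenvalues) > 1 &&
      any(diff(object@eigenvalues) > 1e-9)) {
    return("eigenvalues must be sorted in decreasing order")
  }
  TRUE
})

#' PipelineConfig: one end-to-end analysis run
#'
#' Bundles schedule design, generator, preprocessing, decoding and
#' evaluation parameters plus the global seed. See \code{\link{runPipeline}}.
#'
#' @slot environments display environments to simulate ("MR", "VR")
#' @slot depths stimulus depths in metres
#' @slot frequencies flicker frequencies in Hz
#' @slot repsPerCell trials per (depth, frequency) cell
#' @slot generator a \linkS4class{GeneratorConfig}
#' @slot preprocessing list(low, high, order, window, targetRate, peakToPeak)
#' @slot decoding list(methods, nHarmonics)
#' @slot evaluation list(nRepetitions, trainFraction)
#' @slot seed global integer seed
#' @slot outDir output directory for reports
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(
    environments = "character",
    depths = "numeric",
    frequencies = "numeric",
    repsPerCell = "integer",
    generator = "GeneratorConfig",
    preprocessing = "list",
    decoding = "list",
    evaluation = "list",
    seed = "integer",
    outDir = "character"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (!length(object@environments)) msg <- c(msg, "need >= 1 environment")
  if (!length(object@depths)) msg <- c(msg, "need >= 1 depth")
  if (!length(object@frequencies)) msg <- c(msg, "need >= 1 frequency")
  if (object@repsPerCell < 1L) msg <- c(msg, "repsPerCell must be >= 1")
  if (length(msg)) msg else TRUE
})
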