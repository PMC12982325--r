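#' Physical diameter of a stimulus subtending a fixed visual angle
#'
#' A disc that subtends a visual angle \eqn{\theta} at viewing distance
#' \eqn{D} has physical diameter \eqn{d = 2 D \tan(\theta / 2)}. Keeping the
#' angle constant across depths equalises the retinal image size, so the
#' rendered disc must grow with distance.
#'
#' @param depth viewing distance in metres (>= 0)
#' @param angle visual angle in degrees, in (0, 180)
#' @return diameter in metres
#' @examples
#' visualAngleToDiameter(1.8, 2.07)   # ~0.065 m, i.e. 6.5 cm
#' @export
visualAngleToDiameter <- function(depth, angle) {
  if (!is.numeric(depth) || any(!is.finite(depth)) || any(depth < 0)) {
    stop("depth must be finite and non-negative (metres)")
  }
  if (!is.numeric(angle) || any(!is.finite(angle)) ||
      any(angle <= 0) || any(angle >= 180)) {
    stop("angle must lie strictly between 0 and 180 degrees")
  }
  2 * depth * tan(angle * pi / 360)
}

#' Frame-locked flicker frequencies for a given refresh rate
#'
#' On a display refreshing at \code{refreshRate} Hz, a flicker period must be
#' a whole number of frames, so admissible frequencies are
#' \code{refreshRate / n} for integer n. At 90 Hz, n = 12, 8 and 5 give
#' 7.5, 11.25 and 18 Hz.
#'
#' @param refreshRate display refresh rate in Hz (> 0)
#' @param nMin,nMax integer range of frames per cycle (1 <= nMin <= nMax;
#'   an empty range returns an empty result)
#' @return data.frame with columns \code{frames_per_cycle} and
#'   \code{frequency}, ordered by frames per cycle
#' @examples
#' admissibleFrequencies(90, 8, 8)   # 11.25 Hz
#' @export
admissibleFrequencies <- function(refreshRate, nMin, nMax) {
  if (refreshRate <= 0) stop("refreshRate must be positive")
  if (nMin < 1) stop("nMin must be >= 1")
  if (nMax < nMin) {
    return(data.frame(frames_per_cycle = integer(), frequency = numeric()))
  }
  n <- seq.int(as.integer(nMin), as.integer(nMax))
  data.frame(frames_per_cycle = n, frequency = refreshRate / n)
}

#' Construct a frame-locked stimulus specification
#'
#' Exactly one of \code{frequency} or \code{framesPerCycle} must be given;
#' the other is derived from the refresh rate. The physical diameter is
#' derived from depth and visual angle via
#' \code{\link{visualAngleToDiameter}}. Duty cycles that do not correspond
#' to a whole number of on-frames are rejected: fractional frames cannot be
#' rendered and would distort the flicker waveform.
#'
#' @param frequency flicker frequency in Hz (must divide the refresh rate)
#' @param framesPerCycle integer number of frames per flicker cycle
#' @param refreshRate display refresh rate in Hz (default 90)
#' @param dutyCycle on-fraction per cycle in (0, 1); default 0.5
#' @param depth viewing distance in metres
#' @param visualAngle angular size in degrees (default 2.07)
#' @param peakIntensity normalised on-intensity (default 1)
#' @return a \linkS4class{StimulusSpec}
#' @examples
#' stimulusSpec(framesPerCycle = 8, depth = 1.8)   # 11.25 Hz at 90 Hz refresh
#' @export
stimulusSpec <- function(frequency = NULL, framesPerCycle = NULL,
                         refreshRate = 90, dutyCycle = 0.5,
                         depth = 1.0, visualAngle = 2.07,
                         peakIntensity = 1) {
  if (is.null(framesPerCycle)) {
    if (is.null(frequency)) stop("give frequency or framesPerCycle")
    framesPerCycle <- refreshRate / frequency
    if (abs(framesPerCycle - round(framesPerCycle)) > 1e-9) {
      stop("frequency ", frequency, " Hz is not frame-locked: it must ",
           "satisfy frequency = refreshRate / n for integer n ",
           "(refresh ", refreshRate, " Hz)")
    }
    framesPerCycle <- as.integer(round(framesPerCycle))
  } else {
    framesPerCycle <- as.integer(framesPerCycle)
  }
  frequency <- refreshRate / framesPerCycle
  new("StimulusSpec",
      frequency = frequency,
      refreshRate = refreshRate,
      framesPerCycle = framesPerCycle,
      dutyCycle = dutyCycle,
      depth = depth,
      visualAngle = visualAngle,
      diameter = visualAngleToDiameter(depth, visualAngle),
      peakIntensity = peakIntensity)
}

#' Sample the square-wave flicker of a stimulus
#'
#' The luminance follows S(t) = Imax while (t mod T) < alpha * T and 0
#' otherwise, with period T = 1/f and duty cycle alpha. The sampling rate
#' must be an integer multiple of the flicker frequency (frame-locked
#' sampling), and alpha times the samples-per-cycle must be integral, so
#' the mean over any whole number of cycles equals alpha exactly.
#'
#' @param spec a \linkS4class{StimulusSpec}
#' @param duration length of the sampled waveform in seconds (>= 0)
#' @param sampleRate sampling rate in Hz; defaults to the refresh rate
#' @return a \linkS4class{FlickerWaveform}
#' @examples
#' w <- squareWave(stimulusSpec(framesPerCycle = 8), duration = 8 / 90)
#' w@samples   # 1 1 1 1 0 0 0 0
#' @export
squareWave <- function(spec, duration, sampleRate = spec@refreshRate) {
  stopifnot(is(spec, "StimulusSpec"))
  if (duration < 0) stop("duration must be >= 0")
  spc <- sampleRate / spec@frequency
  if (abs(spc - round(spc)) > 1e-9) {
    stop("sampleRate must be an integer multiple of the flicker frequency; ",
         "pick a frame-locked frequency f = refreshRate / n")
  }
  spc <- as.integer(round(spc))
  onSamples <- spec@dutyCycle * spc
  if (abs(onSamples - round(onSamples)) > 1e-9) {
    stop("dutyCycle * samplesPerCycle must be integral (whole on-frames)")
  }
  onSamples <- as.integer(round(onSamples))
  n <- as.integer(round(duration * sampleRate))
  phase <- (seq_len(n) - 1L) %% spc
  samples <- ifelse(phase < onSamples, spec@peakIntensity, 0)
  new("FlickerWaveform",
      samples = as.numeric(samples),
      sampleRate = sampleRate,
      period = 1 / spec@frequency,
      dutyCycle = spec@dutyCycle,
      peakIntensity = spec@peakIntensity)
}

#' Build a blocked trial schedule
#'
#' One session presents every (depth, frequency) cell \code{repsPerCell}
#' times per environment. Each trial is a 1-s fixation cue, a 5-s flicker
#' and a 3-s rest by default. Ordering is blocked: within an environment,
#' trials are grouped by depth and, within a depth block, by frequency in
#' sub-blocks of \code{repsPerCell} consecutive flashes
#' (\code{order = "blocked"}), or fully randomised within the environment
#' (\code{order = "random"}).
#'
#' @param environments character vector of display environments (e.g. "MR",
#'   "VR"); sessions are concatenated in this order
#' @param depths stimulus depths in metres
#' @param frequencies flicker frequencies in Hz
#' @param repsPerCell trials per (depth, frequency) cell (>= 1)
#' @param cueDuration,stimDuration,restDuration per-trial segment lengths
#'   in seconds (defaults 1, 5, 3)
#' @param ordering "blocked" (default) or "random"
#' @param rounds number of repeats of the whole per-environment block;
#'   analysis pools rounds
#' @param seed RNG seed used when \code{order = "random"}
#' @return a \linkS4class{TrialSchedule}
#' @examples
#' sched <- buildSchedule("MR", c(0.4, 1, 1.8), c(7.5, 11.25, 18), 10)
#' nTrials(sched)        # 90
#' totalDuration(sched)  # 810 s = 13.5 min
#' @export
buildSchedule <- function(environments = "MR",
                          depths = c(0.4, 1.0, 1.8),
                          frequencies = c(7.5, 11.25, 18),
                          repsPerCell = 10,
                          cueDuration = 1, stimDuration = 5,
                          restDuration = 3,
                          ordering = c("blocked", "random"),
                          rounds = 1, seed = 1L) {
  ordering <- match.arg(ordering)
  if (!length(environments) || !length(depths) || !length(frequencies)) {
    stop("environments, depths and frequencies must be non-empty")
  }
  if (repsPerCell < 1) stop("repsPerCell must be >= 1")
  if (cueDuration <= 0 || stimDuration <= 0 || restDuration <= 0) {
    stop("durations must be positive")
  }
  rows <- list()
  for (env in environments) {
    for (rnd in seq_len(rounds)) {
      block <- expand.grid(frequency = frequencies, depth = depths,
                           rep = seq_len(repsPerCell),
                           KEEP.OUT.ATTRS = FALSE)
      # blocked: depth blocks, frequency sub-blocks of repsPerCell flashes
      block <- block[order(match(block$depth, depths),
                           match(block$frequency, frequencies),
                           block$rep), ]
      if (ordering == "random") {
        block <- .withSeed(.subSeed(seed, paste0(env, rnd)),
                           block[sample.int(nrow(block)), ])
      }
      block$environment <- env
      block$round <- rnd
      rows[[length(rows) + 1L]] <- block
    }
  }
  tab <- do.call(rbind, rows)
  n <- nrow(tab)
  per <- cueDuration + stimDuration + restDuration
  start <- (seq_len(n) - 1L) * per
  trials <- data.frame(
    index = seq_len(n),
    environment = tab$environment,
    depth = tab$depth,
    frequency = tab$frequency,
    round = tab$round,
    cue_onset = start,
    stim_onset = start + cueDuration,
    stim_offset = start + cueDuration + stimDuration,
    rest_end = start + per,
    row.names = NULL)
  new("TrialSchedule", trials = trials,
      cueDuration = cueDuration, stimDuration = stimDuration,
      restDuration = restDuration)
}
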