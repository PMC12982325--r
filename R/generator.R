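#' Default per-condition SNR targets
#'
#' Narrow-band SNR (dB) the generator aims for per (environment, depth)
#' condition: decreasing with depth and lower in VR than MR, the orderings
#' reported for real recordings. MR targets are 1.8, 1.4 and 1.0 dB at
#' 0.4, 1.0 and 1.8 m; VR sits 0.85 dB below MR at every depth.
#'
#' @param environments environments to include
#' @param depths depths (m) to include
#' @return data.frame with columns environment, depth, snr_db
#' @export
defaultSnrTargets <- function(environments = c("MR", "VR"),
                              depths = c(0.4, 1.0, 1.8)) {
  mr <- c(`0.4` = 1.8, `1` = 1.4, `1.8` = 1.0)
  grid <- expand.grid(depth = depths, environment = environments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- mr[as.character(grid$depth)]
  if (any(is.na(base))) {
    # linear interpolation in depth for non-standard depths
    base[is.na(base)] <- stats::approx(c(0.4, 1.0, 1.8), c(1.8, 1.4, 1.0),
                                       xout = grid$depth[is.na(base)],
                                       rule = 2)$y
  }
  grid$snr_db <- unname(base) - ifelse(grid$environment == "VR", 0.85, 0)
  grid[, c("environment", "depth", "snr_db")]
}

#' Default occipitally weighted topography
#'
#' Evoked-component gain per channel: largest over the midline occipital
#' sites, smallest at Pz, reflecting the occipital dominance of SSVEPs.
#'
#' @param channels channel labels
#' @return named numeric gain vector
#' @export
defaultTopography <- function(channels = standardChannels()) {
  gains <- c(Oz = 1.0, O1 = 0.9, O2 = 0.9, PO3 = 0.7, PO4 = 0.7,
             PO5 = 0.7, PO6 = 0.7, POz = 1.0, Pz = 0.5)
  out <- gains[channels]
  out[is.na(out)] <- 0.7
  names(out) <- channels
  out
}

#' Construct a synthetic-EEG generator configuration
#'
#' @param channelNames electrode labels (default 9 posterior channels)
#' @param sampleRate acquisition rate in Hz (default 1000)
#' @param fundamentalAmplitude fixed evoked amplitude in microvolts, or NULL
#'   (default) to calibrate each condition to \code{targetSnrDb}
#' @param harmonicRatio second-harmonic amplitude relative to the
#'   fundamental (default 0.5)
#' @param topography per-channel evoked gain (default occipital weighting)
#' @param targetSnrDb data.frame (environment, depth, snr_db); default
#'   \code{\link{defaultSnrTargets}()}
#' @param noise list(pink_exponent, pink_sigma, white_sigma, alpha_center,
#'   alpha_amplitude, spatial_coherence); sigma/amplitude entries are RMS
#'   microvolts, spatial_coherence is the fraction of pink-noise power in
#'   the spatially shared component. The default places a 10 Hz alpha
#'   component deliberately close to the 11.25 Hz stimulus to stress the
#'   decoders.
#' @param responseLatency evoked onset delay after stimulus onset (s)
#' @param phaseJitterSd SD in radians of the per-trial phase jitter around
#'   each class's stimulus-locked base phase (default 0.2). SSVEPs are
#'   phase-locked to the flicker, which is what task-related component
#'   analysis exploits; the jitter models physiological latency variation.
#' @param seed integer RNG seed
#' @return a \linkS4class{GeneratorConfig}
#' @export
generatorConfig <- function(channelNames = standardChannels(),
                            sampleRate = 1000,
                            fundamentalAmplitude = NULL,
                            harmonicRatio = 0.5,
                            topography = defaultTopography(channelNames),
                            targetSnrDb = defaultSnrTargets(),
                            noise = list(pink_exponent = 1,
                                         pink_sigma = 10,
                                         white_sigma = 2,
                                         alpha_center = 10,
                                         alpha_amplitude = 4,
                                         spatial_coherence = 0.9),
                            responseLatency = 0.14,
                            phaseJitterSd = 0.2,
                            seed = 1L) {
  new("GeneratorConfig",
      channelNames = channelNames,
      sampleRate = sampleRate,
      fundamentalAmplitude = as.numeric(fundamentalAmplitude %||% numeric()),
      harmonicRatio = harmonicRatio,
      topography = as.numeric(topography),
      targetSnrDb = targetSnrDb,
      noise = noise,
      responseLatency = responseLatency,
      phaseJitterSd = phaseJitterSd,
      seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Real-valued noise with a prescribed amplitude-spectrum shape, synthesised
# in the frequency domain with random phases. Normalised to unit RMS
# analytically (not per realisation), so the process is exactly stationary
# Gaussian with identical statistics at any record length.
.spectralNoise <- function(n, fs, magnitude) {
  m <- floor(n / 2)
  f <- (1:m) * fs / n
  mag <- magnitude(f)
  h <- mag * complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  if (n %% 2 == 0) {
    h[m] <- complex(real = Re(h[m]), imaginary = 0)
    tot <- 4 * sum(mag[-m]^2) + mag[m]^2
  } else {
    tot <- 4 * sum(mag^2)
  }
  spec <- c(0, h, if (n %% 2 == 0) Conj(rev(h[-m])) else Conj(rev(h)))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  if (tot == 0) x else x * (n / sqrt(tot))
}

# Multi-channel background activity. Scalp EEG over a compact posterior
# montage is strongly spatially correlated (volume conduction), so the 1/f
# ("pink") background is split into a shared component added coherently to
# every channel (fraction `spatial_coherence` of the pink power) and an
# independent residual per channel; broadband white sensor noise is
# independent per channel; the narrow-band alpha oscillation is one shared
# posterior source.
.backgroundMatrix <- function(C, n, fs, noise) {
  coh <- noise$spatial_coherence %||% 0.9
  pinkMag <- function(f) {
    ifelse(f >= 0.1, f^(-noise$pink_exponent / 2), 0)
  }
  shared <- .spectralNoise(n, fs, pinkMag) * noise$pink_sigma * sqrt(coh)
  out <- matrix(NA_real_, C, n)
  for (c in seq_len(C)) {
    pink <- .spectralNoise(n, fs, pinkMag) *
      noise$pink_sigma * sqrt(1 - coh)
    white <- stats::rnorm(n) * noise$white_sigma
    out[c, ] <- pink + white
  }
  alpha <- .spectralNoise(n, fs, function(f) {
    exp(-(f - noise$alpha_center)^2 / 2)
  }) * noise$alpha_amplitude
  sweep(out, 2, shared + alpha, `+`)
}

# Preprocess one raw-rate trial matrix the same way the analysis chain does:
# zero-phase band-pass then anti-aliased decimation.
.calibrationPreproc <- function(x, fs, preprocessing) {
  x <- .bandpassMatrix(x, preprocessing$low, preprocessing$high,
                       preprocessing$order, fs)
  .decimateMatrix(x, fs, preprocessing$targetRate)
}

# Memoised store of preprocessed calibration noise trials (they depend only
# on the noise model, montage size, durations, preprocessing and the fixed
# calibration seed — not on the stimulus frequency or session seed).
.calCache <- new.env(parent = emptyenv())

.calNoiseTrials <- function(config, stimDuration, preprocessing,
                            nTrialsCal, calibrationSeed) {
  fs <- config@sampleRate
  C <- length(config@channelNames)
  key <- paste(C, fs, stimDuration, nTrialsCal, calibrationSeed,
               paste(unlist(config@noise), collapse = ","),
               paste(unlist(preprocessing), collapse = ","), sep = "|")
  if (!is.null(.calCache[[key]])) return(.calCache[[key]])
  nRaw <- round(stimDuration * fs)
  trials <- .withSeed(calibrationSeed, {
    lapply(seq_len(nTrialsCal), function(j) {
      .calibrationPreproc(.backgroundMatrix(C, nRaw, fs, config@noise),
                          fs, preprocessing)
    })
  })
  .calCache[[key]] <- trials
  trials
}

# Per-trial, per-channel spectral powers of preprocessed noise-only trials:
# at f0 and 2*f0 and averaged over the two noise neighbourhoods. Used by the
# amplitude calibration.
.noisePowerEstimate <- function(config, f0, stimDuration, preprocessing,
                                nTrialsCal, calibrationSeed) {
  trials <- .calNoiseTrials(config, stimDuration, preprocessing,
                            nTrialsCal, calibrationSeed)
  C <- length(config@channelNames)
  fsW <- preprocessing$targetRate
  zf0 <- z2f0 <- matrix(NA_complex_, length(trials), C)
  pnoise <- matrix(NA_real_, length(trials), C)
  for (j in seq_along(trials)) {
    xw <- trials[[j]]
    n <- ncol(xw)
    T <- n / fsW
    nf <- .noiseFrequencies(f0, T, 1.0, 0.1)
    tt <- (seq_len(n) - 1L) / fsW
    # complex spectral amplitudes at the peaks (normalised like .powerAt),
    # so the signal-plus-noise cross term can be modelled exactly
    zf0[j, ] <- sqrt(2) / n * (xw %*% exp(-2i * pi * tt * f0))
    z2f0[j, ] <- sqrt(2) / n * (xw %*% exp(-2i * pi * tt * 2 * f0))
    # per-component background means, summed (see snrDb)
    nearF0 <- abs(nf - f0) <= 1 + 1e-9
    pn <- .powerAt(xw, nf, fsW)
    pnoise[j, ] <- rowMeans(pn[, nearF0, drop = FALSE]) +
      rowMeans(pn[, !nearF0, drop = FALSE])
  }
  list(zf0 = zf0, z2f0 = z2f0, pnoise = pnoise)
}

#' Calibrate the evoked amplitude for a target SNR
#'
#' Finds the fundamental amplitude (microvolts, at the topography-gain-1
#' reference channel) whose expected narrow-band SNR — measured by
#' \code{\link{snrDb}} after the standard preprocessing chain — equals
#' \code{targetDb}. The expected per-trial SNR is modelled from a fixed-seed
#' Monte-Carlo estimate of the preprocessed noise spectrum, with the
#' deterministic sinusoid power added analytically, and solved by bisection.
#'
#' @param config a \linkS4class{GeneratorConfig}
#' @param frequency stimulus fundamental in Hz
#' @param targetDb desired SNR in dB; \code{-Inf} returns amplitude 0
#' @param stimDuration analysed stimulus window in seconds (default 5)
#' @param preprocessing list(low, high, order, targetRate) matching the
#'   analysis chain
#' @param nTrialsCal Monte-Carlo noise trials (default 384; estimate is memoised)
#' @param calibrationSeed fixed seed for the noise estimate
#' @return fundamental amplitude in microvolts
#' @export
calibrateAmplitude <- function(config, frequency, targetDb,
                               stimDuration = 5,
                               preprocessing = list(low = 0.1, high = 40,
                                                    order = 4,
                                                    targetRate = 250),
                               nTrialsCal = 384,
                               calibrationSeed = 20260117) {
  if (identical(targetDb, -Inf)) return(0)
  g <- config@topography
  if (all(g == 0)) stop("unattainable target: topography is identically zero")
  est <- .noisePowerEstimate(config, frequency, stimDuration, preprocessing,
                             nTrialsCal, calibrationSeed)
  nCal <- nrow(est$pnoise)
  gmat <- matrix(g, nCal, length(g), byrow = TRUE)
  # deterministic attenuation of the evoked sinusoids: zero-phase band-pass
  # and anti-alias gains at f0 / 2 f0, and the response-latency duty factor
  # (the evoked covers only (stimDuration - latency) of the window)
  fs <- config@sampleRate
  # power gain of the zero-phase chain: amplitude response is |H1|^2, so
  # the sinusoid's power is scaled by its square
  filtGain <- function(f) {
    (.butterGainSq(f, preprocessing$order, fs, "pass",
                   low = preprocessing$low, high = preprocessing$high) *
       .butterGainSq(f, 4, fs, "low",
                     high = 0.8 * preprocessing$targetRate / 2))^2
  }
  latF <- (stimDuration - config@responseLatency) / stimDuration
  s1 <- latF * sqrt(filtGain(frequency) / 2)
  s2 <- config@harmonicRatio * latF * sqrt(filtGain(2 * frequency) / 2)
  # fixed random evoked phases per calibration trial (shared across
  # channels, as in generation) so the signal-noise cross term is included
  phi <- .withSeed(calibrationSeed + 1L,
                   matrix(stats::runif(2 * nCal, 0, 2 * pi), nCal, 2))
  e1 <- matrix(exp(1i * phi[, 1]), nCal, length(g))
  e2 <- matrix(exp(1i * phi[, 2]), nCal, length(g))
  meanDb <- function(a) {
    num <- rowMeans(Mod(est$zf0 + a * gmat * s1 * e1)^2 +
                    Mod(est$z2f0 + a * gmat * s2 * e2)^2)
    den <- rowMeans(est$pnoise)
    mean(10 * log10(num / den))
  }
  floorDb <- meanDb(0)
  if (targetDb <= floorDb) {
    if (targetDb < floorDb - 0.5) {
      warning(sprintf(
        "target %.2f dB is below the noise floor (%.2f dB); returning 0",
        targetDb, floorDb))
    }
    return(0)
  }
  upper <- 1
  while (meanDb(upper) < targetDb && upper < 1e6) upper <- upper * 4
  stats::uniroot(function(a) meanDb(a) - targetDb, c(0, upper),
                 tol = 1e-8)$root
}

#' Simulate a synthetic EEG session for a trial schedule
#'
#' Generates continuous multi-channel background activity (1/f + white +
#' alpha) for the full session and, during each stimulus window, adds an
#' evoked component: a fundamental sinusoid at the trial's flicker frequency
#' plus a second harmonic at \code{harmonicRatio} of its amplitude, with a
#' stimulus-locked base phase per class and small per-trial jitter
#' (\code{phaseJitterSd}), scaled per channel by the
#' topography and per condition by a calibrated amplitude so the measured
#' narrow-band SNR matches the configured target in expectation. The evoked
#' response starts \code{responseLatency} seconds after stimulus onset.
#' Output is bit-identical for a fixed config seed.
#'
#' @param config a \linkS4class{GeneratorConfig}
#' @param schedule a \linkS4class{TrialSchedule}
#' @return an \linkS4class{EegRecording} with markers and ground truth
#' @export
simulateSession <- function(config, schedule) {
  stopifnot(is(config, "GeneratorConfig"), is(schedule, "TrialSchedule"))
  tr <- trialInfo(schedule)
  if (!nrow(tr)) stop("schedule is empty")
  fs <- config@sampleRate

  # resolve the evoked amplitude for every condition before touching the
  # session RNG stream (calibration uses its own fixed seed)
  conds <- unique(tr[, c("environment", "depth", "frequency")])
  if (length(config@fundamentalAmplitude) == 1L) {
    conds$amplitude <- config@fundamentalAmplitude
  } else {
    tgt <- merge(conds, config@targetSnrDb,
                 by = c("environment", "depth"), all.x = TRUE)
    if (any(is.na(tgt$snr_db))) {
      bad <- tgt[is.na(tgt$snr_db), c("environment", "depth")]
      stop("targetSnrDb has no entry for condition(s): ",
           paste(unique(paste0(bad$environment, "/", bad$depth, " m")),
                 collapse = ", "))
    }
    key <- paste(tgt$frequency, tgt$snr_db)
    amp <- vapply(unique(key), function(k) {
      row <- tgt[match(k, key), ]
      calibrateAmplitude(config, row$frequency, row$snr_db,
                         stimDuration = schedule@stimDuration)
    }, numeric(1))
    tgt$amplitude <- amp[key]
    conds <- merge(conds, tgt[, c("environment", "depth", "frequency",
                                  "amplitude")],
                   by = c("environment", "depth", "frequency"))
  }

  n <- round(totalDuration(schedule) * fs)
  C <- length(config@channelNames)
  hr <- config@harmonicRatio
  lat <- config@responseLatency

  .withSeed(config@seed, {
    signal <- .backgroundMatrix(C, n, fs, config@noise)
    # stimulus-locked base phase per class (SSVEPs are phase-locked to the
    # flicker; TRCA relies on this inter-trial consistency), with small
    # per-trial physiological jitter
    classFreqs <- sort(unique(tr$frequency))
    base1 <- stats::runif(length(classFreqs), 0, 2 * pi)
    base2 <- stats::runif(length(classFreqs), 0, 2 * pi)
    names(base1) <- names(base2) <- as.character(classFreqs)
    for (i in seq_len(nrow(tr))) {
      row <- tr[i, ]
      a <- conds$amplitude[conds$environment == row$environment &
                           conds$depth == row$depth &
                           conds$frequency == row$frequency]
      jit <- stats::rnorm(2, 0, config@phaseJitterSd)
      phi1 <- base1[as.character(row$frequency)] + jit[1]
      phi2 <- base2[as.character(row$frequency)] + jit[2]
      if (a <= 0) next
      onset <- row$stim_onset + lat
      i0 <- floor(onset * fs) + 1L
      i1 <- round(row$stim_offset * fs)
      tau <- (seq.int(i0, i1) - 1L) / fs - onset
      wave <- a * (sin(2 * pi * row$frequency * tau + phi1) +
                   hr * sin(2 * pi * 2 * row$frequency * tau + phi2))
      signal[, i0:i1] <- signal[, i0:i1] +
        outer(config@topography, wave)
    }
    rownames(signal) <- config@channelNames
    new("EegRecording",
        signal = signal,
        sampleRate = fs,
        channelNames = config@channelNames,
        markers = data.frame(sample_index =
                               as.integer(round(tr$stim_onset * fs)) + 1L,
                             trial_index = as.integer(tr$index)),
        groundTruth = data.frame(trial_index = tr$index,
                                 environment = tr$environment,
                                 depth = tr$depth,
                                 frequency = tr$frequency),
        metadata = list(generator = list(
          seed = config@seed,
          harmonic_ratio = hr,
          response_latency = lat,
          phase_jitter_sd = config@phaseJitterSd,
          noise = config@noise,
          amplitudes = conds)))
  })
}
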