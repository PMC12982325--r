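# Shared fixtures, all generated in code.

# A small raw recording built by hand: known sinusoids + white noise,
# markers at given onsets. channels x samples at `fs`.
makeToyRecording <- function(nTrials = 4, fs = 250, trialSpacing = 7,
                             freq = 11.25, amplitude = 0, noiseSd = 1,
                             nChannels = 3, seed = 1) {
  n <- round((nTrials * trialSpacing + 2) * fs)
  set.seed(seed)
  sig <- matrix(rnorm(nChannels * n, sd = noiseSd), nChannels, n)
  onsets <- (seq_len(nTrials) - 1) * trialSpacing + 1.5
  if (amplitude > 0) {
    for (k in seq_len(nTrials)) {
      idx <- round(onsets[k] * fs) + seq_len(5 * fs)
      tt <- (idx - 1) / fs
      sig[, idx] <- sig[, idx] +
        rep(amplitude * sin(2 * pi * freq * tt), each = nChannels)
    }
  }
  chn <- paste0("ch", seq_len(nChannels))
  rownames(sig) <- chn
  new("EegRecording", signal = sig, sampleRate = fs, channelNames = chn,
      markers = data.frame(sample_index = as.integer(round(onsets * fs)) + 1L,
                           trial_index = seq_len(nTrials)),
      groundTruth = data.frame(trial_index = seq_len(nTrials),
                               environment = "MR", depth = 1.0,
                               frequency = freq),
      metadata = list())
}

# An EpochSet of planted-sinusoid epochs (stimulus window only) for decoder
# tests: trials x channels x samples at `fs`, labels carrying the true
# frequency. `snrScale` controls the sinusoid amplitude relative to unit
# white noise.
makePlantedEpochs <- function(freqs = c(7.5, 11.25, 18), repsPerFreq = 4,
                              fs = 250, nSamples = 1250, nChannels = 4,
                              snrScale = 0.35, harmonicRatio = 0.5,
                              seed = 7, lockPhase = FALSE) {
  set.seed(seed)
  labels <- rep(freqs, each = repsPerFreq)
  nT <- length(labels)
  dat <- array(rnorm(nT * nChannels * nSamples), c(nT, nChannels, nSamples))
  gains <- seq(1, 0.5, length.out = nChannels)
  tt <- (seq_len(nSamples) - 1) / fs
  classPhi <- matrix(runif(2 * length(freqs), 0, 2 * pi), ncol = 2,
                     dimnames = list(as.character(freqs), NULL))
  for (i in seq_len(nT)) {
    phi <- if (lockPhase) classPhi[as.character(labels[i]), ]
           else runif(2, 0, 2 * pi)
    wave <- snrScale * (sin(2 * pi * labels[i] * tt + phi[1]) +
                        harmonicRatio * sin(2 * pi * 2 * labels[i] * tt +
                                            phi[2]))
    dat[i, , ] <- dat[i, , ] + outer(gains, wave)
  }
  new("EpochSet", data = dat, sampleRate = fs, window = c(0, nSamples / fs),
      labels = data.frame(trial_index = seq_len(nT), environment = "MR",
                          depth = 1.0, frequency = labels),
      keptMask = rep(TRUE, nT),
      channelNames = paste0("ch", seq_len(nChannels)),
      provenance = list())
}

# 95% binomial confidence band for chance-level (1/3) accuracy.
chanceBand <- function(n) {
  p <- 1 / 3
  c(p - 1.96 * sqrt(p * (1 - p) / n), p + 1.96 * sqrt(p * (1 - p) / n))
}
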