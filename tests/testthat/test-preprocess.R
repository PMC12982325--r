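test_that("band-pass matches the designed Butterworth response", {
  skip_if_not_installed("signal")
  fs <- 1000
  n <- 20 * fs
  tt <- (seq_len(n) - 1) / fs
  fitAmp <- function(y, f) {
    keep <- (2 * fs):(n - 2 * fs)   # trim edges
    co <- coef(lm(y[keep] ~ sin(2 * pi * f * tt[keep]) +
                    cos(2 * pi * f * tt[keep])))
    sqrt(co[2]^2 + co[3]^2)
  }
  mkRec <- function(x) {
    m <- matrix(x, 1, n, dimnames = list("Oz", NULL))
    new("EegRecording", signal = m, sampleRate = fs, channelNames = "Oz",
        markers = data.frame(sample_index = integer(),
                             trial_index = integer()),
        groundTruth = data.frame(), metadata = list())
  }
  # oracle: squared magnitude of the recursive design (two passes)
  bf <- signal::butter(4, c(0.1, 40) / (fs / 2), type = "pass")
  oracle <- function(f) {
    h <- signal::freqz(bf, Fs = fs, n = 2^14)
    Mod(h$h[which.min(abs(h$f - f))])^2
  }

  zero <- bandpass(mkRec(rep(0, n)))
  expect_true(all(zero@signal == 0))

  inband <- bandpass(mkRec(sin(2 * pi * 10 * tt)))
  expect_equal(unname(fitAmp(inband@signal[1, ], 10)), oracle(10),
               tolerance = 0.05)
  outband <- bandpass(mkRec(sin(2 * pi * 50 * tt)))
  expect_equal(unname(fitAmp(outband@signal[1, ], 50)), oracle(50),
               tolerance = 0.10)

  expect_error(bandpass(mkRec(rep(0, n)), low = 0.1, high = 600),
               "Nyquist")
  expect_error(bandpass(mkRec(rep(0, n)), low = 50, high = 40), "edges")
})

test_that("epoching cuts exact half-open windows with labels attached", {
  rec <- makeToyRecording(nTrials = 4, fs = 250)
  ep <- epochRecording(rec, c(-1, 5))
  expect_equal(dim(ep@data), c(4L, 3L, 1500L))
  expect_equal(trialInfo(ep)$frequency, rep(11.25, 4))
  # epoch content equals the corresponding slice of the recording
  i0 <- rec@markers$sample_index[2] - 250
  expect_equal(ep@data[2, , ], unname(rec@signal[, i0:(i0 + 1499)]))

  empty <- initialize(rec,
                      markers = data.frame(sample_index = integer(),
                                           trial_index = integer()))
  ep0 <- epochRecording(empty, c(-1, 5))
  expect_equal(nTrials(ep0), 0L)

  bad <- initialize(rec,
                    markers = data.frame(sample_index = c(100L, 2000L),
                                         trial_index = 1:2))
  expect_error(epochRecording(bad, c(-1, 5)), "trial\\(s\\): 1")
})

test_that("decimation preserves in-band content at the exact factor", {
  rec <- makeToyRecording(nTrials = 3, fs = 1000, noiseSd = 0)
  tt <- (seq_len(ncol(rec@signal)) - 1) / 1000
  sig <- rbind(sin(2 * pi * 11.25 * tt),
               rep(1, length(tt)),
               sin(2 * pi * 11.25 * tt))
  rownames(sig) <- rec@channelNames
  rec@signal <- sig
  ep <- epochRecording(rec, c(-1, 5))
  expect_equal(dim(ep@data)[3], 6000L)
  dec <- decimateEpochs(ep, 250)
  expect_equal(dim(dec@data)[3], 1500L)
  expect_equal(sampleRate(dec), 250)
  # DC preserved exactly-ish
  expect_equal(dec@data[1, 2, ], rep(1, 1500), tolerance = 1e-6)
  # 11.25 Hz amplitude preserved within 2% against the closed-form sinusoid
  onset <- (rec@markers$sample_index[1] - 1) / 1000 - 1
  t250 <- onset + (seq_len(1500) - 1) / 250
  co <- coef(lm(dec@data[1, 1, ] ~ sin(2 * pi * 11.25 * t250) +
                  cos(2 * pi * 11.25 * t250)))
  expect_equal(unname(sqrt(co[2]^2 + co[3]^2)), 1, tolerance = 0.02)

  expect_error(decimateEpochs(ep, 300), "integer")
})

test_that("peak-to-peak rejection flags exactly the constructed exceedance", {
  rec <- makeToyRecording(nTrials = 5, fs = 250, noiseSd = 5)
  ep <- epochRecording(rec, c(-1, 5))
  clean <- rejectArtifacts(ep, peakToPeak = 1e6)
  expect_true(all(keptMask(clean)))

  burst <- ep
  burst@data[3, 2, 700:720] <- burst@data[3, 2, 700:720] + 500
  rej <- rejectArtifacts(burst, peakToPeak = 200)
  expect_identical(which(!keptMask(rej)), 3L)
  expect_equal(nTrials(keptEpochs(rej)), 4L)

  noop <- rejectArtifacts(burst, peakToPeak = Inf)
  expect_identical(keptMask(noop), keptMask(burst))
  expect_error(rejectArtifacts(ep, peakToPeak = -1))
})

test_that("stimulus and baseline windows partition the epoch", {
  rec <- makeToyRecording(nTrials = 2, fs = 250)
  ep <- epochRecording(rec, c(-1, 5))
  stim <- stimulusWindow(ep, 5)
  base <- baselineWindow(ep)
  expect_equal(dim(stim@data)[3], 1250L)
  expect_equal(dim(base@data)[3], 250L)
  expect_equal(stim@window, c(0, 5))
  expect_equal(base@window, c(-1, 0))
  recon <- array(NA_real_, dim(ep@data))
  recon[, , 1:250] <- base@data
  recon[, , 251:1500] <- stim@data
  expect_identical(recon, ep@data)
  expect_error(stimulusWindow(ep, 7), "exceeds")
})
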