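#' Zero-phase Butterworth band-pass of a continuous recording
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to every
#' channel, with odd-symmetric reflection padding to suppress edge
#' transients. Length is preserved.
#'
#' @param raw an \linkS4class{EegRecording}
#' @param low,high band edges in Hz; must satisfy 0 < low < high < Nyquist
#' @param order Butterworth design order (default 4)
#' @return the filtered \linkS4class{EegRecording}
#' @export
bandpass <- function(raw, low = 0.1, high = 40, order = 4) {
  stopifnot(is(raw, "EegRecording"))
  filtered <- .bandpassMatrix(raw@signal, low, high, order, raw@sampleRate)
  rownames(filtered) <- raw@channelNames
  initialize(raw, signal = filtered,
             metadata = c(raw@metadata,
                          list(bandpass = list(low = low, high = high,
                                               order = order))))
}

#' Segment a continuous recording into trial epochs
#'
#' Cuts one epoch per marker over the half-open window
#' [\code{window[1]}, \code{window[2]}) seconds relative to the marker
#' (stimulus onset). Labels are copied from the recording's ground truth
#' when present.
#'
#' @param raw an \linkS4class{EegRecording}
#' @param window c(start, end) in seconds relative to each marker; default
#'   c(-1, 5): a 1-s baseline plus the 5-s stimulus
#' @return an \linkS4class{EpochSet}
#' @export
epochRecording <- function(raw, window = c(-1, 5)) {
  stopifnot(is(raw, "EegRecording"), length(window) == 2,
            window[1] < window[2])
  fs <- raw@sampleRate
  nSamp <- round((window[2] - window[1]) * fs)
  mk <- raw@markers
  C <- nrow(raw@signal)
  if (!nrow(mk)) {
    return(new("EpochSet",
               data = array(numeric(), c(0L, C, nSamp)),
               sampleRate = fs, window = as.numeric(window),
               labels = data.frame(trial_index = integer(),
                                   environment = character(),
                                   depth = numeric(), frequency = numeric()),
               keptMask = logical(), channelNames = raw@channelNames,
               provenance = list(window = window)))
  }
  start <- mk$sample_index + round(window[1] * fs)
  end <- start + nSamp - 1L
  bad <- start < 1 | end > ncol(raw@signal)
  if (any(bad)) {
    stop("epoch window out of bounds for trial(s): ",
         paste(mk$trial_index[bad], collapse = ", "))
  }
  dat <- array(NA_real_, c(nrow(mk), C, nSamp))
  for (i in seq_len(nrow(mk))) {
    dat[i, , ] <- raw@signal[, start[i]:end[i]]
  }
  gt <- raw@groundTruth
  labels <- if (nrow(gt)) {
    gt[match(mk$trial_index, gt$trial_index),
       c("trial_index", "environment", "depth", "frequency")]
  } else {
    data.frame(trial_index = mk$trial_index, environment = NA_character_,
               depth = NA_real_, frequency = NA_real_)
  }
  rownames(labels) <- NULL
  new("EpochSet", data = dat, sampleRate = fs,
      window = as.numeric(window), labels = labels,
      keptMask = rep(TRUE, nrow(mk)), channelNames = raw@channelNames,
      provenance = list(window = window, source = raw@metadata))
}

# Anti-aliased integer-factor decimation of a channels x samples matrix:
# zero-phase Butterworth low-pass at 80% of the new Nyquist, then take
# every q-th sample.
.decimateMatrix <- function(x, fs, targetRate) {
  q <- fs / targetRate
  if (abs(q - round(q)) > 1e-9) {
    stop("sampleRate must be an integer multiple of targetRate")
  }
  q <- as.integer(round(q))
  if (q == 1L) return(x)
  y <- .lowpassMatrix(x, 0.8 * targetRate / 2, 4, fs)
  y[, seq.int(1L, ncol(x), by = q), drop = FALSE]
}

#' Decimate epochs to a lower working rate
#'
#' Integer-factor downsampling with a zero-phase anti-alias low-pass (the
#' data are normally already band-limited well below the new Nyquist by the
#' 0.1-40 Hz band-pass). Epoch length scales by the exact rational factor.
#'
#' @param epochs an \linkS4class{EpochSet}
#' @param targetRate new sampling rate in Hz; must divide the current rate
#' @return the decimated \linkS4class{EpochSet}
#' @export
decimateEpochs <- function(epochs, targetRate = 250) {
  stopifnot(is(epochs, "EpochSet"))
  fs <- epochs@sampleRate
  q <- fs / targetRate
  if (abs(q - round(q)) > 1e-9) {
    stop("decimation factor must be an integer (", fs, " -> ", targetRate,
         " Hz)")
  }
  d <- dim(epochs@data)
  if (d[1] == 0L) {
    return(initialize(epochs,
                      data = array(numeric(),
                                   c(0L, d[2], as.integer(d[3] / q))),
                      sampleRate = targetRate))
  }
  nNew <- as.integer(d[3] / round(q))
  out <- array(NA_real_, c(d[1], d[2], nNew))
  for (i in seq_len(d[1])) {
    out[i, , ] <- .decimateMatrix(epochs@data[i, , , drop = TRUE], fs,
                                  targetRate)
  }
  initialize(epochs, data = out, sampleRate = targetRate,
             provenance = c(epochs@provenance,
                            list(decimate = list(from = fs,
                                                 to = targetRate))))
}

#' Reject epochs exceeding a peak-to-peak amplitude limit
#'
#' Clears the kept-mask of every epoch whose peak-to-peak amplitude on any
#' channel exceeds the limit. A per-condition rejection tally is stored in
#' the provenance.
#'
#' @param epochs an \linkS4class{EpochSet}
#' @param peakToPeak rejection threshold in microvolts (default 200);
#'   \code{Inf} keeps everything
#' @return the \linkS4class{EpochSet} with an updated kept-mask
#' @export
rejectArtifacts <- function(epochs, peakToPeak = 200) {
  stopifnot(is(epochs, "EpochSet"), peakToPeak > 0)
  d <- dim(epochs@data)
  if (d[1] == 0L) return(epochs)
  p2p <- apply(epochs@data, 1L, function(tr) {
    max(apply(tr, 1L, function(ch) diff(range(ch))))
  })
  keep <- epochs@keptMask & (p2p <= peakToPeak)
  tally <- stats::aggregate(
    list(rejected = !keep),
    by = list(environment = epochs@labels$environment,
              depth = epochs@labels$depth),
    FUN = sum)
  initialize(epochs, keptMask = keep,
             provenance = c(epochs@provenance,
                            list(rejection = list(limit = peakToPeak,
                                                  per_condition = tally))))
}

#' Subset an EpochSet
#'
#' @param epochs an \linkS4class{EpochSet}
#' @param i trial indices (logical or integer)
#' @return the subset \linkS4class{EpochSet}
#' @export
subsetEpochs <- function(epochs, i) {
  lab <- epochs@labels[i, , drop = FALSE]
  rownames(lab) <- NULL
  initialize(epochs,
             data = epochs@data[i, , , drop = FALSE],
             labels = lab,
             keptMask = epochs@keptMask[i])
}

#' Kept trials only
#'
#' @param epochs an \linkS4class{EpochSet}
#' @return the \linkS4class{EpochSet} restricted to trials whose kept-mask
#'   is TRUE
#' @export
keptEpochs <- function(epochs) subsetEpochs(epochs, epochs@keptMask)

#' Extract the stimulus window of each epoch
#'
#' Restricts epochs to [0, stimDuration) seconds relative to stimulus
#' onset, dropping the pre-stimulus baseline. Decoding and SNR estimation
#' operate on this window.
#'
#' @param epochs an \linkS4class{EpochSet}
#' @param stimDuration stimulus length in seconds (default: the epoch end)
#' @return an \linkS4class{EpochSet} windowed to [0, stimDuration)
#' @export
stimulusWindow <- function(epochs, stimDuration = epochs@window[2]) {
  .timeWindow(epochs, 0, stimDuration)
}

#' Extract the pre-stimulus baseline of each epoch
#'
#' @param epochs an \linkS4class{EpochSet}
#' @return an \linkS4class{EpochSet} windowed to [window start, 0)
#' @export
baselineWindow <- function(epochs) {
  .timeWindow(epochs, epochs@window[1], 0)
}

.timeWindow <- function(epochs, from, to) {
  fs <- epochs@sampleRate
  w <- epochs@window
  if (from < w[1] - 1e-9 || to > w[2] + 1e-9) {
    stop("requested window exceeds the epoch extent")
  }
  i0 <- round((from - w[1]) * fs) + 1L
  i1 <- round((to - w[1]) * fs)
  initialize(epochs,
             data = epochs@data[, , i0:i1, drop = FALSE],
             window = c(from, to))
}

#' Run the full preprocessing chain
#'
#' Band-pass, epoch, decimate, reject — in that order.
#'
#' @param raw an \linkS4class{EegRecording}
#' @param low,high,order band-pass parameters (defaults 0.1-40 Hz, order 4)
#' @param window epoch window in seconds relative to stimulus onset
#' @param targetRate working rate after decimation (default 250 Hz)
#' @param peakToPeak rejection threshold in microvolts (default 200)
#' @return an \linkS4class{EpochSet}
#' @export
preprocess <- function(raw, low = 0.1, high = 40, order = 4,
                       window = c(-1, 5), targetRate = 250,
                       peakToPeak = 200) {
  rejectArtifacts(
    decimateEpochs(
      epochRecording(bandpass(raw, low, high, order), window),
      targetRate),
    peakToPeak)
}
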