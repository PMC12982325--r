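#' Narrow-band spectral SNR of one epoch, in dB
#'
#' Computes the rectangular-window periodogram power of the stimulus-window
#' signal at the target frequency f0 and its second harmonic 2*f0, and a
#' background estimate from the neighbouring spectrum: frequencies offset
#' from each peak by multiples of the spectral resolution 1/T out to
#' +/- \code{noiseHalfWidth} Hz, excluding offsets within +/-
#' \code{exclude} Hz of the peaks. These offsets coincide with the
#' Dirichlet-kernel nulls of a T-long sinusoid at the peak, so the evoked
#' component does not leak into the background estimate. The SNR is
#' 10*log10((P_f0 + P_2f0) / P_noise) with P_noise the sum of the two
#' per-neighbourhood background means (one per spectral component), so
#' noise-only data is centred near 0 dB. Powers are averaged across
#' channels before the ratio; per-channel dB values are also returned.
#'
#' @param x channels x samples matrix (stimulus window only) or a numeric
#'   vector for a single channel
#' @param f0 target fundamental frequency in Hz; 2*f0 must be below Nyquist
#' @param sampleRate sampling rate in Hz
#' @param noiseHalfWidth background neighbourhood half-width in Hz
#'   (default 1.0)
#' @param exclude half-width of the exclusion zone around each peak in Hz
#'   (default 0.1)
#' @return list(snr_db, p_f0, p_2f0, p_noise, per_channel_db,
#'   psd_resolution)
#' @export
snrDb <- function(x, f0, sampleRate, noiseHalfWidth = 1.0, exclude = 0.1) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (2 * f0 >= sampleRate / 2) {
    stop("second harmonic ", 2 * f0, " Hz is at or above Nyquist")
  }
  T <- ncol(x) / sampleRate
  nf <- .noiseFrequencies(f0, T, noiseHalfWidth, exclude)
  if (!length(nf)) stop("empty noise band; widen noiseHalfWidth")
  pf0 <- .powerAt(x, f0, sampleRate)[, 1]
  p2f0 <- .powerAt(x, 2 * f0, sampleRate)[, 1]
  pn <- .powerAt(x, nf, sampleRate)
  nearF0 <- abs(nf - f0) <= noiseHalfWidth + 1e-9
  pnoise <- rowMeans(pn[, nearF0, drop = FALSE]) +
    rowMeans(pn[, !nearF0, drop = FALSE])
  list(snr_db = 10 * log10((mean(pf0) + mean(p2f0)) / mean(pnoise)),
       p_f0 = mean(pf0),
       p_2f0 = mean(p2f0),
       p_noise = mean(pnoise),
       per_channel_db = 10 * log10((pf0 + p2f0) / pnoise),
       psd_resolution = 1 / T)
}

#' Per-trial SNR report for an epoch set
#'
#' Applies \code{\link{snrDb}} to the stimulus window of every kept trial,
#' using each trial's true stimulus frequency as the target.
#'
#' @param epochs an \linkS4class{EpochSet} with frequency labels
#' @param stimDuration analysed stimulus length in seconds (default 5)
#' @param ... passed to \code{\link{snrDb}}
#' @return data.frame: trial_index, environment, depth, frequency, snr_db,
#'   p_f0, p_2f0, p_noise
#' @export
snrReport <- function(epochs, stimDuration = 5, ...) {
  ep <- stimulusWindow(keptEpochs(epochs), stimDuration)
  lab <- ep@labels
  rows <- lapply(seq_len(nrow(lab)), function(i) {
    x <- ep@data[i, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    s <- snrDb(x, lab$frequency[i], ep@sampleRate, ...)
    data.frame(trial_index = lab$trial_index[i],
               environment = lab$environment[i],
               depth = lab$depth[i],
               frequency = lab$frequency[i],
               snr_db = s$snr_db, p_f0 = s$p_f0, p_2f0 = s$p_2f0,
               p_noise = s$p_noise)
  })
  do.call(rbind, rows)
}

#' Summarise an SNR report per condition
#'
#' @param report output of \code{\link{snrReport}}
#' @param by grouping columns (default environment and depth)
#' @return data.frame of per-condition mean, sd and trial count
#' @export
summarizeSnr <- function(report, by = c("environment", "depth")) {
  agg <- stats::aggregate(report$snr_db, by = report[by], FUN = function(v) {
    c(mean = mean(v), sd = stats::sd(v), n = length(v))
  })
  out <- cbind(agg[by], as.data.frame(agg$x))
  names(out) <- c(by, "mean_snr_db", "sd_snr_db", "n")
  out
}

#' Averaged amplitude spectrum of the stimulus windows
#'
#' Magnitude spectrum (2 |X(f)| / N, so a unit sinusoid on an exact bin has
#' amplitude 1) of each kept trial's stimulus window, averaged across
#' trials and the selected channels.
#'
#' @param epochs an \linkS4class{EpochSet}; all epochs must share one length
#' @param channels channel labels to include (default: all)
#' @param stimDuration analysed stimulus length in seconds (default 5)
#' @return data.frame(frequency, amplitude) up to Nyquist
#' @export
amplitudeSpectrum <- function(epochs, channels = NULL, stimDuration = 5) {
  ep <- stimulusWindow(keptEpochs(epochs), stimDuration)
  sel <- if (is.null(channels)) seq_along(ep@channelNames)
         else match(channels, ep@channelNames)
  if (anyNA(sel)) stop("unknown channel(s): ",
                       paste(channels[is.na(sel)], collapse = ", "))
  d <- dim(ep@data)
  n <- d[3]
  m <- floor(n / 2) + 1L
  acc <- numeric(m)
  cnt <- 0L
  for (i in seq_len(d[1])) {
    for (c in sel) {
      X <- stats::fft(ep@data[i, c, ])
      acc <- acc + 2 * Mod(X[seq_len(m)]) / n
      cnt <- cnt + 1L
    }
  }
  data.frame(frequency = (seq_len(m) - 1L) * ep@sampleRate / n,
             amplitude = if (cnt) acc / cnt else acc)
}

#' Stratified Monte-Carlo validation splits
#'
#' Builds seeded repetitions of random train/test partitions stratified by
#' the (depth, frequency) cell: each stratum contributes its own rounded
#' 70/30 split, so a 90-trial session (9 cells of 10) always yields 63
#' training and 27 test trials. Train and test are disjoint by
#' construction.
#'
#' @param labels data.frame with columns depth and frequency (one row per
#'   trial), e.g. \code{trialInfo(epochs)}
#' @param nRepetitions number of repetitions (default 10)
#' @param trainFraction training fraction (default 0.7)
#' @param seed RNG seed
#' @return list of \code{nRepetitions} elements, each list(train, test) of
#'   row indices into \code{labels}
#' @export
makeCvSplits <- function(labels, nRepetitions = 10, trainFraction = 0.7,
                         seed = 1L) {
  strata <- split(seq_len(nrow(labels)),
                  interaction(labels$depth, labels$frequency, drop = TRUE))
  small <- vapply(strata, length, integer(1)) < 2
  if (any(small)) {
    stop("stratum/strata with fewer than 2 trials: ",
         paste(names(strata)[small], collapse = ", "))
  }
  .withSeed(.subSeed(seed, "cv"), {
    lapply(seq_len(nRepetitions), function(r) {
      train <- unlist(lapply(strata, function(idx) {
        sample(idx, round(trainFraction * length(idx)))
      }), use.names = FALSE)
      list(train = sort(train),
           test = sort(setdiff(seq_len(nrow(labels)), train)))
    })
  })
}

#' Classification accuracy report
#'
#' Tallies correct decisions per cell of the grouping columns and pools the
#' whole table. When decisions carry a \code{repetition} column, the
#' per-cell and pooled summaries also report the mean and standard
#' deviation of accuracy across repetitions. Empty cells are reported as
#' NA, not 0.
#'
#' @param decisions data.frame with columns true_frequency,
#'   predicted_frequency (as produced by the decoders), plus any grouping
#'   columns
#' @param by grouping columns present in \code{decisions}
#' @return list(cells, overall): per-cell data.frame (n_correct, n_total,
#'   accuracy in percent) and the pooled summary
#' @export
accuracyReport <- function(decisions, by = c("environment", "depth")) {
  correct <- decisions$predicted_frequency == decisions$true_frequency
  by <- intersect(by, names(decisions))
  cells <- if (length(by)) {
    agg <- stats::aggregate(correct, by = decisions[by], FUN = function(v) {
      c(n_correct = sum(v), n_total = length(v))
    })
    out <- cbind(agg[by], as.data.frame(agg$x))
    out$accuracy <- ifelse(out$n_total > 0,
                           100 * out$n_correct / out$n_total, NA_real_)
    out
  } else {
    data.frame(n_correct = sum(correct), n_total = length(correct),
               accuracy = 100 * mean(correct))
  }
  overall <- list(n_correct = sum(correct), n_total = length(correct),
                  accuracy = if (length(correct)) 100 * mean(correct)
                             else NA_real_)
  if ("repetition" %in% names(decisions)) {
    perRep <- tapply(correct, decisions$repetition, function(v) 100 * mean(v))
    overall$mean_accuracy <- mean(perRep)
    overall$sd_accuracy <- stats::sd(perRep)
  }
  list(cells = cells, overall = overall)
}

#' Wilcoxon signed-rank test, SPSS-compatible normal approximation
#'
#' Paired two-sided test on \code{b - a}: zero differences are dropped,
#' tied absolute differences are mid-ranked, and the Z statistic uses the
#' tie-corrected variance without continuity correction,
#' Z = (T_neg - mu) / sigma with T_neg the sum of ranks where b < a,
#' mu = n(n+1)/4 and sigma^2 = n(n+1)(2n+1)/24 - sum(t^3 - t)/48. With
#' a = MR scores and b = VR scores, VR > MR therefore yields a negative Z.
#' If every difference is zero, Z = 0 and p = 1 with \code{degenerate =
#' TRUE}.
#'
#' @param a,b paired numeric score vectors of equal length
#' @param alpha family-wise significance level (default 0.05)
#' @param m number of comparisons for the Bonferroni correction (default 1)
#' @return list with medians/IQRs of both samples, rank counts
#'   (n_negative = b < a, n_positive = b > a, n_tied = zero differences),
#'   z, p (two-sided), the Bonferroni-corrected level and the significance
#'   flag
#' @export
wilcoxonSignedRank <- function(a, b, alpha = 0.05, m = 1) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- b - a
  iqr <- function(v) stats::quantile(v, c(0.25, 0.75), names = FALSE)
  nz <- d != 0
  out <- list(median_a = stats::median(a), iqr_a = iqr(a),
              median_b = stats::median(b), iqr_b = iqr(b),
              n_negative = sum(d < 0), n_positive = sum(d > 0),
              n_tied = sum(!nz))
  if (!any(nz)) {
    out <- c(out, list(z = 0, p = 1, degenerate = TRUE))
  } else {
    dd <- d[nz]
    n <- length(dd)
    r <- rank(abs(dd))
    tneg <- sum(r[dd < 0])
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (tneg - mu) / sqrt(sigma2)
    out <- c(out, list(z = z, p = 2 * stats::pnorm(-abs(z)),
                       degenerate = FALSE))
  }
  out$alpha_corrected <- bonferroniAlpha(alpha, m)
  out$significant_after_bonferroni <- out$p < out$alpha_corrected
  out
}

#' Bonferroni-corrected significance level
#'
#' @param familyAlpha family-wise level in (0, 1)
#' @param m number of comparisons (>= 1)
#' @return per-comparison level familyAlpha / m
#' @examples
#' bonferroniAlpha(0.05, 10)  # 0.005
#' @export
bonferroniAlpha <- function(familyAlpha, m) {
  if (m < 1) stop("m must be >= 1")
  if (familyAlpha <= 0 || familyAlpha >= 1) {
    stop("familyAlpha must lie in (0, 1)")
  }
  familyAlpha / m
}

#' Least-squares line and Pearson correlation
#'
#' @param x,y numeric vectors of equal length, n >= 2; x must not be
#'   constant. A constant y is reported with r = 0 and a flag.
#' @return list(slope, intercept, r, n, constant_y)
#' @export
linearFit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 points")
  if (stats::sd(x) == 0) stop("x is constant; slope undefined")
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  constantY <- stats::sd(y) == 0
  r <- if (constantY) 0 else stats::cor(x, y)
  list(slope = slope, intercept = intercept, r = r, n = length(x),
       constant_y = constantY)
}
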