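#' Sinusoidal reference templates for CCA decoding
#'
#' For each candidate frequency f builds a matrix whose rows are
#' unit-amplitude sin and cos waves at h * f, h = 1..nHarmonics. Every
#' harmonic must lie below the Nyquist frequency.
#'
#' @param frequencies candidate stimulus frequencies in Hz
#' @param nHarmonics harmonics per frequency (default 2: fundamental plus
#'   second harmonic, matching the SNR definition and the 0.1-40 Hz band)
#' @param sampleRate sampling rate in Hz
#' @param nSamples template length in samples
#' @return a \linkS4class{ReferenceSet}
#' @export
makeReferences <- function(frequencies, nHarmonics = 2, sampleRate,
                           nSamples) {
  nHarmonics <- as.integer(nHarmonics)
  hmax <- max(frequencies) * nHarmonics
  if (hmax >= sampleRate / 2) {
    stop(sprintf("harmonic %d of %g Hz (= %g Hz) is at or above Nyquist (%g Hz)",
                 nHarmonics, max(frequencies), hmax, sampleRate / 2))
  }
  tt <- (seq_len(nSamples) - 1L) / sampleRate
  refs <- lapply(frequencies, function(f) {
    rows <- lapply(seq_len(nHarmonics), function(h) {
      rbind(sin(2 * pi * h * f * tt), cos(2 * pi * h * f * tt))
    })
    do.call(rbind, rows)
  })
  names(refs) <- as.character(frequencies)
  new("ReferenceSet", frequencies = as.numeric(frequencies),
      nHarmonics = nHarmonics, sampleRate = sampleRate,
      nSamples = as.integer(nSamples), refs = refs)
}

#' Largest canonical correlation between two multivariate signals
#'
#' Finds weight vectors w_x, w_y maximising the Pearson correlation between
#' w_x' X and w_y' Y. Solved through the whitened cross-covariance
#' singular-value formulation with a small ridge on the auto-covariances
#' for numerical stability; rank-deficient inputs are handled by the ridge
#' with a warning.
#'
#' @param x channels x samples matrix (rows are centered internally)
#' @param y references x samples matrix
#' @param ridge relative ridge added to the auto-covariances (default 1e-9)
#' @return list(rho, wx, wy): the largest canonical correlation in [0, 1]
#'   and the corresponding weight vectors
#' @export
ccaCorrelation <- function(x, y, ridge = 1e-9) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  n <- ncol(x)
  if (ncol(y) != n) stop("x and y must have the same number of samples")
  if (n < nrow(x) + nrow(y)) {
    stop("need at least channels + references samples")
  }
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  cxx <- tcrossprod(xc) / (n - 1)
  cyy <- tcrossprod(yc) / (n - 1)
  cxy <- tcrossprod(xc, yc) / (n - 1)
  whiten <- function(cmat) {
    scale <- mean(diag(cmat))
    if (scale <= 0) scale <- 1
    e <- eigen(cmat + ridge * scale * diag(nrow(cmat)), symmetric = TRUE)
    if (min(e$values) < 1e-12 * max(e$values)) {
      warning("rank-deficient input; ridge-regularized solve")
      e$values <- pmax(e$values, 1e-12 * max(e$values))
    }
    e$vectors %*% (t(e$vectors) / sqrt(e$values))
  }
  wxh <- whiten(cxx)
  wyh <- whiten(cyy)
  k <- crossprod(wxh, cxy %*% wyh)
  sv <- svd(k)
  list(rho = min(1, sv$d[1]),
       wx = as.numeric(wxh %*% sv$u[, 1]),
       wy = as.numeric(wyh %*% sv$v[, 1]))
}

# argmax with lowest-frequency tie-break
.pickFrequency <- function(scores, frequencies) {
  best <- which(scores >= max(scores) - 0)
  frequencies[min(best)]
}

#' Classify one epoch by canonical correlation
#'
#' Computes the largest canonical correlation between the epoch and each
#' frequency's sine/cosine reference matrix and predicts the frequency with
#' the highest correlation (ties broken towards the lowest frequency).
#'
#' @param x channels x samples matrix, the stimulus window of one epoch
#' @param refs a \linkS4class{ReferenceSet} of matching length
#' @return list(rho, predicted, wx, wy): per-frequency correlations (named
#'   by frequency), the predicted frequency and the weights of the winner
#' @export
ccaClassify <- function(x, refs) {
  stopifnot(is(refs, "ReferenceSet"))
  if (ncol(x) != refs@nSamples) {
    stop("epoch length (", ncol(x), ") does not match reference length (",
         refs@nSamples, ")")
  }
  fits <- lapply(refs@refs, function(y) ccaCorrelation(x, y))
  rho <- vapply(fits, `[[`, numeric(1), "rho")
  names(rho) <- names(refs@refs)
  pred <- .pickFrequency(rho, refs@frequencies)
  win <- which(refs@frequencies == pred)[1]
  list(rho = rho, predicted = pred,
       wx = fits[[win]]$wx, wy = fits[[win]]$wy)
}

#' Subband fusion weights for filter-bank CCA
#'
#' w(n) = n^(-1.25) + 0.25 for subband index n = 1..N: strictly positive
#' and strictly decreasing, down-weighting higher subbands.
#'
#' @param n number of subbands
#' @param a,b weight parameters (defaults 1.25 and 0.25)
#' @return numeric weight vector
#' @export
fbccaWeights <- function(n, a = 1.25, b = 0.25) {
  seq_len(n)^(-a) + b
}

#' Construct a filter-bank specification
#'
#' @param bands list of c(low, high) edges in Hz; the default four subbands
#'   are 0.1-10, 10-20, 20-30 and 30-40 Hz, covering the fundamentals
#'   (7.5, 11.25, 18 Hz) and their second harmonics
#' @param order Butterworth design order per subband (default 4)
#' @return a \linkS4class{FilterBankSpec}
#' @export
filterBankSpec <- function(bands = list(c(0.1, 10), c(10, 20),
                                        c(20, 30), c(30, 40)),
                           order = 4) {
  new("FilterBankSpec", bands = bands, order = as.integer(order),
      weights = fbccaWeights(length(bands)))
}

#' Classify one epoch by filter-bank CCA
#'
#' Decomposes the epoch into subbands with zero-phase Butterworth band-pass
#' filters, computes the largest canonical correlation against each
#' frequency's reference in each subband, and fuses them per frequency as
#' the weighted sum of squared correlations. The frequency with the largest
#' fused feature wins (ties towards the lowest frequency).
#'
#' @param x channels x samples matrix, the stimulus window of one epoch
#' @param refs a \linkS4class{ReferenceSet}
#' @param bank a \linkS4class{FilterBankSpec}
#' @return list(rho, fused, predicted): subbands x frequencies correlation
#'   matrix, fused per-frequency features, and the predicted frequency
#' @export
fbccaClassify <- function(x, refs, bank = filterBankSpec()) {
  stopifnot(is(refs, "ReferenceSet"), is(bank, "FilterBankSpec"))
  if (ncol(x) != refs@nSamples) {
    stop("epoch length (", ncol(x), ") does not match reference length (",
         refs@nSamples, ")")
  }
  fs <- refs@sampleRate
  nb <- length(bank@bands)
  rho <- matrix(NA_real_, nb, length(refs@frequencies),
                dimnames = list(NULL, names(refs@refs)))
  for (b in seq_len(nb)) {
    edges <- bank@bands[[b]]
    xb <- .bandpassMatrix(x, edges[1], edges[2], bank@order, fs)
    rho[b, ] <- vapply(refs@refs,
                       function(y) ccaCorrelation(xb, y)$rho, numeric(1))
  }
  fused <- colSums(bank@weights * rho^2)
  list(rho = rho, fused = fused,
       predicted = .pickFrequency(fused, refs@frequencies))
}

#' Decode every kept epoch with CCA or filter-bank CCA
#'
#' @param epochs an \linkS4class{EpochSet}; decoding uses the stimulus
#'   window (baseline excluded)
#' @param method "cca" or "fbcca"
#' @param frequencies candidate frequencies; default: those in the labels
#' @param nHarmonics reference harmonics (default 2)
#' @param bank filter bank for "fbcca"
#' @param stimDuration analysed stimulus length in seconds (default 5)
#' @return data.frame with one row per kept trial: trial_index,
#'   environment, depth, true and predicted frequency, correct flag, and
#'   one score column per candidate frequency
#' @export
decodeEpochs <- function(epochs, method = c("cca", "fbcca"),
                         frequencies = NULL, nHarmonics = 2,
                         bank = filterBankSpec(), stimDuration = 5) {
  method <- match.arg(method)
  ep <- stimulusWindow(keptEpochs(epochs), stimDuration)
  lab <- ep@labels
  if (is.null(frequencies)) frequencies <- sort(unique(lab$frequency))
  refs <- makeReferences(frequencies, nHarmonics, ep@sampleRate,
                         dim(ep@data)[3])
  n <- dim(ep@data)[1]
  scores <- matrix(NA_real_, n, length(frequencies))
  pred <- numeric(n)
  for (i in seq_len(n)) {
    x <- ep@data[i, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    fit <- if (method == "cca") ccaClassify(x, refs)
           else fbccaClassify(x, refs, bank)
    scores[i, ] <- if (method == "cca") fit$rho else fit$fused
    pred[i] <- fit$predicted
  }
  colnames(scores) <- paste0("score_", frequencies)
  out <- data.frame(trial_index = lab$trial_index,
                    environment = lab$environment,
                    depth = lab$depth,
                    true_frequency = lab$frequency,
                    predicted_frequency = pred,
                    correct = pred == lab$frequency,
                    method = method)
  cbind(out, as.data.frame(scores))
}
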