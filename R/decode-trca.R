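#' Train task-related component analysis filters for one class
#'
#' Given K >= 2 trials of one stimulus class, finds spatial filters w that
#' maximise the consistency of the projected signal across trials by
#' solving the generalized eigenproblem S_t w = lambda S_n w, where S_t
#' sums the cross-trial covariances over all ordered trial pairs (j != k)
#' and S_n is either the total covariance summed over trials (default) or
#' the identity. Filters are returned sorted by decreasing eigenvalue and
#' normalised so w' S_n w = 1; a near-singular S_n is ridge-regularised
#' with a warning.
#'
#' @param trials K x channels x samples array, or list of channels x
#'   samples matrices, all of one class
#' @param normalization "covariance" (default) or "identity" for S_n
#' @param frequency optional class label (Hz) stored in the model
#' @param channelNames optional channel labels
#' @param nComponents components retained by default when filtering
#' @return a \linkS4class{TrcaModel}
#' @export
trcaTrain <- function(trials, normalization = c("covariance", "identity"),
                      frequency = NA_real_, channelNames = NULL,
                      nComponents = 1) {
  normalization <- match.arg(normalization)
  if (is.array(trials) && length(dim(trials)) == 3) {
    trials <- lapply(seq_len(dim(trials)[1]),
                     function(i) trials[i, , , drop = TRUE])
  }
  K <- length(trials)
  if (K < 2) stop("TRCA needs at least 2 trials per class")
  C <- nrow(trials[[1]])
  Tn <- ncol(trials[[1]])
  if (Tn <= C) stop("need more time points than channels")
  centered <- lapply(trials, function(x) x - rowMeans(x))
  total <- Reduce(`+`, lapply(centered, tcrossprod)) / (Tn - 1)
  s <- Reduce(`+`, centered)
  st <- (tcrossprod(s) / (Tn - 1) - total)
  st <- (st + t(st)) / 2
  sn <- if (normalization == "identity") diag(C) else (total + t(total)) / 2
  scale <- mean(diag(sn))
  ev <- eigen(sn, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev)) {
    warning("near-singular S_n; ridge-regularized solve")
    sn <- sn + 1e-8 * scale * diag(C)
  }
  u <- chol(sn)
  ui <- backsolve(u, diag(C))
  b <- crossprod(ui, st %*% ui)
  b <- (b + t(b)) / 2
  eg <- eigen(b, symmetric = TRUE)
  w <- ui %*% eg$vectors
  if (is.null(channelNames)) {
    channelNames <- rownames(trials[[1]]) %||% paste0("ch", seq_len(C))
  }
  rownames(w) <- channelNames
  template <- Reduce(`+`, trials) / K
  new("TrcaModel", filters = w, eigenvalues = eg$values,
      st = st, sn = sn, template = template,
      channelNames = channelNames, frequency = as.numeric(frequency),
      nComponents = as.integer(nComponents))
}

#' Train one TRCA model per stimulus class
#'
#' @param epochs an \linkS4class{EpochSet} of training trials
#' @param stimDuration stimulus window length in seconds used for training
#' @param ... passed to \code{\link{trcaTrain}}
#' @return named list of \linkS4class{TrcaModel}, one per frequency
#' @export
trcaTrainAll <- function(epochs, stimDuration = 5, ...) {
  ep <- stimulusWindow(keptEpochs(epochs), stimDuration)
  freqs <- sort(unique(ep@labels$frequency))
  models <- lapply(freqs, function(f) {
    idx <- which(ep@labels$frequency == f)
    if (length(idx) < 2) {
      stop("class ", f, " Hz has fewer than 2 training trials")
    }
    trials <- lapply(idx, function(i) {
      x <- ep@data[i, , , drop = TRUE]
      rownames(x) <- ep@channelNames
      x
    })
    trcaTrain(trials, frequency = f, channelNames = ep@channelNames, ...)
  })
  names(models) <- as.character(freqs)
  models
}

#' Spatially filter epochs with trained TRCA models
#'
#' Projects each epoch onto the leading TRCA components. With a named list
#' of per-class models, each trial is projected with the model of its own
#' (true-label) class — the configuration used to quantify SNR enhancement.
#' With a single model, all trials share its filters.
#'
#' @param epochs an \linkS4class{EpochSet}
#' @param models a \linkS4class{TrcaModel} or a named list of them (names =
#'   frequencies)
#' @param nComponents components to retain (default 1)
#' @return an \linkS4class{EpochSet} whose channels are TRCA components
#' @export
trcaFilter <- function(epochs, models, nComponents = 1) {
  stopifnot(is(epochs, "EpochSet"))
  single <- is(models, "TrcaModel")
  pickW <- function(model) {
    if (nComponents > ncol(model@filters)) {
      stop("nComponents (", nComponents, ") exceeds available filters (",
           ncol(model@filters), ")")
    }
    if (!identical(model@channelNames, epochs@channelNames)) {
      stop("model channels do not match the epochs")
    }
    model@filters[, seq_len(nComponents), drop = FALSE]
  }
  d <- dim(epochs@data)
  out <- array(NA_real_, c(d[1], nComponents, d[3]))
  for (i in seq_len(d[1])) {
    model <- if (single) models else {
      m <- models[[as.character(epochs@labels$frequency[i])]]
      if (is.null(m)) stop("no model for class ",
                           epochs@labels$frequency[i], " Hz")
      m
    }
    x <- epochs@data[i, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    out[i, , ] <- crossprod(pickW(model), x)
  }
  initialize(epochs, data = out,
             channelNames = paste0("TRC", seq_len(nComponents)),
             provenance = c(epochs@provenance, list(trca = TRUE)))
}

#' Classify epochs by correlation with TRCA-filtered class templates
#'
#' For each candidate class, projects both the test epoch and the class's
#' training template through the class's leading TRCA filter and takes
#' their Pearson correlation; the class with the largest correlation wins
#' (ties towards the lowest frequency). Note this classification use goes
#' beyond TRCA's role as an SNR-enhancing spatial filter; it is provided as
#' a calibrated decoder for completeness.
#'
#' @param epochs an \linkS4class{EpochSet} of test trials
#' @param models named list of \linkS4class{TrcaModel} per class
#' @param stimDuration analysed stimulus length in seconds (default 5)
#' @param nComponents filter components used (default 1)
#' @return decision data.frame in the same layout as
#'   \code{\link{decodeEpochs}}
#' @export
trcaDecode <- function(epochs, models, stimDuration = 5, nComponents = 1) {
  ep <- stimulusWindow(keptEpochs(epochs), stimDuration)
  freqs <- sort(as.numeric(names(models)))
  n <- dim(ep@data)[1]
  scores <- matrix(NA_real_, n, length(freqs))
  pred <- numeric(n)
  for (i in seq_len(n)) {
    x <- ep@data[i, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    for (k in seq_along(freqs)) {
      m <- models[[as.character(freqs[k])]]
      w <- m@filters[, seq_len(nComponents), drop = FALSE]
      xs <- as.numeric(crossprod(w, x))
      ts <- as.numeric(crossprod(w, m@template[, seq_len(ncol(x)),
                                               drop = FALSE]))
      scores[i, k] <- stats::cor(xs, ts)
    }
    pred[i] <- .pickFrequency(scores[i, ], freqs)
  }
  colnames(scores) <- paste0("score_", freqs)
  lab <- ep@labels
  out <- data.frame(trial_index = lab$trial_index,
                    environment = lab$environment,
                    depth = lab$depth,
                    true_frequency = lab$frequency,
                    predicted_frequency = pred,
                    correct = pred == lab$frequency,
                    method = "trca")
  cbind(out, as.data.frame(scores))
}
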