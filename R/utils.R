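# Internal numerical helpers shared across modules.

# Amplitude response of a zero-phase (forward-backward) digital Butterworth
# filter at frequencies f (Hz): the squared single-pass magnitude
# |H1(f)|^2, using the bilinear-transform frequency warping
# O = tan(pi f / fs) with prewarped edges, so it matches the response of
# the classic recursive design exactly. `order` is the prototype
# (per-edge) design order.
.butterGainSq <- function(f, order, fs, type = c("pass", "low"),
                          low = NULL, high = NULL) {
  type <- match.arg(type)
  O <- tan(pi * pmin(f, fs / 2) / fs)
  if (type == "low") {
    Oc <- tan(pi * high / fs)
    ratio <- O / Oc
  } else {
    Ol <- tan(pi * low / fs)
    Oh <- tan(pi * high / fs)
    ratio <- ifelse(O == 0, Inf, (O^2 - Ol * Oh) / (O * (Oh - Ol)))
  }
  # |H1|^2 of a single pass, which IS the (real, zero-phase) amplitude
  # response of the forward-backward filter
  1 / (1 + ratio^(2 * order))
}

# Apply a zero-phase filter with gain function gainFun(f) to every row of
# x, via the FFT with odd-symmetric reflection padding (to suppress edge
# transients) and zero padding to a fast transform length.
.spectralFilterRows <- function(x, fs, gainFun, padSamples) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  if (n == 0L) return(x)
  pad <- max(0L, min(n - 1L, as.integer(padSamples)))
  if (pad > 0) {
    head <- 2 * x[, 1] - x[, (pad + 1L):2L, drop = FALSE]
    tail <- 2 * x[, n] - x[, (n - 1L):(n - pad), drop = FALSE]
    xp <- cbind(head, x, tail)
  } else {
    xp <- x
  }
  np <- ncol(xp)
  N <- stats::nextn(np, c(2, 3, 5))
  if (N > np) xp <- cbind(xp, matrix(0, nrow(xp), N - np))
  k <- 0:(N - 1)
  f <- pmin(k, N - k) * fs / N
  g <- gainFun(f)
  X <- stats::mvfft(t(xp))
  y <- Re(stats::mvfft(X * g, inverse = TRUE)) / N
  t(y)[, (pad + 1L):(pad + n), drop = FALSE]
}

# Zero-phase Butterworth band-pass of each row of a matrix. The pad length
# covers ~3 time constants of the slow (low-frequency) edge.
.bandpassMatrix <- function(x, low, high, order, fs) {
  nyq <- fs / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("band edges must satisfy 0 < low < high < sampleRate/2 (Nyquist ",
         nyq, " Hz)")
  }
  .spectralFilterRows(x, fs,
                      function(f) .butterGainSq(f, order, fs, "pass",
                                                low = low, high = high),
                      padSamples = round(3 * fs / low))
}

# Zero-phase Butterworth low-pass (anti-alias) of each row.
.lowpassMatrix <- function(x, cutoff, order, fs) {
  if (!(cutoff > 0 && cutoff < fs / 2)) {
    stop("cutoff must lie in (0, Nyquist)")
  }
  .spectralFilterRows(x, fs,
                      function(f) .butterGainSq(f, order, fs, "low",
                                                high = cutoff),
                      padSamples = round(3 * fs / cutoff))
}

# Rectangular-window periodogram power of each row of x, evaluated at
# arbitrary frequencies (Hz). Normalised so a unit-amplitude sinusoid at an
# evaluation frequency contributes power 0.5 (its mean-square value).
.powerAt <- function(x, freqs, fs) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  tt <- (seq_len(n) - 1L) / fs
  E <- exp(-2i * pi * outer(tt, freqs))        # n x nf
  Z <- x %*% E                                  # channels x nf
  (2 / n^2) * Mod(Z)^2
}

# Frequency grid for the narrow-band noise estimate around f0 and 2*f0:
# offsets k/T (the Dirichlet-kernel nulls of a T-long target sinusoid) out
# to +/- halfWidth Hz, excluding offsets within +/- exclude Hz of each peak.
.noiseFrequencies <- function(f0, T, halfWidth, exclude) {
  df <- 1 / T
  k <- seq_len(floor(halfWidth / df + 1e-9))
  off <- c(-rev(k), k) * df
  off <- off[abs(off) > exclude + 1e-12]
  fr <- sort(unique(c(f0 + off, 2 * f0 + off)))
  fr[fr > 0]
}

# Deterministic 31-bit sub-seed derived from a base seed and a stream label.
.subSeed <- function(seed, stream) {
  v <- utf8ToInt(as.character(stream))
  h <- sum(v * seq_along(v))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}

# Evaluate code with a local RNG state, restoring the caller's stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
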