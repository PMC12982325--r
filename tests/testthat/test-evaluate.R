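test_that("spectral SNR reproduces constructed power ratios exactly", {
  fs <- 250
  n <- 1250
  tt <- (0:(n - 1)) / fs
  # f0 chosen so every component (peaks, noise bins, and their sum/difference
  # images) sits on the exact 1/T orthogonality grid: the ratios are exact
  f0 <- 12
  T <- n / fs
  nf <- ssvepDepth:::.noiseFrequencies(f0, T, 1.0, 0.1)
  mkSignal <- function(aPeak, bNoise) {
    x <- aPeak * sin(2 * pi * f0 * tt + 0.3) +
      aPeak * sin(2 * pi * 2 * f0 * tt + 1.1)
    for (f in nf) x <- x + bNoise * sin(2 * pi * f * tt + f)
    x
  }
  # peaks and noise bins at equal amplitude: (a^2/2 * 2) / (b^2/2 * 2) = 1
  s0 <- snrDb(mkSignal(1, 1), f0, fs)
  expect_equal(s0$snr_db, 0, tolerance = 1e-6)
  # peak power 10x the background -> 10 dB
  s10 <- snrDb(mkSignal(sqrt(10), 1), f0, fs)
  expect_equal(s10$snr_db, 10, tolerance = 1e-6)
  # the reported identity holds to 1e-9
  expect_equal(s10$snr_db,
               10 * log10((s10$p_f0 + s10$p_2f0) / s10$p_noise),
               tolerance = 1e-9)
  expect_equal(s0$psd_resolution, 0.2)
})

test_that("spectral SNR matches an independent periodogram oracle", {
  fs <- 250
  n <- 1250
  tt <- (0:(n - 1)) / fs
  set.seed(31)
  x <- rbind(sin(2 * pi * 11.25 * tt) + rnorm(n, sd = 2),
             0.5 * sin(2 * pi * 11.25 * tt + 1) + rnorm(n, sd = 2))
  # independently coded rectangular periodogram at arbitrary frequencies
  oraclePower <- function(row, f) {
    re <- sum(row * cos(2 * pi * f * tt))
    im <- sum(row * sin(2 * pi * f * tt))
    2 * (re^2 + im^2) / n^2
  }
  f0 <- 11.25
  nf <- ssvepDepth:::.noiseFrequencies(f0, n / fs, 1.0, 0.1)
  near <- abs(nf - f0) <= 1 + 1e-9
  perChan <- function(row) {
    pn <- vapply(nf, function(f) oraclePower(row, f), numeric(1))
    c(oraclePower(row, f0), oraclePower(row, 2 * f0),
      mean(pn[near]) + mean(pn[!near]))
  }
  comp <- vapply(seq_len(nrow(x)), function(i) perChan(x[i, ]), numeric(3))
  oracleDb <- 10 * log10((mean(comp[1, ]) + mean(comp[2, ])) /
                           mean(comp[3, ]))
  expect_equal(snrDb(x, f0, fs)$snr_db, oracleDb, tolerance = 1e-6)
})

test_that("spectral SNR is invariant to global amplitude scaling", {
  set.seed(32)
  x <- matrix(rnorm(3 * 1250), 3, 1250) +
    rep(0.5 * sin(2 * pi * 18 * (0:1249) / 250), each = 3)
  base <- snrDb(x, 18, 250)$snr_db
  for (c in c(1e-3, 0.5, 7, 1e4)) {
    expect_lt(abs(snrDb(c * x, 18, 250)$snr_db - base), 1e-9)
  }
})

test_that("spectral SNR guards its frequency preconditions", {
  x <- matrix(rnorm(500), 1, 500)
  expect_error(snrDb(x, 70, 250), "Nyquist")
  expect_error(snrDb(x, 18, 250, noiseHalfWidth = 0.05), "noise band")
})

test_that("amplitude spectra show planted peaks and handle zero input", {
  zero <- makePlantedEpochs(freqs = 12, repsPerFreq = 2, snrScale = 0)
  zero@data[] <- 0
  spec0 <- amplitudeSpectrum(zero, stimDuration = 5)
  expect_true(all(spec0$amplitude == 0))

  # bin-aligned unit sinusoid (12 Hz = bin 60 at 0.2 Hz resolution)
  one <- zero
  one@data[1, , ] <- rep(sin(2 * pi * 12 * (0:1249) / 250),
                         each = dim(one@data)[2])
  one@data[2, , ] <- one@data[1, , ]
  spec1 <- amplitudeSpectrum(one, stimDuration = 5)
  expect_equal(spec1$amplitude[spec1$frequency == 12], 1, tolerance = 1e-9)

  planted <- makePlantedEpochs(freqs = 12, repsPerFreq = 6, snrScale = 0.8,
                               harmonicRatio = 0.5, seed = 5)
  sp <- amplitudeSpectrum(planted, stimDuration = 5)
  af0 <- sp$amplitude[sp$frequency == 12]
  a2f0 <- sp$amplitude[sp$frequency == 24]
  expect_gt(af0, a2f0)
  expect_gt(a2f0, median(sp$amplitude))

  expect_error(amplitudeSpectrum(planted, channels = "nope"), "nope")
})

test_that("stratified splits reproduce the 63/27 partition in every repetition", {
  labels <- trialInfo(buildSchedule("MR", c(0.4, 1, 1.8),
                                    c(7.5, 11.25, 18), 10))
  splits <- makeCvSplits(labels, nRepetitions = 10, trainFraction = 0.7,
                         seed = 4)
  expect_length(splits, 10L)
  for (sp in splits) {
    expect_length(sp$train, 63L)
    expect_length(sp$test, 27L)
    expect_length(intersect(sp$train, sp$test), 0L)
    # each (depth, frequency) stratum of 10 contributes 7 train / 3 test
    cell <- interaction(labels$depth, labels$frequency)
    expect_true(all(table(cell[sp$train]) == 7))
    expect_true(all(table(cell[sp$test]) == 3))
  }
  # reproducible under the same seed
  splits2 <- makeCvSplits(labels, 10, 0.7, seed = 4)
  expect_identical(splits, splits2)
  tiny <- labels[c(1, 11), ]
  expect_error(makeCvSplits(tiny, 2, 0.7, seed = 1), "fewer than 2")
})

test_that("accuracy reports tally correct decisions per condition", {
  dec <- data.frame(
    environment = rep(c("MR", "VR"), each = 6),
    depth = rep(c(0.4, 1.8), 6),
    true_frequency = rep(c(7.5, 11.25, 18), 4),
    predicted_frequency = c(7.5, 11.25, 18, 7.5, 11.25, 18,   # all correct
                            7.5, 18, 18, 11.25, 11.25, 7.5))  # hand-tallied
  rep1 <- accuracyReport(dec[1:6, ], by = "environment")
  expect_equal(rep1$overall$accuracy, 100)
  full <- accuracyReport(dec, by = "environment")
  # hand count: VR block has 3 of 6 correct
  vr <- full$cells[full$cells$environment == "VR", ]
  expect_equal(vr$n_correct, 3)
  expect_equal(vr$n_total, 6)
  expect_equal(vr$accuracy, 50)
  expect_equal(full$overall$n_correct, 9)

  third <- data.frame(true_frequency = rep(1, 27),
                      predicted_frequency = c(rep(1, 9), rep(2, 18)))
  expect_equal(round(accuracyReport(third, by = NULL)$overall$accuracy, 1),
               33.3)

  withRep <- cbind(dec, repetition = rep(1:2, 6))
  rep2 <- accuracyReport(withRep, by = "environment")
  expect_true(is.finite(rep2$overall$sd_accuracy))
})

test_that("signed-rank test reproduces the printed MR/VR comparison", {
  # five tied pairs, four unit increases and one double increase:
  # T_neg = 0, n = 5, one tie group of 4 -> Z = -2.121, p = 0.034
  mr <- c(2, 2, 2, 2, 2, 2, 2, 2, 2, 1)
  vr <- mr + c(0, 0, 0, 0, 0, 1, 1, 1, 1, 2)
  fit <- wilcoxonSignedRank(mr, vr, alpha = 0.05, m = 10)
  expect_equal(round(fit$z, 3), -2.121)
  expect_equal(round(fit$p, 3), 0.034)
  expect_equal(fit$n_negative, 0)
  expect_equal(fit$n_positive, 5)
  expect_equal(fit$n_tied, 5)
  expect_equal(fit$alpha_corrected, 0.005)
  expect_false(fit$significant_after_bonferroni)

  same <- wilcoxonSignedRank(1:8, 1:8)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  # five equal-magnitude positive differences, fully tied ranks:
  # sigma^2 = 13.75 - (125 - 5)/48 = 11.25 -> Z = -7.5/sqrt(11.25)
  allTied <- wilcoxonSignedRank(rep(0, 5), rep(1, 5))
  expect_equal(round(allTied$z, 3), -2.236)

  expect_error(wilcoxonSignedRank(1:3, 1:4), "equal length")
})

test_that("signed-rank p-values order like an exact permutation oracle", {
  exactP <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    tobs <- sum(r[d < 0])
    mu <- n * (n + 1) / 4
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    tall <- signs %*% r
    mean(abs(tall - mu) >= abs(tobs - mu) - 1e-12)
  }
  set.seed(8)
  cases <- list(c(1, 2, -1.5, 3, 4, -0.5, 2.5, 1.2),
                c(1, 1.1, 1.2, 1.3, -2, 1.5, 1.7, 1.9),
                c(-3, -2, -4, 1, -5, -2.5, -1.2, -0.7),
                c(0.5, -0.6, 0.7, -0.8, 0.9, -1.0, 1.1, 1.2))
  pApprox <- vapply(cases, function(d) {
    wilcoxonSignedRank(rep(0, length(d)), d)$p
  }, numeric(1))
  pExact <- vapply(cases, exactP, numeric(1))
  expect_identical(order(pApprox), order(pExact))
})

test_that("Bonferroni correction and linear fits follow their closed forms", {
  expect_equal(bonferroniAlpha(0.05, 10), 0.005)
  expect_equal(bonferroniAlpha(0.05, 1), 0.05)
  expect_equal(bonferroniAlpha(0.05, 20), 0.0025)
  expect_error(bonferroniAlpha(0.05, 0), "m")
  expect_error(bonferroniAlpha(1.2, 5), "familyAlpha")

  x <- 1:10
  fit <- linearFit(x, 2 * x)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r, 1)

  fit2 <- linearFit(x, -x + 5)
  expect_equal(fit2$slope, -1)
  expect_equal(fit2$r, -1)

  set.seed(17)
  xn <- rnorm(40)
  yn <- 1.7 * xn - 0.4 + rnorm(40)
  fit3 <- linearFit(xn, yn)
  # closed-form normal equations oracle
  X <- cbind(1, xn)
  beta <- solve(crossprod(X), crossprod(X, yn))
  expect_equal(fit3$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit3$slope, beta[2], tolerance = 1e-10)

  expect_error(linearFit(rep(1, 5), 1:5), "constant")
  flat <- linearFit(1:5, rep(2, 5))
  expect_equal(flat$r, 0)
  expect_true(flat$constant_y)
})
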