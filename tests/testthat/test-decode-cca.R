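test_that("reference sets are harmonic sinusoid banks with a Nyquist guard", {
  refs <- makeReferences(11.25, 2, 250, 1250)
  expect_equal(dim(refs@refs[["11.25"]]), c(4L, 1250L))
  tt <- (0:1249) / 250
  expect_equal(refs@refs[["11.25"]][1, ], sin(2 * pi * 11.25 * tt))
  expect_equal(refs@refs[["11.25"]][4, ], cos(2 * pi * 22.5 * tt))
  # whole cycles of 11.25 Hz: 1200 samples = 54 cycles -> zero mean
  expect_equal(mean(refs@refs[["11.25"]][1, 1:1200]), 0, tolerance = 1e-12)
  expect_error(makeReferences(18, 3, 100, 500), "Nyquist")
})

test_that("canonical correlation reduces to Pearson and self-correlation", {
  set.seed(1)
  y <- matrix(rnorm(4 * 300), 4, 300)
  self <- ccaCorrelation(y[1:3, ], y)
  expect_equal(self$rho, 1, tolerance = 1e-6)

  a <- rnorm(200)
  b <- 0.3 * a + rnorm(200)
  expect_equal(ccaCorrelation(a, b)$rho, abs(cor(a, b)), tolerance = 1e-7)

  expect_error(ccaCorrelation(matrix(rnorm(20), 4, 5),
                              matrix(rnorm(15), 3, 5)), "samples")
})

test_that("canonical correlation matches a direct-optimisation oracle", {
  # brute-force oracle: maximise |cor(wx'X, wy'Y)| over the weights
  oracleRho <- function(x, y, restarts = 12) {
    obj <- function(p) {
      wx <- p[seq_len(nrow(x))]
      wy <- p[-seq_len(nrow(x))]
      sx <- drop(crossprod(wx, x))
      sy <- drop(crossprod(wy, y))
      if (sd(sx) == 0 || sd(sy) == 0) return(0)
      -abs(cor(sx, sy))
    }
    best <- -Inf
    for (r in seq_len(restarts)) {
      p0 <- rnorm(nrow(x) + nrow(y))
      fit <- optim(p0, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12))
      best <- max(best, -fit$value)
    }
    best
  }
  set.seed(42)
  for (k in 1:2) {
    x <- matrix(rnorm(3 * 200), 3, 200)
    y <- matrix(rnorm(4 * 200), 4, 200)
    expect_equal(ccaCorrelation(x, y)$rho, oracleRho(x, y),
                 tolerance = 1e-4)
  }
})

test_that("canonical correlation is invariant to invertible channel mixing", {
  set.seed(5)
  x <- matrix(rnorm(5 * 400), 5, 400)
  y <- matrix(rnorm(4 * 400), 4, 400)
  base <- ccaCorrelation(x, y)$rho
  for (k in 1:5) {
    m <- matrix(rnorm(25), 5, 5)
    while (abs(det(m)) < 1e-3) m <- matrix(rnorm(25), 5, 5)
    expect_lt(abs(ccaCorrelation(m %*% x, y)$rho - base), 1e-8)
  }
})

test_that("CCA classification recovers planted frequencies and breaks ties low", {
  fs <- 250
  tt <- (0:1249) / fs
  refs <- makeReferences(c(7.5, 11.25, 18), 2, fs, 1250)
  x <- rbind(sin(2 * pi * 11.25 * tt + 0.7),
             0.8 * sin(2 * pi * 11.25 * tt + 0.7) +
               0.4 * sin(2 * pi * 22.5 * tt + 0.2))
  fit <- ccaClassify(x, refs)
  expect_equal(fit$predicted, 11.25)
  expect_gt(fit$rho[["11.25"]], 0.99)

  # pure noise: the decision is the argmax of independently computed rhos
  set.seed(9)
  xn <- matrix(rnorm(2 * 1250), 2, 1250)
  fitN <- ccaClassify(xn, refs)
  rhoSolo <- vapply(refs@refs, function(y) ccaCorrelation(xn, y)$rho,
                    numeric(1))
  expect_equal(fitN$predicted,
               refs@frequencies[which.max(rhoSolo)])

  # duplicated candidate frequencies tie exactly -> lowest index wins
  refsDup <- makeReferences(c(11.25, 11.25), 2, fs, 1250)
  fitD <- ccaClassify(x, refsDup)
  expect_equal(fitD$predicted, 11.25)
  expect_equal(unname(fitD$rho[1]), unname(fitD$rho[2]), tolerance = 1e-12)

  expect_error(ccaClassify(x[, 1:600], refs), "length")
})

test_that("filter-bank weights follow n^(-1.25) + 0.25", {
  w <- fbccaWeights(4)
  # frozen against independent evaluation: 1 + 1/4, 2^-1.25 + 1/4,
  # exp(-1.25 log 3) + 1/4, 2^-2.5 + 1/4
  expect_equal(w, c(1.25, 0.6704482, 0.5032786, 0.4267767),
               tolerance = 1e-6)
  expect_true(all(diff(w) < 0))
  expect_true(all(w > 0))
  spec <- filterBankSpec()
  expect_equal(spec@weights, fbccaWeights(4))
  expect_equal(length(spec@bands), 4L)
})

test_that("filter-bank CCA fuses subbands and recovers planted signals", {
  fs <- 250
  tt <- (0:1249) / fs
  refs <- makeReferences(c(7.5, 11.25, 18), 2, fs, 1250)
  # noiseless 7.5 Hz with second harmonic
  x <- rbind(sin(2 * pi * 7.5 * tt) + 0.5 * sin(2 * pi * 15 * tt + 1),
             0.7 * sin(2 * pi * 7.5 * tt + 0.3))
  fit <- fbccaClassify(x, refs)
  expect_equal(fit$predicted, 7.5)
  expect_true(all(fit$fused[["7.5"]] > fit$fused[c("11.25", "18")]))
  expect_true(all(fit$fused >= 0))
  expect_equal(dim(fit$rho), c(4L, 3L))
})

test_that("a single full-range band reduces filter-bank CCA to plain CCA", {
  ep <- makePlantedEpochs(repsPerFreq = 4, snrScale = 0.35)
  # band-limit the fixture as preprocessed epochs would be
  for (i in seq_len(nTrials(ep))) {
    ep@data[i, , ] <- ssvepDepth:::.bandpassMatrix(
      ep@data[i, , , drop = TRUE], 0.1, 40, 4, sampleRate(ep))
  }
  wide <- filterBankSpec(bands = list(c(0.1, 40)))
  cca <- decodeEpochs(ep, "cca")
  fb <- decodeEpochs(ep, "fbcca", bank = wide)
  expect_identical(fb$predicted_frequency, cca$predicted_frequency)
})
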