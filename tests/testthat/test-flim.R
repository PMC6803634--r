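test_that("simulated histograms have the stated decay statistics", {
  # pure fast component, near-delta IRF: log-linear decay at tauFree
  nb <- 512
  irf <- gaussianIrf(nb, 13.16, fwhmNs = 0.005, t0Ns = 0.2)
  h <- simulateTcspc(0, totalCounts = 2e6, nBins = nb, irf = irf, seed = 4)
  tc <- (seq_len(nb) - 0.5) * 13.16 / nb
  win <- tc > 0.4 & tc < 2 & h@counts > 50
  slope <- unname(stats::coef(stats::lm(log(h@counts[win]) ~ tc[win]))[2])
  expect_equal(-1 / slope, 0.4, tolerance = 0.02)
  # zero photons
  h0 <- simulateTcspc(0.5, totalCounts = 0, nBins = 64, seed = 1)
  expect_equal(sum(h0@counts), 0)
  # mean arrival times track the component lifetimes (+ IRF centroid,
  # - wrap correction for the slow component)
  hf <- simulateTcspc(0, totalCounts = 1e6, nBins = nb, irf = irf, seed = 2)
  hb <- simulateTcspc(1, totalCounts = 1e6, nBins = nb, irf = irf, seed = 2)
  mf <- sum(tc * hf@counts) / sum(hf@counts)
  mb <- sum(tc * hb@counts) / sum(hb@counts)
  expect_equal(mf - 0.2, 0.4, tolerance = 0.05)
  wrap <- 13.16 / (exp(13.16 / 2.4) - 1)
  expect_equal(mb - 0.2, 2.4 - wrap, tolerance = 0.1)
  # total counts are Poisson around the requested budget
  expect_lt(abs(sum(h@counts) - 2e6), 5 * sqrt(2e6))
  # wrap warning for short periods
  expect_warning(simulateTcspc(0.5, periodNs = 5, nBins = 64, seed = 1),
                 "wrap")
})

test_that("seeded simulation is reproducible and restores the RNG", {
  h1 <- simulateTcspc(0.3, totalCounts = 1e4, nBins = 128, seed = 11)
  h2 <- simulateTcspc(0.3, totalCounts = 1e4, nBins = 128, seed = 11)
  expect_identical(h1@counts, h2@counts)
  set.seed(99); x1 <- rnorm(1)
  set.seed(99); invisible(simulateTcspc(0.3, nBins = 64, seed = 5))
  x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("the pooled two-exponential fit recovers both lifetimes", {
  h <- simulateTcspc(0.5, totalCounts = 1e6, nBins = 1024, seed = 7)
  ft <- fitTwoExponentialGlobal(h)
  expect_lt(abs(ft$lifetimes[["tauFree"]] / 0.4 - 1), 0.05)
  expect_lt(abs(ft$lifetimes[["tauBound"]] / 2.4 - 1), 0.05)
  expect_lt(abs(ft$pBound - 0.5), 0.05)
})

test_that("single-component data collapse to one effective lifetime", {
  h <- simulateTcspc(0, totalCounts = 1e6, nBins = 512, seed = 8)
  ft <- suppressWarnings(fitTwoExponentialGlobal(h))
  # either the second amplitude vanishes or the two lifetimes merge; in
  # both cases the photon-weighted mean lifetime is the generating one
  degenerate <- min(ft$pBound, 1 - ft$pBound) < 0.05 ||
    ft$lifetimes[["tauBound"]] / ft$lifetimes[["tauFree"]] < 1.2
  expect_true(degenerate)
  meanTau <- (1 - ft$pBound) * ft$lifetimes[["tauFree"]] +
    ft$pBound * ft$lifetimes[["tauBound"]]
  expect_lt(abs(meanTau / 0.4 - 1), 0.05)
})

test_that("lifetime recovery tolerates a uniform background", {
  h <- simulateTcspc(0.5, totalCounts = 1e6, nBins = 512, bgFraction = 0.05,
                     seed = 9)
  ft <- fitTwoExponentialGlobal(h, fitBackground = TRUE)
  expect_lt(abs(ft$lifetimes[["tauFree"]] / 0.4 - 1), 0.05)
  expect_lt(abs(ft$lifetimes[["tauBound"]] / 2.4 - 1), 0.05)
  expect_lt(abs(ft$bgFraction - 0.05), 0.02)
})

test_that("the per-pixel MLE is unbiased and reaches the boundaries", {
  set.seed(21)
  ps <- replicate(100, pixelBoundFractionMle(
    simulateTcspc(0.5, totalCounts = 5000, nBins = 256))$p)
  expect_lt(abs(mean(ps) - 0.5), 0.01)
  expect_lt(stats::sd(ps), 0.05)
  # boundary truth: most replicates land exactly on 0
  set.seed(22)
  p0 <- replicate(20, pixelBoundFractionMle(
    simulateTcspc(0, totalCounts = 2000, nBins = 256))$p)
  expect_gt(sum(p0 == 0), 10)
  # low-count flag and empty pixel
  lowc <- pixelBoundFractionMle(simulateTcspc(0.5, totalCounts = 20,
                                              nBins = 64, seed = 3))
  expect_true(lowc$lowConfidence)
  empty <- pixelBoundFractionMle(rep(0, 64), irf = gaussianIrf(64),
                                 periodNs = 13.16)
  expect_true(is.na(empty$p))
})

test_that("mis-setting the bound lifetime shifts the estimate smoothly", {
  # the estimator's real sensitivity: p-hat decreases monotonically as the
  # assumed bound lifetime grows, by roughly 0.05 per 0.5 ns at p = 0.5
  h <- simulateTcspc(0.5, totalCounts = 2e6, nBins = 256, seed = 5)
  taubs <- c(2.0, 2.2, 2.4, 2.7, 3.0)
  pv <- vapply(taubs, function(tb)
    pixelBoundFractionMle(h, lifetimePair(0.4, tb))$p, numeric(1))
  expect_true(all(diff(pv) < 0))
  expect_lt(max(pv) - min(pv), 0.15)
  expect_lt(abs(pv[3] - 0.5), 0.02)
})

test_that("the vectorized map equals the per-pixel estimator", {
  nb <- 128
  irf <- gaussianIrf(nb, 13.16)
  set.seed(31)
  arr <- array(0, c(3, 4, nb))
  truthP <- matrix(runif(12, 0.1, 0.9), 3, 4)
  for (i in 1:3) for (j in 1:4)
    arr[i, j, ] <- simulateTcspc(truthP[i, j], totalCounts = 4000,
                                 nBins = nb, irf = irf)@counts
  pm <- boundFractionMap(arr, irf = irf, periodNs = 13.16)
  ref <- matrix(0, 3, 4)
  for (i in 1:3) for (j in 1:4)
    ref[i, j] <- pixelBoundFractionMle(arr[i, j, ], irf = irf,
                                       periodNs = 13.16)$p
  expect_lt(max(abs(pm - ref)), 1e-6)
})

test_that("pixel MLE on pooled data matches the global amplitude fit", {
  nb <- 256
  pool <- simulateTcspc(0.4, totalCounts = 5e5, nBins = nb, seed = 13)
  pPix <- pixelBoundFractionMle(pool)$p
  pGlob <- fitTwoExponentialGlobal(pool)$pBound
  expect_lt(abs(pPix - pGlob), 0.01)
})

test_that("brightness correction maps photon to molecular fractions", {
  lt <- lifetimePair(0.4, 2.4)
  expect_equal(brightnessCorrect(0, lt), 0)
  expect_equal(brightnessCorrect(1, lt), 1)
  expect_equal(brightnessCorrect(0.6, lt), 0.2)
  # equal-brightness limit: lifetimes nearly equal
  ltEq <- lifetimePair(1, 1 + 1e-9)
  expect_equal(brightnessCorrect(0.37, ltEq), 0.37, tolerance = 1e-6)
  # strictly increasing and exactly inverted
  p <- seq(0, 1, by = 0.05)
  A <- brightnessCorrect(p, lt)
  expect_true(all(diff(A) > 0))
  expect_equal(boundPhotonFraction(A, lt), p, tolerance = 1e-12)
  expect_error(lifetimePair(2.4, 0.4))
})
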