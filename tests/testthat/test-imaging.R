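test_that("alignment recovers integer and sub-pixel translations", {
  img <- blobImage()
  al0 <- alignPair(img, img)
  expect_equal(unname(al0$shift), c(0, 0))
  shifted <- trastkit:::.translateImage(img, -2, -3)
  al <- alignPair(img, shifted)
  expect_equal(unname(al$shift), c(2, 3))
  expect_lt(max(abs(al$slowAligned[5:60, 5:60] - img[5:60, 5:60])), 1e-6)
  # sub-pixel with Poisson noise
  set.seed(12)
  b <- matrix(rpois(64 * 64, trastkit:::.translateImage(img, -0.9, 0) + 20),
              64, 64)
  a <- matrix(rpois(64 * 64, img + 20), 64, 64)
  al2 <- alignPair(a, b)
  expect_lt(abs(al2$shift[["dy"]] - 0.9), 0.1 + 1e-9)
  expect_lt(abs(al2$shift[["dx"]]), 0.1 + 1e-9)
  # featureless pair falls back to zero shift with a warning
  set.seed(13)
  expect_warning(alignPair(matrix(rpois(64 * 64, 5), 64, 64),
                           matrix(rpois(64 * 64, 5), 64, 64)),
                 "zero shift")
})

test_that("alignment removes misregistration artifacts in amplitude maps", {
  lam <- blobImage(amp = 4000) + 100
  lamSlow <- trastkit:::.translateImage(lam * (1 - 0.4), -2, 0)
  set.seed(14)
  fast <- matrix(rpois(length(lam), lam), nrow(lam))
  slow <- matrix(rpois(length(lam), lamSlow), nrow(lam))
  err <- function(slowImg) {
    A <- atrastImage(fast, slowImg, driftCorrect = FALSE,
                     minFastCounts = 0)$A
    mean(abs(A - 0.4)[lam > 500])
  }
  before <- err(slow)
  after <- err(alignPair(fast, slow)$slowAligned)
  expect_gt(before / after, 5)
})

test_that("amplitude maps are exact, thresholded and scale invariant", {
  set.seed(15)
  fast <- matrix(rpois(900, 400), 30, 30)
  res <- atrastImage(fast, fast, driftCorrect = FALSE)
  expect_true(all(res$A == 0))
  expect_error(atrastImage(matrix(0, 4, 4), matrix(0, 4, 4)), "all-zero")
  # low-count pixels are missing, not zero
  fast2 <- fast; fast2[1, 1] <- 5
  res2 <- atrastImage(fast2, fast2 * 0.6, driftCorrect = FALSE,
                      minFastCounts = 20)
  expect_true(is.na(res2$A[1, 1]))
  expect_equal(res2$A[2, 2], 0.4)
  # invariance under a common rescaling of both frames
  res3 <- atrastImage(fast2 * 7, fast2 * 0.6 * 7, driftCorrect = FALSE,
                      minFastCounts = 0)
  expect_equal(res3$A, atrastImage(fast2, fast2 * 0.6,
                                   driftCorrect = FALSE,
                                   minFastCounts = 0)$A)
})

test_that("drift correction compensates linear bleaching of fast frames", {
  specRef <- cellFieldSpec(nCells = 8, condition = "control",
                           backgroundCounts = 0)
  specBl <- cellFieldSpec(nCells = 8, condition = "control",
                          backgroundCounts = 0, bleachSlope = 0.1)
  fRef <- genCellField(specRef, seed = 31)
  fBl <- genCellField(specBl, seed = 31)
  mRef <- mean(analyzeCellField(fRef, align = FALSE)$features$mean_atrast)
  mCor <- mean(analyzeCellField(fBl, align = FALSE)$features$mean_atrast)
  mRaw <- mean(analyzeCellField(fBl, align = FALSE,
                                driftCorrect = FALSE)$features$mean_atrast)
  expect_lt(abs(mCor - mRef), 0.005)
  expect_gt(abs(mRaw - mRef), 0.02)
})

test_that("free/bound splitting conserves counts and separates contrast", {
  # identical bound fractions in fast and slow: both components equal the
  # total amplitude map
  Ff <- matrix(300, 5, 5); Fs <- matrix(180, 5, 5)
  p <- matrix(0.35, 5, 5)
  sp <- splitFreeBoundTrast(Ff, Fs, p, p, minFastCounts = 0)
  Atot <- trastAmplitude(Ff, Fs)
  expect_equal(sp$Afree, Atot)
  expect_equal(sp$Abound, Atot)
  # component photon counts sum to the totals exactly
  expect_equal(Ff * (1 - p) + Ff * p, Ff)
  # contrast only in the free component
  Ff2 <- matrix(150, 4, 4); Fs2 <- matrix(110, 4, 4)
  pF <- matrix(50 / 150, 4, 4); pS <- matrix(50 / 110, 4, 4)
  sp2 <- splitFreeBoundTrast(Ff2, Fs2, pF, pS, minFastCounts = 0)
  expect_equal(sp2$Afree, matrix(0.4, 4, 4))
  expect_equal(sp2$Abound, matrix(0, 4, 4))
  # missing FLIM pixel propagates
  pFna <- pF; pFna[1, 1] <- NA
  sp3 <- splitFreeBoundTrast(Ff2, Fs2, pFna, pS, minFastCounts = 0)
  expect_true(is.na(sp3$Afree[1, 1]))
})

test_that("per-cell features aggregate regions exactly", {
  labels <- matrix(0L, 10, 10)
  labels[2:5, 2:5] <- 1L; labels[7:9, 7:9] <- 2L
  nucleus <- matrix(FALSE, 10, 10); nucleus[3:4, 3:4] <- TRUE
  A <- matrix(0.5, 10, 10)
  A[labels == 1L] <- 0.45
  A[nucleus] <- 0.38
  ft <- perCellFeatures(A, labels, nucleus)
  expect_equal(nrow(ft), 2)
  expect_equal(ft$mean_atrast_nucl[1], 0.38)
  expect_equal(ft$mean_atrast_cyto[1], 0.45)
  expect_equal(ft$n_pixels, c(16, 9))
  # a cell whose pixels are all missing is dropped
  A2 <- A; A2[labels == 2L] <- NA
  expect_message(ft2 <- perCellFeatures(A2, labels, nucleus), "dropped")
  expect_equal(nrow(ft2), 1)
  # count-sum mode agrees with pixel means on homogeneous cells
  Ff <- matrix(200, 10, 10); Fs <- Ff * (1 - A)
  ftc <- perCellFeatures(A, labels, nucleus, mode = "count-sum",
                         Ffast = Ff, Fslow = Fs)
  expect_equal(ftc$mean_atrast_nucl[1], 0.38, tolerance = 1e-12)
})

test_that("the imaging pipeline recovers region truths on a small field", {
  fields <- genCellField(cellFieldSpec(nCells = 24), seed = 11)
  res <- analyzeCellField(fields)
  ft <- res$features
  expect_equal(nrow(ft), 24)
  expect_lt(abs(mean(ft$mean_atrast_nucl) - 0.38), 0.01)
  expect_lt(abs(mean(ft$mean_atrast_cyto) - 0.45), 0.01)
  expect_lt(abs(mean(ft$mean_atrast) - 0.4325), 0.01)
  # dose-matching violation warns
  bad <- fields[[1]]
  bad@wSlowUs <- 500
  expect_warning(analyzeCellField(bad), "dose")
})
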