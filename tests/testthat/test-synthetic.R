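test_that("the solution design reproduces the measurement series", {
  d <- opeSolutionDesign()
  expect_equal(nrow(d), 53)
  expect_true(all(d$Iexc >= 10 & d$Iexc <= 81))
  expect_setequal(unique(d$atmosphere), c("air", "oxygen", "argon"))
  for (s in c("ascorbate", "tris", "hydroxide", "peroxide")) {
    col <- switch(s, ascorbate = "Asc", tris = "TRIS", hydroxide = "OH",
                  peroxide = "H2O2")
    expect_true(all(diff(d[d$series == s, col]) > 0))
  }
  # the hydroxide series is unbuffered
  expect_true(all(d$TRIS[d$series == "hydroxide"] == 0))
})

test_that("solution curve generation is exact at zero noise and seeded", {
  truth <- rateParams()
  d <- opeSolutionDesign()[c(1, 15, 30), ]
  w <- 10^seq(0, 3, length.out = 8)
  cs0 <- genSolutionDataset(truth, d, w = w, noiseSd = 0, seed = 1)
  ref <- simulateStationaryTrast(truth,
    quencherEnvironment(d$atmosphere[1], Asc = d$Asc[1], TRIS = d$TRIS[1],
                        H2O2 = d$H2O2[1], OH = d$OH[1]),
    w, excitationProtocol("ope", Iexc = d$Iexc[1]))
  expect_equal(cs0[[1]]@Fnorm, ref@Fnorm)
  a <- genSolutionDataset(truth, d, w = w, seed = 7)
  b <- genSolutionDataset(truth, d, w = w, seed = 7)
  expect_identical(lapply(a, function(x) x@Fnorm),
                   lapply(b, function(x) x@Fnorm))
  c2 <- genSolutionDataset(truth, d, w = w, seed = 8)
  expect_false(identical(a[[1]]@Fnorm, c2[[1]]@Fnorm))
})

test_that("cell fields are seeded, dose-consistent and truth-annotated", {
  spec <- cellFieldSpec(nCells = 8, tcspc = TRUE, nBins = 64)
  f1 <- genCellField(spec, seed = 3)
  f2 <- genCellField(spec, seed = 3)
  expect_identical(f1@fastStack, f2@fastStack)
  expect_identical(f1@tcspc, f2@tcspc)
  # slow expected counts never exceed the fast-sum expectation
  th <- f1@truth$thetaMap
  expect_true(all(th >= 0 & th <= 1))
  expect_lt(sum(f1@slowFrame), sum(f1@fastStack))
  expect_equal(nrow(f1@truth$cells), 8)
  expect_equal(dim(f1@fastStack)[3] * f1@wFastUs, f1@wSlowUs)
  # labels and nucleus are consistent
  expect_true(all(f1@labels[f1@nucleus] > 0))
})

test_that("a null field yields amplitudes indistinguishable from zero", {
  spec <- cellFieldSpec(nCells = 8, occupancy = c(nucleus = 0, cytosol = 0),
                        betweenCellSd = c(theta = 0, beta = 0.01),
                        backgroundCounts = 0)
  fld <- genCellField(spec, seed = 5)
  res <- analyzeCellField(fld, align = FALSE)
  expect_lt(abs(mean(res$features$mean_atrast)), 0.005)
})

test_that("an injected sub-pixel offset is recovered by alignment", {
  spec <- cellFieldSpec(nCells = 10, injectShiftPx = c(0.9, 0))
  fld <- genCellField(spec, seed = 13)
  res <- analyzeCellField(fld)
  expect_lt(abs(res$shift[["dy"]] - 0.9), 0.1 + 1e-9)
  expect_lt(abs(res$shift[["dx"]]), 0.1 + 1e-9)
})

test_that("impossible placements fail with a clear error", {
  spec <- cellFieldSpec(nCells = 40, shape = c(48, 48), fovUm = 34,
                        cellsPerField = 40)
  expect_error(genCellField(spec, seed = 1), "non-overlapping")
})

test_that("multi-field generation covers the requested cell count", {
  fields <- genCellField(cellFieldSpec(nCells = 30), seed = 2)
  expect_true(is.list(fields))
  ids <- unlist(lapply(fields, function(f)
    setdiff(unique(as.integer(f@labels)), 0L)))
  expect_equal(sort(ids), 1:30)
})
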