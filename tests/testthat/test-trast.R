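test_that("without dark pathways the normalized curve is identically 1", {
  p <- rateParams(kisc = 0, kee = 0)
  crv <- simulateStationaryTrast(p, quencherEnvironment("air"),
                                 w = 10^seq(-0.3, 3, length.out = 10))
  expect_equal(crv@Fnorm, rep(1, 10))
})

test_that("stationary curves are normalized at w0 and decay monotonically", {
  crv <- simulateStationaryTrast(rateParams(),
                                 quencherEnvironment("air", TRIS = 50),
                                 w = 10^seq(log10(0.5), 3,
                                            length.out = 16))
  expect_identical(crv@Fnorm[1], 1)
  expect_true(all(crv@Fnorm > 0 & crv@Fnorm <= 1))
  expect_true(all(diff(crv@Fnorm) <= 0))
  expect_error(simulateStationaryTrast(rateParams(),
                                       quencherEnvironment("air"),
                                       w = numeric(0)))
})

test_that("a short inter-pulse dead time triggers the recovery warning", {
  expect_warning(
    simulateStationaryTrast(rateParams(), quencherEnvironment("air"),
                            w = c(1, 10, 100),
                            protocol = excitationProtocol("ope", Iexc = 43,
                                                          dutyCycle = 0.5)),
    "recovery")
})

test_that("the closed-form pulse average matches dense-grid integration", {
  p <- rateParams()
  env <- quencherEnvironment("air", TRIS = 50)
  beam1 <- beamProfile(nShells = 1)
  pr <- excitationProtocol("ope", Iexc = 43, beam = beam1)
  w <- c(1, 10, 100, 1000)
  crv <- simulateStationaryTrast(p, env, w, pr)
  I1 <- discretizeBeam(beam1, 43, "ope")$irradiance
  M <- buildRateMatrix(p, env, excitationRateOpe(I1, beam1))
  Fref <- vapply(w, function(wi) trapzAvgSinglet(M, wi), numeric(1))
  expect_lt(max(abs(crv@Fnorm - Fref / Fref[1])), 1e-4)
})

test_that("scanned and stationary engines agree at matched dwell times", {
  p <- rateParams()
  env <- quencherEnvironment("air", TRIS = 50)
  beam <- beamProfile()
  wEff <- 10^seq(0.5, 3, length.out = 8)
  prS <- excitationProtocol("ope", Iexc = 43, beam = beam, scanned = TRUE)
  scan <- simulateScannedTrast(p, env, protocol = prS, wEff = wEff)
  stat <- simulateStationaryTrast(p, env, w = wEff,
                                  protocol = excitationProtocol("ope",
                                    Iexc = 43, beam = beam))
  aS <- curveAmplitude(scan); aT <- curveAmplitude(stat)
  expect_lt(abs(aS - aT) / aT, 0.02)
  # speeds are converted through effectiveDwell
  v <- speedForDwell(wEff, beam, "ope")
  scan2 <- simulateScannedTrast(p, env, speeds = v, protocol = prS)
  expect_equal(scan2@w, wEff, tolerance = 1e-12)
})

test_that("the TPE scanned curve decays with amplitude inside (0, 1)", {
  crv <- simulateScannedTrast(rateParams(),
    quencherEnvironment("air", TRIS = 50),
    wEff = 10^seq(log10(2), log10(690), length.out = 14),
    protocol = excitationProtocol("tpe", Iexc = 4.6),
    model = trastModel(eeIexp = 1, IexcRef = 2.6))
  expect_identical(crv@Fnorm[1], 1)
  expect_true(all(diff(crv@Fnorm) < 0))
  a <- curveAmplitude(crv)
  expect_gt(a, 0); expect_lt(a, 1)
})

test_that("trastAmplitude and the oxidation-rate proxy are exact", {
  expect_equal(trastAmplitude(1.0, 0.57), 0.43)
  expect_equal(trastAmplitude(1.0, 0.48), 0.52)
  expect_equal(trastAmplitude(5, 5), 0)
  expect_true(is.na(trastAmplitude(0, 1)))
  expect_true(is.na(trastAmplitude(-2, 1)))
  expect_equal(effectiveOxidationRate(0.5), 1)
  expect_equal(effectiveOxidationRate(0), 0)
  expect_equal(effectiveOxidationRate(0.43), 0.43 / 0.57)
  expect_error(effectiveOxidationRate(1))
})

test_that("amplitude grows with the ejection rate and falls with ascorbate", {
  env <- quencherEnvironment("air", TRIS = 50)
  w <- 10^seq(log10(0.5), 3, length.out = 10)
  aKee <- vapply(c(1, 3, 5, 10), function(ke)
    curveAmplitude(simulateStationaryTrast(rateParams(kee = ke), env, w)),
    numeric(1))
  expect_true(all(diff(aKee) > 0))
  aAsc <- vapply(c(0, 1, 3, 10), function(a)
    curveAmplitude(simulateStationaryTrast(rateParams(),
      quencherEnvironment("air", TRIS = 50, Asc = a), w)), numeric(1))
  expect_true(all(diff(aAsc) < 0))
})

test_that("oxidation proxy follows the one- and three-photon power laws", {
  p <- rateParams()
  env <- quencherEnvironment("air", TRIS = 50)
  w <- 10^seq(log10(0.5), 3, length.out = 12)
  Is <- exp(seq(log(10), log(81), length.out = 6))
  A <- vapply(Is, function(I) curveAmplitude(
    simulateStationaryTrast(p, env, w,
                            excitationProtocol("ope", Iexc = I))),
    numeric(1))
  sl <- logLogSlope(Is, effectiveOxidationRate(A))$slope
  expect_gt(sl, 0.95); expect_lt(sl, 1.05)
  # TPE: excitation quadratic, effective ejection linear in irradiance
  Is2 <- exp(seq(log(2.6), log(5.2), length.out = 5))
  A2 <- vapply(Is2, function(I) curveAmplitude(
    simulateScannedTrast(p, env,
      wEff = 10^seq(log10(2), log10(690), length.out = 12),
      protocol = excitationProtocol("tpe", Iexc = I),
      model = trastModel(eeIexp = 1, IexcRef = 2.6))), numeric(1))
  sl2 <- logLogSlope(Is2, effectiveOxidationRate(A2))$slope
  expect_gt(sl2, 2.7); expect_lt(sl2, 3.0)
})
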