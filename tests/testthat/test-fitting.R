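test_that("noiseless curves are refit to the generating rates", {
  truth <- tab1Truth()
  curves <- smallCurveSet(truth, noiseSd = 0)
  init <- rateParams(kisc = 2 * 0.93, kee = 2 * 5.3, kred0 = 2 * 2.8,
                     kdeprot0 = 2 * 3.9)
  pmap <- defaultParameterMap(init,
                              free = c("kisc", "kee", "kred0", "kdeprot0"))
  fit <- suppressWarnings(globalFit(curves, truth, pmap))
  tgt <- c(kisc = 0.93, kee = 5.3, kred0 = 2.8, kdeprot0 = 3.9)
  expect_lt(max(abs(fit@estimates[names(tgt)] / tgt - 1)), 0.01)
  expect_true(all(fit@ci[, 1] <= fit@estimates &
                    fit@estimates <= fit@ci[, 2]))
})

test_that("a flat curve drives the ejection rate to its lower bound", {
  env <- quencherEnvironment("air", TRIS = 50)
  pr <- excitationProtocol("ope", Iexc = 43)
  flat <- methods::new("TrastCurve", w = 10^seq(0, 3, length.out = 10),
                       Fnorm = rep(1, 10), sd = rep(NA_real_, 10),
                       env = env, protocol = pr, meta = list())
  pmap <- parameterMap(kee = fitPar(5, lower = 0.01, upper = 100))
  fit <- suppressWarnings(globalFit(list(flat), rateParams(), pmap))
  expect_lt(fit@estimates[["kee"]], 0.02)
})

test_that("fitting is invariant to the order of the curves", {
  truth <- tab1Truth()
  curves <- smallCurveSet(truth, noiseSd = 0.01, seed = 5)
  pmap <- defaultParameterMap(rateParams(kee = 9, kQred_Asc = 0.5),
                              free = c("kee", "kQred_Asc"))
  f1 <- globalFit(curves, truth, pmap)
  f2 <- globalFit(rev(curves), truth, pmap)
  expect_equal(f1@estimates, f2@estimates, tolerance = 1e-3)
  expect_equal(f1@ssr, f2@ssr, tolerance = 1e-6)
})

test_that("log-log slopes are exact for power laws", {
  x <- c(1, 2, 5, 10, 20)
  expect_equal(suppressWarnings(logLogSlope(x, 2 * x))$slope, 1,
               tolerance = 1e-12)
  expect_equal(suppressWarnings(logLogSlope(x, x^3))$slope, 3,
               tolerance = 1e-12)
  sl <- logLogSlope(x, x^2 * exp(rnorm(5, 0, 0.01)))
  expect_true(sl$ci[1] <= sl$slope && sl$slope <= sl$ci[2])
  expect_error(logLogSlope(c(-1, 1, 2), c(1, 2, 3)))
  expect_error(logLogSlope(1:2, 1:2))
})

test_that("information criteria penalize free parameters as defined", {
  mkFit <- function(ssr, k, n = 100) {
    methods::new("TrastFit", estimates = numeric(0),
                 ci = matrix(numeric(0), 0, 2), se = numeric(0),
                 ssr = ssr, nObs = n, nFree = k,
                 aic = n * log(ssr / n) + 2 * k,
                 bic = n * log(ssr / n) + k * log(n),
                 residuals = list(), converged = TRUE,
                 info = list(dataHash = c(n = n, s = 1, s2 = 1)))
  }
  sel <- modelSelection(list(mkFit(1, 3), mkFit(1, 3)))
  expect_equal(sel$dAic, c(0, 0))
  expect_equal(sel$dBic, c(0, 0))
  sel2 <- modelSelection(list(mkFit(1, 3), mkFit(1, 4)), c("small", "big"))
  expect_equal(sel2$model[1], "small")
  expect_equal(sel2$dAic[2], 2)
  expect_equal(sel2$relLik[2], exp(-1))
  # mismatched data are refused
  bad <- mkFit(1, 3, n = 50)
  expect_error(modelSelection(list(mkFit(1, 3), bad)), "identical")
})

test_that("the generating ejection mechanism wins the model comparison", {
  r <- suppressWarnings(eeModelSelectionExperiment(seed = 42,
                                                   nReplicates = 5))
  expect_equal(r$fractionCorrect, 1)
  expect_equal(r$lastSelection$model[1], "singlet")
  expect_gt(r$lastSelection$dAic[2], 10)
})

test_that("linearized confidence intervals cover the truth", {
  # one-parameter fit on a single curve, 50 noisy replicates
  truth <- tab1Truth()
  env <- quencherEnvironment("air", TRIS = 50)
  pr <- excitationProtocol("ope", Iexc = 43)
  w <- 10^seq(log10(0.5), 3, length.out = 12)
  base <- simulateStationaryTrast(truth, env, w, pr)
  pmap <- parameterMap(kee = fitPar(8, lower = 0.5, upper = 50))
  set.seed(77)
  hits <- 0
  for (r in 1:50) {
    Fn <- base@Fnorm * c(1, 1 + rnorm(11, 0, 0.01)) # keep F[w0] = 1
    crv <- methods::initialize(base, Fnorm = Fn)
    fit <- globalFit(list(crv), truth, pmap)
    ci <- fit@ci["kee", ]
    if (ci[1] <= 5.3 && 5.3 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("the two-photon preset fits per-curve ejection rates", {
  truth <- tab1Truth()
  Is <- c(2.6, 3.7, 5.2)
  keeTrue <- 5.3 * Is / 2.6
  wEff <- 10^seq(log10(2), log10(690), length.out = 12)
  env <- quencherEnvironment("air", TRIS = 50)
  curves <- lapply(seq_along(Is), function(i) {
    p <- rateParams(kee = keeTrue[i])
    simulateScannedTrast(p, env, wEff = wEff,
                         protocol = excitationProtocol("tpe",
                                                       Iexc = Is[i]))
  })
  pmap <- tpeParameterMap(rateParams(kee = 10))
  fit <- globalFit(curves, truth, pmap)
  est <- fit@estimates[sprintf("kee[%d]", 1:3)]
  expect_lt(max(abs(est / keeTrue - 1)), 0.05)
  # fitted individual rates rise with irradiance
  expect_true(all(diff(est) > 0))
})
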