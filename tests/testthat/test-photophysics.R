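test_that("effective rates compose linearly in quencher concentrations", {
  p <- rateParams()
  r <- effectiveRates(p, quencherEnvironment(O2 = 1))
  expect_equal(unname(r["kT"]), 0.021 + 1.6 * 1)
  r2 <- effectiveRates(p, quencherEnvironment("argon", Asc = 10))
  expect_equal(unname(r2["kred"]), 2.8 + 0.25 * 10)
  # all concentrations zero: first-order rates unchanged
  r0 <- effectiveRates(p, quencherEnvironment("argon"))
  expect_equal(unname(r0[c("kT", "kred", "kdeprot")]),
               c(p@kT0, p@kred0, p@kdeprot0))
})

test_that("negative composed rates raise an error naming the rate", {
  p <- rateParams()
  # kQred(O2) is negative: enough oxygen drives kred below zero
  expect_error(effectiveRates(p, quencherEnvironment(O2 = 2)), "kred")
  # unknown quencher names are rejected at construction
  expect_error(quencherEnvironment("helium"), "atmosphere")
  expect_error(methods::new("QuencherEnvironment",
                            conc = c(O2 = 0, Asc = 0, TRIS = 0, H2O2 = 0,
                                     XYZ = 1),
                            atmosphere = "air"))
})

test_that("the lifetime constraint fixes k10 and rejects impossible rates", {
  p <- rateParams()
  expect_equal(k10(p), 1e3 / 0.4 - 0.93 - 5.3)
  # combined singlet decay rates must equal 1/tauF after constraint
  expect_equal(k10(p) + p@kisc + p@kee, 1e3 / p@tauF, tolerance = 1e-12)
  expect_error(rateParams(kisc = 2000, kee = 600), "k10")
})

test_that("the rate matrix conserves probability and encodes transitions", {
  p <- rateParams()
  env <- quencherEnvironment("air")
  M <- buildRateMatrix(p, env, k01 = 1.54)
  expect_lt(max(abs(colSums(M))), 1e-12 * max(abs(M)))
  expect_equal(M["singlet", "ground"], 1.54)
  expect_equal(M["ground", "singlet"], 2500 - 0.93 - 5.3)
  # triplet-source variant moves the ejection edge and relaxes k10
  Mt <- buildRateMatrix(p, env, 1.54, eeSource = "triplet")
  expect_equal(Mt["radical", "triplet"], p@kee)
  expect_equal(Mt["radical", "singlet"], 0)
  expect_equal(Mt["ground", "singlet"], 2500 - 0.93)
  expect_error(buildRateMatrix(p, env, -1))
})

test_that("propagation is exact at t = 0 and conserves populations", {
  p <- rateParams()
  M <- buildRateMatrix(p, quencherEnvironment("air"), 1.54)
  p0 <- c(1, 0, 0, 0, 0, 0)
  P <- propagateStates(M, p0, c(0, 0.1, 1, 10, 100, 1000))
  expect_equal(unname(P[, 1]), p0)
  expect_lt(max(abs(colSums(P) - 1)), 1e-9)
  expect_true(all(P >= 0 & P <= 1))
  # k01 = 0 makes the ground state absorbing
  M0 <- buildRateMatrix(p, quencherEnvironment("air"), 0)
  P0 <- propagateStates(M0, p0, c(0, 1, 1000))
  expect_equal(unname(P0[1, ]), rep(1, 3))
})

test_that("matrix-exponential propagation matches a 10 ps Euler oracle", {
  p <- rateParams()
  M <- buildRateMatrix(p, quencherEnvironment("air", TRIS = 50), 1.54)
  p0 <- c(1, 0, 0, 0, 0, 0)
  times <- c(0.1, 1, 10, 100, 1000)
  P <- propagateStates(M, p0, times)
  for (i in seq_along(times)) {
    ref <- eulerPropagate(M, p0, times[i], dt = 1e-5)
    expect_lt(max(abs(P[, i] - ref)), 1e-6)
  }
})

test_that("without dark pathways the singlet reaches the two-state value", {
  p <- rateParams(kisc = 0, kee = 0)
  k01 <- 1.54
  M <- buildRateMatrix(p, quencherEnvironment("air"), k01)
  P <- propagateStates(M, c(1, 0, 0, 0, 0, 0), c(0, 1))
  expect_equal(unname(P[2, 2]), k01 / (k01 + k10(p)), tolerance = 1e-9)
})

test_that("dark states accumulate monotonically when recovery is off", {
  p <- rateParams(krecRadial = 0, krecAxial = 0)
  M <- buildRateMatrix(p, quencherEnvironment("air", TRIS = 50), 1.54)
  P <- propagateStates(M, c(1, 0, 0, 0, 0, 0),
                       10^seq(-1, 3, length.out = 40))
  expect_true(all(diff(P[1, ]) <= 1e-12))
})

test_that("quantum yields follow Phi = k tauF", {
  qy <- quantumYields(rateParams())
  expect_equal(unname(qy["PhiT"]), 0.93 * 0.4e-3)
  expect_equal(unname(qy["PhiEe"]), 5.3 * 0.4e-3)
  expect_equal(unname(quantumYields(rateParams(kisc = 0))["PhiT"]), 0)
})
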