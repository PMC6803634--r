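# Independent numerical oracles and small fixtures used across tests.

# Explicit fixed-step Euler propagation p(t) = (I + M dt)^N p0, computed
# exactly (in exact arithmetic it IS explicit Euler) via binary powering of
# the step matrix, which makes dt = 10 ps over millisecond horizons
# tractable. Independent of the eigendecomposition used by the package.
eulerPropagate <- function(M, p0, t, dt = 1e-5) {
  if (t == 0) return(p0)
  N <- round(t / dt)
  A <- diag(nrow(M)) + M * dt
  P <- diag(nrow(M))
  base <- A
  n <- N
  while (n > 0) {
    if (n %% 2 == 1) P <- P %*% base
    base <- base %*% base
    n <- n %/% 2
  }
  as.numeric(P %*% p0)
}

# Dense-grid trapezoid pulse average of the singlet population, using the
# package's propagator only as an ODE solver on an explicit grid; oracle
# for the closed-form eigenvalue average used by the TRAST engine.
trapzAvgSinglet <- function(M, w, nGrid = 4000) {
  k01 <- M[2, 1]
  pS <- k01 / (k01 - M[2, 2])
  p0 <- c(1 - pS, pS, 0, 0, 0, 0)
  tt <- unique(c(0, exp(seq(log(w * 1e-5), log(w), length.out = nGrid))))
  P <- propagateStates(M, p0, tt)
  sum(diff(tt) * (P[2, -1] + P[2, -length(tt)]) / 2) / w
}

# Small curve family for fitting tests: three irradiances in air, one
# argon, one ascorbate curve.
smallCurveSet <- function(params, w = 10^seq(log10(0.5), 3,
                                             length.out = 12),
                          noiseSd = 0, seed = 1) {
  design <- data.frame(
    Iexc = c(15, 43, 81, 43, 43),
    atmosphere = c("air", "air", "air", "argon", "air"),
    Asc = c(0, 0, 0, 0, 5), TRIS = 50, H2O2 = 0, OH = 0,
    series = "test")
  genSolutionDataset(params, design = design, w = w, noiseSd = noiseSd,
                     seed = seed)
}

# blobby test image with a few Gaussian spots
blobImage <- function(ny = 64, nx = 64, nBlobs = 6, amp = 200, seed = 3) {
  set.seed(seed)
  img <- matrix(0, ny, nx)
  for (k in seq_len(nBlobs)) {
    cy <- runif(1, 15, ny - 15); cx <- runif(1, 15, nx - 15)
    s <- runif(1, 3, 6)
    img <- img + outer(seq_len(ny), seq_len(nx), function(y, x)
      amp * exp(-((y - cy)^2 + (x - cx)^2) / (2 * s^2)))
  }
  img
}

tab1Truth <- function() rateParams()

tab1CiHalf <- c(kisc = 0.21, kT0 = 0.0044, kQT_O2 = 0.29, kee = 0.49,
                kred0 = 0.51, kQred_O2 = 0.34, kQred_Asc = 0.027,
                kdeprot0 = 0.38, kQdeprot_TRIS = 0.0033,
                kQdeprot_H2O2 = 0.23, kQdeprot_OH = 0.055)
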