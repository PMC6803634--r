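# Forward simulation of TRAST curves and TRAST summary statistics.

#' TRAST model variants
#'
#' Options selecting between candidate electronic-state models when
#' simulating or fitting: where electron ejection departs from
#' (singlet/triplet) and how the effective ejection rate scales with local
#' irradiance (exponent 0: constant, the linear one-photon model; 1:
#' proportional to irradiance, used for the effective rate through higher
#' excited states under TPE; 2: quadratic).
#'
#' @param eeSource \code{"singlet"} or \code{"triplet"}.
#' @param eeIexp irradiance exponent of the effective kee.
#' @param IexcRef reference irradiance at which kee equals the nominal
#'   parameter value (same unit as the protocol irradiance).
#' @return list of class options.
#' @export
trastModel <- function(eeSource = c("singlet", "triplet"), eeIexp = 0,
                       IexcRef = 43) {
  list(eeSource = match.arg(eeSource), eeIexp = eeIexp, IexcRef = IexcRef)
}

# (exp(z) - 1)/z, stable near 0; z may be complex
.phi1 <- function(z) {
  small <- Mod(z) < 1e-8
  z[small] <- 1e-8 # avoid 0/0; overwritten below
  out <- (exp(z) - 1) / z
  out[small] <- 1
  out
}

# Pulse-averaged singlet population for one rate matrix over durations w,
# starting from the singlet-equilibrated bright manifold (the ns-scale
# singlet rise is excluded from the average; w >> tauF always holds here).
.pulseAvgSinglet <- function(M, w) {
  k01 <- M[2, 1]
  kS <- -M[2, 2] # total singlet depopulation rate
  # bright-manifold equilibration: k01 p_ground = kS p_singlet
  pS <- k01 / (k01 + kS)
  p0 <- c(1 - pS, pS, 0, 0, 0, 0)
  out <- .pulseAvgSingletCpp(M, w)
  if (length(out) == length(w)) return(out)
  ek <- .eigenKinetics(M)
  out <- NULL
  if (!is.null(ek)) {
    alpha <- tryCatch(solve(ek$vectors, as.complex(p0)),
                      error = function(e) NULL)
    if (!is.null(alpha)) {
      c2 <- ek$vectors[2, ] * alpha
      Z <- outer(ek$values, w)
      out <- Re(drop(crossprod(.phi1(Z), c2)))
      if (any(!is.finite(out))) out <- NULL
    }
  }
  if (!is.null(out)) out else {
    # fallback: dense propagation + trapezoid time average
    vapply(w, function(wi) {
      tt <- unique(c(0, exp(seq(log(wi * 1e-4), log(wi), length.out = 400))))
      P <- propagateStates(M, p0, tt)
      sum(diff(tt) * (P[2, -1] + P[2, -length(tt)]) / 2) / wi
    }, numeric(1))
  }
}

# fast matrix assembly from precomposed rates (hot path of the fitter)
.buildM <- function(r, params, k01, eeSource, keeScale) {
  kee <- params@kee * keeScale
  singlet <- eeSource == "singlet"
  k10v <- 1e3 / params@tauF - params@kisc - if (singlet) params@kee else 0
  M <- matrix(0, 6, 6)
  M[2, 1] <- k01
  M[1, 2] <- k10v
  M[3, 2] <- r[["kisc"]]
  if (singlet) M[4, 2] <- kee else M[4, 3] <- kee
  M[1, 3] <- r[["kT"]]
  M[1, 4] <- r[["kred"]]
  M[5, 4] <- params@fRadial * r[["kdeprot"]]
  M[6, 4] <- (1 - params@fRadial) * r[["kdeprot"]]
  M[1, 5] <- params@krecRadial
  M[1, 6] <- params@krecAxial
  diag(M) <- -colSums(M)
  M
}

# per-curve constants of the shell average (reused across fit iterations)
.shellSetup <- function(protocol, model) {
  shells <- discretizeBeam(protocol@beam, protocol@Iexc, protocol@mode)
  k01s <- if (protocol@mode == "ope")
    excitationRateOpe(shells$irradiance, protocol@beam)
  else excitationRateTpe(shells$irradiance, protocol)
  keeScales <- if (model$eeIexp == 0) rep(1, nrow(shells)) else
    (shells$irradiance / model$IexcRef)^model$eeIexp
  list(k01s = k01s, keeScales = keeScales, weights = shells$weight)
}

# Shell-averaged unnormalized TRAST signal F(w) for one curve's conditions.
.simulateTrastF <- function(params, env, protocol, w,
                            model = trastModel(), setup = NULL) {
  if (is.null(setup)) setup <- .shellSetup(protocol, model)
  r <- effectiveRates(params, env) # composed once per curve
  singlet <- model$eeSource == "singlet"
  k10v <- 1e3 / params@tauF - params@kisc - if (singlet) params@kee else 0
  rates <- c(k10v, r[["kisc"]], params@kee, r[["kT"]], r[["kred"]],
             r[["kdeprot"]], params@fRadial, params@krecRadial,
             params@krecAxial)
  F <- .trastShellSumCpp(rates, singlet, setup$k01s, setup$keeScales,
                         setup$weights, w)
  if (length(F) == length(w)) return(F)
  # fallback: per-shell R path (dense propagation inside if needed)
  F <- numeric(length(w))
  for (j in seq_along(setup$k01s)) {
    M <- .buildM(r, params, setup$k01s[j], model$eeSource,
                 setup$keeScales[j])
    F <- F + setup$weights[j] * .pulseAvgSinglet(M, w)
  }
  F
}

.trastCurve <- function(w, Fnorm, sd, env, protocol, meta = list()) {
  methods::new("TrastCurve", w = w, Fnorm = Fnorm,
               sd = as.numeric(sd), env = env, protocol = protocol,
               meta = meta)
}

#' Simulate a stationary (pulse-train) TRAST curve
#'
#' For each shell of the discretized beam the six-state kinetics are
#' propagated over a rectangular pulse [0, w] from the singlet-equilibrated
#' bright state; the singlet population is pulse-averaged in closed form
#' from the eigendecomposition of the generator, CEF-weighted over shells,
#' and normalized at the shortest duration. All pulses of the train are
#' assumed identical (low duty cycle); a warning is issued when the
#' inter-pulse dead time at the longest duration is too short for the
#' slowest recovery pool to relax (rate x dead time < 5).
#'
#' @param params a [RateParams-class].
#' @param env a [QuencherEnvironment-class].
#' @param w ascending pulse durations, us.
#' @param protocol an [ExcitationProtocol-class] (stationary OPE by default).
#' @param model a [trastModel()] variant.
#' @return a [TrastCurve-class].
#' @examples
#' crv <- simulateStationaryTrast(rateParams(),
#'   quencherEnvironment("air", TRIS = 50),
#'   w = 10^seq(-0.3, 3, length.out = 12),
#'   protocol = excitationProtocol("ope", Iexc = 43))
#' @export
simulateStationaryTrast <- function(params, env, w,
                                    protocol = excitationProtocol("ope",
                                      Iexc = 43),
                                    model = trastModel()) {
  if (!length(w)) stop("w must be non-empty")
  if (is.unsorted(w, strictly = TRUE)) stop("w must be strictly ascending")
  deadTime <- max(w) * (1 / protocol@dutyCycle - 1)
  slowest <- min(params@krecRadial, params@krecAxial)
  if (slowest * deadTime < 5)
    warning("inter-pulse dead time may be too short for full recovery ",
            "(slowest recovery rate x dead time = ",
            signif(slowest * deadTime, 3), " < 5)")
  F <- .simulateTrastF(params, env, protocol, w, model)
  .trastCurve(w, F / F[1], rep(NA_real_, length(w)), env, protocol,
              meta = list(engine = "stationary"))
}

#' Simulate a scanned TRAST curve
#'
#' Converts each scan speed to its effective rectangular dwell via
#' [effectiveDwell()] and reuses the stationary engine; the curve is
#' normalized at the dwell of the fastest speed.
#'
#' @param params a [RateParams-class].
#' @param env a [QuencherEnvironment-class].
#' @param speeds scan speeds (um/ms), or NULL when \code{wEff} is given.
#' @param protocol an [ExcitationProtocol-class] (its mode selects the
#'   OPE/TPE dwell rule and excitation law).
#' @param wEff effective dwell times (us), alternative to \code{speeds}.
#' @param model a [trastModel()] variant.
#' @return a [TrastCurve-class] (w holds the ascending effective dwells).
#' @export
simulateScannedTrast <- function(params, env, speeds = NULL,
                                 protocol = excitationProtocol("tpe",
                                   Iexc = 2.6),
                                 wEff = NULL, model = trastModel()) {
  if (is.null(wEff)) {
    if (is.null(speeds) || !length(speeds)) stop("give speeds or wEff")
    wEff <- effectiveDwell(speeds, protocol@beam, protocol@mode)
  }
  wEff <- sort(wEff)
  F <- .simulateTrastF(params, env, protocol, wEff, model)
  .trastCurve(wEff, F / F[1], rep(NA_real_, length(wEff)), env, protocol,
              meta = list(engine = "scanned"))
}

#' TRAST decay amplitude from fast/slow fluorescence
#'
#' \code{A = (F_fast - F_slow) / F_fast}. Non-positive fast signal yields NA
#' (an undefined-pixel marker), never 0.
#'
#' @param Ffast,Fslow fluorescence signals (counts), vectorized.
#' @return numeric amplitude(s) in (-Inf, 1).
#' @examples
#' trastAmplitude(1.0, 0.57)  # 0.43
#' @export
trastAmplitude <- function(Ffast, Fslow) {
  A <- (Ffast - Fslow) / Ffast
  A[!is.finite(Ffast) | Ffast <= 0] <- NA_real_
  A
}

#' Decay amplitude of a TRAST curve
#'
#' A_TRAST between the curve's shortest duration and a slow duration
#' (default: the longest simulated/measured w), interpolating on log(w).
#'
#' @param curve a [TrastCurve-class].
#' @param wSlow slow duration, us.
#' @return amplitude in [0, 1).
#' @export
curveAmplitude <- function(curve, wSlow = max(curve@w)) {
  Fs <- stats::approx(log(curve@w), curve@Fnorm, xout = log(wSlow),
                      rule = 2)$y
  trastAmplitude(1, Fs)
}

#' Effective photo-oxidation rate proxy
#'
#' In the absence of excitation saturation the effective oxidation rate is
#' proportional to \code{A / (1 - A)}.
#'
#' @param A TRAST amplitude(s), < 1.
#' @return A/(1-A).
#' @export
effectiveOxidationRate <- function(A) {
  if (any(A >= 1, na.rm = TRUE)) stop("amplitude must be < 1")
  A / (1 - A)
}
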