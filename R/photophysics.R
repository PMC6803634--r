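# Six-state electronic model of NADH and its rate-matrix kinetics.
# State ordering used everywhere:
#   1 ground (0NADH), 2 singlet (1NADH), 3 triplet (TNADH),
#   4 radical cation (.NADH+), 5 NAD+ radial pool, 6 NAD+ axial pool
.STATES <- c("ground", "singlet", "triplet", "radical", "oxRadial", "oxAxial")

#' Construct photophysical rate parameters
#'
#' Defaults are the rate constants determined for NADH in aqueous solution
#' under 355 nm one-photon excitation by global TRAST-curve fitting
#' (rates in 1/us, quencher coefficients in 1/(mM us), tauF in ns).
#' \code{k10} is derived from the lifetime constraint
#' \code{k10 + kisc + kee = 1/tauF} and is not an argument.
#'
#' The two oxidized pools model diffusion-mediated replenishment of intact
#' NADH in the detection volume along the radial and axial directions of the
#' focus; their recovery rates and the branching \code{fRadial} are
#' configurable defaults (millisecond-scale recovery), not literature values.
#'
#' @param kisc,kT0,kQT_O2,kee,kred0,kQred_O2,kQred_Asc,kdeprot0,kQdeprot_TRIS,kQdeprot_H2O2,kQdeprot_OH
#'   rate constants; see [RateParams-class].
#' @param tauF fluorescence lifetime in ns.
#' @param fRadial branching of oxidized NAD+ into the radial recovery pool.
#' @param krecRadial,krecAxial recovery rates of the two pools, 1/us.
#' @return a [RateParams-class] object.
#' @examples
#' p <- rateParams()
#' k10(p)          # ~2493.77 1/us
#' quantumYields(p)
#' @export
rateParams <- function(kisc = 0.93, kT0 = 0.021, kQT_O2 = 1.6,
                       kee = 5.3, kred0 = 2.8,
                       kQred_O2 = -1.6, kQred_Asc = 0.25,
                       kdeprot0 = 3.9, kQdeprot_TRIS = 0.012,
                       kQdeprot_H2O2 = 0.4, kQdeprot_OH = 0.16,
                       tauF = 0.4, fRadial = 0.5,
                       krecRadial = 1e-3, krecAxial = 1e-4) {
  methods::new("RateParams",
    kisc = kisc, kT0 = kT0, kQT = c(O2 = kQT_O2),
    kee = kee, kred0 = kred0,
    kQred = c(O2 = kQred_O2, Asc = kQred_Asc),
    kdeprot0 = kdeprot0,
    kQdeprot = c(TRIS = kQdeprot_TRIS, H2O2 = kQdeprot_H2O2,
                 OH = kQdeprot_OH),
    tauF = tauF, fRadial = fRadial,
    krecRadial = krecRadial, krecAxial = krecAxial)
}

#' Derived singlet decay rate from the lifetime constraint
#'
#' @param params a [RateParams-class].
#' @param eeFromSinglet does electron ejection depart from the singlet
#'   (default) or from the triplet (alternative model variants)? The
#'   constraint removes from 1/tauF only rates that depopulate the singlet.
#' @return k10 in 1/us.
#' @export
k10 <- function(params, eeFromSinglet = TRUE) {
  1e3 / params@tauF - params@kisc - if (eeFromSinglet) params@kee else 0
}

#' Dark-state quantum yields
#'
#' Phi_T = kisc * tauF and Phi_ee = kee * tauF, the probabilities per
#' excitation of crossing to the triplet or ejecting an electron.
#'
#' @param params a [RateParams-class].
#' @return named numeric \code{c(PhiT, PhiEe)}.
#' @export
quantumYields <- function(params) {
  stopifnot(params@tauF > 0)
  tauUs <- params@tauF * 1e-3
  c(PhiT = params@kisc * tauUs, PhiEe = params@kee * tauUs)
}

#' Construct a solution environment
#'
#' Oxygen concentration is resolved from the atmosphere tag unless given
#' explicitly. The aqueous solubility defaults (air 0.27 mM, pure oxygen
#' 1.3 mM, argon 0 mM) are configurable implementation defaults.
#'
#' @param atmosphere \code{"air"}, \code{"oxygen"} or \code{"argon"}.
#' @param O2 explicit O2 concentration in mM (overrides the atmosphere).
#' @param Asc,TRIS,H2O2,OH quencher concentrations, mM.
#' @param o2Map named numeric mapping atmosphere tags to O2 mM.
#' @return a [QuencherEnvironment-class].
#' @examples
#' quencherEnvironment("air", TRIS = 50)
#' @export
quencherEnvironment <- function(atmosphere = "air", O2 = NULL,
                                Asc = 0, TRIS = 0, H2O2 = 0, OH = 0,
                                o2Map = c(air = 0.27, oxygen = 1.3,
                                          argon = 0)) {
  if (is.null(O2)) {
    if (!atmosphere %in% names(o2Map))
      stop("unknown atmosphere: ", atmosphere)
    O2 <- unname(o2Map[atmosphere])
  } else {
    atmosphere <- "custom"
  }
  methods::new("QuencherEnvironment",
    conc = c(O2 = O2, Asc = Asc, TRIS = TRIS, H2O2 = H2O2, OH = OH),
    atmosphere = atmosphere)
}

.composeRate <- function(k0, kQ, conc, what) {
  k <- k0 + sum(kQ * conc[names(kQ)])
  if (!is.finite(k) || k < 0)
    stop("invalid environment: composed rate ", what, " = ",
         signif(k, 4), " 1/us is negative", call. = FALSE)
  k
}

#' Compose environment-dependent first-order rates
#'
#' Applies the linear quencher-concentration dependencies:
#' \code{kT = kT0 + kQT_O2 [O2]}, \code{kred = kred0 + sum kQred [X]},
#' \code{kdeprot = kdeprot0 + sum kQdeprot [X]}. A composed rate that comes
#' out negative (possible because kQred(O2) < 0) is an error, not a clamp:
#' it flags unphysical extrapolation of the linear model.
#'
#' @param params a [RateParams-class].
#' @param env a [QuencherEnvironment-class].
#' @return named numeric with \code{kT, kred, kdeprot} (plus the
#'   environment-independent \code{kisc, kee, k10} for convenience).
#' @examples
#' p <- rateParams()
#' effectiveRates(p, quencherEnvironment(O2 = 1))["kT"]    # 1.621
#' effectiveRates(p, quencherEnvironment("argon", Asc = 10))["kred"] # 5.3
#' @export
effectiveRates <- function(params, env) {
  methods::validObject(env)
  conc <- env@conc
  c(kT = .composeRate(params@kT0, params@kQT, conc, "kT"),
    kred = .composeRate(params@kred0, params@kQred, conc, "kred"),
    kdeprot = .composeRate(params@kdeprot0, params@kQdeprot, conc,
                           "kdeprot"),
    kisc = params@kisc, kee = params@kee, k10 = k10(params))
}

#' Assemble the 6x6 rate-matrix generator
#'
#' Encodes the electronic-state kinetics dp/dt = M p with columns summing to
#' zero (probability conservation). Transitions: ground->singlet (k01),
#' singlet->ground (k10, derived from the lifetime constraint),
#' singlet->triplet (kisc), triplet->ground (kT), electron ejection to the
#' radical cation (kee, from the singlet by default or from the triplet for
#' the alternative model variant), radical->ground (kred), radical->oxidized
#' pools (fRadial kdeprot and (1-fRadial) kdeprot), and pool recovery
#' (krecRadial, krecAxial).
#'
#' @param params a [RateParams-class].
#' @param env a [QuencherEnvironment-class].
#' @param k01 excitation rate, 1/us.
#' @param eeSource \code{"singlet"} (default) or \code{"triplet"}: which
#'   state the electron is ejected from.
#' @param keeScale multiplier on kee (used by model variants where the
#'   effective ejection rate scales with local irradiance).
#' @return 6x6 numeric matrix with dimnames over the model states.
#' @export
buildRateMatrix <- function(params, env, k01, eeSource = c("singlet",
                            "triplet"), keeScale = 1) {
  eeSource <- match.arg(eeSource)
  if (!is.finite(k01) || k01 < 0) stop("k01 must be finite and >= 0")
  r <- effectiveRates(params, env)
  kee <- params@kee * keeScale
  k10v <- k10(params, eeFromSinglet = eeSource == "singlet")
  M <- matrix(0, 6, 6, dimnames = list(.STATES, .STATES))
  M[2, 1] <- k01
  M[1, 2] <- k10v
  M[3, 2] <- r[["kisc"]]
  if (eeSource == "singlet") M[4, 2] <- kee else M[4, 3] <- kee
  M[1, 3] <- r[["kT"]]
  M[1, 4] <- r[["kred"]]
  M[5, 4] <- params@fRadial * r[["kdeprot"]]
  M[6, 4] <- (1 - params@fRadial) * r[["kdeprot"]]
  M[1, 5] <- params@krecRadial
  M[1, 6] <- params@krecAxial
  diag(M) <- -colSums(M)
  M
}

# Eigendecomposition helper shared by propagation and the TRAST engine.
# Returns NULL when the eigenvector basis is too ill-conditioned, in which
# case callers fall back to scaling-and-squaring matrix exponentials.
.eigenKinetics <- function(M) {
  e <- eigen(M)
  if (any(!is.finite(Mod(e$vectors)))) return(NULL)
  list(values = e$values, vectors = e$vectors)
}

#' Propagate state populations in time
#'
#' Solves p(t) = expm(M t) p0 through the eigendecomposition of the
#' generator, with a scaling-and-squaring matrix exponential as fallback for
#' (near-)defective generators.
#'
#' @param M generator from [buildRateMatrix()].
#' @param p0 initial populations (length 6, sums to 1).
#' @param times ascending non-negative times, us.
#' @return 6 x length(times) matrix of populations (states in rows).
#' @export
propagateStates <- function(M, p0, times) {
  stopifnot(length(p0) == nrow(M))
  if (abs(sum(p0) - 1) > 1e-9) stop("p0 must sum to 1")
  if (any(times < 0) || is.unsorted(times)) stop("times must be ascending, >= 0")
  ek <- .eigenKinetics(M)
  alpha <- if (!is.null(ek))
    tryCatch(solve(ek$vectors, as.complex(p0)), error = function(e) NULL)
  else NULL
  if (!is.null(alpha)) {
    P <- vapply(times, function(t)
      Re(ek$vectors %*% (alpha * exp(ek$values * t)))[, 1],
      numeric(nrow(M)))
  } else {
    P <- vapply(times, function(t)
      as.numeric(Matrix::expm(M * t) %*% p0), numeric(nrow(M)))
  }
  P <- matrix(P, nrow = nrow(M),
              dimnames = list(rownames(M), NULL))
  if (any(!is.finite(P)))
    stop("non-finite populations at t = ",
         times[which(!is.finite(colSums(P)))[1]])
  # clip tiny negative round-off
  P[P < 0 & P > -1e-9] <- 0
  P
}
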