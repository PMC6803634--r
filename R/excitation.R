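# Conversion of instrument settings (irradiance, beam geometry, pulse train,
# scan speed) into excitation rates and effective dwell times.

#' Construct a beam profile
#'
#' Defaults correspond to the one-photon setup (355 nm, 863 nm waist,
#' sigma = 2.0e-17 cm^2); use [tpeBeam()] for the two-photon geometry.
#' The collection efficiency function (CEF) is modeled as a Gaussian weight
#' whose 1/e^2 radius defaults to twice the beam waist (broad, near-open
#' pinhole).
#'
#' @param wavelength nm.
#' @param waist 1/e^2 focal radius, nm.
#' @param sigmaOpe one-photon cross section, cm^2.
#' @param sigmaTpe two-photon cross section, GM.
#' @param nShells radial discretization of the Gaussian profile.
#' @param cefRadius CEF 1/e^2 radius, nm (default 2 x waist).
#' @return a [BeamProfile-class].
#' @export
beamProfile <- function(wavelength = 355, waist = 863, sigmaOpe = 2.0e-17,
                        sigmaTpe = 0.4, nShells = 16,
                        cefRadius = 2 * waist) {
  methods::new("BeamProfile", wavelength = wavelength, waist = waist,
               sigmaOpe = sigmaOpe, sigmaTpe = sigmaTpe,
               nShells = nShells, cefRadius = cefRadius)
}

#' Two-photon beam profile preset
#'
#' 735 nm, 327 nm waist, 0.4 GM cross section.
#' @inheritParams beamProfile
#' @return a [BeamProfile-class].
#' @export
tpeBeam <- function(wavelength = 735, waist = 327, sigmaTpe = 0.4,
                    nShells = 16, cefRadius = 2 * waist) {
  beamProfile(wavelength = wavelength, waist = waist, sigmaOpe = 0,
              sigmaTpe = sigmaTpe, nShells = nShells,
              cefRadius = cefRadius)
}

#' Construct an excitation protocol
#'
#' @param mode \code{"ope"} or \code{"tpe"}.
#' @param Iexc time-averaged peak irradiance: kW/cm^2 (OPE) or MW/cm^2 (TPE).
#' @param beam a [BeamProfile-class]; defaults to the mode's preset.
#' @param scanned TRUE for scan-speed modulated excitation.
#' @param dutyCycle stationary pulse-train duty cycle.
#' @param repRateMHz,pulseFs fs-laser repetition rate and pulse width (TPE).
#' @return an [ExcitationProtocol-class].
#' @export
excitationProtocol <- function(mode = c("ope", "tpe"), Iexc,
                               beam = NULL, scanned = mode == "tpe",
                               dutyCycle = 0.01, repRateMHz = 76,
                               pulseFs = 150) {
  mode <- match.arg(mode)
  if (is.null(beam)) beam <- if (mode == "ope") beamProfile() else tpeBeam()
  methods::new("ExcitationProtocol", mode = mode, scanned = scanned,
               Iexc = Iexc, beam = beam, dutyCycle = dutyCycle,
               repRateMHz = repRateMHz, pulseFs = pulseFs)
}

#' One-photon excitation rate
#'
#' k01 = sigma * Phi_exc with the photon flux Phi_exc = I lambda / (h c).
#'
#' @param Iexc irradiance, kW/cm^2.
#' @param beam a [BeamProfile-class].
#' @return excitation rate, 1/us.
#' @examples
#' excitationRateOpe(43, beamProfile())  # ~1.54 1/us
#' @export
excitationRateOpe <- function(Iexc, beam) {
  stopifnot(all(Iexc >= 0))
  flux <- Iexc * 1e3 * beam@wavelength * 1e-9 / .HC_JM # photons/(cm^2 s)
  beam@sigmaOpe * flux * 1e-6
}

#' Period-averaged two-photon excitation rate
#'
#' Each fs pulse is treated as rectangular of width pulseFs, so the peak
#' photon flux is \code{Phi_pk = (I_avg / (f tau_p)) lambda / (h c)} and the
#' period-averaged excitation rate is
#' \code{k01 = sigma2 Phi_pk^2 f tau_p = sigma2 (I_avg lambda / hc)^2 / (f tau_p)},
#' quadratic in the time-averaged irradiance.
#'
#' @param Iavg time-averaged irradiance, MW/cm^2.
#' @param protocol an [ExcitationProtocol-class] in TPE mode (supplies the
#'   repetition rate and pulse width).
#' @param beam a [BeamProfile-class]; defaults to the protocol's beam.
#' @return excitation rate, 1/us.
#' @examples
#' pr <- excitationProtocol("tpe", Iexc = 2.6)
#' excitationRateTpe(2.6, pr)  # ~0.033 1/us (3.3e4 1/s)
#' @export
excitationRateTpe <- function(Iavg, protocol, beam = protocol@beam) {
  stopifnot(all(Iavg >= 0))
  fsDuty <- protocol@repRateMHz * 1e6 * protocol@pulseFs * 1e-15
  stopifnot(fsDuty > 0, fsDuty < 1)
  fluxAvg <- Iavg * 1e6 * beam@wavelength * 1e-9 / .HC_JM
  beam@sigmaTpe * 1e-50 * fluxAvg^2 / fsDuty * 1e-6
}

# mode-dependent dwell constants: a Gaussian (OPE) or squared-Gaussian (TPE)
# beam pass is replaced by the rectangular pulse of equal time-integral of
# k01 (OPE) resp. k01^2-driven excitation (TPE) at the pass-peak amplitude.
.dwellConst <- function(mode) {
  switch(mode, ope = sqrt(pi / 2), tpe = sqrt(pi) / 2,
         stop("mode must be 'ope' or 'tpe'"))
}

#' Effective excitation duration of a beam pass
#'
#' Converts scan speed to the duration of the integral-preserving
#' rectangular pulse: \code{w_eff = sqrt(pi/2) w0 / v} for OPE and
#' \code{w_eff = (sqrt(pi)/2) w0 / v} for TPE (the excitation profile of a
#' scanned pass is the Gaussian beam profile, squared under TPE).
#'
#' @param v scan speed, um/ms.
#' @param beam a [BeamProfile-class].
#' @param mode \code{"ope"} or \code{"tpe"}.
#' @return effective dwell time, us.
#' @examples
#' effectiveDwell(100, beamProfile(waist = 327), "ope")  # ~4.10 us
#' @export
effectiveDwell <- function(v, beam, mode = c("ope", "tpe")) {
  mode <- match.arg(mode)
  if (any(v <= 0)) stop("scan speed must be > 0")
  .dwellConst(mode) * (beam@waist * 1e-3) / v * 1e3
}

#' Scan speed giving a requested effective dwell
#'
#' Exact inverse of [effectiveDwell()].
#' @param wEff effective dwell, us.
#' @param beam a [BeamProfile-class].
#' @param mode \code{"ope"} or \code{"tpe"}.
#' @return scan speed, um/ms.
#' @export
speedForDwell <- function(wEff, beam, mode = c("ope", "tpe")) {
  mode <- match.arg(mode)
  if (any(wEff <= 0)) stop("wEff must be > 0")
  .dwellConst(mode) * (beam@waist * 1e-3) / (wEff * 1e-3)
}

#' Discretize the Gaussian beam into equal-probability shells
#'
#' The radial excitation profile is split into \code{nShells} annuli of
#' equal detected-signal probability (measure proportional to
#' \code{I(r)^m CEF(r)} with m = 1 for OPE, 2 for TPE), each represented by
#' its probability-median irradiance and its CEF volume weight. With
#' \code{nShells = 1} this degenerates to a single evaluation at the
#' CEF-averaged irradiance.
#'
#' @param beam a [BeamProfile-class].
#' @param Ipeak peak (on-axis) irradiance, any unit.
#' @param mode \code{"ope"} or \code{"tpe"}.
#' @param nShells override of \code{beam@nShells}.
#' @return data.frame with columns \code{irradiance} and \code{weight}
#'   (weights sum to 1).
#' @export
discretizeBeam <- function(beam, Ipeak, mode = c("ope", "tpe"),
                           nShells = beam@nShells) {
  mode <- match.arg(mode)
  n <- as.integer(nShells)
  stopifnot(n >= 1)
  m <- if (mode == "ope") 1 else 2
  w2 <- (beam@waist * 1e-3)^2      # um^2
  wc2 <- (beam@cefRadius * 1e-3)^2
  c0 <- 2 * m / w2                 # excitation-law profile ~ exp(-c0 u)
  b <- 2 / wc2                     # CEF measure            ~ exp(-b u)
  a <- b + c0                      # detected-signal measure ~ exp(-a u)
  # equal-probability edges in the signal measure; u = r^2
  qs <- seq(0, 1, length.out = n + 1)
  uEdge <- -log(1 - qs) / a        # last edge = Inf
  expd <- function(k) exp(-k * uEdge[-(n + 1)]) - exp(-k * uEdge[-1])
  cefMass <- expd(b) / b
  qMass <- expd(a) / a
  # representative irradiance preserves the CEF-weighted mean of I^m within
  # each shell, so the low-saturation signal is exact at any n
  Ij <- Ipeak * (qMass / cefMass)^(1 / m)
  data.frame(irradiance = Ij, weight = cefMass / sum(cefMass))
}
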