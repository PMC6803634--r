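# Internal unit conventions, used throughout:
#   time        micro-seconds (fluorescence lifetimes in ns where stated)
#   rates       1/us; second-order quencher coefficients 1/(mM us)
#   conc        mM
#   irradiance  kW/cm^2 (one-photon), MW/cm^2 (time-averaged, two-photon)
#   lengths     nm (beam geometry), um (images, scan paths)

.HC_JM <- 1.98644586e-25 # Planck constant x speed of light [J m]

.QUENCHERS <- c("O2", "Asc", "TRIS", "H2O2", "OH")

#' Photophysical rate parameters for the NADH dark-state model
#'
#' Holds all first-order rate constants of the six-state electronic model of
#' NADH (ground, excited singlet, triplet, radical cation, and two oxidized
#' recovery pools), together with the linear quencher-concentration
#' coefficients of the triplet decay, radical reduction and radical
#' deprotonation rates. The combined singlet decay is constrained by the
#' fluorescence lifetime: \code{k10 = 1/tauF - kisc - kee}, so \code{k10} is
#' always derived, never set directly.
#'
#' @slot kisc intersystem crossing rate, 1/us.
#' @slot kT0 triplet decay rate at zero quencher, 1/us.
#' @slot kQT named numeric, second-order triplet quenching coefficients
#'   (1/(mM us)); currently \code{O2}.
#' @slot kee electron ejection rate from the excited singlet, 1/us. Under
#'   two-photon excitation this is interpreted as the effective rate through
#'   higher excited states.
#' @slot kred0 first-order radical reduction rate, 1/us.
#' @slot kQred named numeric, second-order reduction coefficients (may be
#'   negative, e.g. for O2), 1/(mM us).
#' @slot kdeprot0 first-order radical deprotonation rate, 1/us.
#' @slot kQdeprot named numeric, second-order deprotonation coefficients,
#'   1/(mM us).
#' @slot tauF fluorescence lifetime, ns.
#' @slot fRadial branching fraction of oxidized NAD+ into the radial
#'   (fast-recovery) pool, in [0, 1].
#' @slot krecRadial,krecAxial diffusion-mediated recovery rates of the two
#'   oxidized pools, 1/us.
#' @seealso [rateParams()], [effectiveRates()], [buildRateMatrix()]
#' @exportClass RateParams
setClass("RateParams", representation(
  kisc = "numeric", kT0 = "numeric", kQT = "numeric",
  kee = "numeric", kred0 = "numeric", kQred = "numeric",
  kdeprot0 = "numeric", kQdeprot = "numeric",
  tauF = "numeric", fRadial = "numeric",
  krecRadial = "numeric", krecAxial = "numeric"))

setValidity("RateParams", function(object) {
  msg <- character()
  first <- c(kisc = object@kisc, kT0 = object@kT0, kee = object@kee,
             kred0 = object@kred0, kdeprot0 = object@kdeprot0,
             krecRadial = object@krecRadial, krecAxial = object@krecAxial)
  if (any(!is.finite(first)) || any(first < 0))
    msg <- c(msg, "first-order rates must be finite and >= 0")
  if (!is.finite(object@tauF) || object@tauF <= 0)
    msg <- c(msg, "tauF must be > 0")
  if (object@fRadial < 0 || object@fRadial > 1)
    msg <- c(msg, "fRadial must be in [0, 1]")
  if (!all(names(object@kQT) %in% .QUENCHERS) ||
      !all(names(object@kQred) %in% .QUENCHERS) ||
      !all(names(object@kQdeprot) %in% .QUENCHERS))
    msg <- c(msg, sprintf("quencher coefficients must be named among: %s",
                          paste(.QUENCHERS, collapse = ", ")))
  k10 <- 1e3 / object@tauF - object@kisc - object@kee
  if (is.finite(k10) && k10 <= 0)
    msg <- c(msg, "kisc + kee exceeds 1/tauF; derived k10 would be negative")
  if (length(msg)) msg else TRUE
})

#' Solution environment: quencher concentrations and atmosphere
#'
#' @slot conc named numeric of quencher concentrations in mM over
#'   \code{O2, Asc, TRIS, H2O2, OH}.
#' @slot atmosphere one of \code{"air"}, \code{"oxygen"}, \code{"argon"}
#'   (or \code{"custom"} when O2 was given directly).
#' @seealso [quencherEnvironment()]
#' @exportClass QuencherEnvironment
setClass("QuencherEnvironment", representation(
  conc = "numeric", atmosphere = "character"))

setValidity("QuencherEnvironment", function(object) {
  if (!identical(sort(names(object@conc)), sort(.QUENCHERS)))
    return(sprintf("conc must be named exactly: %s",
                   paste(.QUENCHERS, collapse = ", ")))
  if (any(!is.finite(object@conc)) || any(object@conc < 0))
    return("concentrations must be finite and >= 0")
  TRUE
})

#' Excitation beam geometry and cross sections
#'
#' @slot wavelength excitation wavelength, nm.
#' @slot waist 1/e^2 beam radius in the focal plane, nm.
#' @slot sigmaOpe one-photon excitation cross section, cm^2.
#' @slot sigmaTpe two-photon excitation cross section, GM (1e-50 cm^4 s).
#' @slot nShells number of equal-probability radial shells used when
#'   averaging the Gaussian excitation profile over the detection volume.
#' @slot cefRadius Gaussian collection-efficiency-function 1/e^2 radius, nm.
#' @seealso [beamProfile()], [discretizeBeam()]
#' @exportClass BeamProfile
setClass("BeamProfile", representation(
  wavelength = "numeric", waist = "numeric",
  sigmaOpe = "numeric", sigmaTpe = "numeric",
  nShells = "numeric", cefRadius = "numeric"))

setValidity("BeamProfile", function(object) {
  if (object@waist <= 0) return("waist must be > 0")
  if (object@nShells < 1) return("nShells must be >= 1")
  if (object@cefRadius <= 0) return("cefRadius must be > 0")
  TRUE
})

#' Excitation protocol: how the sample is illuminated
#'
#' Describes a stationary pulse-train (one-photon) or laser-scanning
#' (one- or two-photon) excitation modality with its irradiance and beam.
#'
#' @slot mode \code{"ope"} or \code{"tpe"}.
#' @slot scanned logical; TRUE when excitation modulation is achieved by
#'   scanning the beam rather than pulsing a stationary beam.
#' @slot Iexc time-averaged peak irradiance: kW/cm^2 for OPE, MW/cm^2 for TPE.
#' @slot beam a [BeamProfile-class].
#' @slot dutyCycle pulse-train duty cycle (stationary mode).
#' @slot repRateMHz,pulseFs femtosecond-laser repetition rate (MHz) and pulse
#'   width (fs) for TPE.
#' @seealso [excitationProtocol()]
#' @exportClass ExcitationProtocol
setClass("ExcitationProtocol", representation(
  mode = "character", scanned = "logical", Iexc = "numeric",
  beam = "BeamProfile", dutyCycle = "numeric",
  repRateMHz = "numeric", pulseFs = "numeric"))

setValidity("ExcitationProtocol", function(object) {
  if (!object@mode %in% c("ope", "tpe")) return("mode must be 'ope' or 'tpe'")
  if (object@Iexc < 0) return("Iexc must be >= 0")
  if (object@mode == "ope" &&
      (object@dutyCycle <= 0 || object@dutyCycle > 1))
    return("dutyCycle must be in (0, 1]")
  if (object@mode == "tpe") {
    duty <- object@repRateMHz * 1e6 * object@pulseFs * 1e-15
    if (!is.finite(duty) || duty <= 0 || duty >= 1)
      return("repRateMHz * pulseFs must give an fs duty cycle in (0, 1)")
  }
  TRUE
})

#' A TRAST curve: normalized mean fluorescence versus excitation duration
#'
#' @slot w excitation pulse durations (or effective scan dwell times), us,
#'   strictly ascending.
#' @slot Fnorm normalized time-averaged fluorescence; equals 1 at the
#'   shortest duration by construction.
#' @slot sd optional per-point relative standard deviation (NA when unknown).
#' @slot env the [QuencherEnvironment-class] of the measurement.
#' @slot protocol the [ExcitationProtocol-class] used.
#' @slot meta free-form list (generator truth, labels, ...).
#' @seealso [simulateStationaryTrast()], [simulateScannedTrast()]
#' @exportClass TrastCurve
setClass("TrastCurve", representation(
  w = "numeric", Fnorm = "numeric", sd = "numeric",
  env = "QuencherEnvironment", protocol = "ExcitationProtocol",
  meta = "list"))

setValidity("TrastCurve", function(object) {
  if (length(object@w) != length(object@Fnorm))
    return("w and Fnorm must have the same length")
  if (is.unsorted(object@w, strictly = TRUE))
    return("w must be strictly ascending")
  if (any(object@Fnorm <= 0)) return("Fnorm must be > 0")
  if (abs(object@Fnorm[1] - 1) > 1e-12)
    return("Fnorm must equal 1 at the shortest duration")
  TRUE
})

#' Result of a global TRAST-curve fit
#'
#' @slot estimates named numeric of fitted parameter values (per-curve
#'   parameters are suffixed with the curve index).
#' @slot ci two-column matrix of linearized 95 percent confidence bounds.
#' @slot se named numeric of standard errors.
#' @slot ssr summed squared (weighted) residuals.
#' @slot nObs,nFree number of observations and free parameters.
#' @slot aic,bic Gaussian-likelihood information criteria.
#' @slot residuals list of per-curve residual vectors.
#' @slot converged logical.
#' @slot info list: optimizer diagnostics, model options, data checksum.
#' @exportClass TrastFit
setClass("TrastFit", representation(
  estimates = "numeric", ci = "matrix", se = "numeric", ssr = "numeric",
  nObs = "numeric", nFree = "numeric", aic = "numeric", bic = "numeric",
  residuals = "list", converged = "logical", info = "list"))

setValidity("TrastFit", function(object) {
  if (!all(is.finite(c(object@aic, object@bic))))
    return("AIC/BIC must be finite")
  if (nrow(object@ci) &&
      (any(object@ci[, 1] > object@estimates + 1e-12) ||
       any(object@ci[, 2] < object@estimates - 1e-12)))
    return("confidence bounds must bracket the estimates")
  TRUE
})

#' A TCSPC micro-time histogram with its instrument response
#'
#' @slot counts non-negative photon counts per micro-time bin (uniform bins
#'   spanning one laser period).
#' @slot periodNs laser period, ns.
#' @slot irf normalized instrument response function sampled on the same
#'   bins (sums to 1).
#' @slot meta list (bin width, generator truth, ...).
#' @seealso [simulateTcspc()], [fitTwoExponentialGlobal()]
#' @exportClass TcspcHistogram
setClass("TcspcHistogram", representation(
  counts = "numeric", periodNs = "numeric", irf = "numeric", meta = "list"))

setValidity("TcspcHistogram", function(object) {
  if (any(object@counts < 0)) return("counts must be >= 0")
  if (length(object@irf) != length(object@counts))
    return("irf must match counts binning")
  if (abs(sum(object@irf) - 1) > 1e-8) return("irf must sum to 1")
  if (object@periodNs <= 0) return("periodNs must be > 0")
  TRUE
})

#' A synthetic or measured cell imaging field
#'
#' Container for one field of view of the combined TRAST + FLIM experiment:
#' the repeated fast-scan frame stack, the dose-matched slow-scan frame,
#' per-pixel TCSPC micro-time histograms, cell/nucleus label masks, and
#' (for synthetic fields) the ground truth used to generate them.
#'
#' @slot fastStack numeric array (ny, nx, nFrames) of fast-scan photon counts.
#' @slot slowFrame numeric matrix (ny, nx) of slow-scan photon counts.
#' @slot labels integer matrix; 0 = background, k = cell k.
#' @slot nucleus logical matrix marking nuclear pixels.
#' @slot tcspc numeric array (ny, nx, nBins) of per-pixel micro-time counts,
#'   or a zero-length array when not recorded.
#' @slot irf normalized IRF for the TCSPC bins.
#' @slot periodNs TCSPC laser period, ns.
#' @slot pixelUm pixel size, um.
#' @slot wFastUs,wSlowUs effective dwell times of the two scan speeds, us.
#' @slot truth list of generator ground truth (empty for real data).
#' @seealso [genCellField()], [analyzeCellField()]
#' @exportClass CellField
setClass("CellField", representation(
  fastStack = "array", slowFrame = "matrix", labels = "matrix",
  nucleus = "matrix", tcspc = "array", irf = "numeric", periodNs = "numeric",
  pixelUm = "numeric", wFastUs = "numeric", wSlowUs = "numeric",
  truth = "list"))

setValidity("CellField", function(object) {
  dF <- dim(object@fastStack)
  if (!identical(dF[1:2], dim(object@slowFrame)))
    return("fastStack and slowFrame shapes must match")
  if (!identical(dim(object@labels), dim(object@slowFrame)))
    return("labels must match image shape")
  if (any(object@fastStack < 0) || any(object@slowFrame < 0))
    return("counts must be >= 0")
  TRUE
})
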