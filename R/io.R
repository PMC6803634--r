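# Serialization: flat key/value configs for rate parameters and
# environments (JSON/YAML), TRAST curve CSVs with JSON sidecars, and TIFF
# maps/masks.

.RATE_KEYS <- c("k_isc", "k_T0", "kQ_T_O2", "k_ee", "k_red0", "kQ_red_O2",
                "kQ_red_Asc", "k_deprot0", "kQ_deprot_TRIS",
                "kQ_deprot_H2O2", "kQ_deprot_OH", "tau_F", "f_radial",
                "k_rec_radial", "k_rec_axial")

#' Write rate parameters to a flat JSON/YAML config
#'
#' Keys: k_isc, k_T0, kQ_T_O2, k_ee, k_red0, kQ_red_O2, kQ_red_Asc,
#' k_deprot0, kQ_deprot_TRIS, kQ_deprot_H2O2, kQ_deprot_OH, tau_F,
#' f_radial, k_rec_radial, k_rec_axial (units 1/us, 1/(mM us), ns).
#' The format follows the file extension (.json / .yaml / .yml).
#'
#' @param params a [RateParams-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeRateParams <- function(params, path) {
  x <- list(k_isc = params@kisc, k_T0 = params@kT0,
            kQ_T_O2 = unname(params@kQT[["O2"]]), k_ee = params@kee,
            k_red0 = params@kred0,
            kQ_red_O2 = unname(params@kQred[["O2"]]),
            kQ_red_Asc = unname(params@kQred[["Asc"]]),
            k_deprot0 = params@kdeprot0,
            kQ_deprot_TRIS = unname(params@kQdeprot[["TRIS"]]),
            kQ_deprot_H2O2 = unname(params@kQdeprot[["H2O2"]]),
            kQ_deprot_OH = unname(params@kQdeprot[["OH"]]),
            tau_F = params@tauF, f_radial = params@fRadial,
            k_rec_radial = params@krecRadial,
            k_rec_axial = params@krecAxial)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read rate parameters from a flat JSON/YAML config
#'
#' @param path config file written by [writeRateParams()] (or hand-written
#'   with the same keys; missing keys fall back to the defaults of
#'   [rateParams()]).
#' @return a [RateParams-class].
#' @export
readRateParams <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path)
  bad <- setdiff(names(x), .RATE_KEYS)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  defs <- rateParams()
  g <- function(key, def) if (!is.null(x[[key]])) as.numeric(x[[key]]) else def
  rateParams(
    kisc = g("k_isc", defs@kisc), kT0 = g("k_T0", defs@kT0),
    kQT_O2 = g("kQ_T_O2", defs@kQT[["O2"]]), kee = g("k_ee", defs@kee),
    kred0 = g("k_red0", defs@kred0),
    kQred_O2 = g("kQ_red_O2", defs@kQred[["O2"]]),
    kQred_Asc = g("kQ_red_Asc", defs@kQred[["Asc"]]),
    kdeprot0 = g("k_deprot0", defs@kdeprot0),
    kQdeprot_TRIS = g("kQ_deprot_TRIS", defs@kQdeprot[["TRIS"]]),
    kQdeprot_H2O2 = g("kQ_deprot_H2O2", defs@kQdeprot[["H2O2"]]),
    kQdeprot_OH = g("kQ_deprot_OH", defs@kQdeprot[["OH"]]),
    tauF = g("tau_F", defs@tauF), fRadial = g("f_radial", defs@fRadial),
    krecRadial = g("k_rec_radial", defs@krecRadial),
    krecAxial = g("k_rec_axial", defs@krecAxial))
}

#' Write a set of TRAST curves as CSVs with JSON sidecars
#'
#' Each curve i becomes \code{curve_i.csv} (columns w_us, F_norm, sd) and
#' \code{curve_i.json} describing environment and protocol.
#'
#' @param curves list of [TrastCurve-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeTrastCurves <- function(curves, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(curves)) {
    cr <- curves[[i]]
    utils::write.csv(
      data.frame(w_us = cr@w, F_norm = cr@Fnorm, sd = cr@sd),
      file.path(dir, sprintf("curve_%03d.csv", i)), row.names = FALSE)
    side <- list(
      env = list(atmosphere = cr@env@atmosphere,
                 conc = as.list(cr@env@conc)),
      protocol = list(mode = cr@protocol@mode,
                      scanned = cr@protocol@scanned,
                      Iexc = cr@protocol@Iexc,
                      dutyCycle = cr@protocol@dutyCycle,
                      repRateMHz = cr@protocol@repRateMHz,
                      pulseFs = cr@protocol@pulseFs,
                      beam = list(wavelength = cr@protocol@beam@wavelength,
                                  waist = cr@protocol@beam@waist,
                                  sigmaOpe = cr@protocol@beam@sigmaOpe,
                                  sigmaTpe = cr@protocol@beam@sigmaTpe,
                                  nShells = cr@protocol@beam@nShells,
                                  cefRadius = cr@protocol@beam@cefRadius)),
      series = cr@meta$series)
    jsonlite::write_json(side,
                         file.path(dir, sprintf("curve_%03d.json", i)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read TRAST curves written by [writeTrastCurves()]
#'
#' @param dir directory of curve_*.csv / curve_*.json pairs.
#' @return list of [TrastCurve-class].
#' @export
readTrastCurves <- function(dir) {
  csvs <- sort(list.files(dir, "^curve_[0-9]+\\.csv$", full.names = TRUE))
  lapply(csvs, function(f) {
    tab <- utils::read.csv(f)
    side <- jsonlite::read_json(sub("\\.csv$", ".json", f))
    conc <- lapply(side$env$conc, as.numeric)
    env <- quencherEnvironment(O2 = conc$O2, Asc = conc$Asc,
                               TRIS = conc$TRIS, H2O2 = conc$H2O2,
                               OH = conc$OH)
    env@atmosphere <- side$env$atmosphere
    bm <- side$protocol$beam
    beam <- beamProfile(wavelength = bm$wavelength, waist = bm$waist,
                        sigmaOpe = bm$sigmaOpe, sigmaTpe = bm$sigmaTpe,
                        nShells = bm$nShells, cefRadius = bm$cefRadius)
    pr <- excitationProtocol(side$protocol$mode, Iexc = side$protocol$Iexc,
                             beam = beam, scanned = side$protocol$scanned,
                             dutyCycle = side$protocol$dutyCycle,
                             repRateMHz = side$protocol$repRateMHz,
                             pulseFs = side$protocol$pulseFs)
    .trastCurve(tab$w_us, tab$F_norm, tab$sd, env, pr,
                meta = list(series = side$series))
  })
}

# amplitude/bound-fraction maps are stored as 32-bit samples over the fixed
# affine range [-1, 2]; the top of the range is the missing-pixel sentinel
.MAP_LO <- -1
.MAP_HI <- 2

#' Write a float map or integer label mask as TIFF
#'
#' Maps (amplitudes, bound fractions) are quantized to 32-bit samples over
#' the fixed range [-1, 2] (step ~7e-10), with missing pixels stored as the
#' range maximum; label masks are written as 16-bit integers.
#'
#' @param img numeric matrix (map) or integer matrix (mask).
#' @param path output .tif path.
#' @param labels write as a 16-bit label mask instead of a float map.
#' @return the path, invisibly.
#' @export
writeMapTiff <- function(img, path, labels = FALSE) {
  if (labels) {
    tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  } else {
    if (any(img < .MAP_LO | img >= .MAP_HI, na.rm = TRUE))
      stop("map values outside the storable range [-1, 2)")
    u <- (img - .MAP_LO) / (.MAP_HI - .MAP_LO)
    u[is.na(u)] <- 1
    tiff::writeTIFF(u, path, bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(path)
}

#' Read a TIFF map or label mask written by [writeMapTiff()]
#'
#' @param path .tif path.
#' @param labels interpret as a 16-bit label mask.
#' @return numeric (or integer) matrix with NA for missing pixels.
#' @export
readMapTiff <- function(path, labels = FALSE) {
  img <- tiff::readTIFF(path, as.is = labels)
  if (labels) {
    storage.mode(img) <- "integer"
    return(img)
  }
  out <- img * (.MAP_HI - .MAP_LO) + .MAP_LO
  out[img >= 1 - 1e-9] <- NA_real_
  out
}
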