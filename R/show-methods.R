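#' Compact display of trastkit objects
#'
#' @name show-methods
#' @param object the object to display.
#' @return invisible NULL, called for its side effect.
#' @keywords internal
NULL

#' @rdname show-methods
#' @export
setMethod("show", "RateParams", function(object) {
  cat("RateParams (1/us; quencher coefficients 1/(mM us))\n")
  cat(sprintf("  kisc %.3g  kee %.3g  k10 %.4g (tauF %.3g ns)\n",
              object@kisc, object@kee, k10(object), object@tauF))
  cat(sprintf("  kT0 %.3g + %.3g [O2]\n", object@kT0, object@kQT[["O2"]]))
  cat(sprintf("  kred0 %.3g + %.3g [O2] + %.3g [Asc]\n", object@kred0,
              object@kQred[["O2"]], object@kQred[["Asc"]]))
  cat(sprintf("  kdeprot0 %.3g + %.3g [TRIS] + %.3g [H2O2] + %.3g [OH]\n",
              object@kdeprot0, object@kQdeprot[["TRIS"]],
              object@kQdeprot[["H2O2"]], object@kQdeprot[["OH"]]))
  cat(sprintf("  recovery: fRadial %.2f, krec %.3g / %.3g\n",
              object@fRadial, object@krecRadial, object@krecAxial))
})

#' @rdname show-methods
#' @export
setMethod("show", "QuencherEnvironment", function(object) {
  cat("QuencherEnvironment (", object@atmosphere, ")  [mM]: ",
      paste(sprintf("%s=%.3g", names(object@conc), object@conc),
            collapse = " "), "\n", sep = "")
})

#' @rdname show-methods
#' @export
setMethod("show", "TrastCurve", function(object) {
  cat(sprintf(
    "TrastCurve: %d points, w %.3g-%.3g us, amplitude %.3f (%s, %s%.3g)\n",
    length(object@w), min(object@w), max(object@w),
    1 - min(object@Fnorm), object@protocol@mode,
    if (object@protocol@mode == "ope") "kW/cm2 " else "MW/cm2 ",
    object@protocol@Iexc))
})

#' @rdname show-methods
#' @export
setMethod("show", "TrastFit", function(object) {
  cat(sprintf(
    "TrastFit: %d obs, %d free, SSR %.4g, AIC %.1f, BIC %.1f%s\n",
    object@nObs, object@nFree, object@ssr, object@aic, object@bic,
    if (object@converged) "" else " (NOT converged)"))
  tab <- cbind(estimate = object@estimates, se = object@se, object@ci)
  print(signif(tab, 4))
})

#' @rdname show-methods
#' @export
setMethod("show", "TcspcHistogram", function(object) {
  cat(sprintf(
    "TcspcHistogram: %d bins over %.2f ns, %g counts\n",
    length(object@counts), object@periodNs, sum(object@counts)))
})

#' @rdname show-methods
#' @export
setMethod("show", "CellField", function(object) {
  d <- dim(object@fastStack)
  cat(sprintf(
    "CellField: %dx%d px (%.2f um/px), %d fast frames (w %g/%g us), %d cells%s\n",
    d[1], d[2], object@pixelUm, d[3], object@wFastUs, object@wSlowUs,
    length(setdiff(unique(as.integer(object@labels)), 0L)),
    if (length(object@tcspc)) sprintf(", TCSPC %d bins",
                                      dim(object@tcspc)[3]) else ""))
})
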