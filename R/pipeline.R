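# End-to-end analysis of a cell imaging field: alignment, background
# subtraction, A_TRAST mapping, per-pixel FLIM, per-cell features.

#' Analyze a TRAST + FLIM cell imaging field
#'
#' Runs the full imaging pipeline on a [CellField-class]: per-frame drift
#' correction and summation of the fast stack, sub-pixel alignment of the
#' slow frame onto the fast sum, constant background subtraction estimated
#' from the unlabeled region, pixel-wise TRAST amplitude, per-pixel
#' bound-fraction MLE with fixed lifetimes followed by brightness
#' correction (when micro-time data are present), and the per-cell feature
#' table. Warns when the dose-matching convention (repeats x wFast = wSlow)
#' is violated.
#'
#' @param field a [CellField-class] or a list of them (features are then
#'   concatenated; maps are returned per field).
#' @param lifetimes fixed [lifetimePair()] for the pixel MLE.
#' @param align run sub-pixel alignment (translation only).
#' @param driftCorrect rescale fast frames by their bleaching trend.
#' @param minFastCounts missing-pixel threshold.
#' @param featureMode \code{"pixel-mean"} or \code{"count-sum"}.
#' @param flimMinCounts per-pixel photon floor for the bound-fraction MLE.
#' @return list with \code{features} (data.frame), \code{A}, \code{Abound},
#'   \code{shift}, \code{background} (per-field lists when a list was
#'   given).
#' @export
analyzeCellField <- function(field, lifetimes = lifetimePair(),
                             align = TRUE, driftCorrect = TRUE,
                             minFastCounts = 20,
                             featureMode = "pixel-mean",
                             flimMinCounts = 50) {
  if (is.list(field)) {
    parts <- lapply(field, analyzeCellField, lifetimes = lifetimes,
                    align = align, driftCorrect = driftCorrect,
                    minFastCounts = minFastCounts,
                    featureMode = featureMode,
                    flimMinCounts = flimMinCounts)
    return(list(
      features = do.call(rbind, lapply(parts, `[[`, "features")),
      A = lapply(parts, `[[`, "A"),
      Abound = lapply(parts, `[[`, "Abound"),
      shift = lapply(parts, `[[`, "shift"),
      background = lapply(parts, `[[`, "background")))
  }
  stopifnot(methods::is(field, "CellField"))
  nF <- dim(field@fastStack)[3]
  if (abs(nF * field@wFastUs - field@wSlowUs) >
      1e-6 * field@wSlowUs)
    warning("dose matching violated: repeats x wFast != wSlow")
  fac <- if (driftCorrect) driftFactors(field@fastStack) else rep(1, nF)
  Ffast <- matrix(0, nrow(field@slowFrame), ncol(field@slowFrame))
  for (k in seq_len(nF)) Ffast <- Ffast + field@fastStack[, , k] * fac[k]
  slow <- field@slowFrame
  shift <- c(dy = 0, dx = 0)
  if (align) {
    al <- alignPair(Ffast, slow, pixelUm = field@pixelUm)
    slow <- al$slowAligned
    shift <- al$shift
  }
  bg <- c(fast = backgroundEstimate(Ffast, field@labels),
          slow = backgroundEstimate(slow, field@labels))
  maps <- atrastImage(Ffast, slow, driftCorrect = FALSE,
                      background = bg, minFastCounts = minFastCounts)
  Abound <- NULL
  if (length(field@tcspc)) {
    pMap <- boundFractionMap(field@tcspc, lifetimes, field@irf,
                             field@periodNs, minCounts = flimMinCounts)
    Abound <- brightnessCorrect(pMap, lifetimes)
  }
  features <- perCellFeatures(maps$A, field@labels, field@nucleus,
                              Abound = Abound,
                              condition = if (!is.null(field@truth$spec))
                                field@truth$spec$condition else
                                NA_character_,
                              mode = featureMode,
                              Ffast = maps$Ffast, Fslow = maps$Fslow)
  list(features = features, A = maps$A, Abound = Abound, shift = shift,
       background = bg)
}
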