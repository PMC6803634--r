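# Seeded generators for all three input classes: solution TRAST curve
# datasets, TCSPC histograms (via simulateTcspc), and cell imaging fields
# with ground truth.

#' The 53-curve one-photon solution measurement design
#'
#' Reconstructs the solution-phase experimental design: an irradiance series
#' in air, oxygen/argon atmospheres at several irradiances, and titrations
#' of ascorbate, TRIS, hydroxide (unbuffered) and hydrogen peroxide. All
#' curves are in 50 mM TRIS buffer except the hydroxide series. Irradiances
#' span 10-81 kW/cm2; the titration series are measured at 43 kW/cm2
#' (H2O2 at 50 kW/cm2).
#'
#' @return data.frame with one row per curve: Iexc, atmosphere,
#'   Asc, TRIS, H2O2, OH (mM), series.
#' @export
opeSolutionDesign <- function() {
  tris <- 50
  rows <- list()
  add <- function(Iexc, atmosphere = "air", Asc = 0, TRIS = tris,
                  H2O2 = 0, OH = 0, series)
    rows[[length(rows) + 1]] <<- data.frame(
      Iexc = Iexc, atmosphere = atmosphere, Asc = Asc, TRIS = TRIS,
      H2O2 = H2O2, OH = OH, series = series)
  for (I in round(exp(seq(log(10), log(81), length.out = 9)), 1))
    add(I, series = "irradiance")                      # 9
  for (I in c(15, 28, 43, 61, 81)) {
    add(I, atmosphere = "oxygen", series = "oxygen")   # 5
    add(I, atmosphere = "argon", series = "argon")     # 5
  }
  for (a in c(0.25, 0.5, 1, 1.5, 2, 3, 5, 7, 10))
    add(43, Asc = a, series = "ascorbate")             # 9
  for (tr in c(12.5, 25, 75, 150, 300, 500, 850, 1000))
    add(43, TRIS = tr, series = "tris")                # 8
  for (oh in c(0.5, 1, 2, 4, 7, 12, 20, 40))
    add(43, TRIS = 0, OH = oh, series = "hydroxide")   # 8
  for (h in c(0.1, 0.25, 0.5, 1, 2, 3.5, 5, 7, 10))
    add(50, H2O2 = h, series = "peroxide")             # 9
  do.call(rbind, rows)
}

#' Generate a synthetic solution TRAST dataset
#'
#' Simulates noiseless curves for every design row via the stationary TRAST
#' engine, then applies multiplicative Gaussian noise of relative SD
#' \code{noiseSd} and renormalizes at the shortest duration. Bit-stable
#' under a fixed seed; the generating truth is recorded in each curve's
#' metadata.
#'
#' @param params true [RateParams-class].
#' @param design design table as from [opeSolutionDesign()].
#' @param w pulse-duration grid, us (default: 500 ns to 1 ms,
#'   log-distributed at 10 points per decade, the typical acquisition
#'   density of stationary TRAST measurements).
#' @param noiseSd relative noise SD (0.01 emulates the ~1 percent
#'   experimental residuals; 0 gives noiseless curves).
#' @param seed RNG seed.
#' @param beam a [BeamProfile-class] shared by all curves.
#' @param model a [trastModel()] variant.
#' @return list of [TrastCurve-class].
#' @export
genSolutionDataset <- function(params, design = opeSolutionDesign(),
                               w = 10^seq(log10(0.5), 3,
                                          length.out = 34),
                               noiseSd = 0.01, seed = 1,
                               beam = beamProfile(),
                               model = trastModel()) {
  rs <- .localSeed(seed); on.exit(.restoreSeed(rs))
  lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    env <- quencherEnvironment(d$atmosphere, Asc = d$Asc, TRIS = d$TRIS,
                               H2O2 = d$H2O2, OH = d$OH)
    pr <- excitationProtocol("ope", Iexc = d$Iexc, beam = beam)
    crv <- simulateStationaryTrast(params, env, w, pr, model)
    Fn <- crv@Fnorm
    if (noiseSd > 0) {
      Fn <- Fn * (1 + stats::rnorm(length(Fn), 0, noiseSd))
      Fn <- Fn / Fn[1]
    }
    .trastCurve(crv@w, Fn, rep(noiseSd, length(Fn)), env, pr,
                meta = list(series = d$series, noiseSd = noiseSd,
                            truth = params))
  })
}

#' Ground-truth presets of the three imaged cell conditions
#'
#' Region dark-state occupancies and molecular bound fractions chosen so
#' that, at the expected nuclear area fraction (~0.25 of the cell), the
#' pixel-weighted cell means reproduce the reported condition averages
#' (A_TRAST 0.43 control / 0.52 cyanide / 0.36 DNP, nuclear 0.38 and
#' cytosolic 0.45 in control; A_bound 0.20 / 0.18 / 0.21).
#'
#' @param condition \code{"control"}, \code{"cyanide"} or \code{"dnp"}.
#' @return list with \code{occupancy} and \code{bound}, each
#'   c(nucleus, cytosol), and \code{nCells} as imaged per condition.
#' @export
conditionPreset <- function(condition = c("control", "cyanide", "dnp")) {
  condition <- match.arg(condition)
  switch(condition,
    control = list(occupancy = c(nucleus = 0.38, cytosol = 0.45),
                   bound = c(nucleus = 0.17, cytosol = 0.21),
                   nCells = 131),
    cyanide = list(occupancy = c(nucleus = 0.4675, cytosol = 0.5375),
                   bound = c(nucleus = 0.15, cytosol = 0.19),
                   nCells = 160),
    dnp = list(occupancy = c(nucleus = 0.3075, cytosol = 0.3775),
               bound = c(nucleus = 0.18, cytosol = 0.22),
               nCells = 130))
}

#' Specification of a synthetic cell imaging field
#'
#' @param nCells number of cells to place (across as many 128x128 fields of
#'   view as needed; see \code{cellsPerField}).
#' @param condition condition preset name (sets occupancy/bound truths).
#' @param occupancy,bound optional c(nucleus, cytosol) overrides.
#' @param shape field shape in pixels.
#' @param fovUm field of view, um.
#' @param photonBudget expected background-free fast-sum counts per in-cell
#'   pixel.
#' @param backgroundCounts expected background counts per pixel added to
#'   both the summed fast and the slow image.
#' @param nFrames fast-scan repeats (dose matching: nFrames * wFast =
#'   wSlow).
#' @param wFastUs,wSlowUs effective dwell times, us.
#' @param betweenCellSd c(theta, beta): between-cell SD of the region
#'   occupancy and bound-fraction means.
#' @param cellAxisUm range of cell ellipse axis lengths (full axes), um.
#' @param nucleusScale range of the nucleus/cell axis ratio.
#' @param tcspc generate per-pixel micro-time histograms?
#' @param tcspcCounts expected TCSPC photons per in-cell pixel.
#' @param nBins micro-time bins (kept moderate: per-pixel statistics, not
#'   bin resolution, limit the estimator).
#' @param periodNs laser period, ns.
#' @param lifetimes generating [lifetimePair()].
#' @param irfFwhmNs IRF width.
#' @param injectShiftPx c(dy, dx) sub-pixel offset of the slow frame
#'   relative to the fast frame (scan-speed dependent instrument offset).
#' @param bleachSlope fractional linear intensity decay across the fast
#'   frames (0.1 = 10 percent from first to last).
#' @param cellsPerField maximum cells placed in one field of view.
#' @return list specification.
#' @export
cellFieldSpec <- function(nCells = 131, condition = "control",
                          occupancy = NULL, bound = NULL,
                          shape = c(128, 128), fovUm = 90,
                          photonBudget = 500, backgroundCounts = 5,
                          nFrames = 50, wFastUs = 12, wSlowUs = 600,
                          betweenCellSd = c(theta = 0.02, beta = 0.01),
                          cellAxisUm = c(8, 15),
                          nucleusScale = c(0.4, 0.6),
                          tcspc = FALSE, tcspcCounts = 1000, nBins = 256,
                          periodNs = 13.16, lifetimes = lifetimePair(),
                          irfFwhmNs = 0.3, injectShiftPx = c(0, 0),
                          bleachSlope = 0, cellsPerField = 12) {
  preset <- conditionPreset(condition)
  if (is.null(occupancy)) occupancy <- preset$occupancy
  if (is.null(bound)) bound <- preset$bound
  stopifnot(all(occupancy >= 0 & occupancy <= 1),
            all(bound >= 0 & bound <= 1), photonBudget > 0)
  list(nCells = nCells, condition = condition, occupancy = occupancy,
       bound = bound, shape = shape, fovUm = fovUm,
       photonBudget = photonBudget, backgroundCounts = backgroundCounts,
       nFrames = nFrames, wFastUs = wFastUs, wSlowUs = wSlowUs,
       betweenCellSd = betweenCellSd, cellAxisUm = cellAxisUm,
       nucleusScale = nucleusScale, tcspc = tcspc,
       tcspcCounts = tcspcCounts, nBins = nBins, periodNs = periodNs,
       lifetimes = lifetimes, irfFwhmNs = irfFwhmNs,
       injectShiftPx = injectShiftPx, bleachSlope = bleachSlope,
       cellsPerField = cellsPerField)
}

.truncNorm <- function(n, mean, sd, lo = 0, hi = 1) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

# rejection-sample non-overlapping ellipse placements; returns per-cell
# geometry (px units)
.placeCells <- function(nCells, shape, pxUm, axisUm, nucScale,
                        maxTries = 500) {
  cells <- list()
  for (k in seq_len(nCells)) {
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      a <- stats::runif(1, axisUm[1], axisUm[2]) / 2 / pxUm # semi-axis px
      b <- stats::runif(1, axisUm[1], axisUm[2]) / 2 / pxUm
      phi <- stats::runif(1, 0, pi)
      r <- max(a, b)
      cy <- stats::runif(1, r + 2, shape[1] - r - 1)
      cx <- stats::runif(1, r + 2, shape[2] - r - 1)
      clear <- all(vapply(cells, function(cl)
        (cl$cy - cy)^2 + (cl$cx - cx)^2 > (r + max(cl$a, cl$b) + 1)^2,
        logical(1)))
      if (clear) {
        cells[[k]] <- list(cy = cy, cx = cx, a = a, b = b, phi = phi,
                           s = stats::runif(1, nucScale[1], nucScale[2]))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place ", nCells, " non-overlapping cells; ",
                  "reduce cellsPerField or cell size")
  }
  cells
}

# pixel masks of one ellipse cell and its concentric nucleus
.ellipseMasks <- function(cell, shape) {
  yy <- matrix(seq_len(shape[1]), shape[1], shape[2])
  xx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dy <- yy - cell$cy; dx <- xx - cell$cx
  u <- dy * cos(cell$phi) + dx * sin(cell$phi)
  v <- -dy * sin(cell$phi) + dx * cos(cell$phi)
  q <- (u / cell$a)^2 + (v / cell$b)^2
  list(cell = q <= 1, nucleus = q <= cell$s^2)
}

#' Generate a synthetic cell imaging field with ground truth
#'
#' Places elliptical cells with concentric nuclei in one or more fields of
#' view, draws per-cell region means (dark-state occupancy theta and
#' molecular bound fraction beta) from truncated normals around the
#' condition truth, and synthesizes: a fast-scan frame stack (expected
#' in-cell fast-sum counts = photon budget, split over the repeats, with
#' optional linear bleaching), a dose-matched slow frame with expected
#' counts reduced by the factor (1 - theta), optional per-pixel TCSPC
#' micro-time histograms whose photon fraction follows from beta through
#' the brightness relation, uniform expected background in both images, and
#' an optional injected sub-pixel shift of the slow frame. All counts are
#' Poisson; everything is reproducible under the seed.
#'
#' When \code{nCells} exceeds \code{cellsPerField} several fields are
#' generated and returned as a list; cell labels are unique across fields.
#'
#' @param spec a [cellFieldSpec()].
#' @param seed RNG seed.
#' @return a [CellField-class], or a list of them (one per field of view)
#'   when more than one field is needed.
#' @export
genCellField <- function(spec = cellFieldSpec(), seed = 1) {
  rs <- .localSeed(seed); on.exit(.restoreSeed(rs))
  nFields <- ceiling(spec$nCells / spec$cellsPerField)
  perField <- diff(round(seq(0, spec$nCells, length.out = nFields + 1)))
  nextId <- 1L
  fields <- lapply(seq_len(nFields), function(f) {
    out <- .genOneField(spec, perField[f], nextId)
    nextId <<- nextId + perField[f]
    out
  })
  if (length(fields) == 1) fields[[1]] else fields
}

.genOneField <- function(spec, nCells, firstId) {
  shape <- spec$shape
  pxUm <- spec$fovUm / shape[1]
  cells <- .placeCells(nCells, shape, pxUm, spec$cellAxisUm,
                       spec$nucleusScale)
  labels <- matrix(0L, shape[1], shape[2])
  nucleus <- matrix(FALSE, shape[1], shape[2])
  thetaMap <- matrix(0, shape[1], shape[2]) # dark-state occupancy
  betaMap <- matrix(NA_real_, shape[1], shape[2])
  truthCells <- list()
  for (k in seq_along(cells)) {
    mk <- .ellipseMasks(cells[[k]], shape)
    cellPx <- mk$cell & labels == 0L
    nucPx <- mk$nucleus & cellPx
    id <- firstId + k - 1L
    labels[cellPx] <- id
    nucleus[nucPx] <- TRUE
    thN <- .truncNorm(1, spec$occupancy[["nucleus"]],
                      spec$betweenCellSd[["theta"]])
    thC <- .truncNorm(1, spec$occupancy[["cytosol"]],
                      spec$betweenCellSd[["theta"]])
    beN <- .truncNorm(1, spec$bound[["nucleus"]],
                      spec$betweenCellSd[["beta"]])
    beC <- .truncNorm(1, spec$bound[["cytosol"]],
                      spec$betweenCellSd[["beta"]])
    thetaMap[cellPx] <- thC; thetaMap[nucPx] <- thN
    betaMap[cellPx] <- beC; betaMap[nucPx] <- beN
    truthCells[[k]] <- data.frame(cell_id = id,
      theta_nucleus = thN, theta_cytosol = thC,
      beta_nucleus = beN, beta_cytosol = beC)
  }
  lamFast <- matrix(0, shape[1], shape[2])
  lamFast[labels > 0L] <- spec$photonBudget
  lamSlowSig <- lamFast * (1 - thetaMap)
  if (any(spec$injectShiftPx != 0))
    lamSlowSig <- .translateImage(lamSlowSig, -spec$injectShiftPx[1],
                                  -spec$injectShiftPx[2])
  lamFastTot <- lamFast + spec$backgroundCounts
  lamSlow <- lamSlowSig + spec$backgroundCounts
  # linear bleaching across the repeated fast frames; the slow frame is
  # acquired first and carries the unbleached signal
  nF <- spec$nFrames
  frameScale <- 1 - spec$bleachSlope *
    (seq_len(nF) - 1) / max(nF - 1, 1)
  fastStack <- array(0, c(shape[1], shape[2], nF))
  npx <- prod(shape)
  for (fr in seq_len(nF))
    fastStack[, , fr] <- matrix(
      stats::rpois(npx, lamFastTot / nF * frameScale[fr]),
      shape[1], shape[2])
  slowFrame <- matrix(stats::rpois(npx, lamSlow), shape[1], shape[2])
  irf <- gaussianIrf(spec$nBins, spec$periodNs, spec$irfFwhmNs)
  tcspcArr <- array(0, c(0, 0, 0))
  if (spec$tcspc) {
    cp <- .componentProbs(spec$lifetimes, spec$nBins, spec$periodNs, irf)
    pMap <- boundPhotonFraction(betaMap, spec$lifetimes)
    tcspcArr <- array(0, c(shape[1], shape[2], spec$nBins))
    inCell <- which(labels > 0L)
    # expected per-bin counts per pixel: tcspcCounts x mixture(p)
    Pmix <- outer(1 - pMap[inCell], cp$free) + outer(pMap[inCell], cp$bound)
    draw <- matrix(stats::rpois(length(Pmix), spec$tcspcCounts * Pmix),
                   nrow = length(inCell))
    for (jb in seq_len(spec$nBins)) {
      sl <- matrix(0, shape[1], shape[2])
      sl[inCell] <- draw[, jb]
      tcspcArr[, , jb] <- sl
    }
  }
  methods::new("CellField",
    fastStack = fastStack, slowFrame = slowFrame, labels = labels,
    nucleus = nucleus, tcspc = tcspcArr, irf = irf,
    periodNs = spec$periodNs, pixelUm = pxUm, wFastUs = spec$wFastUs,
    wSlowUs = spec$wSlowUs,
    truth = list(spec = spec, cells = do.call(rbind, truthCells),
                 thetaMap = thetaMap, betaMap = betaMap))
}
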