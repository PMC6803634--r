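# TRAST imaging: sub-pixel alignment of fast/slow scan frames, dark-state
# amplitude maps, free/bound-resolved maps, and per-cell feature tables.
# Pixel convention: matrices are [row = y, col = x], 0-based shifts reported
# as (dy, dx); a shift (dy, dx) means the slow frame content sits at
# (y + dy, x + dx) relative to the fast frame.

# bilinear translation: returns img evaluated at (y + dy, x + dx),
# replicating edge pixels
.translateImage <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  ys <- pmin(pmax(seq_len(ny) + dy, 1), ny)
  xs <- pmin(pmax(seq_len(nx) + dx, 1), nx)
  y0 <- pmin(floor(ys), ny - 1); x0 <- pmin(floor(xs), nx - 1)
  fy <- ys - y0; fx <- xs - x0
  A <- img[y0, x0, drop = FALSE]; B <- img[y0 + 1, x0, drop = FALSE]
  C <- img[y0, x0 + 1, drop = FALSE]; D <- img[y0 + 1, x0 + 1, drop = FALSE]
  wy <- matrix(fy, ny, nx); wx <- matrix(fx, ny, nx, byrow = TRUE)
  (1 - wy) * (1 - wx) * A + wy * (1 - wx) * B +
    (1 - wy) * wx * C + wy * wx * D
}

# cross-correlation of two equally sized images on an oversampled shift
# grid, via zero-padding of the cross-power spectrum (equivalent to
# correlating the sinc-oversampled images)
.upsampledCorrPeak <- function(a, b, oversample, maxShiftPx) {
  ny <- nrow(a); nx <- ncol(a)
  A <- stats::fft(a - mean(a)); B <- stats::fft(b - mean(b))
  R <- A * Conj(B)
  NY <- ny * oversample; NX <- nx * oversample
  Rbig <- matrix(0 + 0i, NY, NX)
  iy <- c(seq_len(ceiling(ny / 2)), NY - rev(seq_len(floor(ny / 2))) + 1)
  ix <- c(seq_len(ceiling(nx / 2)), NX - rev(seq_len(floor(nx / 2))) + 1)
  Rbig[iy, ix] <- R
  cc <- Re(stats::fft(Rbig, inverse = TRUE))
  # admissible shifts: |shift| <= maxShiftPx (in original pixels)
  m <- round(maxShiftPx * oversample)
  idx <- c(seq_len(m + 1), NY - rev(seq_len(m)) + 1) # 0..m and -m..-1
  idxx <- c(seq_len(m + 1), NX - rev(seq_len(m)) + 1)
  sub <- cc[idx, idxx, drop = FALSE]
  pk <- unname(which(sub == max(sub), arr.ind = TRUE)[1, ])
  toShift <- function(i, mm) { s <- i - 1; if (s > mm) s <- s - (2 * mm + 1); s }
  # sign so that slow(y, x) = fast(y - dy, x - dx) reports positive (dy, dx)
  dy <- -toShift(pk[1], m) / oversample
  dx <- -toShift(pk[2], m) / oversample
  # normalized peak correlation for the featureless-image guard
  denom <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  list(dy = dy, dx = dx,
       peak = max(sub) / (ny * nx) / max(denom, .Machine$double.eps))
}

#' Sub-pixel alignment of a fast/slow scan image pair
#'
#' Finds the translation between the (summed) fast frame and the slow frame
#' by maximizing their cross-correlation on a 10x oversampled grid, then
#' translates the slow frame onto the fast frame (bilinear interpolation)
#' and returns both at original resolution. Featureless pairs (normalized
#' correlation peak below \code{minPeak}) yield a zero shift with a warning.
#'
#' @param fast summed fast-scan image (matrix).
#' @param slow slow-scan image, same shape.
#' @param oversample oversampling factor of the correlation grid.
#' @param maxShiftPx largest admissible shift, px.
#' @param minPeak normalized-correlation floor for a trustworthy peak.
#' @param pixelUm optional pixel size to report the shift in um.
#' @return list with \code{shift} (dy, dx in px), \code{shiftUm},
#'   \code{slowAligned}, \code{peak}.
#' @export
alignPair <- function(fast, slow, oversample = 10, maxShiftPx = 5,
                      minPeak = 0.1, pixelUm = NA_real_) {
  stopifnot(identical(dim(fast), dim(slow)))
  if (stats::sd(fast) == 0 || stats::sd(slow) == 0) {
    warning("featureless image(s): returning zero shift")
    return(list(shift = c(dy = 0, dx = 0), shiftUm = c(0, 0) * pixelUm,
                slowAligned = slow, peak = 0))
  }
  pk <- .upsampledCorrPeak(fast, slow, oversample, maxShiftPx)
  if (pk$peak < minPeak) {
    warning("correlation peak below threshold (", signif(pk$peak, 3),
            "): returning zero shift")
    pk$dy <- 0; pk$dx <- 0
  }
  aligned <- if (pk$dy == 0 && pk$dx == 0) slow else
    .translateImage(slow, pk$dy, pk$dx)
  list(shift = c(dy = pk$dy, dx = pk$dx),
       shiftUm = c(dy = pk$dy, dx = pk$dx) * pixelUm,
       slowAligned = aligned, peak = pk$peak)
}

#' Per-frame drift (bleaching) correction factors
#'
#' The repeated fast frames serve as bleaching references: a linear trend is
#' fitted to the frame totals and every frame is rescaled to the trend's
#' initial value.
#'
#' @param fastStack array (ny, nx, nFrames).
#' @return numeric vector of per-frame multiplicative factors.
#' @export
driftFactors <- function(fastStack) {
  tot <- apply(fastStack, 3, sum)
  i <- seq_along(tot)
  fitted <- stats::fitted(stats::lm(tot ~ i))
  unname(fitted[1] / fitted)
}

#' Pixel-wise TRAST amplitude image from a fast/slow pair
#'
#' Sums the fast frames (optionally after per-frame drift correction),
#' subtracts constant backgrounds, and forms
#' \code{A = (F_fast - F_slow) / F_fast} per pixel. Pixels whose
#' background-subtracted fast sum falls below \code{minFastCounts} are
#' returned as NA (undefined, not 0).
#'
#' @param fastStack array (ny, nx, nFrames) of fast-scan counts (or an
#'   already summed matrix).
#' @param slow slow-scan frame, aligned to the fast frame.
#' @param driftCorrect apply [driftFactors()] to the fast frames.
#' @param background length-2 numeric: constant background of the summed
#'   fast image and of the slow image (counts/px).
#' @param minFastCounts missing-pixel threshold on the fast sum.
#' @return list with \code{A} (matrix), \code{Ffast}, \code{Fslow}.
#' @export
atrastImage <- function(fastStack, slow, driftCorrect = TRUE,
                        background = c(fast = 0, slow = 0),
                        minFastCounts = 20) {
  if (length(dim(fastStack)) == 3) {
    fac <- if (driftCorrect) driftFactors(fastStack) else
      rep(1, dim(fastStack)[3])
    Ffast <- matrix(0, dim(fastStack)[1], dim(fastStack)[2])
    for (k in seq_len(dim(fastStack)[3]))
      Ffast <- Ffast + fastStack[, , k] * fac[k]
  } else Ffast <- fastStack
  if (all(Ffast == 0)) stop("all-zero fast image")
  Ffast <- Ffast - background[[1]]
  Fslow <- slow - background[[2]]
  A <- trastAmplitude(Ffast, Fslow)
  A[Ffast < minFastCounts] <- NA_real_
  list(A = A, Ffast = Ffast, Fslow = Fslow)
}

#' Estimate a constant image background from unlabeled pixels
#'
#' @param img image matrix.
#' @param labels integer label matrix (0 = background region).
#' @return scalar mean background (counts/px).
#' @export
backgroundEstimate <- function(img, labels) {
  stopifnot(identical(dim(img), dim(labels)))
  mean(img[labels == 0])
}

#' TRAST amplitude maps of free and bound fluorophore separately
#'
#' Splits the fast and slow photon counts into their free/bound components
#' using FLIM bound-photon-fraction maps recorded under both dwell
#' conditions, then applies the amplitude formula per component. Component
#' counts sum to the totals exactly; missing FLIM pixels propagate as NA.
#'
#' @param Ffast,Fslow background-subtracted, aligned count images.
#' @param pFast,pSlow bound-photon-fraction maps for the fast and slow
#'   acquisitions.
#' @param minFastCounts missing-pixel threshold on the component fast sum.
#' @return list with \code{Afree}, \code{Abound} matrices.
#' @export
splitFreeBoundTrast <- function(Ffast, Fslow, pFast, pSlow,
                                minFastCounts = 20) {
  stopifnot(identical(dim(Ffast), dim(pFast)),
            identical(dim(Fslow), dim(pSlow)))
  fFree <- Ffast * (1 - pFast); fBound <- Ffast * pFast
  sFree <- Fslow * (1 - pSlow); sBound <- Fslow * pSlow
  Afree <- trastAmplitude(fFree, sFree)
  Abound <- trastAmplitude(fBound, sBound)
  Afree[fFree < minFastCounts] <- NA_real_
  Abound[fBound < minFastCounts] <- NA_real_
  list(Afree = Afree, Abound = Abound)
}

#' Per-cell feature table from amplitude and bound-fraction maps
#'
#' Computes per-cell means of A_TRAST and A_bound, with nuclear and
#' cytosolic (cell minus nucleus) region means where a nucleus mask is
#' available. Missing (NA) pixels are excluded; cells left with no valid
#' pixels are dropped with a message. The \code{"count-sum"} mode computes
#' region amplitudes from summed counts instead of pixel means (requires
#' \code{Ffast}/\code{Fslow}).
#'
#' @param A A_TRAST map.
#' @param labels integer cell label image (0 = background).
#' @param nucleus optional logical nucleus mask.
#' @param Abound optional molecular bound-fraction map.
#' @param condition label stored in the table.
#' @param mode \code{"pixel-mean"} or \code{"count-sum"}.
#' @param Ffast,Fslow count images for \code{"count-sum"} mode.
#' @return data.frame with columns cell_id, condition, mean_atrast,
#'   mean_abound, mean_atrast_nucl, mean_atrast_cyto, mean_abound_nucl,
#'   mean_abound_cyto, n_pixels.
#' @export
perCellFeatures <- function(A, labels, nucleus = NULL, Abound = NULL,
                            condition = NA_character_,
                            mode = c("pixel-mean", "count-sum"),
                            Ffast = NULL, Fslow = NULL) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(A), dim(labels)))
  ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  regMean <- function(map, sel) {
    v <- map[sel]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  regA <- function(sel) {
    if (mode == "pixel-mean") return(regMean(A, sel))
    ok <- sel & !is.na(A)
    trastAmplitude(sum(Ffast[ok]), sum(Fslow[ok]))
  }
  if (mode == "count-sum" && (is.null(Ffast) || is.null(Fslow)))
    stop("count-sum mode needs Ffast and Fslow")
  rows <- lapply(ids, function(id) {
    inCell <- labels == id
    nValid <- sum(inCell & !is.na(A))
    if (nValid == 0) {
      message("cell ", id, " has no valid pixels; dropped")
      return(NULL)
    }
    nuc <- if (!is.null(nucleus)) inCell & nucleus else
      matrix(FALSE, nrow(A), ncol(A))
    cyto <- inCell & !nuc
    data.frame(cell_id = id, condition = condition,
      mean_atrast = regA(inCell),
      mean_abound = if (!is.null(Abound)) regMean(Abound, inCell) else
        NA_real_,
      mean_atrast_nucl = if (any(nuc)) regA(nuc) else NA_real_,
      mean_atrast_cyto = if (any(cyto)) regA(cyto) else NA_real_,
      mean_abound_nucl = if (!is.null(Abound) && any(nuc))
        regMean(Abound, nuc) else NA_real_,
      mean_abound_cyto = if (!is.null(Abound) && any(cyto))
        regMean(Abound, cyto) else NA_real_,
      n_pixels = nValid)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
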