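# TCSPC decay simulation and analysis: global two-exponential Poisson MLE,
# per-pixel bound-fraction MLE with fixed lifetimes, brightness correction.

#' Free/bound lifetime pair
#'
#' @param tauFree,tauBound lifetimes in ns, 0 < tauFree < tauBound. Defaults
#'   are the free and average protein-bound NAD(P)H lifetimes used for the
#'   per-pixel analysis (0.4 and 2.4 ns).
#' @return named numeric c(tauFree, tauBound).
#' @export
lifetimePair <- function(tauFree = 0.4, tauBound = 2.4) {
  if (!(tauFree > 0 && tauFree < tauBound))
    stop("need 0 < tauFree < tauBound")
  c(tauFree = tauFree, tauBound = tauBound)
}

#' Synthetic Gaussian instrument response function
#'
#' @param nBins number of micro-time bins over one period.
#' @param periodNs laser period, ns (13.16 ns at 76 MHz).
#' @param fwhmNs IRF full width at half maximum, ns.
#' @param t0Ns IRF peak position, ns.
#' @return numeric vector summing to 1.
#' @export
gaussianIrf <- function(nBins = 4096, periodNs = 13.16, fwhmNs = 0.3,
                        t0Ns = 1) {
  tc <- (seq_len(nBins) - 0.5) * periodNs / nBins
  s <- fwhmNs / (2 * sqrt(2 * log(2)))
  # wrap a few periods so the tail mass is conserved
  irf <- rowSums(vapply(-1:1, function(k)
    stats::dnorm(tc + k * periodNs, t0Ns, s), numeric(nBins)))
  irf / sum(irf)
}

# wrapped single-exponential decay, normalized over one period
.wrappedExp <- function(tauNs, nBins, periodNs) {
  tc <- (seq_len(nBins) - 0.5) * periodNs / nBins
  d <- exp(-tc / tauNs) / (1 - exp(-periodNs / tauNs))
  d / sum(d)
}

# circular convolution with the IRF (both normalized to sum 1)
.convolveIrf <- function(d, irf) {
  n <- length(d)
  out <- Re(stats::fft(stats::fft(d) * stats::fft(irf), inverse = TRUE)) / n
  out[out < 0] <- 0
  out / sum(out)
}

# per-bin probabilities of the two decay components (IRF-convolved) plus a
# uniform background fraction
.componentProbs <- function(lifetimes, nBins, periodNs, irf) {
  list(free = .convolveIrf(.wrappedExp(lifetimes[["tauFree"]], nBins,
                                       periodNs), irf),
       bound = .convolveIrf(.wrappedExp(lifetimes[["tauBound"]], nBins,
                                        periodNs), irf))
}

.mixProbs <- function(cp, p, bgFraction) {
  (1 - bgFraction) * ((1 - p) * cp$free + p * cp$bound) +
    bgFraction / length(cp$free)
}

#' Simulate a TCSPC micro-time histogram
#'
#' The expected decay is a two-exponential mixture (photon fraction
#' \code{pBound} in the slow component), wrapped over the laser period,
#' circularly convolved with the IRF, plus a uniform background; counts are
#' independent Poisson draws per bin.
#'
#' @param pBound photon fraction of the bound (slow) component, in [0, 1].
#' @param lifetimes a [lifetimePair()].
#' @param totalCounts expected total photon count.
#' @param periodNs laser period, ns.
#' @param nBins number of bins.
#' @param irf normalized IRF (defaults to [gaussianIrf()] on the same bins).
#' @param bgFraction uniform background photon fraction.
#' @param seed optional RNG seed (local; caller's RNG state is restored).
#' @return a [TcspcHistogram-class].
#' @export
simulateTcspc <- function(pBound, lifetimes = lifetimePair(),
                          totalCounts = 1e4, periodNs = 13.16,
                          nBins = 4096, irf = NULL, bgFraction = 0,
                          seed = NULL) {
  stopifnot(pBound >= 0, pBound <= 1, totalCounts >= 0)
  if (periodNs < 5 * lifetimes[["tauBound"]])
    warning("period < 5 x tauBound: strong wrap-around of the slow decay")
  if (is.null(irf)) irf <- gaussianIrf(nBins, periodNs)
  cp <- .componentProbs(lifetimes, nBins, periodNs, irf)
  mu <- totalCounts * .mixProbs(cp, pBound, bgFraction)
  rs <- .localSeed(seed); on.exit(.restoreSeed(rs))
  methods::new("TcspcHistogram",
    counts = as.numeric(stats::rpois(nBins, mu)), periodNs = periodNs,
    irf = irf,
    meta = list(truth = list(pBound = pBound, lifetimes = lifetimes,
                             totalCounts = totalCounts,
                             bgFraction = bgFraction)))
}

# Poisson negative log-likelihood (up to the count-factorial constant)
.poisNll <- function(counts, mu) {
  mu <- pmax(mu, 1e-12)
  sum(mu) - sum(counts * log(mu))
}

#' Global two-exponential Poisson fit of pooled TCSPC data
#'
#' Maximum-likelihood fit of two lifetimes, their relative amplitude and
#' (optionally) a uniform background fraction to a pooled micro-time
#' histogram, with IRF convolution. The overall amplitude is profiled out
#' (it equals the observed total count at the optimum).
#'
#' @param hist a [TcspcHistogram-class] (pooled over many pixels/cells).
#' @param init named start values: tauFree, tauBound (ns), pBound,
#'   bgFraction.
#' @param fitBackground fit the uniform background fraction?
#' @return list with \code{lifetimes} (a lifetime pair, sorted),
#'   \code{pBound}, \code{bgFraction}, \code{logLik}, \code{convergence}.
#' @export
fitTwoExponentialGlobal <- function(hist,
                                    init = c(tauFree = 0.2, tauBound = 3,
                                             pBound = 0.5,
                                             bgFraction = 0.01),
                                    fitBackground = FALSE) {
  counts <- hist@counts
  n <- length(counts)
  N <- sum(counts)
  if (N < 1e5)
    warning("pooled counts < 1e5; lifetime estimates may be unstable")
  irf <- hist@irf
  period <- hist@periodNs
  nll <- function(par) {
    t1 <- exp(par[1]); t2 <- exp(par[2])
    p <- stats::plogis(par[3])
    bg <- if (fitBackground) stats::plogis(par[4]) else 0
    taus <- sort(c(t1, t2))
    cp <- .componentProbs(c(tauFree = taus[1], tauBound = taus[2]), n,
                          period, irf)
    pp <- if (t1 <= t2) p else 1 - p
    .poisNll(counts, N * .mixProbs(cp, pp, bg))
  }
  par0 <- c(log(init[["tauFree"]]), log(init[["tauBound"]]),
            stats::qlogis(min(max(init[["pBound"]], 1e-3), 1 - 1e-3)))
  if (fitBackground)
    par0 <- c(par0, stats::qlogis(min(max(init[["bgFraction"]], 1e-4),
                                      0.5)))
  opt <- stats::optim(par0, nll, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  opt <- stats::optim(opt$par, nll, method = "BFGS",
                      control = list(maxit = 500))
  t1 <- exp(opt$par[1]); t2 <- exp(opt$par[2])
  p <- stats::plogis(opt$par[3])
  if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp; p <- 1 - p }
  if (t2 / t1 < 1.2)
    warning("fitted lifetimes nearly degenerate (ratio < 1.2); ",
            "components may not be identifiable")
  list(lifetimes = c(tauFree = t1, tauBound = t2), pBound = p,
       bgFraction = if (fitBackground) stats::plogis(opt$par[4]) else 0,
       logLik = -opt$value, convergence = opt$convergence)
}

#' Per-pixel bound-photon-fraction MLE with fixed lifetimes
#'
#' One-dimensional Poisson maximum likelihood for the photon fraction of
#' the slow component, on the closed interval [0, 1] (exact boundary
#' estimates are reachable). Pixels with fewer than 50 photons are flagged
#' low-confidence; an empty histogram returns NA.
#'
#' @param hist a [TcspcHistogram-class] or a bare counts vector.
#' @param lifetimes a [lifetimePair()], held fixed.
#' @param irf,periodNs required when \code{hist} is a bare vector.
#' @param bgFraction known uniform background photon fraction (0 to omit
#'   the background term).
#' @return list with \code{p}, \code{logLik}, \code{lowConfidence}.
#' @export
pixelBoundFractionMle <- function(hist, lifetimes = lifetimePair(),
                                  irf = NULL, periodNs = NULL,
                                  bgFraction = 0) {
  if (methods::is(hist, "TcspcHistogram")) {
    counts <- hist@counts; irf <- hist@irf; periodNs <- hist@periodNs
  } else {
    counts <- as.numeric(hist)
    if (is.null(irf) || is.null(periodNs))
      stop("irf and periodNs are required with bare counts")
  }
  if (sum(counts) == 0)
    return(list(p = NA_real_, logLik = NA_real_, lowConfidence = TRUE))
  cp <- .componentProbs(lifetimes, length(counts), periodNs, irf)
  ll <- function(p) -.poisNll(counts, sum(counts) *
                                .mixProbs(cp, p, bgFraction))
  opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-7)
  # optimize() cannot land exactly on a boundary: compare explicitly
  cand <- c(opt$maximum, 0, 1)
  vals <- c(opt$objective, ll(0), ll(1))
  best <- which.max(vals)
  list(p = cand[best], logLik = vals[best],
       lowConfidence = sum(counts) < 50)
}

#' Vectorized bound-fraction MLE over an image
#'
#' Same estimator as [pixelBoundFractionMle()] applied to every pixel of a
#' micro-time array, solved by vectorized bisection of the score equation
#' (the Poisson log-likelihood in the mixture fraction is concave).
#'
#' @param tcspc numeric array (ny, nx, nBins) of per-pixel counts.
#' @param lifetimes a [lifetimePair()].
#' @param irf normalized IRF on the same bins.
#' @param periodNs laser period, ns.
#' @param bgFraction known uniform background fraction.
#' @param minCounts pixels with fewer photons are returned as NA.
#' @return matrix (ny, nx) of photon-fraction estimates.
#' @export
boundFractionMap <- function(tcspc, lifetimes = lifetimePair(), irf,
                             periodNs, bgFraction = 0, minCounts = 50) {
  dm <- dim(tcspc)
  stopifnot(length(dm) == 3)
  nBins <- dm[3]
  cp <- .componentProbs(lifetimes, nBins, periodNs, irf)
  C <- matrix(tcspc, ncol = nBins) # pixels x bins
  tot <- rowSums(C)
  f <- (1 - bgFraction) * cp$free + bgFraction / nBins
  b <- (1 - bgFraction) * cp$bound + bgFraction / nBins
  d <- b - f # d/dp of the per-bin mean shape
  fM <- matrix(f, nrow = nrow(C), ncol = nBins, byrow = TRUE)
  dM <- matrix(d, nrow = nrow(C), ncol = nBins, byrow = TRUE)
  # score(p) = sum_j C_j d_j / (f_j + p d_j): decreasing in p (concave ll)
  scoreAt <- function(Csub, fSub, dSub, p)
    rowSums(Csub * (dSub / pmax(fSub + p * dSub, 1e-14)))
  p <- rep(NA_real_, nrow(C))
  sLo <- scoreAt(C, fM, dM, 0); sHi <- scoreAt(C, fM, dM, 1)
  p[sLo <= 0] <- 0; p[sHi >= 0] <- 1
  open <- which(sLo > 0 & sHi < 0 & tot > 0)
  if (length(open)) {
    lo <- rep(0, length(open)); hi <- rep(1, length(open))
    Co <- C[open, , drop = FALSE]
    fo <- fM[open, , drop = FALSE]; do <- dM[open, , drop = FALSE]
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      up <- scoreAt(Co, fo, do, mid) > 0
      lo[up] <- mid[up]; hi[!up] <- mid[!up]
    }
    p[open] <- (lo + hi) / 2
  }
  p[tot < minCounts] <- NA_real_
  matrix(p, dm[1], dm[2])
}

#' Brightness-corrected molecular bound fraction
#'
#' Converts the photon fraction of the slow component into the molecular
#' fraction of bound fluorophore, assuming fluorescence quantum yields
#' proportional to the lifetimes:
#' \code{A = (p/tauBound) / ((1-p)/tauFree + p/tauBound)}.
#'
#' @param p bound-photon fraction(s) in [0, 1].
#' @param lifetimes a [lifetimePair()].
#' @return molecular bound fraction(s) in [0, 1].
#' @examples
#' brightnessCorrect(0.6, lifetimePair(0.4, 2.4))  # 0.2
#' @export
brightnessCorrect <- function(p, lifetimes = lifetimePair()) {
  tf <- lifetimes[["tauFree"]]; tb <- lifetimes[["tauBound"]]
  (p / tb) / ((1 - p) / tf + p / tb)
}

#' Photon fraction implied by a molecular bound fraction
#'
#' Exact inverse of [brightnessCorrect()].
#' @param A molecular bound fraction(s) in [0, 1].
#' @param lifetimes a [lifetimePair()].
#' @return photon fraction(s) in [0, 1].
#' @export
boundPhotonFraction <- function(A, lifetimes = lifetimePair()) {
  tf <- lifetimes[["tauFree"]]; tb <- lifetimes[["tauBound"]]
  A * tb / ((1 - A) * tf + A * tb)
}
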