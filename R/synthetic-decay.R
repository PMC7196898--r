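# TCSPC decay and polarized-pair simulators.

# Per-bin probability of photon arrival for a single exponential component
# under periodic (wrapped) pulsed excitation, convolved with the IRF.
# Returns a vector over the histogram bins summing to 1.
periodicComponentProbs <- function(binCenters, repetitionPeriod, tau, irf) {
  n <- length(binCenters)
  t0 <- binCenters - binCenters[1]
  # wrapped mono-exponential: sum_k exp(-(t + kT)/tau) over k >= 0
  dec <- exp(-t0 / tau) / (1 - exp(-repetitionPeriod / tau))
  g <- irfBinWeights(binCenters, repetitionPeriod, irf)
  p <- circConv(dec, g)
  p / sum(p)
}

# IRF discretized onto the histogram bins, wrapped at the repetition period
irfBinWeights <- function(binCenters, repetitionPeriod, irf) {
  n <- length(binCenters)
  dt <- binCenters[2] - binCenters[1]
  if (is(irf, "IRFModel") && irf@kind == "measured") {
    h <- irf@histogram
    if (length(h) != n) stop("measured IRF must share the histogram binning")
    return(h / sum(h))
  }
  center <- irf@center
  sigma <- irf@sigma
  if (sigma <= 0) {
    # delta IRF: split between the two adjacent bins (linear interpolation)
    pos <- ((center - binCenters[1]) / dt) %% n
    lo <- floor(pos)
    w <- pos - lo
    g <- numeric(n)
    g[(lo %% n) + 1] <- 1 - w
    g[((lo + 1) %% n) + 1] <- g[((lo + 1) %% n) + 1] + w
    return(g)
  }
  # wrapped Gaussian density at bin centers
  g <- numeric(n)
  for (k in -3:3) {
    g <- g + exp(-(binCenters - center + k * repetitionPeriod)^2 /
                   (2 * sigma^2))
  }
  g / sum(g)
}

circConv <- function(a, b) {
  n <- length(a)
  Re(fft(fft(a) * fft(b), inverse = TRUE)) / n
}

# Expected counts per bin for a multi-exponential decay model.
# amplitudes are fractional (sum 1); backgroundFraction in [0,1).
decayModelExpectation <- function(binCenters, repetitionPeriod, lifetimes,
                                  amplitudes, nPhotons, irf,
                                  backgroundFraction = 0) {
  p <- numeric(length(binCenters))
  for (i in seq_along(lifetimes)) {
    p <- p + amplitudes[i] *
      periodicComponentProbs(binCenters, repetitionPeriod, lifetimes[i], irf)
  }
  nPhotons * ((1 - backgroundFraction) * p +
                backgroundFraction / length(binCenters))
}

#' Simulate a TCSPC decay histogram
#'
#' Expected bin counts follow the periodic (wrapped) sum of exponentials
#' convolved with a Gaussian IRF plus a uniform background, scaled to
#' \code{nPhotons}; observed counts are Poisson draws, so the total count is
#' itself Poisson(\code{nPhotons}). The 25 ns default repetition period is
#' 40 MHz pulsed excitation.
#'
#' @param lifetimes component lifetimes, ns (> 0).
#' @param amplitudeFractions fractional amplitudes, each > 0, summing to 1.
#' @param nPhotons expected total photon count (>= 0).
#' @param seed RNG seed.
#' @param nBins histogram bins (>= 2; default 256).
#' @param repetitionPeriod ns (default 25).
#' @param irfCenter,irfSigma Gaussian IRF centre and width, ns.
#' @param backgroundFraction uniform background fraction in [0, 1).
#' @return A \linkS4class{DecayHistogram}.
#' @examples
#' h <- simulateDecay(2.5, 1, nPhotons = 1e4, seed = 1)
#' h
#' @export
simulateDecay <- function(lifetimes, amplitudeFractions, nPhotons, seed,
                          nBins = 256L, repetitionPeriod = 25,
                          irfCenter = 2, irfSigma = 0.1,
                          backgroundFraction = 0) {
  if (any(lifetimes <= 0)) stop("lifetimes must be > 0")
  if (any(amplitudeFractions <= 0)) stop("amplitude fractions must be > 0")
  if (abs(sum(amplitudeFractions) - 1) > 1e-9)
    stop("amplitude fractions must sum to 1")
  if (length(lifetimes) != length(amplitudeFractions))
    stop("lifetimes and amplitudeFractions must be congruent")
  if (nPhotons < 0) stop("nPhotons must be >= 0")
  if (nBins < 2) stop("need at least 2 bins")
  if (backgroundFraction < 0 || backgroundFraction >= 1)
    stop("backgroundFraction must be in [0, 1)")
  dt <- repetitionPeriod / nBins
  binCenters <- (seq_len(nBins) - 0.5) * dt
  irf <- IRFModel("gaussian", center = irfCenter, sigma = irfSigma)
  mu <- decayModelExpectation(binCenters, repetitionPeriod, lifetimes,
                              amplitudeFractions, nPhotons, irf,
                              backgroundFraction)
  rng <- localRNG(seed)
  counts <- rng(rpois(nBins, mu))
  DecayHistogram(binCenters, counts, repetitionPeriod)
}

#' Simulate a parallel/perpendicular polarized intensity pair
#'
#' Inverts the configured anisotropy expression so that the noiseless
#' \code{\link{computeAnisotropy}} of the returned pair equals
#' \code{rTrue} exactly; with Poisson noise the channel intensities are
#' independent Poisson draws at those expectations.
#'
#' @param rTrue target anisotropy.
#' @param totalCounts expected total photons (both channels).
#' @param calib \linkS4class{CalibrationConstants}.
#' @param noise "none" or "poisson".
#' @param seed RNG seed (used for the poisson mode).
#' @param grouping anisotropy formula variant (see
#'   \code{\link{computeAnisotropy}}).
#' @return A \linkS4class{PolarizedPair} (scalar channels).
#' @export
simulatePolarizedPair <- function(rTrue, totalCounts,
                                  calib = CalibrationConstants(),
                                  noise = c("none", "poisson"), seed = 1,
                                  grouping = "na_corrected") {
  noise <- match.arg(noise)
  G <- calib@G; L1 <- calib@L1; L2 <- calib@L2
  # solve I_par/I_perp from r; attainable range keeps both intensities > 0
  ratio <- switch(grouping,
    na_corrected = {
      den <- 1 - rTrue * (1 - 3 * L2)
      num <- G * (1 + rTrue * (2 - 3 * L1))
      if (den <= 0 || num <= 0)
        stop("rTrue outside the representable range of this formula")
      num / den
    },
    literal = {
      den <- 1 - rTrue * (1 - 3 * L2)
      num <- G + rTrue * (2 - 3 * L1)
      if (den <= 0 || num <= 0)
        stop("rTrue outside the representable range of this formula")
      num / den
    },
    classic = {
      den <- 1 - rTrue
      num <- G * (1 + 2 * rTrue)
      if (den <= 0 || num <= 0)
        stop("rTrue outside the representable range of this formula")
      num / den
    },
    stop("unknown grouping"))
  iPar <- totalCounts * ratio / (1 + ratio)
  iPerp <- totalCounts / (1 + ratio)
  if (noise == "poisson") {
    rng <- localRNG(seed)
    iPar <- rng(rpois(1, iPar))
    iPerp <- rng(rpois(1, iPerp))
  }
  PolarizedPair(iPar, iPerp)
}
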