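# Steady-state anisotropy, TCSPC lifetime fitting, FRET efficiency.

#' Merge a series of polarized frames by summation
#'
#' @param frames list of \linkS4class{PolarizedPair} with congruent shapes.
#' @return A \linkS4class{PolarizedPair} with summed channels and
#'   \code{nFramesMerged} set.
#' @export
mergeFrames <- function(frames) {
  if (length(frames) < 1) stop("need at least one frame")
  ref <- frames[[1]]
  p <- iPar(ref); q <- iPerp(ref)
  n <- sum(vapply(frames, nFramesMerged, integer(1)))
  for (f in frames[-1]) {
    if (!identical(dim(iPar(f)), dim(p)) || length(iPar(f)) != length(p))
      stop("frames have mismatching shapes")
    p <- p + iPar(f)
    q <- q + iPerp(f)
  }
  PolarizedPair(p, q, nFramesMerged = n)
}

#' Compute steady-state fluorescence anisotropy
#'
#' Default grouping is the objective-NA-corrected form
#' \deqn{r = (I_\parallel - G I_\perp) /
#'       ((1 - 3 L_2) I_\parallel + (2 - 3 L_1) G I_\perp)}
#' which reduces to the classic \eqn{(I_\parallel - I_\perp) /
#' (I_\parallel + 2 I_\perp)} at G = 1, L1 = L2 = 0. Two alternative
#' groupings are selectable for sensitivity analysis: "literal" omits G from
#' the denominator; "classic" ignores the L corrections.
#'
#' @param pair a \linkS4class{PolarizedPair} (scalars or per-pixel maps;
#'   computed element-wise).
#' @param calib \linkS4class{CalibrationConstants} (default G = 0.481,
#'   L1 = 0.013, L2 = 0.037).
#' @param grouping "na_corrected" (default), "literal" or "classic".
#' @return anisotropy r, same shape as the input channels.
#' @examples
#' computeAnisotropy(PolarizedPair(481, 1000))       # r = 0 at I_par = G I_perp
#' computeAnisotropy(PolarizedPair(3, 1), CalibrationConstants(1, 0, 0))
#' @export
computeAnisotropy <- function(pair, calib = CalibrationConstants(),
                              grouping = c("na_corrected", "literal",
                                           "classic")) {
  grouping <- match.arg(grouping)
  p <- iPar(pair); q <- iPerp(pair)
  G <- calib@G; L1 <- calib@L1; L2 <- calib@L2
  den <- switch(grouping,
    na_corrected = (1 - 3 * L2) * p + (2 - 3 * L1) * G * q,
    literal      = (1 - 3 * L2) * p + (2 - 3 * L1) * q,
    classic      = p + 2 * G * q)
  if (any(den == 0)) stop("undefined anisotropy: zero denominator")
  (p - G * q) / den
}

#' Photon-weighted anisotropy per ROI
#'
#' Sums the parallel and perpendicular intensities over each ROI's pixels
#' first, then applies \code{\link{computeAnisotropy}} to the pooled sums
#' (photon-weighted; averaging per-pixel r would be noise-biased).
#'
#' @param pair \linkS4class{PolarizedPair} with per-pixel matrix channels.
#' @param roiSet \linkS4class{ROISet} on the same plane.
#' @param calib \linkS4class{CalibrationConstants}.
#' @param grouping formula variant, see \code{\link{computeAnisotropy}}.
#' @return named numeric vector of r values (one per ROI); ROIs that
#'   collected zero photons are skipped with a warning.
#' @export
anisotropyByRoi <- function(pair, roiSet, calib = CalibrationConstants(),
                            grouping = "na_corrected") {
  p <- iPar(pair); q <- iPerp(pair)
  if (is.null(dim(p))) stop("anisotropyByRoi needs per-pixel channel maps")
  if (!all(dim(p) == roiSet@dimPlane))
    stop("ROI plane dimensions do not match the channel maps")
  out <- numeric(0)
  for (r in rois(roiSet)) {
    sp <- sum(p[r$pixels]); sq <- sum(q[r$pixels])
    if (sp == 0 && sq == 0) {
      warning(sprintf("ROI %s skipped: zero photons", r$label))
      next
    }
    out[r$label] <- computeAnisotropy(PolarizedPair(sp, sq), calib,
                                      grouping = grouping)
  }
  out
}

# Poisson deviance of counts k under model mu (zero-safe)
poissonDeviance <- function(k, mu) {
  mu <- pmax(mu, 1e-12)
  term <- mu - k
  nz <- k > 0
  term[nz] <- term[nz] + k[nz] * log(k[nz] / mu[nz])
  2 * sum(term)
}

# deviance of the multi-exponential model at unconstrained parameters
# theta = (log tau_1..n, weight logits (n-1), background logit, log N)
decayFitObjective <- function(theta, binCenters, counts, repetitionPeriod,
                              irf, nComponents) {
  taus <- exp(theta[seq_len(nComponents)])
  if (any(!is.finite(taus)) || any(taus > 1e3) || any(taus < 1e-3))
    return(1e12)
  if (nComponents > 1) {
    w <- c(theta[nComponents + seq_len(nComponents - 1)], 0)
    w <- exp(w - max(w)); w <- w / sum(w)
  } else w <- 1
  b <- plogis(theta[2 * nComponents])
  N <- exp(theta[2 * nComponents + 1])
  mu <- decayModelExpectation(binCenters, repetitionPeriod, taus, w, N, irf, b)
  poissonDeviance(counts, mu)
}

#' Fit a multi-exponential model to a TCSPC decay by Poisson MLE
#'
#' Maximizes the Poisson likelihood of the bin counts under a periodic
#' (wrapped) multi-exponential model convolved with the IRF, plus a free
#' uniform background (floored at 0). Optimization is multi-start over a
#' lifetime grid of 0.5, 1, 2 and 4 ns (all pairs for two components, plus
#' a start seeded at the one-component solution so the two-component
#' deviance can never exceed it).
#'
#' @param hist a \linkS4class{DecayHistogram} with >= 100 total counts.
#' @param irf an \linkS4class{IRFModel}.
#' @param nComponents 1 or 2.
#' @return A \linkS4class{LifetimeFit}; lifetimes sorted ascending,
#'   fractional amplitudes summing to 1, background in counts/bin.
#' @examples
#' h <- simulateDecay(c(0.8, 3.0), c(0.4, 0.6), 1e5, seed = 7)
#' fitDecay(h, IRFModel("gaussian", center = 2, sigma = 0.1), 2)
#' @export
fitDecay <- function(hist, irf = IRFModel("gaussian", center = 2, sigma = 0.1),
                     nComponents = 2L) {
  if (!nComponents %in% c(1L, 2L)) stop("nComponents must be 1 or 2")
  counts <- photonCounts(hist)
  if (sum(counts) < 100)
    stop("low-count histogram: need >= 100 photons to fit")
  bc <- binCenters(hist)
  T <- repetitionPeriod(hist)
  Ntot <- sum(counts)
  grid <- c(0.5, 1, 2, 4)
  starts <- list()
  if (nComponents == 1L) {
    for (t1 in grid) starts[[length(starts) + 1L]] <- c(log(t1), qlogis(0.01),
                                                        log(Ntot))
  } else {
    for (i in 1:(length(grid) - 1)) for (j in (i + 1):length(grid))
      starts[[length(starts) + 1L]] <-
        c(log(grid[i]), log(grid[j]), 0, qlogis(0.01), log(Ntot))
    fit1 <- fitDecay(hist, irf, 1L)
    t1 <- lifetimes(fit1)
    starts[[length(starts) + 1L]] <-
      c(log(t1 * 0.8), log(t1 * 1.2), 0, qlogis(0.01), log(Ntot))
  }
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, decayFitObjective, binCenters = bc, counts = counts,
            repetitionPeriod = T, irf = irf, nComponents = nComponents,
            method = "BFGS", control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop("decay fit failed to converge from every start")
  th <- best$par
  taus <- exp(th[seq_len(nComponents)])
  if (nComponents > 1) {
    w <- c(th[nComponents + seq_len(nComponents - 1)], 0)
    w <- exp(w - max(w)); w <- w / sum(w)
  } else w <- 1
  b <- plogis(th[2 * nComponents])
  N <- exp(th[2 * nComponents + 1])
  ord <- order(taus)
  taus <- taus[ord]; w <- w[ord]
  new("LifetimeFit", amplitudes = as.numeric(w), lifetimes = as.numeric(taus),
      background = N * b / length(counts),
      tauAv = sum(w * taus) / sum(w),
      fitDeviance = best$value, nComponents = as.integer(nComponents))
}

#' Amplitude-weighted average lifetime
#'
#' \eqn{\tau_{Av} = \sum_i \alpha_i \tau_i / \sum_i \alpha_i}; this is the
#' FRET-sensitive statistic: adding a quenched (shorter-lifetime) component
#' with nonzero amplitude strictly decreases it. An intensity-weighted
#' variant (\eqn{\sum \alpha \tau^2 / \sum \alpha \tau}) is available.
#'
#' @param fit a \linkS4class{LifetimeFit}, or a list with \code{amplitudes}
#'   and \code{lifetimes}.
#' @param weighting "amplitude" (default) or "intensity".
#' @return tau_Av in ns.
#' @export
amplitudeWeightedLifetime <- function(fit, weighting = c("amplitude",
                                                         "intensity")) {
  weighting <- match.arg(weighting)
  a <- if (is(fit, "LifetimeFit")) amplitudes(fit) else fit$amplitudes
  t <- if (is(fit, "LifetimeFit")) lifetimes(fit) else fit$lifetimes
  if (sum(a) == 0) stop("undefined tau_Av: amplitudes sum to zero")
  if (weighting == "amplitude") sum(a * t) / sum(a)
  else sum(a * t^2) / sum(a * t)
}

#' Lifetime-FRET efficiency
#'
#' \eqn{E = 1 - \tau_{DA}/\tau_D}. Negative values (donor lifetime longer
#' with acceptor than without) are reported with a warning rather than
#' clipped.
#'
#' @param tauDa donor lifetime in the presence of acceptor, ns.
#' @param tauD donor-only lifetime, ns (> 0).
#' @return E, dimensionless.
#' @export
fretEfficiency <- function(tauDa, tauD) {
  if (tauD <= 0) stop("tauD must be > 0")
  e <- 1 - tauDa / tauD
  if (any(e < 0)) warning("negative FRET efficiency (tauDa > tauD)")
  e
}

#' Condition contrast in FRET efficiency with a bootstrap CI
#'
#' Converts each ROI's amplitude-weighted lifetime to a FRET efficiency
#' against the common donor-only lifetime, averages per condition, and
#' reports \eqn{\Delta E = 100 (E_a - E_b)} in percentage points with a
#' seeded bootstrap percentile confidence interval.
#'
#' @param tauD donor-only lifetime, ns (> 0).
#' @param tauDaConditionA,tauDaConditionB per-ROI tau_Av values (ns) for
#'   the two conditions (non-empty).
#' @param nBoot bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @param level CI level (default 0.95).
#' @return list with \code{deltaE} (percentage points), \code{ci}
#'   (length-2), \code{eA}, \code{eB}.
#' @export
deltaFret <- function(tauD, tauDaConditionA, tauDaConditionB,
                      nBoot = 2000L, seed = 1, level = 0.95) {
  if (tauD <= 0) stop("tauD must be > 0")
  if (length(tauDaConditionA) < 1 || length(tauDaConditionB) < 1)
    stop("both condition lists must be non-empty")
  eA <- mean(1 - tauDaConditionA / tauD)
  eB <- mean(1 - tauDaConditionB / tauD)
  dE <- 100 * (eA - eB)
  rng <- localRNG(seed)
  na <- length(tauDaConditionA); nb <- length(tauDaConditionB)
  boots <- rng(vapply(seq_len(nBoot), function(i) {
    ba <- mean(1 - sample(tauDaConditionA, na, replace = TRUE) / tauD)
    bb <- mean(1 - sample(tauDaConditionB, nb, replace = TRUE) / tauD)
    100 * (ba - bb)
  }, numeric(1)))
  alpha <- (1 - level) / 2
  list(deltaE = dE,
       ci = as.numeric(quantile(boots, c(alpha, 1 - alpha), names = FALSE)),
       eA = eA, eB = eB)
}
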