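# Shared fixtures and independent oracles.

# match detected spots to truth: centroid within `tol` px in-plane and
# <= 1 plane axially; returns c(nMatched, nDetected, nTruth)
matchSpots <- function(spotSet, truth, tol = 2) {
  dt <- spotTable(spotSet)
  tr <- truth
  matched <- 0L
  used <- rep(FALSE, nrow(dt))
  for (i in seq_len(nrow(tr))) {
    d <- sqrt((dt$y - tr$y[i])^2 + (dt$x - tr$x[i])^2)
    hit <- which(d <= tol & abs(dt$z - tr$z[i]) <= 1 & !used)
    if (length(hit)) {
      matched <- matched + 1L
      used[hit[1]] <- TRUE
    }
  }
  c(matched = matched, detected = nrow(dt), truth = nrow(tr))
}

# a callose-like render: bright compact puncta over a faint wall, scaled so
# the punctum peak over the background noise floor is about `snr`
calloseRender <- function(seed, nPuncta = 25, snr = 10, size = 192, nZ = 3,
                          pm = 8, readSd = 2) {
  mosaic <- makeCellMosaic(size, size, 10, seed = seed)
  noiseSd <- sqrt(pm + readSd^2)
  pdIdx <- 1 + snr * noiseSd / pm   # added peak ~ snr * background noise sd
  renderMembraneStack(mosaic, nZ = nZ, pdIndexTrue = pdIdx, pmIntensity = pm,
                      psfSigma = 0.8, readNoiseSd = readSd, seed = seed + 1,
                      nPuncta = nPuncta)
}

# independent TCSPC model oracle: direct O(n^2) circular convolution of the
# wrapped exponential with a wrapped-Gaussian IRF (no fft, no package code)
oracleDecayExpectation <- function(nBins, period, lifetimes, fracs, nPhotons,
                                   irfCenter, irfSigma, bg = 0) {
  dt <- period / nBins
  t <- (seq_len(nBins) - 0.5) * dt
  p <- numeric(nBins)
  for (ci in seq_along(lifetimes)) {
    dec <- exp(-(t - t[1]) / lifetimes[ci]) /
      (1 - exp(-period / lifetimes[ci]))
    g <- numeric(nBins)
    for (k in -3:3)
      g <- g + exp(-(t - irfCenter + k * period)^2 / (2 * irfSigma^2))
    g <- g / sum(g)
    conv <- numeric(nBins)
    for (j in seq_len(nBins)) {
      idx <- ((j - seq_len(nBins)) %% nBins) + 1
      conv[j] <- sum(dec[idx] * g)
    }
    p <- p + fracs[ci] * conv / sum(conv)
  }
  nPhotons * ((1 - bg) * p + bg / nBins)
}

# truth tau pair/amplitudes giving a target amplitude-weighted lifetime with
# a fixed quenched component (used by the FLIM recovery checks)
biexpForTauAv <- function(tauAvTarget, tauD = 2.9, tauQ = 1.2) {
  a2 <- (tauD - tauAvTarget) / (tauD - tauQ)
  list(lifetimes = c(tauQ, tauD), fracs = c(a2, 1 - a2))
}
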