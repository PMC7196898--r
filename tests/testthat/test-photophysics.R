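# Anisotropy, decay fitting, tau_Av and FRET efficiency.

test_that("frame merging sums channels and counts frames", {
  f <- PolarizedPair(matrix(1, 4, 4), matrix(2, 4, 4))
  one <- mergeFrames(list(f))
  expect_equal(iPar(one), iPar(f))
  expect_equal(nFramesMerged(one), 1L)
  twenty <- mergeFrames(rep(list(f), 20))
  expect_equal(iPar(twenty), matrix(20, 4, 4))
  expect_equal(nFramesMerged(twenty), 20L)
  g <- PolarizedPair(matrix(1, 3, 3), matrix(1, 3, 3))
  expect_error(mergeFrames(list(f, g)), "shape")
})

test_that("anisotropy formula: null case, classic limit, direct arithmetic", {
  calib <- CalibrationConstants()   # G = 0.481, L1 = 0.013, L2 = 0.037
  expect_equal(computeAnisotropy(PolarizedPair(481, 1000), calib), 0)
  expect_equal(
    computeAnisotropy(PolarizedPair(3, 1), CalibrationConstants(1, 0, 0)),
    0.4)
  # direct high-precision arithmetic oracle for the default grouping
  p <- 200; q <- 100
  oracle <- (p - 0.481 * q) /
    ((1 - 3 * 0.037) * p + (2 - 3 * 0.013) * 0.481 * q)
  expect_equal(computeAnisotropy(PolarizedPair(p, q), calib), oracle,
               tolerance = 1e-15)
  # r invariant under joint scaling
  expect_equal(computeAnisotropy(PolarizedPair(p * 7, q * 7), calib), oracle)
  expect_error(computeAnisotropy(PolarizedPair(1, 0),
                                 CalibrationConstants(1, 0, 0),
                                 grouping = "classic"), NA)
})

test_that("alternative formula groupings are selectable and distinct", {
  pair <- PolarizedPair(200, 100)
  calib <- CalibrationConstants()
  rDef <- computeAnisotropy(pair, calib)
  rLit <- computeAnisotropy(pair, calib, grouping = "literal")
  rCls <- computeAnisotropy(pair, calib, grouping = "classic")
  expect_false(isTRUE(all.equal(rDef, rLit)))
  expect_false(isTRUE(all.equal(rDef, rCls)))
  # all variants coincide in the uncorrected limit
  u <- CalibrationConstants(1, 0, 0)
  expect_equal(computeAnisotropy(pair, u),
               computeAnisotropy(pair, u, grouping = "literal"))
  expect_equal(computeAnisotropy(pair, u),
               computeAnisotropy(pair, u, grouping = "classic"))
})

test_that("ROI anisotropy pools photons and preserves condition ordering", {
  # homogeneous image: every ROI returns the same r
  pp <- PolarizedPair(matrix(150, 32, 32), matrix(100, 32, 32))
  rs <- ROISet(list(list(label = "a", class = "PD", pixels = 1:50),
                    list(label = "b", class = "PM", pixels = 200:400)),
               c(32, 32))
  r <- anisotropyByRoi(pp, rs)
  expect_equal(unname(r["a"]), unname(r["b"]))
  # painted round trip at r_true = 0.25
  calib <- CalibrationConstants()
  tgt <- simulatePolarizedPair(0.25, 1e4, calib)
  ip <- matrix(0, 16, 16); iq <- matrix(0, 16, 16)
  ip[1:20] <- iPar(tgt) / 20; iq[1:20] <- iPerp(tgt) / 20
  ip[100] <- 1e-9  # keep the pair valid outside the ROI
  one <- anisotropyByRoi(PolarizedPair(ip, iq),
                         ROISet(list(list(label = "roi", class = "PD",
                                          pixels = 1:20)), c(16, 16)), calib)
  expect_equal(unname(one), 0.25, tolerance = 1e-9)
  # cytosol-like (0.30) vs PM-like (0.22) ordering under Poisson noise
  ord <- vapply(1:100, function(s) {
    a <- computeAnisotropy(simulatePolarizedPair(0.30, 1e5, calib, "poisson",
                                                 seed = 2 * s), calib)
    b <- computeAnisotropy(simulatePolarizedPair(0.22, 1e5, calib, "poisson",
                                                 seed = 2 * s + 1), calib)
    a > b
  }, logical(1))
  expect_gte(mean(ord), 0.99)
})

test_that("decay fitting is self-consistent on exact mono-exponential data", {
  # noiseless (expectation) counts, narrow IRF
  nb <- 250
  mu <- oracleDecayExpectation(nb, 25, 2.5, 1, 1e6, irfCenter = 2,
                               irfSigma = 0.05)
  h <- DecayHistogram((seq_len(nb) - 0.5) * 25 / nb, round(mu), 25)
  f <- fitDecay(h, IRFModel("gaussian", center = 2, sigma = 0.05), 1L)
  expect_equal(lifetimes(f), 2.5, tolerance = 4e-3)
  expect_equal(tauAv(f), 2.5, tolerance = 4e-3)
})

test_that("biexponential fits match a coarse grid-search MLE oracle", {
  h <- simulateDecay(c(0.8, 3.0), c(0.4, 0.6), 1e6, seed = 7,
                     irfCenter = 2, irfSigma = 0.1)
  irf <- IRFModel("gaussian", center = 2, sigma = 0.1)
  f <- fitDecay(h, irf, 2L)
  expect_equal(lifetimes(f), c(0.8, 3.0), tolerance = 0.05)
  expect_equal(amplitudes(f), c(0.4, 0.6), tolerance = 0.05)
  # independent coarse grid search over (tau1, tau2, a2) by Poisson deviance
  counts <- photonCounts(h); nph <- sum(counts)
  dev <- function(mu) 2 * sum(mu - counts +
                                ifelse(counts > 0,
                                       counts * log(counts / mu), 0))
  best <- c(Inf, NA, NA, NA)
  for (t1 in seq(0.6, 1.0, 0.1)) for (t2 in seq(2.6, 3.4, 0.1))
    for (a2 in seq(0.45, 0.75, 0.05)) {
      mu <- oracleDecayExpectation(length(counts), 25, c(t1, t2),
                                   c(1 - a2, a2), nph, 2, 0.1)
      d <- dev(pmax(mu, 1e-12))
      if (d < best[1]) best <- c(d, t1, t2, a2)
    }
  expect_equal(lifetimes(f)[1], best[2], tolerance = 0.1)
  expect_equal(lifetimes(f)[2], best[3], tolerance = 0.1)
  # the smooth MLE must fit at least as well as the best grid point
  expect_lte(fitDeviance(f), best[1] + 1e-6)
})

test_that("decay fitting validates inputs and nests deviances", {
  h0 <- DecayHistogram((1:64 - 0.5) * 25 / 64, rep(0, 64), 25)
  expect_error(fitDecay(h0), "low-count")
  h <- simulateDecay(c(0.9, 2.8), c(0.3, 0.7), 2e4, seed = 3)
  irf <- IRFModel("gaussian", center = 2, sigma = 0.1)
  f1 <- fitDecay(h, irf, 1L)
  f2 <- fitDecay(h, irf, 2L)
  expect_lte(fitDeviance(f2), fitDeviance(f1) + 1e-6)
  expect_error(fitDecay(h, irf, 3L), "1 or 2")
})

test_that("tau_Av recovery across repeated simulated decays", {
  truth <- biexpForTauAv(2.61)
  errs <- vapply(1:50, function(s) {
    h <- simulateDecay(truth$lifetimes, truth$fracs, 1e5, seed = 400 + s,
                       irfCenter = 2, irfSigma = 0.1)
    abs(tauAv(fitDecay(h, IRFModel("gaussian", 2, 0.1), 2L)) - 2.61)
  }, numeric(1))
  expect_gte(mean(errs <= 0.05), 0.90)
})

test_that("amplitude-weighted lifetime follows its definition", {
  expect_equal(amplitudeWeightedLifetime(list(amplitudes = 1,
                                              lifetimes = 2.0)), 2.0)
  expect_equal(amplitudeWeightedLifetime(list(amplitudes = c(0.5, 0.5),
                                              lifetimes = c(1, 3))), 2.0)
  expect_equal(amplitudeWeightedLifetime(list(amplitudes = c(0.4, 0.6),
                                              lifetimes = c(0.8, 3.0))),
               2.12)
  # intensity weighting differs and exceeds the amplitude weighting here
  iw <- amplitudeWeightedLifetime(list(amplitudes = c(0.4, 0.6),
                                       lifetimes = c(0.8, 3.0)), "intensity")
  expect_equal(iw, (0.4 * 0.8^2 + 0.6 * 3^2) / 2.12)
  # adding a quenched component strictly decreases tau_Av
  expect_lt(amplitudeWeightedLifetime(list(amplitudes = c(0.2, 0.8),
                                           lifetimes = c(1.0, 2.9))),
            2.9)
})

test_that("FRET efficiency and condition contrasts", {
  expect_equal(fretEfficiency(2.9, 2.9), 0)
  expect_equal(fretEfficiency(0, 2.9), 1)
  expect_equal(fretEfficiency(2.8, 2.9), 1 - 2.8 / 2.9)  # ~ 0.0345
  expect_warning(fretEfficiency(3.0, 2.9), "negative")
  expect_error(fretEfficiency(2.8, 0), "tauD")
  same <- deltaFret(2.9, c(2.6, 2.7), c(2.6, 2.7))
  expect_equal(same$deltaE, 0)
  d <- deltaFret(2.9, 2.61, 2.70)
  expect_equal(d$deltaE, 100 * (2.70 - 2.61) / 2.9, tolerance = 1e-9)
  # bootstrap CI is seeded, reproducible, and brackets the point estimate
  set.seed(17)
  a <- rnorm(20, 2.61, 0.02); b <- rnorm(20, 2.70, 0.02)
  d2 <- deltaFret(2.9, a, b, seed = 5)
  expect_identical(d2$ci, deltaFret(2.9, a, b, seed = 5)$ci)
  expect_true(d2$ci[1] <= d2$deltaE && d2$deltaE <= d2$ci[2])
})
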