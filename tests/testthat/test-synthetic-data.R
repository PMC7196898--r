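# Generators: determinism, validity, and agreement with analytic oracles.

test_that("cell mosaic tessellation is complete, labelled and deterministic", {
  m1 <- makeCellMosaic(256, 256, 12, seed = 1)
  expect_identical(sort(unique(as.integer(labelImage(m1)))), 1:12)
  expect_false(any(is.na(labelImage(m1))))
  m1b <- makeCellMosaic(256, 256, 12, seed = 1)
  expect_identical(labelImage(m1), labelImage(m1b))
  # degenerate tessellation: a single cell has no internal interfaces
  m0 <- makeCellMosaic(256, 256, 1, seed = 0)
  expect_equal(sum(boundaryMask(m0)), 0)
  expect_error(makeCellMosaic(16, 256, 3, seed = 1), "32")
})

test_that("membrane render conserves photons and places puncta on walls", {
  m <- makeCellMosaic(128, 128, 6, seed = 3)
  r <- renderMembraneStack(m, nZ = 3, pdIndexTrue = 2, pmIntensity = 50,
                           psfSigma = 1, readNoiseSd = 0, seed = 4,
                           nPuncta = 8, shotNoise = FALSE)
  meta <- mosaicMeta(r$truth)
  expect_equal(sum(voxels(r$stack)), meta$pmMass + meta$spotMass,
               tolerance = 1e-6)
  # truth puncta sit on the boundary mask (<= 1 px dilation, via validity)
  expect_true(validObject(r$truth))
  expect_equal(nrow(spotTruth(r$truth)), 8)
  # zero density -> membrane only, no truth spots
  r0 <- renderMembraneStack(m, nZ = 2, pdPer100um = 0, pdIndexTrue = 2,
                            pmIntensity = 10, seed = 5)
  expect_equal(nrow(spotTruth(r0$truth)), 0)
  expect_error(renderMembraneStack(m, nZ = 0, seed = 1), "nZ")
  expect_error(renderMembraneStack(m, nZ = 1, pdIndexTrue = 0.5, seed = 1),
               "pdIndexTrue")
})

test_that("noiseless punctum peak is pdIndexTrue times the membrane plateau", {
  m <- makeCellMosaic(128, 128, 4, seed = 7)
  r <- renderMembraneStack(m, nZ = 1, pdIndexTrue = 2, pmIntensity = 50,
                           psfSigma = 0.8, readNoiseSd = 0, seed = 8,
                           nPuncta = 5, shotNoise = FALSE)
  tr <- spotTruth(r$truth)
  v <- voxels(r$stack)[1, , ]
  peaks <- v[cbind(tr$y, tr$x)]
  # oracle: an isolated enriched patch much wider than the PSF keeps its
  # center at the full enriched level, so peak ~ pdIndexTrue * plateau
  expect_true(all(abs(peaks - 2 * 50) < 0.05 * 100))
  # identity ratio: pdIndexTrue = 1 renders indistinguishable from membrane
  r1 <- renderMembraneStack(m, nZ = 1, pdIndexTrue = 1, pmIntensity = 50,
                            psfSigma = 0.8, readNoiseSd = 0, seed = 8,
                            nPuncta = 5, shotNoise = FALSE)
  rNone <- renderMembraneStack(m, nZ = 1, pdPer100um = 0, pdIndexTrue = 1,
                               pmIntensity = 50, psfSigma = 0.8,
                               readNoiseSd = 0, seed = 8, shotNoise = FALSE)
  expect_equal(voxels(r1$stack), voxels(rNone$stack), tolerance = 1e-12)
})

test_that("decay simulator matches the independent convolution oracle", {
  nb <- 128; nph <- 1e4
  mu <- oracleDecayExpectation(nb, 25, c(0.8, 3.0), c(0.4, 0.6), nph,
                               irfCenter = 2, irfSigma = 0.15)
  acc <- matrix(0, 200, nb)
  for (s in 1:200) {
    h <- simulateDecay(c(0.8, 3.0), c(0.4, 0.6), nph, seed = s, nBins = nb,
                       irfCenter = 2, irfSigma = 0.15)
    acc[s, ] <- photonCounts(h)
  }
  mbar <- colMeans(acc)
  se <- sqrt(pmax(mu, 1) / 200)
  expect_gte(mean(abs(mbar - mu) <= 3 * se), 0.95)
  # totals are ~ Poisson(nPhotons)
  expect_equal(mean(rowSums(acc)), nph, tolerance = 0.01)
})

test_that("mono-exponential expectations decay at exp(-dt/tau) with delta IRF", {
  nb <- 250
  acc <- rowSums(vapply(1:200, function(s)
    photonCounts(simulateDecay(2.5, 1, 2e4, seed = s, nBins = nb,
                               irfCenter = 0, irfSigma = 0)),
    numeric(nb)))
  dt <- 25 / nb
  # compare mean bin ratios over the well-populated early range
  ratios <- acc[21:80] / acc[20:79]
  expect_equal(mean(ratios), exp(-dt / 2.5), tolerance = 0.002)
})

test_that("decay simulator validates its inputs", {
  expect_error(simulateDecay(c(0.8, 3), c(0.7, 0.4), 1e3, seed = 1), "sum to 1")
  expect_error(simulateDecay(-1, 1, 1e3, seed = 1), "> 0")
  h0 <- simulateDecay(2.5, 1, 0, seed = 1)
  expect_true(all(photonCounts(h0) == 0))
})

test_that("polarized pair inverts the anisotropy formula exactly", {
  calib <- CalibrationConstants()
  p0 <- simulatePolarizedPair(0, 1e4, calib)
  expect_equal(iPar(p0), calib@G * iPerp(p0), tolerance = 1e-12)
  p3 <- simulatePolarizedPair(0.3, 1e6, calib)
  expect_equal(computeAnisotropy(p3, calib), 0.3, tolerance = 1e-12)
  expect_error(simulatePolarizedPair(5, 1e4, calib), "representable")
  # Monte-Carlo: Poisson noise at 1e6 photons keeps r within 0.01
  rs <- vapply(1:200, function(s)
    computeAnisotropy(simulatePolarizedPair(0.3, 1e6, calib, "poisson",
                                            seed = s), calib), numeric(1))
  expect_lt(max(abs(rs - 0.3)), 0.01)
})

test_that("FRAP simulator hits its closed-form recovery values", {
  # full recovery, no acquisition bleaching -> asymptote at prebleach level
  tr <- simulateFrap(mobileFractionTrue = 100, recoveryTau = 5, noiseSd = 0,
                     nPost = 120, seed = 1)
  fn <- normalizeFrap(tr)
  expect_equal(fn[length(fn)], 1, tolerance = 1e-6)
  # immobile -> flat at the bleach floor
  tr0 <- simulateFrap(mobileFractionTrue = 0, bleachDepth = 0.3, noiseSd = 0,
                      seed = 1)
  fn0 <- normalizeFrap(tr0)
  post <- seq(bleachFrameIndex(tr0), length(fn0))
  expect_equal(unname(fn0[post]), rep(0.3, length(post)), tolerance = 1e-9)
  # closed form: Mf=40, tau=10 -> normalized recovery at 60 s = 40(1-e^-6)
  tr40 <- simulateFrap(mobileFractionTrue = 40, recoveryTau = 10, noiseSd = 0,
                       nPost = 90, seed = 1)
  mf <- mobileFraction(tr40, tEval = 60, endpointWindow = 1)
  expect_equal(mf$mobileFraction, 40 * (1 - exp(-6)), tolerance = 1e-9)
  expect_warning(simulateFrap(recoveryTau = 500, nPost = 10, seed = 1),
                 "unidentifiable")
})

test_that("luminescence simulator produces the stated burst kinetics", {
  flat <- simulateLuminescence(burstAmplitude = 0, noiseSd = 0, seed = 1)
  expect_true(all(flat$rlu == flat$rlu[1]))
  expect_error(simulateLuminescence(interval = 0, seed = 1), "interval")
  expect_error(simulateLuminescence(burstAmplitude = -5, seed = 1), ">= 0")
  expect_error(simulateLuminescence(duration = 20, seed = 1), "25")
})

test_that("bombardment counts are valid, reproducible and overdispersed", {
  tab <- simulateBombardment(seed = 11)
  expect_silent(validateBombardmentTable(tab))
  expect_identical(tab, simulateBombardment(seed = 11))
  expect_error(simulateBombardment(nSitesPerGroup = 0, seed = 1), ">= 1")
  # Poisson limit: huge dispersion at mu = 5 gives variance ~ 5 (the
  # zero-truncated Poisson oracle value is 4.863)
  big <- simulateBombardment(muMock = 5, treatmentRatio = 1,
                             dispersion = 1e9, nSitesPerGroup = 50000,
                             treatments = "mock", seed = 12)
  ztVar <- 5 * 6 / (1 - exp(-5)) - (5 / (1 - exp(-5)))^2
  expect_equal(var(big$n_cells), ztVar, tolerance = 0.05)
  expect_equal(var(big$n_cells), 5, tolerance = 0.2)
  # null treatment ratio: two-sample test non-significant in >= 94% of reps
  rej <- vapply(1:100, function(s) {
    t <- simulateBombardment(treatmentRatio = 1, nSitesPerGroup = 40,
                             seed = 100 + s)
    suppressWarnings(wilcox.test(n_cells ~ treatment, t)$p.value) < 0.05
  }, logical(1))
  expect_gte(mean(!rej), 0.94)
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(makeCellMosaic(64, 64, 3, seed = 5))
  invisible(simulateDecay(2.5, 1, 100, seed = 6))
  invisible(simulateBombardment(seed = 7))
  expect_identical(.Random.seed, before)
})
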