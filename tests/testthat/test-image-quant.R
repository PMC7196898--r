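# Spot detection, ROI construction and PD index.

test_that("detection recovers synthetic puncta with high recall/precision", {
  r <- calloseRender(seed = 21, nPuncta = 25, snr = 10)
  s <- detectSpots(r$stack, SpotDetectionParams())
  m <- matchSpots(s, spotTruth(r$truth))
  expect_gte(m["matched"] / m["truth"], 0.96)
  expect_gte(m["matched"] / m["detected"], 0.96)
})

test_that("degenerate images are handled without false detections", {
  z <- ImageStack(array(0, c(2, 64, 64)))
  expect_equal(nSpots(detectSpots(z)), 0)
  sat <- ImageStack(array(4095, c(2, 64, 64)))
  expect_warning(s <- detectSpots(sat), "saturated")
  expect_equal(nSpots(s), 0)
  # pure-noise stacks: at most one false spot at default parameters
  fp <- vapply(1:50, function(s) {
    set.seed(s)
    v <- array(pmax(rnorm(96 * 96 * 3, 10, 2), 0), c(3, 96, 96))
    nSpots(detectSpots(ImageStack(v)))
  }, integer(1))
  expect_true(all(fp <= 1))
})

test_that("size filter and spot-set invariants hold", {
  # a single 2-voxel blob is rejected by minVoxels = 3
  v <- array(0, c(3, 32, 32))
  v[2, 16, 16] <- 100; v[2, 16, 17] <- 100
  s <- detectSpots(ImageStack(v),
                   SpotDetectionParams(smoothSigma = 0, backgroundRadius = 5,
                                       thresholdMode = "absolute",
                                       thresholdValue = 10, minVoxels = 3L))
  expect_equal(nSpots(s), 0)
  # integrated = mean * voxels enforced by the class validity
  r <- calloseRender(seed = 22, nPuncta = 10)
  tab <- spotTable(detectSpots(r$stack))
  expect_equal(tab$integrated, tab$mean * tab$voxels, tolerance = 1e-9)
  expect_true(all(diff(tab$integrated) <= 1e-9))  # sorted descending
})

test_that("threshold monotonicity and intensity/translation equivariance", {
  r <- calloseRender(seed = 23, nPuncta = 12, size = 128)
  v <- voxels(r$stack)
  base <- SpotDetectionParams(thresholdMode = "absolute", thresholdValue = 5)
  nAt <- function(thr, img = r$stack)
    nSpots(detectSpots(img, SpotDetectionParams(thresholdMode = "absolute",
                                                thresholdValue = thr)))
  # thresholds above the background-residual floor: below it neighbouring
  # puncta bridge into merged components and counting is no longer monotone
  ns <- vapply(c(10, 20, 40, 80), nAt, integer(1))
  expect_true(all(diff(ns) <= 0))
  # scaling by c > 0 scales integrated intensity by c (otsu mode)
  s1 <- detectSpots(r$stack)
  s2 <- detectSpots(ImageStack(v * 3.7))
  expect_equal(nSpots(s1), nSpots(s2))
  expect_equal(spotTable(s2)$integrated, 3.7 * spotTable(s1)$integrated,
               tolerance = 1e-6)
  # whole-pixel translation shifts interior centroids by the same offset
  vT <- array(0, dim(v))
  vT[, 4:dim(v)[2], 6:dim(v)[3]] <-
    v[, 1:(dim(v)[2] - 3), 1:(dim(v)[3] - 5)]
  sT <- detectSpots(ImageStack(vT))
  t1 <- spotTable(s1); t2 <- spotTable(sT)
  interior <- t1$y < dim(v)[2] - 10 & t1$x < dim(v)[3] - 10 &
    t1$y > 8 & t1$x > 8
  for (i in which(interior)) {
    d <- sqrt((t2$y - t1$y[i] - 3)^2 + (t2$x - t1$x[i] - 5)^2)
    expect_lt(min(d), 0.5)
  }
})

test_that("spot fluorescence summaries follow the arithmetic contract", {
  empty <- summarizeSpotFluorescence(SpotSet())
  expect_equal(empty$nSpots, 0)
  expect_equal(empty$totalSpotFluorescence, 0)
  expect_true(is.nan(empty$meanSpotFluorescence))
  two <- SpotSet(data.frame(z = c(1, 1), y = c(5, 9), x = c(5, 9),
                            voxels = c(5L, 6L), integrated = c(10, 30),
                            mean = c(2, 5)))
  s <- summarizeSpotFluorescence(two)
  expect_equal(s$totalSpotFluorescence, 40)
  expect_equal(s$meanSpotFluorescence, 20)
})

test_that("brighter treated puncta raise the mean spot fluorescence", {
  # chitin-like renders carry 1.5x the punctum amplitude of mock
  diffs <- vapply(1:25, function(s) {
    mo <- makeCellMosaic(128, 128, 6, seed = s)
    mock <- renderMembraneStack(mo, nZ = 2, pdIndexTrue = 9, pmIntensity = 8,
                                readNoiseSd = 2, seed = 1000 + s, nPuncta = 12)
    chit <- renderMembraneStack(mo, nZ = 2, pdIndexTrue = 13, pmIntensity = 8,
                                readNoiseSd = 2, seed = 2000 + s, nPuncta = 12)
    a <- summarizeSpotFluorescence(detectSpots(mock$stack))
    b <- summarizeSpotFluorescence(detectSpots(chit$stack))
    b$meanSpotFluorescence - a$meanSpotFluorescence
  }, numeric(1))
  expect_gte(mean(diffs > 0), 0.95)
})

test_that("ROI construction respects geometry and the boundary mask", {
  bm <- matrix(FALSE, 64, 64); bm[32, ] <- TRUE; bm[33, ] <- TRUE
  spot <- data.frame(z = 1, y = 32, x = 32)
  rs <- deriveRois(spot, bm, pdRadius = 2, pmBand = c(4, 10),
                   exclusionRadius = 0)
  cls <- vapply(rois(rs), `[[`, character(1), "class")
  pd <- rois(rs)[[which(cls == "PD")]]
  expect_lte(length(pd$pixels), 13)   # discrete disk of radius 2
  pm <- rois(rs)[[which(cls == "PM")]]
  expect_true(all(bm[pm$pixels]))
  # degenerate band: every spot dropped -> empty ROI set
  expect_warning(rs0 <- deriveRois(spot, bm, pdRadius = 2, pmBand = c(0, 0)),
                 "dropped")
  expect_equal(length(rois(rs0)), 0)
  expect_error(deriveRois(SpotSet(), bm), "non-empty")
})

test_that("PM ROIs from synthetic mosaics lie on the boundary mask", {
  r <- calloseRender(seed = 24, nPuncta = 8, size = 128)
  rs <- deriveRois(spotTruth(r$truth), boundaryMask(r$truth))
  bm <- boundaryMask(r$truth)
  for (roi in rois(rs))
    if (roi$class == "PM") expect_true(all(bm[roi$pixels]))
})

test_that("PD index arithmetic and scale invariance", {
  v <- array(100, c(1, 32, 32))
  rs <- ROISet(list(list(label = "PD_1", class = "PD", pixels = 1:10),
                    list(label = "PM_1", class = "PM", pixels = 101:140)),
               c(32, 32))
  expect_equal(computePdIndex(ImageStack(v), rs)$pdIndex, 1)
  v2 <- v; v2[1, , ][1:10] <- 200
  expect_equal(computePdIndex(ImageStack(v2), rs)$pdIndex, 2)
  # scaling the image leaves the index unchanged
  expect_equal(computePdIndex(ImageStack(v2 * 13), rs)$pdIndex, 2)
  vz <- array(0, c(1, 32, 32))
  expect_error(computePdIndex(ImageStack(vz), rs), "zero")
})

test_that("PD index recovers the constructed truth on noiseless renders", {
  m <- makeCellMosaic(160, 160, 8, seed = 25)
  r <- renderMembraneStack(m, nZ = 1, pdIndexTrue = 2, pmIntensity = 50,
                           psfSigma = 0.8, readNoiseSd = 0, seed = 26,
                           nPuncta = 10, shotNoise = FALSE)
  rs <- deriveRois(spotTruth(r$truth), boundaryMask(r$truth))
  expect_equal(computePdIndex(r$stack, rs)$pdIndex, 2, tolerance = 0.05)
})
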