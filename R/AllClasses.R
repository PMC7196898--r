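#' @import methods
#' @importFrom stats approx mad median optim quantile rnbinom rnorm rpois
#'   runif sd t.test var wilcox.test TukeyHSD aov setNames fft plogis
#'   qlogis dgamma
#' @importFrom utils read.csv write.csv head str
NULL

# ---------------------------------------------------------------------------
# Imaging containers
# ---------------------------------------------------------------------------

#' ImageStack: a 3D fluorescence image with physical calibration
#'
#' Voxel intensities are stored as a numeric array indexed (z, y, x); all
#' physical sizes are carried as metadata so downstream code never guesses
#' the calibration.
#'
#' @slot voxels numeric array, dim = c(nz, ny, nx); finite, non-negative.
#' @slot pixelSizeXY in-plane pixel size, micrometres per pixel.
#' @slot zStep axial step between planes, micrometres.
#' @slot channelName free-text channel label (e.g. "aniline_blue").
#' @export
setClass("ImageStack",
  representation(
    voxels      = "array",
    pixelSizeXY = "numeric",
    zStep       = "numeric",
    channelName = "character"
  ),
  prototype(pixelSizeXY = 0.1, zStep = 0.5, channelName = "unknown")
)

setValidity("ImageStack", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L) return("voxels must be a 3D (z,y,x) array")
  if (any(dim(v) < 1L)) return("all dimensions must be >= 1")
  if (!all(is.finite(v))) return("intensities must be finite")
  if (any(v < 0)) return("intensities must be non-negative")
  if (object@pixelSizeXY <= 0 || object@zStep <= 0)
    return("pixel sizes must be positive")
  TRUE
})

#' Construct an ImageStack
#'
#' @param voxels 3D numeric array (z, y, x).
#' @param pixelSizeXY µm per pixel in-plane.
#' @param zStep µm between z planes.
#' @param channelName channel label.
#' @return An \linkS4class{ImageStack}.
#' @export
ImageStack <- function(voxels, pixelSizeXY = 0.1, zStep = 0.5,
                       channelName = "unknown") {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, dim(voxels)))
  new("ImageStack", voxels = voxels, pixelSizeXY = pixelSizeXY,
      zStep = zStep, channelName = channelName)
}

#' SpotSet: detected puncta and per-image summary statistics
#'
#' @slot spots data.frame with one row per punctum: z, y, x (centroid, px,
#'   1-based), voxels, integrated, mean. Sorted by integrated intensity
#'   descending, ties broken (z, y, x) lexicographically.
#' @slot nSpots integer count.
#' @slot totalFluorescence sum of per-spot integrated intensities.
#' @slot meanFluorescence mean per-spot integrated intensity (NaN if empty).
#' @export
setClass("SpotSet",
  representation(
    spots             = "data.frame",
    nSpots            = "integer",
    totalFluorescence = "numeric",
    meanFluorescence  = "numeric"
  )
)

setValidity("SpotSet", function(object) {
  s <- object@spots
  need <- c("z", "y", "x", "voxels", "integrated", "mean")
  if (!all(need %in% names(s))) return("spots must have z,y,x,voxels,integrated,mean")
  if (nrow(s) != object@nSpots) return("nSpots must match nrow(spots)")
  if (nrow(s) > 0) {
    rel <- abs(s$integrated - s$mean * s$voxels) /
      pmax(abs(s$integrated), .Machine$double.eps)
    if (any(rel > 1e-6)) return("integrated must equal mean * voxels")
  }
  TRUE
})

emptySpotTable <- function() {
  data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
             voxels = integer(0), integrated = numeric(0), mean = numeric(0))
}

#' Construct a SpotSet from a per-spot table
#'
#' @param spots data.frame with columns z, y, x, voxels, integrated, mean.
#' @return A \linkS4class{SpotSet}; summary slots are computed here.
#' @export
SpotSet <- function(spots = emptySpotTable()) {
  n <- nrow(spots)
  if (n > 0) {
    ord <- order(-spots$integrated, spots$z, spots$y, spots$x)
    spots <- spots[ord, , drop = FALSE]
    rownames(spots) <- NULL
  }
  new("SpotSet", spots = spots, nSpots = as.integer(n),
      totalFluorescence = if (n) sum(spots$integrated) else 0,
      meanFluorescence  = if (n) mean(spots$integrated) else NaN)
}

#' ROISet: labelled pixel regions of a single image plane
#'
#' Each ROI is a set of linear pixel indices into a (ny, nx) plane together
#' with a class drawn from the fixed vocabulary PD / PM / background /
#' reference.
#'
#' @slot rois list; each element has fields label, class, pixels (integer
#'   linear indices, 1-based, column-major into the plane).
#' @slot dimPlane integer c(ny, nx) of the plane the indices refer to.
#' @export
setClass("ROISet",
  representation(rois = "list", dimPlane = "integer")
)

setValidity("ROISet", function(object) {
  ok <- c("PD", "PM", "background", "reference")
  for (r in object@rois) {
    if (!all(c("label", "class", "pixels") %in% names(r)))
      return("each ROI needs label, class, pixels")
    if (!r$class %in% ok) return(paste("unknown ROI class:", r$class))
    if (length(r$pixels) == 0) return("ROIs must be non-empty")
    if (any(r$pixels < 1 | r$pixels > prod(object@dimPlane)))
      return("ROI pixels out of plane bounds")
  }
  TRUE
})

#' Construct an ROISet
#' @param rois list of ROIs (label, class, pixels).
#' @param dimPlane c(ny, nx) of the host plane.
#' @return An \linkS4class{ROISet}.
#' @export
ROISet <- function(rois, dimPlane) {
  new("ROISet", rois = rois, dimPlane = as.integer(dimPlane))
}

# ---------------------------------------------------------------------------
# Photophysics containers
# ---------------------------------------------------------------------------

#' PolarizedPair: parallel / perpendicular intensity images or scalars
#'
#' @slot iPar parallel-channel intensity (scalar or matrix), >= 0.
#' @slot iPerp perpendicular-channel intensity, congruent with iPar.
#' @slot nFramesMerged number of frames summed into this pair.
#' @export
setClass("PolarizedPair",
  representation(iPar = "ANY", iPerp = "ANY", nFramesMerged = "integer"),
  prototype(nFramesMerged = 1L)
)

setValidity("PolarizedPair", function(object) {
  if (!identical(dim(object@iPar), dim(object@iPerp)) ||
      length(object@iPar) != length(object@iPerp))
    return("iPar and iPerp must have identical shape")
  if (any(object@iPar < 0) || any(object@iPerp < 0))
    return("intensities must be non-negative")
  if (all(object@iPar == 0) && all(object@iPerp == 0))
    return("iPar and iPerp must not both be identically zero")
  TRUE
})

#' Construct a PolarizedPair
#' @param iPar parallel intensity (scalar or matrix).
#' @param iPerp perpendicular intensity, same shape.
#' @param nFramesMerged frames summed (default 1).
#' @return A \linkS4class{PolarizedPair}.
#' @export
PolarizedPair <- function(iPar, iPerp, nFramesMerged = 1L) {
  new("PolarizedPair", iPar = iPar, iPerp = iPerp,
      nFramesMerged = as.integer(nFramesMerged))
}

#' CalibrationConstants for polarization detection
#'
#' G corrects the relative sensitivity of the two detection channels; L1 and
#' L2 are the high-numerical-aperture depolarization factors of the
#' objective.
#'
#' @slot G dimensionless, > 0.
#' @slot L1 dimensionless, in [0, 1/3).
#' @slot L2 dimensionless, in [0, 1/3).
#' @export
setClass("CalibrationConstants",
  representation(G = "numeric", L1 = "numeric", L2 = "numeric")
)

setValidity("CalibrationConstants", function(object) {
  if (object@G <= 0) return("G must be > 0")
  if (object@L1 < 0 || object@L1 >= 1 / 3) return("L1 must be in [0, 1/3)")
  if (object@L2 < 0 || object@L2 >= 1 / 3) return("L2 must be in [0, 1/3)")
  TRUE
})

#' Construct CalibrationConstants
#'
#' Defaults are the instrument calibration used throughout this package's
#' worked examples (G = 0.481, L1 = 0.013, L2 = 0.037).
#'
#' @param G detection-channel sensitivity ratio.
#' @param L1,L2 high-NA depolarization factors.
#' @return A \linkS4class{CalibrationConstants}.
#' @export
CalibrationConstants <- function(G = 0.481, L1 = 0.013, L2 = 0.037) {
  new("CalibrationConstants", G = G, L1 = L1, L2 = L2)
}

#' DecayHistogram: TCSPC photon counts per arrival-time bin
#'
#' @slot binCenters ns, ascending, equally spaced.
#' @slot counts non-negative integer photon counts per bin.
#' @slot repetitionPeriod laser repetition period, ns (25 ns = 40 MHz).
#' @export
setClass("DecayHistogram",
  representation(
    binCenters       = "numeric",
    counts           = "numeric",
    repetitionPeriod = "numeric"
  )
)

setValidity("DecayHistogram", function(object) {
  t <- object@binCenters
  if (length(t) < 2) return("need at least 2 bins")
  d <- diff(t)
  if (any(d <= 0)) return("binCenters must be ascending")
  if (max(d) - min(d) > 1e-9 * mean(d)) return("bins must be equally spaced")
  if (length(object@counts) != length(t))
    return("counts and binCenters must be congruent")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (any(abs(object@counts - round(object@counts)) > 1e-9))
    return("counts must be integers")
  span <- t[length(t)] - t[1] + mean(d)
  if (span > object@repetitionPeriod * (1 + 1e-9))
    return("bin span must not exceed the repetition period")
  TRUE
})

#' Construct a DecayHistogram
#' @param binCenters bin centres, ns.
#' @param counts photon counts.
#' @param repetitionPeriod ns (default 25, i.e. 40 MHz excitation).
#' @return A \linkS4class{DecayHistogram}.
#' @export
DecayHistogram <- function(binCenters, counts, repetitionPeriod = 25) {
  new("DecayHistogram", binCenters = binCenters, counts = counts,
      repetitionPeriod = repetitionPeriod)
}

#' IRFModel: instrument response function
#'
#' @slot kind "gaussian" or "measured".
#' @slot center ns (gaussian kind).
#' @slot sigma ns >= 0 (gaussian kind).
#' @slot histogram measured IRF values per bin, unit area (measured kind).
#' @export
setClass("IRFModel",
  representation(kind = "character", center = "numeric", sigma = "numeric",
                 histogram = "numeric"),
  prototype(kind = "gaussian", center = 0, sigma = 0, histogram = numeric(0))
)

setValidity("IRFModel", function(object) {
  if (!object@kind %in% c("gaussian", "measured"))
    return("kind must be gaussian or measured")
  if (object@kind == "gaussian" && object@sigma < 0)
    return("sigma must be >= 0")
  if (object@kind == "measured") {
    if (length(object@histogram) < 2) return("measured IRF needs >= 2 bins")
    if (abs(sum(object@histogram) - 1) > 1e-6)
      return("measured IRF must be normalized to unit area")
  }
  TRUE
})

#' Construct an IRFModel
#' @param kind "gaussian" (default) or "measured".
#' @param center Gaussian centre, ns.
#' @param sigma Gaussian width, ns.
#' @param histogram measured IRF per bin (normalized internally).
#' @return An \linkS4class{IRFModel}.
#' @export
IRFModel <- function(kind = "gaussian", center = 0, sigma = 0,
                     histogram = numeric(0)) {
  if (kind == "measured" && length(histogram) && sum(histogram) > 0)
    histogram <- histogram / sum(histogram)
  new("IRFModel", kind = kind, center = center, sigma = sigma,
      histogram = histogram)
}

#' LifetimeFit: fitted multi-exponential TCSPC model
#'
#' @slot amplitudes fractional amplitudes, >= 0, summing to 1.
#' @slot lifetimes ns, > 0, one per component.
#' @slot background fitted uniform background, counts per bin, >= 0.
#' @slot tauAv amplitude-weighted average lifetime, ns.
#' @slot fitDeviance Poisson deviance of the converged fit.
#' @slot nComponents 1 or 2.
#' @export
setClass("LifetimeFit",
  representation(
    amplitudes  = "numeric",
    lifetimes   = "numeric",
    background  = "numeric",
    tauAv       = "numeric",
    fitDeviance = "numeric",
    nComponents = "integer"
  )
)

setValidity("LifetimeFit", function(object) {
  a <- object@amplitudes; t <- object@lifetimes
  if (length(a) != length(t)) return("amplitudes/lifetimes length mismatch")
  if (any(a < 0)) return("amplitudes must be >= 0")
  if (any(t <= 0)) return("lifetimes must be > 0")
  if (object@background < 0) return("background must be >= 0")
  tav <- sum(a * t) / sum(a)
  if (abs(tav - object@tauAv) > 1e-6 * max(1, tav))
    return("tauAv must equal sum(a*t)/sum(a)")
  if (object@tauAv < min(t) - 1e-9 || object@tauAv > max(t) + 1e-9)
    return("tauAv must lie within [min(tau), max(tau)]")
  TRUE
})

# ---------------------------------------------------------------------------
# Kinetics containers
# ---------------------------------------------------------------------------

#' FrapTrace: bleach / background / reference ROI time series
#'
#' @slot time seconds, strictly increasing.
#' @slot bleachRoi intensity of the bleached ROI.
#' @slot backgroundRoi intensity of a background ROI.
#' @slot referenceRoi intensity of an unbleached reference ROI.
#' @slot bleachFrameIndex 1-based index of the first post-bleach frame.
#' @export
setClass("FrapTrace",
  representation(
    time             = "numeric",
    bleachRoi        = "numeric",
    backgroundRoi    = "numeric",
    referenceRoi     = "numeric",
    bleachFrameIndex = "integer"
  )
)

setValidity("FrapTrace", function(object) {
  n <- length(object@time)
  if (any(diff(object@time) <= 0)) return("time must be strictly increasing")
  if (length(object@bleachRoi) != n || length(object@backgroundRoi) != n ||
      length(object@referenceRoi) != n)
    return("all channels must match time length")
  b <- object@bleachFrameIndex
  if (b < 3L || b > n) return("bleachFrameIndex out of range (need >= 2 prebleach frames)")
  TRUE
})

#' Construct a FrapTrace
#' @param time seconds.
#' @param bleachRoi,backgroundRoi,referenceRoi channel intensities.
#' @param bleachFrameIndex 1-based index of the first post-bleach frame.
#' @return A \linkS4class{FrapTrace}.
#' @export
FrapTrace <- function(time, bleachRoi, backgroundRoi, referenceRoi,
                      bleachFrameIndex) {
  new("FrapTrace", time = time, bleachRoi = bleachRoi,
      backgroundRoi = backgroundRoi, referenceRoi = referenceRoi,
      bleachFrameIndex = as.integer(bleachFrameIndex))
}

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageStack '%s': %d z x %d y x %d x px (%.3g um/px, dz %.3g um)\n",
              object@channelName, d[1], d[2], d[3],
              object@pixelSizeXY, object@zStep))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "SpotSet", function(object) {
  cat(sprintf("SpotSet: %d spots, total fluorescence %.4g, mean %.4g\n",
              object@nSpots, object@totalFluorescence,
              object@meanFluorescence))
})

setMethod("show", "ROISet", function(object) {
  cls <- vapply(object@rois, `[[`, character(1), "class")
  cat(sprintf("ROISet on %d x %d plane: %d ROIs (%s)\n",
              object@dimPlane[1], object@dimPlane[2], length(object@rois),
              paste(sprintf("%s=%d", names(table(cls)), table(cls)),
                    collapse = ", ")))
})

setMethod("show", "DecayHistogram", function(object) {
  cat(sprintf("DecayHistogram: %d bins over %.3g ns, %d photons (rep period %.3g ns)\n",
              length(object@counts),
              diff(range(object@binCenters)),
              as.integer(sum(object@counts)), object@repetitionPeriod))
})

setMethod("show", "LifetimeFit", function(object) {
  cat(sprintf("LifetimeFit (%d component%s): tau = %s ns, alpha = %s\n",
              object@nComponents, if (object@nComponents > 1) "s" else "",
              paste(sprintf("%.3f", object@lifetimes), collapse = ", "),
              paste(sprintf("%.3f", object@amplitudes), collapse = ", ")))
  cat(sprintf("  tau_Av = %.4f ns, background = %.3g counts/bin, deviance = %.4g\n",
              object@tauAv, object@background, object@fitDeviance))
})

setMethod("show", "FrapTrace", function(object) {
  cat(sprintf("FrapTrace: %d frames, bleach at frame %d (t = %.3g s)\n",
              length(object@time), object@bleachFrameIndex,
              object@time[object@bleachFrameIndex]))
})

setMethod("show", "PolarizedPair", function(object) {
  cat(sprintf("PolarizedPair (%s, %d frame%s merged): sum I_par %.4g, sum I_perp %.4g\n",
              if (is.null(dim(object@iPar))) "scalar" else
                paste(dim(object@iPar), collapse = " x "),
              object@nFramesMerged,
              if (object@nFramesMerged > 1) "s" else "",
              sum(object@iPar), sum(object@iPerp)))
})

setMethod("show", "CalibrationConstants", function(object) {
  cat(sprintf("CalibrationConstants: G = %.4g, L1 = %.4g, L2 = %.4g\n",
              object@G, object@L1, object@L2))
})
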