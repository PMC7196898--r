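# Punctum detection and PD-index quantification.
#
# Detection pipeline: Gaussian smooth -> grayscale top-hat background
# suppression -> threshold -> 3D connected components -> size filter; all
# per-spot statistics are computed on the ORIGINAL (unsmoothed) intensities.

# --- small image-morphology kernel (no R image-processing package ships in
#     this environment, so erosion/dilation/Otsu are implemented here) -----

shiftApply <- function(img, radius, fun) {
  ny <- nrow(img); nx <- ncol(img)
  out <- img
  r <- as.integer(ceiling(radius))
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0 && dx == 0) next
    if (dy * dy + dx * dx > radius * radius) next
    y1 <- max(1, 1 + dy); y2 <- min(ny, ny + dy)
    x1 <- max(1, 1 + dx); x2 <- min(nx, nx + dx)
    if (y1 > y2 || x1 > x2) next
    out[y1:y2, x1:x2] <- fun(out[y1:y2, x1:x2],
                             img[(y1 - dy):(y2 - dy), (x1 - dx):(x2 - dx)])
  }
  out
}

erodeGray  <- function(img, radius) shiftApply(img, radius, pmin)
dilateGray <- function(img, radius) shiftApply(img, radius, pmax)

# top-hat: image minus its grayscale opening (removes structures larger than
# the disk, keeps compact bright detail)
topHat <- function(img, radius) {
  if (radius <= 0) return(img)
  img - dilateGray(erodeGray(img, radius), radius)
}

# Otsu's threshold on a 256-bin histogram
otsuThreshold <- function(x, nbins = 256L) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(hi)
  h <- as.numeric(tabulate(pmin(as.integer((x - lo) / (hi - lo) * nbins) + 1L,
                                nbins), nbins))
  w <- cumsum(h)
  centers <- lo + (seq_len(nbins) - 0.5) * (hi - lo) / nbins
  m <- cumsum(h * centers)
  n <- w[nbins]; mt <- m[nbins]
  w0 <- w[-nbins]; w1 <- n - w0
  mu0 <- m[-nbins] / w0
  mu1 <- (mt - m[-nbins]) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  k <- which.max(bcv)
  lo + k * (hi - lo) / nbins
}

#' Spot-detection parameters
#'
#' Defaults are tuned for diffraction-limited callose puncta: light
#' smoothing, top-hat radius larger than a punctum, Otsu threshold on the
#' background-suppressed image (floored at median + 5 MAD so a spotless
#' noise image yields no detections), size gate 3-200 voxels, 26-connectivity.
#'
#' @param smoothSigma Gaussian pre-smoothing sigma, px (>= 0).
#' @param backgroundRadius top-hat disk radius, px.
#' @param thresholdMode "otsu", "absolute" or "percentile".
#' @param thresholdValue threshold (absolute mode, a.u.) or percentile in
#'   [0, 100] (percentile mode); ignored for "otsu".
#' @param minVoxels,maxVoxels inclusive component-size gate (min < max).
#' @param connectivity 6, 18 or 26.
#' @return A validated parameter list of class "SpotDetectionParams".
#' @export
SpotDetectionParams <- function(smoothSigma = 1, backgroundRadius = 5,
                                thresholdMode = c("otsu", "absolute",
                                                  "percentile"),
                                thresholdValue = NA_real_,
                                minVoxels = 3L, maxVoxels = 200L,
                                connectivity = 26L) {
  thresholdMode <- match.arg(thresholdMode)
  if (smoothSigma < 0) stop("smoothSigma must be >= 0")
  if (minVoxels >= maxVoxels) stop("minVoxels must be < maxVoxels")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  if (thresholdMode %in% c("absolute", "percentile") && !is.finite(thresholdValue))
    stop("thresholdValue required for absolute/percentile modes")
  if (thresholdMode == "percentile" &&
      (thresholdValue < 0 || thresholdValue > 100))
    stop("percentile thresholdValue must be in [0, 100]")
  structure(list(smoothSigma = smoothSigma,
                 backgroundRadius = backgroundRadius,
                 thresholdMode = thresholdMode,
                 thresholdValue = thresholdValue,
                 minVoxels = as.integer(minVoxels),
                 maxVoxels = as.integer(maxVoxels),
                 connectivity = as.integer(connectivity)),
            class = "SpotDetectionParams")
}

connOffsets <- function(connectivity) {
  off <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  off <- off[!(off$dz == 0 & off$dy == 0 & off$dx == 0), ]
  deg <- abs(off$dz) + abs(off$dy) + abs(off$dx)
  off <- switch(as.character(connectivity),
    "6"  = off[deg == 1, ],
    "18" = off[deg <= 2, ],
    "26" = off)
  # half-space: each undirected neighbour pair counted once
  keep <- off$dz > 0 | (off$dz == 0 & off$dy > 0) |
          (off$dz == 0 & off$dy == 0 & off$dx > 0)
  off[keep, , drop = FALSE]
}

# label 3D connected components of a logical (z,y,x) array; returns integer
# membership per foreground voxel plus their linear indices
connComp3d <- function(fg, connectivity) {
  idx <- which(fg)
  if (length(idx) == 0)
    return(list(idx = integer(0), membership = integer(0)))
  d <- dim(fg)
  co <- arrayInd(idx, d)
  rank <- array(0L, d)
  rank[idx] <- seq_along(idx)
  off <- connOffsets(connectivity)
  edges <- vector("list", nrow(off))
  for (i in seq_len(nrow(off))) {
    z <- co[, 1] + off$dz[i]; y <- co[, 2] + off$dy[i]; x <- co[, 3] + off$dx[i]
    ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
    if (!any(ok)) next
    nidx <- z[ok] + (y[ok] - 1L) * d[1] + (x[ok] - 1L) * d[1] * d[2]
    nr <- rank[nidx]
    hit <- nr > 0L
    if (any(hit))
      edges[[i]] <- cbind(rank[idx[ok]][hit], nr[hit])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  list(idx = idx, membership = igraph::components(g)$membership)
}

#' Detect plasmodesmata-associated puncta in a z-stack
#'
#' Runs the detection pipeline described above and reports per-spot
#' centroids (z, y, x; 1-based px), voxel counts and intensities measured on
#' the original image. Spots are sorted by integrated intensity descending
#' (ties broken lexicographically by centroid).
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param params a \code{\link{SpotDetectionParams}} list.
#' @return A \linkS4class{SpotSet}. An all-zero image yields an empty set;
#'   a saturated-everywhere image yields an empty set with a warning.
#' @examples
#' m <- makeCellMosaic(96, 96, 6, seed = 1)
#' r <- renderMembraneStack(m, nZ = 3, pdIndexTrue = 10, pmIntensity = 5,
#'                          readNoiseSd = 1, seed = 2)
#' detectSpots(r$stack, SpotDetectionParams())
#' @export
detectSpots <- function(stack, params = SpotDetectionParams()) {
  stopifnot(inherits(params, "SpotDetectionParams"))
  v <- voxels(stack)
  if (all(v == 0)) return(SpotSet())
  if (length(unique(as.vector(v))) == 1L) {
    warning("image is saturated/constant everywhere; no spots detectable")
    return(SpotSet())
  }
  d <- dim(v)
  th <- array(0, d)
  for (z in seq_len(d[1])) {
    pl <- v[z, , , drop = TRUE]
    if (d[2] == 1 || d[3] == 1) pl <- matrix(pl, d[2], d[3])
    if (params$smoothSigma > 0) pl <- gaussBlur2d(pl, params$smoothSigma)
    th[z, , ] <- topHat(pl, params$backgroundRadius)
  }
  thr <- switch(params$thresholdMode,
    otsu = {
      # floor at median + 5 MAD: plain Otsu always splits a pure-noise
      # image, flooding the detector with false components
      max(otsuThreshold(as.vector(th)),
          median(th) + 5 * mad(th))
    },
    absolute = params$thresholdValue,
    percentile = as.numeric(quantile(th, params$thresholdValue / 100,
                                     names = FALSE)))
  cc <- connComp3d(th > thr, params$connectivity)
  if (length(cc$idx) == 0) return(SpotSet())
  size <- tabulate(cc$membership)
  keep <- which(size >= params$minVoxels & size <= params$maxVoxels)
  if (length(keep) == 0) return(SpotSet())
  sel <- cc$membership %in% keep
  memb <- match(cc$membership[sel], keep)
  idx <- cc$idx[sel]
  co <- arrayInd(idx, d)
  inten <- v[idx]
  nvox <- tabulate(memb, length(keep))
  integ <- as.vector(rowsum(inten, memb))
  cz <- as.vector(rowsum(co[, 1], memb)) / nvox
  cy <- as.vector(rowsum(co[, 2], memb)) / nvox
  cx <- as.vector(rowsum(co[, 3], memb)) / nvox
  SpotSet(data.frame(z = cz, y = cy, x = cx, voxels = nvox,
                     integrated = integ, mean = integ / nvox))
}

#' Per-image summary of spot fluorescence
#'
#' @param spots a \linkS4class{SpotSet}.
#' @return list with \code{nSpots}, \code{totalSpotFluorescence} and
#'   \code{meanSpotFluorescence} (NaN when the set is empty).
#' @export
summarizeSpotFluorescence <- function(spots) {
  stopifnot(is(spots, "SpotSet"))
  list(nSpots = nSpots(spots),
       totalSpotFluorescence = spots@totalFluorescence,
       meanSpotFluorescence = spots@meanFluorescence)
}

#' Construct PD and neighbouring-PM ROIs around detected spots
#'
#' PD ROIs are discrete disks of radius \code{pdRadius} at the rounded spot
#' centroids, clipped to the image. Each spot's PM ROI is the set of
#' boundary-mask pixels whose distance d from the centroid satisfies
#' \code{pmBand[1] < d <= pmBand[2]}, excluding every PD ROI pixel and any
#' pixel within \code{exclusionRadius} of any spot centroid (so the PM
#' sample never contains another punctum's PSF skirt). Spots whose PM ROI
#' is empty after exclusion are dropped with a warning.
#'
#' @param spots a \linkS4class{SpotSet} (non-empty), or any data.frame with
#'   y/x columns (e.g. a generator's \code{spotTruth} for annotated ROIs).
#' @param boundaryMask logical (y, x) matrix of cell-cell interfaces.
#' @param pdRadius PD disk radius, px.
#' @param pmBand numeric c(inner, outer) annulus radii, px.
#' @param exclusionRadius radius around every spot centroid masked out of
#'   PM ROIs (px; should exceed the punctum radius plus ~3 PSF sigma).
#' @return An \linkS4class{ROISet} with paired PD_i / PM_i ROIs.
#' @export
deriveRois <- function(spots, boundaryMask, pdRadius = 2, pmBand = c(7, 14),
                       exclusionRadius = 7) {
  tab <- if (is(spots, "SpotSet")) spotTable(spots) else as.data.frame(spots)
  if (nrow(tab) == 0) stop("spots must be non-empty")
  ny <- nrow(boundaryMask); nx <- ncol(boundaryMask)
  roiList <- list()
  dropped <- 0L
  pdUnion <- rep(FALSE, ny * nx)
  pdPixList <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    y0 <- round(tab$y[i]); x0 <- round(tab$x[i])
    ys <- max(1, y0 - pdRadius):min(ny, y0 + pdRadius)
    xs <- max(1, x0 - pdRadius):min(nx, x0 + pdRadius)
    gy <- rep(ys, times = length(xs)); gx <- rep(xs, each = length(ys))
    pd <- (gy - y0)^2 + (gx - x0)^2 <= pdRadius^2
    pix <- gy[pd] + (gx[pd] - 1L) * ny
    pdPixList[[i]] <- pix
    pdUnion[pix] <- TRUE
  }
  for (i in seq_len(nrow(tab))) {
    y0 <- round(tab$y[i]); x0 <- round(tab$x[i])
    r <- ceiling(pmBand[2])
    ys <- max(1, y0 - r):min(ny, y0 + r)
    xs <- max(1, x0 - r):min(nx, x0 + r)
    gy <- rep(ys, times = length(xs)); gx <- rep(xs, each = length(ys))
    d2 <- (gy - y0)^2 + (gx - x0)^2
    inBand <- d2 > pmBand[1]^2 & d2 <= pmBand[2]^2
    pix <- gy[inBand] + (gx[inBand] - 1L) * ny
    pix <- pix[boundaryMask[pix] & !pdUnion[pix]]
    if (length(pix) && exclusionRadius > 0) {
      py <- (pix - 1L) %% ny + 1L
      px <- (pix - 1L) %/% ny + 1L
      minD2 <- rep(Inf, length(pix))
      for (k in seq_len(nrow(tab))) {
        d2k <- (py - round(tab$y[k]))^2 + (px - round(tab$x[k]))^2
        minD2 <- pmin(minD2, d2k)
      }
      pix <- pix[minD2 > exclusionRadius^2]
    }
    if (length(pix) == 0) {
      warning(sprintf("spot %d dropped: PM ROI empty after PD exclusion", i))
      dropped <- dropped + 1L
      next
    }
    roiList[[length(roiList) + 1L]] <-
      list(label = sprintf("PD_%d", i), class = "PD", pixels = pdPixList[[i]])
    roiList[[length(roiList) + 1L]] <-
      list(label = sprintf("PM_%d", i), class = "PM", pixels = pix)
  }
  ROISet(roiList, c(ny, nx))
}

#' Compute the plasmodesmal index of a single plane
#'
#' The PD index is the mean intensity over all PD-class ROI pixels divided
#' by the mean over all PM-class pixels; > 1 indicates plasmodesmal
#' enrichment of the tagged protein.
#'
#' @param stack an \linkS4class{ImageStack} (the analysis plane is selected
#'   by \code{plane}, matching single-plane confocal acquisitions).
#' @param roiSet an \linkS4class{ROISet} with at least one PD and one PM ROI.
#' @param plane z index of the plane to measure (default 1).
#' @return list with \code{pdMean}, \code{pmMean}, \code{pdIndex}.
#' @export
computePdIndex <- function(stack, roiSet, plane = 1L) {
  v <- voxels(stack)
  pl <- matrix(v[plane, , ], dim(v)[2], dim(v)[3])
  if (!identical(dim(pl), as.integer(roiSet@dimPlane)) &&
      !all(dim(pl) == roiSet@dimPlane))
    stop("ROI plane dimensions do not match the image")
  cls <- vapply(rois(roiSet), `[[`, character(1), "class")
  pdPix <- unique(unlist(lapply(rois(roiSet)[cls == "PD"], `[[`, "pixels")))
  pmPix <- unique(unlist(lapply(rois(roiSet)[cls == "PM"], `[[`, "pixels")))
  if (length(pdPix) == 0 || length(pmPix) == 0)
    stop("need at least one PD and one PM ROI")
  pdMean <- mean(pl[pdPix])
  pmMean <- mean(pl[pmPix])
  if (pmMean == 0) stop("undefined PD index: PM mean intensity is zero")
  list(pdMean = pdMean, pmMean = pmMean, pdIndex = pdMean / pmMean)
}
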