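# Synthetic epidermal-mosaic renderer: the ground-truth world against which
# spot detection and PD-index recovery are validated.

#' MosaicGroundTruth: a synthetic epidermal cell mosaic with known truth
#'
#' @slot labelImage integer matrix (y, x); contiguous positive cell labels.
#' @slot boundaryMask logical matrix; TRUE at pixels adjacent to >= 2 labels.
#' @slot spotTruth data.frame (z, y, x, amplitude): ground-truth puncta;
#'   amplitude is the punctum peak added above the membrane plateau.
#' @slot pdIndexTrue constructed punctum-peak : membrane-plateau ratio.
#' @slot pmIntensity membrane plateau, photons per pixel.
#' @slot meta list of bookkeeping (signal masses, render parameters).
#' @export
setClass("MosaicGroundTruth",
  representation(
    labelImage   = "matrix",
    boundaryMask = "matrix",
    spotTruth    = "data.frame",
    pdIndexTrue  = "numeric",
    pmIntensity  = "numeric",
    meta         = "list"
  ),
  prototype(pdIndexTrue = NA_real_, pmIntensity = NA_real_, meta = list())
)

setValidity("MosaicGroundTruth", function(object) {
  lab <- object@labelImage
  if (!identical(dim(lab), dim(object@boundaryMask)))
    return("labelImage and boundaryMask must be congruent")
  u <- sort(unique(as.integer(lab)))
  if (!identical(u, seq_along(u)))
    return("labels must be contiguous positive integers 1..n")
  st <- object@spotTruth
  if (nrow(st) > 0) {
    if (!all(c("z", "y", "x", "amplitude") %in% names(st)))
      return("spotTruth needs z, y, x, amplitude")
    # every truth punctum on the boundary mask dilated by <= 1 px
    bm <- dilateMask(object@boundaryMask, 1L)
    on <- bm[cbind(round(st$y), round(st$x))]
    if (!all(on)) return("truth puncta must lie on the (dilated) boundary mask")
  }
  TRUE
})

setMethod("show", "MosaicGroundTruth", function(object) {
  cat(sprintf("MosaicGroundTruth: %d x %d px, %d cells, %d boundary px, %d truth puncta\n",
              nrow(object@labelImage), ncol(object@labelImage),
              max(object@labelImage), sum(object@boundaryMask),
              nrow(object@spotTruth)))
})

#' @rdname MosaicGroundTruth-class
#' @param x an object.
#' @export
setGeneric("labelImage", function(x) standardGeneric("labelImage"))
#' @rdname MosaicGroundTruth-class
#' @export
setMethod("labelImage", "MosaicGroundTruth", function(x) x@labelImage)

#' @rdname MosaicGroundTruth-class
#' @export
setGeneric("boundaryMask", function(x) standardGeneric("boundaryMask"))
#' @rdname MosaicGroundTruth-class
#' @export
setMethod("boundaryMask", "MosaicGroundTruth", function(x) x@boundaryMask)

#' @rdname MosaicGroundTruth-class
#' @export
setGeneric("spotTruth", function(x) standardGeneric("spotTruth"))
#' @rdname MosaicGroundTruth-class
#' @export
setMethod("spotTruth", "MosaicGroundTruth", function(x) x@spotTruth)

#' @rdname MosaicGroundTruth-class
#' @export
setGeneric("pdIndexTrue", function(x) standardGeneric("pdIndexTrue"))
#' @rdname MosaicGroundTruth-class
#' @export
setMethod("pdIndexTrue", "MosaicGroundTruth", function(x) x@pdIndexTrue)

#' @rdname MosaicGroundTruth-class
#' @export
setGeneric("mosaicMeta", function(x) standardGeneric("mosaicMeta"))
#' @rdname MosaicGroundTruth-class
#' @export
setMethod("mosaicMeta", "MosaicGroundTruth", function(x) x@meta)

# binary dilation of a logical matrix by a Euclidean disk of given radius
dilateMask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  ny <- nrow(mask); nx <- ncol(mask)
  out <- mask
  r <- as.integer(ceiling(radius))
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0 && dx == 0) next
    if (dy * dy + dx * dx > radius * radius) next
    ys <- pmin(pmax(seq_len(ny) - dy, 1L), ny)
    xs <- pmin(pmax(seq_len(nx) - dx, 1L), nx)
    # shifted copy with replicate border; border pixels never gain spurious TRUE
    sy <- seq_len(ny) - dy; sx <- seq_len(nx) - dx
    oky <- sy >= 1 & sy <= ny; okx <- sx >= 1 & sx <= nx
    if (!any(oky) || !any(okx)) next
    out[oky, okx] <- out[oky, okx] | mask[sy[oky], sx[okx], drop = FALSE]
  }
  out
}

#' Generate a space-filling epidermal cell mosaic
#'
#' Cells are a seeded Voronoi tessellation: \code{nCells} generator points
#' are placed uniformly at random and every pixel takes the label of its
#' nearest generator (ties resolved to the lowest label, so the result is
#' deterministic for a fixed seed). The boundary mask marks pixels with at
#' least one 4-neighbour carrying a different label, i.e. the cell-cell
#' interfaces where plasmodesmata live.
#'
#' @param width,height image size in pixels (>= 32).
#' @param nCells number of cells (>= 1).
#' @param seed RNG seed (mandatory; no hidden global state).
#' @return A \linkS4class{MosaicGroundTruth} with labels and boundary only.
#' @examples
#' m <- makeCellMosaic(64, 64, 4, seed = 1)
#' table(labelImage(m))
#' @export
makeCellMosaic <- function(width, height, nCells, seed) {
  if (width < 32 || height < 32) stop("width and height must be >= 32")
  if (nCells < 1) stop("nCells must be >= 1")
  rng <- localRNG(seed)
  cx <- rng(runif(nCells, 0.5, width + 0.5))
  cy <- rng(runif(nCells, 0.5, height + 0.5))
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), width), height, width)
  lab <- matrix(1L, height, width)
  if (nCells > 1) {
    best <- (ys - cy[1])^2 + (xs - cx[1])^2
    for (k in 2:nCells) {
      d <- (ys - cy[k])^2 + (xs - cx[k])^2
      upd <- d < best          # strict: ties keep the lower label
      lab[upd] <- k
      best[upd] <- d[upd]
    }
  }
  # relabel to contiguous 1..n in case a generator claimed no pixel
  u <- sort(unique(as.integer(lab)))
  lab <- matrix(match(as.integer(lab), u), height, width)
  bnd <- boundaryFromLabels(lab)
  new("MosaicGroundTruth", labelImage = lab, boundaryMask = bnd,
      spotTruth = data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                             amplitude = numeric(0)),
      meta = list(seed = seed))
}

boundaryFromLabels <- function(lab) {
  ny <- nrow(lab); nx <- ncol(lab)
  bnd <- matrix(FALSE, ny, nx)
  if (ny > 1) {
    d <- lab[-1, , drop = FALSE] != lab[-ny, , drop = FALSE]
    bnd[-ny, ][d] <- TRUE
    bnd[-1, ][d] <- TRUE
  }
  if (nx > 1) {
    d <- lab[, -1, drop = FALSE] != lab[, -nx, drop = FALSE]
    bnd[, -nx][d] <- TRUE
    bnd[, -1][d] <- TRUE
  }
  bnd
}

# run expr with an isolated RNG seeded at `seed`; global state untouched
localRNG <- function(seed) {
  state <- NULL
  if (exists(".Random.seed", envir = globalenv())) {
    state <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", state, envir = globalenv()))
  }
  set.seed(seed)
  inner <- get(".Random.seed", envir = globalenv())
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
  function(expr) {
    outer <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", inner, envir = globalenv())
    on.exit({
      inner <<- get(".Random.seed", envir = globalenv())
      if (is.null(outer)) {
        rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", outer, envir = globalenv())
    })
    expr
  }
}

# circular 2D Gaussian blur by FFT; conserves total intensity exactly
gaussBlur2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  ny <- nrow(img); nx <- ncol(img)
  wy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1))
  wx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1))
  ky <- exp(-wy^2 / (2 * sigma^2))
  kx <- exp(-wx^2 / (2 * sigma^2))
  kern <- outer(ky, kx)
  kern <- kern / sum(kern)
  Re(fft(fft(img) * fft(kern), inverse = TRUE)) / (ny * nx)
}

#' Render a membrane + plasmodesmata z-stack with known ground truth
#'
#' Paints plasma-membrane signal along the (dilated) cell boundaries of a
#' mosaic, enriches small boundary patches by the factor
#' \code{pdIndexTrue} to emulate plasmodesmata-localized puncta, blurs each
#' plane with a Gaussian point-spread function, then applies Poisson shot
#' noise followed by Gaussian read noise. The punctum peak-over-plateau
#' ratio of the noiseless render equals \code{pdIndexTrue} by construction
#' (up to PSF edge attenuation), which is what the PD index estimates.
#'
#' Puncta are placed at Poisson-random boundary positions with linear
#' density \code{pdPer100um} per 100 um of boundary; positions are kept at
#' least \code{minSeparation} px apart so truth matching is unambiguous.
#'
#' @param mosaic a \linkS4class{MosaicGroundTruth} (labels + boundary).
#' @param nZ number of z planes (>= 1).
#' @param pdPer100um punctum linear density per 100 um of cell boundary.
#' @param pdIndexTrue punctum : membrane intensity ratio (>= 1).
#' @param pmIntensity membrane plateau in expected photons/pixel (> 0).
#' @param psfSigma in-plane PSF sigma, px.
#' @param readNoiseSd Gaussian read noise sd, a.u.
#' @param seed RNG seed.
#' @param pixelSizeXY um per pixel (default 0.2).
#' @param zStep um per plane (default 0.5).
#' @param membraneHalfWidth boundary dilation radius painting the membrane
#'   (px; default 3, a realistic confocal wall width).
#' @param spotRadius in-plane radius of punctum enrichment (px, default 4).
#' @param shotNoise apply Poisson noise? Set \code{FALSE} (with
#'   \code{readNoiseSd = 0}) for a noiseless render.
#' @param nPuncta optionally force an exact punctum count instead of the
#'   Poisson draw (used by benchmarks needing a fixed truth size).
#' @param minSeparation minimum punctum separation, px.
#' @return list with elements \code{stack} (\linkS4class{ImageStack}) and
#'   \code{truth} (updated \linkS4class{MosaicGroundTruth}; its \code{meta}
#'   carries \code{pmMass} and \code{spotMass}, the noiseless photon masses).
#' @examples
#' m <- makeCellMosaic(64, 64, 4, seed = 1)
#' r <- renderMembraneStack(m, nZ = 3, pdPer100um = 4, pdIndexTrue = 2,
#'                          pmIntensity = 50, psfSigma = 0.8,
#'                          readNoiseSd = 1, seed = 2)
#' r$stack
#' @export
renderMembraneStack <- function(mosaic, nZ, pdPer100um = 5, pdIndexTrue = 2,
                                pmIntensity = 50, psfSigma = 0.8,
                                readNoiseSd = 1, seed = 1,
                                pixelSizeXY = 0.2, zStep = 0.5,
                                membraneHalfWidth = 3, spotRadius = 4,
                                shotNoise = TRUE, nPuncta = NULL,
                                minSeparation = 12) {
  if (nZ < 1) stop("nZ must be >= 1")
  if (pdIndexTrue < 1) stop("pdIndexTrue must be >= 1 for enriched puncta")
  if (pmIntensity <= 0) stop("pmIntensity must be > 0")
  bnd <- boundaryMask(mosaic)
  ny <- nrow(bnd); nx <- ncol(bnd)
  membrane <- dilateMask(bnd, membraneHalfWidth)
  rng <- localRNG(seed)

  # punctum count: Poisson in the boundary length (um); boundary mask is two
  # pixels wide across each interface, hence the factor 1/2
  lenUm <- sum(bnd) * pixelSizeXY / 2
  nSpots <- if (is.null(nPuncta)) {
    if (pdPer100um <= 0) 0L else rng(rpois(1, lenUm * pdPer100um / 100))
  } else as.integer(nPuncta)

  cand <- which(bnd, arr.ind = TRUE)
  # keep candidates away from the frame edge so ROIs stay in-bounds
  margin <- spotRadius + 4
  keep <- cand[, 1] > margin & cand[, 1] < ny - margin &
          cand[, 2] > margin & cand[, 2] < nx - margin
  cand <- cand[keep, , drop = FALSE]
  spotY <- numeric(0); spotX <- numeric(0)
  if (nSpots > 0) {
    ord <- rng(sample.int(nrow(cand)))
    for (i in ord) {
      yy <- cand[i, 1]; xx <- cand[i, 2]
      if (length(spotY) &&
          any((spotY - yy)^2 + (spotX - xx)^2 < minSeparation^2)) next
      spotY <- c(spotY, yy); spotX <- c(spotX, xx)
      if (length(spotY) >= nSpots) break
    }
  }
  nSpots <- length(spotY)
  spotZ <- if (nSpots > 0) rng(sample.int(nZ, nSpots, replace = TRUE)) else integer(0)

  # noiseless render: membrane plateau everywhere on the painted membrane,
  # multiplied by pdIndexTrue inside each punctum's in-plane disk
  planes <- vector("list", nZ)
  base <- pmIntensity * membrane
  spotPixelCount <- 0L
  for (z in seq_len(nZ)) {
    factor <- matrix(1, ny, nx)
    sel <- which(spotZ == z)
    for (s in sel) {
      ys <- max(1, spotY[s] - spotRadius):min(ny, spotY[s] + spotRadius)
      xs <- max(1, spotX[s] - spotRadius):min(nx, spotX[s] + spotRadius)
      dy <- outer(ys - spotY[s], rep(1, length(xs)))
      dx <- outer(rep(1, length(ys)), xs - spotX[s])
      disk <- dy^2 + dx^2 <= spotRadius^2
      sub <- factor[ys, xs]
      sub[disk & membrane[ys, xs]] <- pdIndexTrue
      factor[ys, xs] <- sub
    }
    spotPixelCount <- spotPixelCount + sum(factor > 1)
    planes[[z]] <- base * factor
  }
  pmMass <- pmIntensity * sum(membrane) * nZ
  spotMass <- pmIntensity * (pdIndexTrue - 1) * spotPixelCount

  vox <- array(0, c(nZ, ny, nx))
  for (z in seq_len(nZ)) {
    pl <- planes[[z]]
    if (psfSigma > 0) pl <- gaussBlur2d(pl, psfSigma)
    vox[z, , ] <- pl
  }
  if (shotNoise) {
    vox[] <- rng(rpois(length(vox), pmax(vox, 0)))
  }
  if (readNoiseSd > 0) {
    vox <- vox + rng(rnorm(length(vox), 0, readNoiseSd))
  }
  vox <- pmax(vox, 0)

  truth <- new("MosaicGroundTruth",
    labelImage = labelImage(mosaic), boundaryMask = bnd,
    spotTruth = data.frame(z = as.numeric(spotZ), y = as.numeric(spotY),
                           x = as.numeric(spotX),
                           amplitude = rep((pdIndexTrue - 1) * pmIntensity,
                                           nSpots)),
    pdIndexTrue = pdIndexTrue, pmIntensity = pmIntensity,
    meta = list(seed = seed, pmMass = pmMass, spotMass = spotMass,
                membraneHalfWidth = membraneHalfWidth,
                spotRadius = spotRadius, psfSigma = psfSigma,
                pixelSizeXY = pixelSizeXY))
  stack <- ImageStack(vox, pixelSizeXY = pixelSizeXY, zStep = zStep,
                      channelName = "synthetic_membrane")
  list(stack = stack, truth = truth)
}
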