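# FRAP, luminescence and bombardment-count simulators.

#' Simulate a FRAP trace with background and reference channels
#'
#' The bleached-ROI truth curve is a prebleach plateau, an instantaneous
#' bleach to \code{bleachDepth} of the prebleach level, then a
#' single-exponential recovery toward the mobile plateau
#' \code{bleachDepth + (mobileFractionTrue/100) * (1 - bleachDepth)}.
#' All fluorescent channels are multiplied by
#' \code{exp(-acquisitionBleachRate * t)} (imaging-induced bleaching), and
#' Gaussian noise is added. The plateau of the noiseless double-normalized
#' curve equals the injected mobile fraction by construction.
#'
#' @param prebleachLevel bleached-ROI prebleach intensity, a.u.
#' @param bleachDepth fraction of the prebleach level remaining at t = 0+.
#' @param mobileFractionTrue percent in [0, 100].
#' @param recoveryTau recovery time constant, s (> 0).
#' @param acquisitionBleachRate 1/s (>= 0).
#' @param noiseSd Gaussian noise sd on the bleach/reference channels, a.u.
#' @param frameInterval s between frames.
#' @param nPre,nPost prebleach / postbleach frame counts (nPre >= 2).
#' @param referenceLevel unbleached reference ROI prebleach intensity.
#' @param backgroundLevel constant background intensity.
#' @param seed RNG seed.
#' @return A \linkS4class{FrapTrace}.
#' @examples
#' tr <- simulateFrap(mobileFractionTrue = 40, recoveryTau = 10,
#'                    noiseSd = 0, nPost = 60, seed = 1)
#' mobileFraction(tr, tEval = 60, endpointWindow = 1)$mobileFraction
#' @export
simulateFrap <- function(prebleachLevel = 100, bleachDepth = 0.3,
                         mobileFractionTrue = 50, recoveryTau = 10,
                         acquisitionBleachRate = 0, noiseSd = 0,
                         frameInterval = 1, nPre = 5L, nPost = 90L,
                         referenceLevel = 500, backgroundLevel = 20,
                         seed = 1) {
  if (recoveryTau <= 0) stop("recoveryTau must be > 0")
  if (mobileFractionTrue < 0 || mobileFractionTrue > 100)
    stop("mobileFractionTrue must be a percentage in [0, 100]")
  if (bleachDepth < 0 || bleachDepth >= 1)
    stop("bleachDepth must be in [0, 1)")
  if (nPre < 2) stop("need >= 2 prebleach frames")
  if (nPost * frameInterval < recoveryTau / 10)
    warning("postbleach window shorter than recoveryTau/10: recovery unidentifiable")
  n <- nPre + nPost
  time <- (seq_len(n) - 1) * frameInterval
  bleachIdx <- nPre + 1L
  tPost <- time - time[bleachIdx]
  plateau <- bleachDepth + (mobileFractionTrue / 100) * (1 - bleachDepth)
  f <- ifelse(tPost < 0, 1,
              plateau - (plateau - bleachDepth) * exp(-tPost / recoveryTau))
  decay <- exp(-acquisitionBleachRate * time)
  bleach <- prebleachLevel * f * decay + backgroundLevel
  ref <- referenceLevel * decay + backgroundLevel
  bg <- rep(backgroundLevel, n)
  if (noiseSd > 0) {
    rng <- localRNG(seed)
    bleach <- bleach + rng(rnorm(n, 0, noiseSd))
    ref <- ref + rng(rnorm(n, 0, noiseSd))
    bg <- bg + rng(rnorm(n, 0, noiseSd / 4))
  }
  FrapTrace(time, bleach, bg, ref, bleachIdx)
}

#' Simulate a plate-reader luminescence trace
#'
#' A constant baseline plus an elicitor-triggered burst starting at
#' \code{burstOnset}, sampled every \code{interval} minutes from
#' \code{tStart} (negative: pre-elicitation baseline frames) to
#' \code{duration}. The "gamma" burst is a gamma-density pulse scaled to
#' peak amplitude \code{burstAmplitude}; "rect" is a rectangular pulse of
#' that amplitude lasting \code{rectWidth} minutes.
#'
#' @param baseline RLU.
#' @param burstAmplitude peak RLU above baseline (>= 0).
#' @param burstOnset min after elicitation (t = 0).
#' @param burstShape "gamma" or "rect".
#' @param duration min; must be >= 25 to cover the integration window.
#' @param interval sampling interval, min (> 0).
#' @param noiseSd Gaussian noise, RLU.
#' @param seed RNG seed.
#' @param tStart first sample time, min (default -5).
#' @param rectWidth rectangular burst duration, min.
#' @param gammaShape,gammaScale gamma-pulse shape parameters.
#' @param wellId,treatment,genotype metadata columns.
#' @return data.frame (LumTrace): time, rlu, well_id, treatment, genotype.
#' @export
simulateLuminescence <- function(baseline = 100, burstAmplitude = 500,
                                 burstOnset = 2,
                                 burstShape = c("gamma", "rect"),
                                 duration = 30, interval = 0.5, noiseSd = 0,
                                 seed = 1, tStart = -5, rectWidth = 10,
                                 gammaShape = 2, gammaScale = 4,
                                 wellId = "A1", treatment = "chitin",
                                 genotype = "Col-0") {
  burstShape <- match.arg(burstShape)
  if (burstAmplitude < 0) stop("burstAmplitude must be >= 0")
  if (interval <= 0) stop("interval must be > 0")
  if (duration < 25) stop("duration must cover the 25 min integration window")
  time <- seq(tStart, duration, by = interval)
  tb <- time - burstOnset
  burst <- switch(burstShape,
    rect = ifelse(tb >= 0 & tb < rectWidth, burstAmplitude, 0),
    gamma = {
      peak <- (gammaShape - 1) * gammaScale  # mode of the gamma density
      shape <- ifelse(tb > 0,
                      stats::dgamma(tb, shape = gammaShape, scale = gammaScale) /
                        stats::dgamma(peak, shape = gammaShape, scale = gammaScale),
                      0)
      burstAmplitude * shape
    })
  rlu <- baseline + burst
  if (noiseSd > 0) {
    rng <- localRNG(seed)
    rlu <- rlu + rng(rnorm(length(time), 0, noiseSd))
  }
  data.frame(time = time, rlu = rlu, well_id = wellId,
             treatment = treatment, genotype = genotype,
             stringsAsFactors = FALSE)
}

# zero-truncated negative binomial: a bombardment site is only recorded if
# the transformed cell itself is visible, so counts are >= 1
rztnbinom <- function(rng, n, mu, size) {
  x <- rng(rnbinom(n, mu = mu, size = size))
  while (any(x == 0)) {
    z <- x == 0
    x[z] <- rng(rnbinom(sum(z), mu = mu, size = size))
  }
  x
}

#' Simulate a bombardment-assay count table
#'
#' Per-site counts of GFP-expressing cells are drawn from a zero-truncated
#' negative binomial (mean/dispersion parameterization); mock sites have
#' mean \code{muMock} and treated sites \code{muMock * treatmentRatio} per
#' genotype. Zero truncation reflects that a scored site shows at least the
#' transformed cell; for the means used here its effect on the mean is
#' below 4 percent.
#'
#' @param muMock mean cells/site under mock (> 0).
#' @param treatmentRatio multiplicative treatment effect (> 0).
#' @param dispersion NB size parameter (> 0); larger is closer to Poisson.
#' @param nSitesPerGroup sites per genotype x treatment (>= 1).
#' @param genotypes character vector of genotype names.
#' @param treatments treatment labels; the first is the mock baseline.
#' @param nReplicates biological replicates to tag sites with.
#' @param seed RNG seed.
#' @return data.frame (BombardmentTable): genotype, treatment, replicate,
#'   n_cells.
#' @examples
#' tab <- simulateBombardment(muMock = 5, treatmentRatio = 0.6,
#'                            dispersion = 5, nSitesPerGroup = 90, seed = 1)
#' head(tab)
#' @export
simulateBombardment <- function(muMock = 10, treatmentRatio = 0.6,
                                dispersion = 5, nSitesPerGroup = 90L,
                                genotypes = "Col-0",
                                treatments = c("mock", "chitin"),
                                nReplicates = 6L, seed = 1) {
  if (muMock <= 0) stop("muMock must be > 0")
  if (treatmentRatio <= 0) stop("treatmentRatio must be > 0")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (nSitesPerGroup < 1) stop("nSitesPerGroup must be >= 1")
  rng <- localRNG(seed)
  out <- list()
  for (g in genotypes) for (tr in treatments) {
    mu <- if (tr == treatments[1]) muMock else muMock * treatmentRatio
    counts <- rztnbinom(rng, nSitesPerGroup, mu, dispersion)
    out[[length(out) + 1L]] <- data.frame(
      genotype = g, treatment = tr,
      replicate = rng(sample.int(nReplicates, nSitesPerGroup, replace = TRUE)),
      n_cells = counts, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Validate a bombardment count table
#'
#' @param table data.frame with genotype, treatment, replicate, n_cells.
#' @return the table, invisibly, after validation.
#' @export
validateBombardmentTable <- function(table) {
  need <- c("genotype", "treatment", "replicate", "n_cells")
  if (!all(need %in% names(table)))
    stop("table needs columns: ", paste(need, collapse = ", "))
  if (any(table$n_cells < 1) || any(table$n_cells != round(table$n_cells)))
    stop("n_cells must be integers >= 1 (a site shows at least the transformed cell)")
  if (any(table$replicate < 1)) stop("replicate must be >= 1")
  invisible(table)
}
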