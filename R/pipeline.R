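# Configuration handling and the end-to-end demo pipeline.

#' Default pipeline configuration
#'
#' A single hierarchical key-value tree; every parameter surfaced by the
#' analysis modules appears here with its documented default.
#'
#' @return nested list of defaults.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "detect", "summarize", "compare"),
    synthetic = list(
      width = 192L, height = 192L, nCells = 8L, nZ = 3L,
      pdPer100um = 5, pdIndexTrue = 8, pmIntensity = 10,
      psfSigma = 0.8, readNoiseSd = 1,
      chitinAmplitudeFactor = 1.5,   # treated puncta brighter than mock
      nImagesPerCondition = 4L
    ),
    detection = list(
      smoothSigma = 1, backgroundRadius = 5, thresholdMode = "otsu",
      thresholdValue = NA, minVoxels = 3L, maxVoxels = 200L,
      connectivity = 26L
    ),
    pdindex = list(pdRadius = 2, pmBandInner = 7, pmBandOuter = 14),
    anisotropy = list(grouping = "na_corrected",
                      G = 0.481, L1 = 0.013, L2 = 0.037),
    flim = list(nComponents = 2L, tauWeighting = "amplitude"),
    frap = list(method = "endpoint", tEval = 60, endpointWindow = 3L),
    ros = list(windowStart = 0, windowEnd = 25,
               backgroundMode = "pre_window_mean"),
    bombardment = list(test = "mann_whitney", alpha = 0.05)
  )
}

mergeConfig <- function(defaults, user, path = "", errors) {
  for (key in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      errors$msgs <- c(errors$msgs, paste0("unknown key: ", here))
      next
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        errors$msgs <- c(errors$msgs, paste0(here, ": expected a block"))
        next
      }
      defaults[[key]] <- mergeConfig(defaults[[key]], user[[key]], here,
                                     errors)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Merges the user config over the defaults, rejects unknown keys, and
#' checks documented parameter ranges. All violations are reported together.
#'
#' @param config nested list (possibly partial); an empty list yields the
#'   defaults.
#' @return the validated, fully populated config.
#' @export
validateConfig <- function(config = list()) {
  errors <- new.env()
  errors$msgs <- character(0)
  cfg <- mergeConfig(defaultConfig(), config, "", errors)
  chk <- function(cond, msg) if (!cond) errors$msgs <<- c(errors$msgs, msg)
  chk(cfg$detection$minVoxels < cfg$detection$maxVoxels,
      "detection.minVoxels must be < detection.maxVoxels")
  chk(cfg$detection$smoothSigma >= 0, "detection.smoothSigma must be >= 0")
  chk(cfg$detection$connectivity %in% c(6, 18, 26),
      "detection.connectivity must be 6, 18 or 26")
  chk(cfg$bombardment$alpha > 0 && cfg$bombardment$alpha < 1,
      "bombardment.alpha must be in (0, 1)")
  chk(cfg$synthetic$pdIndexTrue >= 1, "synthetic.pdIndexTrue must be >= 1")
  chk(cfg$synthetic$pmIntensity > 0, "synthetic.pmIntensity must be > 0")
  chk(cfg$anisotropy$G > 0, "anisotropy.G must be > 0")
  chk(cfg$anisotropy$L1 >= 0 && cfg$anisotropy$L1 < 1 / 3,
      "anisotropy.L1 must be in [0, 1/3)")
  chk(cfg$anisotropy$L2 >= 0 && cfg$anisotropy$L2 < 1 / 3,
      "anisotropy.L2 must be in [0, 1/3)")
  chk(cfg$flim$nComponents %in% c(1, 2), "flim.nComponents must be 1 or 2")
  chk(cfg$frap$tEval > 0, "frap.tEval must be > 0")
  chk(cfg$ros$windowEnd > cfg$ros$windowStart,
      "ros window must be non-degenerate")
  if (length(errors$msgs))
    stop("invalid configuration:\n  ", paste(errors$msgs, collapse = "\n  "))
  cfg
}

configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end demo pipeline
#'
#' Simulates mock and chitin-treated callose stacks (chitin puncta brighter
#' by \code{synthetic$chitinAmplitudeFactor}), detects spots in each,
#' summarizes per-image spot fluorescence, and compares conditions with a
#' Wilcoxon rank-sum test. Per-image failures are logged into the report
#' and skipped, not fatal.
#'
#' @param config validated config (see \code{\link{validateConfig}}); a raw
#'   partial config is validated here.
#' @param outDir optional directory for CSV outputs (spot tables,
#'   summaries); created if missing.
#' @return a RunReport: list with per-stage records, seed, package version
#'   and config hash. Reports are byte-identical for identical config+seed.
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
  cfg <- validateConfig(config)
  report <- list(packageVersion = as.character(utils::packageVersion("pdquant")),
                 seed = cfg$seed, configHash = configHash(cfg),
                 stages = list(), warnings = character(0))
  syn <- cfg$synthetic
  images <- list()
  if ("simulate" %in% cfg$stages) {
    mosaic <- makeCellMosaic(syn$width, syn$height, syn$nCells,
                             seed = cfg$seed)
    k <- 0L
    for (cond in c("mock", "chitin")) {
      fac <- if (cond == "chitin") syn$chitinAmplitudeFactor else 1
      pdIdx <- 1 + (syn$pdIndexTrue - 1) * fac
      for (i in seq_len(syn$nImagesPerCondition)) {
        k <- k + 1L
        r <- renderMembraneStack(mosaic, nZ = syn$nZ,
                                 pdPer100um = syn$pdPer100um,
                                 pdIndexTrue = pdIdx,
                                 pmIntensity = syn$pmIntensity,
                                 psfSigma = syn$psfSigma,
                                 readNoiseSd = syn$readNoiseSd,
                                 seed = cfg$seed * 1000L + k)
        images[[paste(cond, i, sep = "_")]] <-
          list(condition = cond, stack = r$stack, truth = r$truth)
      }
    }
    report$stages$simulate <- list(nImages = length(images),
                                   images = names(images))
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      for (nm in names(images))
        writeImageStack(images[[nm]]$stack,
                        file.path(outDir, paste0(nm, ".csv")))
    }
  }
  summaries <- NULL
  if ("detect" %in% cfg$stages && length(images)) {
    det <- cfg$detection
    params <- SpotDetectionParams(det$smoothSigma, det$backgroundRadius,
                                  det$thresholdMode, det$thresholdValue,
                                  det$minVoxels, det$maxVoxels,
                                  det$connectivity)
    rows <- list()
    for (nm in names(images)) {
      res <- tryCatch(detectSpots(images[[nm]]$stack, params),
                      error = function(e) e)
      if (inherits(res, "error")) {
        report$warnings <- c(report$warnings,
                             paste0(nm, ": ", conditionMessage(res)))
        next
      }
      s <- summarizeSpotFluorescence(res)
      rows[[nm]] <- data.frame(image = nm,
                               condition = images[[nm]]$condition,
                               nSpots = s$nSpots,
                               totalSpotFluorescence = s$totalSpotFluorescence,
                               meanSpotFluorescence = s$meanSpotFluorescence,
                               stringsAsFactors = FALSE)
      if (!is.null(outDir))
        writeSpotsCsv(res, file.path(outDir, paste0(nm, "_spots.csv")), nm)
    }
    summaries <- do.call(rbind, rows)
    report$stages$detect <- list(nProcessed = nrow(summaries),
                                 nSpotsTotal = sum(summaries$nSpots))
  }
  if ("summarize" %in% cfg$stages && !is.null(summaries)) {
    report$stages$summarize <- lapply(split(summaries, summaries$condition),
      function(d) list(n = nrow(d),
                       meanSpotFluorescence = mean(d$meanSpotFluorescence,
                                                   na.rm = TRUE)))
    if (!is.null(outDir))
      write.csv(summaries, file.path(outDir, "summaries.csv"),
                row.names = FALSE)
  }
  if ("compare" %in% cfg$stages && !is.null(summaries) &&
      length(unique(summaries$condition)) == 2) {
    a <- summaries$meanSpotFluorescence[summaries$condition == "mock"]
    b <- summaries$meanSpotFluorescence[summaries$condition == "chitin"]
    wt <- suppressWarnings(wilcox.test(b, a, exact = FALSE))
    report$stages$compare <- list(
      direction = if (mean(b) > mean(a)) "chitin > mock" else "chitin <= mock",
      meanMock = mean(a), meanChitin = mean(b), p_value = wt$p.value)
  }
  report$reportHash <- configHash(report["stages"])
  class(report) <- "RunReport"
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat(sprintf("RunReport (pdquant %s, seed %d, config %s)\n",
              x$packageVersion, x$seed, substr(x$configHash, 1, 8)))
  for (nm in names(x$stages)) {
    cat(" stage", nm, ":\n")
    str(x$stages[[nm]], give.attr = FALSE, indent.str = "   ")
  }
  if (length(x$warnings)) cat(" warnings:", length(x$warnings), "\n")
  invisible(x)
}
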