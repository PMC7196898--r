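# Plain-text round-trip I/O. Image stacks travel as long-format CSV
# (z,y,x,value) with a JSON sidecar carrying the physical calibration; no
# TIFF reader/writer is available in this R environment.

sidecarPath <- function(path) paste0(path, ".json")

#' Write an ImageStack to CSV + JSON sidecar
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output CSV path; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
writeImageStack <- function(stack, path) {
  v <- voxels(stack)
  d <- dim(v)
  co <- arrayInd(seq_along(v), d)
  df <- data.frame(z = co[, 1], y = co[, 2], x = co[, 3], value = as.vector(v))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(dims = d, pixel_size_xy_um = pixelSizeXY(stack),
         z_step_um = zStep(stack), channel_name = stack@channelName),
    sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ImageStack written by \code{\link{writeImageStack}}
#'
#' @param path CSV path with an accompanying JSON sidecar.
#' @return An \linkS4class{ImageStack}.
#' @export
readImageStack <- function(path) {
  meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  df <- read.csv(path)
  d <- as.integer(meta$dims)
  v <- array(0, d)
  v[cbind(df$z, df$y, df$x)] <- df$value
  ImageStack(v, pixelSizeXY = meta$pixel_size_xy_um, zStep = meta$z_step_um,
             channelName = meta$channel_name)
}

#' Write a decay histogram as two-column CSV (time_ns, counts)
#'
#' The repetition period is stored in a JSON sidecar.
#' @param hist a \linkS4class{DecayHistogram}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeDecayCsv <- function(hist, path) {
  write.csv(data.frame(time_ns = binCenters(hist),
                       counts = photonCounts(hist)),
            path, row.names = FALSE)
  jsonlite::write_json(list(repetition_period_ns = repetitionPeriod(hist)),
                       sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a decay histogram CSV
#'
#' @param path CSV path (columns time_ns, counts).
#' @param repetitionPeriod ns; read from the sidecar when present.
#' @return A \linkS4class{DecayHistogram}.
#' @export
readDecayCsv <- function(path, repetitionPeriod = NULL) {
  df <- read.csv(path)
  if (is.null(repetitionPeriod)) {
    sc <- sidecarPath(path)
    repetitionPeriod <- if (file.exists(sc))
      jsonlite::read_json(sc, simplifyVector = TRUE)$repetition_period_ns
    else max(df$time_ns) + (df$time_ns[2] - df$time_ns[1]) / 2
  }
  DecayHistogram(df$time_ns, df$counts, repetitionPeriod)
}

#' Write a FRAP trace as CSV + sidecar (bleach frame index)
#' @param trace a \linkS4class{FrapTrace}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFrapTrace <- function(trace, path) {
  write.csv(data.frame(time_s = frapTime(trace),
                       bleach = trace@bleachRoi,
                       background = trace@backgroundRoi,
                       reference = trace@referenceRoi),
            path, row.names = FALSE)
  jsonlite::write_json(list(bleach_frame_index = bleachFrameIndex(trace)),
                       sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a FRAP trace CSV
#' @param path CSV path written by \code{\link{writeFrapTrace}}.
#' @return A \linkS4class{FrapTrace}.
#' @export
readFrapTrace <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  FrapTrace(df$time_s, df$bleach, df$background, df$reference,
            meta$bleach_frame_index)
}

#' Write a per-spot table as CSV
#' @param spots a \linkS4class{SpotSet}.
#' @param path output CSV path.
#' @param imageId identifier column value.
#' @return \code{path}, invisibly.
#' @export
writeSpotsCsv <- function(spots, path, imageId = "image1") {
  tab <- spotTable(spots)
  tab <- cbind(image_id = rep(imageId, nrow(tab)), tab)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read / write bombardment tables
#' @param table data.frame (genotype, treatment, replicate, n_cells).
#' @param path CSV path.
#' @return the table (read) or \code{path} invisibly (write).
#' @export
writeBombardmentCsv <- function(table, path) {
  validateBombardmentTable(table)
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBombardmentCsv
#' @export
readBombardmentCsv <- function(path) {
  validateBombardmentTable(read.csv(path, stringsAsFactors = FALSE))
}
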