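#' @importFrom jsonlite toJSON fromJSON write_json read_json
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' Write a chamber layout to JSON
#'
#' @param layout a \linkS4class{ChamberLayout}.
#' @param path output file.
#' @export
writeChamberLayout <- function(layout, path) {
  obj <- list(
    format = "hpMRSI-layout-v1",
    centers_mm = unname(apply(layout@centers, 1, as.numeric, simplify = FALSE)),
    diameter_mm = layout@diameter,
    pitch_mm = layout@pitch,
    roles = layout@roles,
    sample_volume_uL = layout@sampleVolume,
    fov_mm = layout@fov)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a chamber layout from JSON
#'
#' @param path file written by \code{\link{writeChamberLayout}}.
#' @return a \linkS4class{ChamberLayout}.
#' @export
readChamberLayout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hpMRSI-layout-v1"))
    stop("not an hpMRSI layout file")
  centers <- if (is.list(obj$centers_mm))
    do.call(rbind, lapply(obj$centers_mm, as.numeric))
  else matrix(as.numeric(obj$centers_mm), ncol = 2,
              byrow = !is.matrix(obj$centers_mm))
  ChamberLayout(centers = centers, diameter = obj$diameter_mm,
                pitch = obj$pitch_mm, roles = obj$roles,
                sampleVolume = obj$sample_volume_uL, fov = obj$fov_mm)
}

#' Read calibration volume pairs from CSV
#'
#' Expects two columns, \code{total_injected_uL} and \code{chamber_volume_uL}.
#'
#' @param path CSV file.
#' @return numeric 2-column matrix suitable for \code{\link{fitDeadVolume}}.
#' @export
readVolumePairs <- function(path) {
  df <- utils::read.csv(path)
  need <- c("total_injected_uL", "chamber_volume_uL")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  as.matrix(df[, need])
}

#' Write a volume calibration to JSON
#'
#' @param calibration a \linkS4class{VolumeCalibration}.
#' @param path output file.
#' @export
writeVolumeCalibration <- function(calibration, path) {
  obj <- list(
    format = "hpMRSI-volume-calibration-v1",
    dead_volume_uL = calibration@deadVolume,
    slope = calibration@slope,
    r_squared_free_fit = calibration@rSquared,
    free_slope = calibration@freeSlope,
    free_intercept_uL = calibration@freeIntercept,
    residuals_uL = calibration@residuals,
    negative_dead_volume = calibration@negativeDeadVolume)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# --- CSIDataset plain-text container --------------------------------------
# A versioned two-file container: <stem>.meta.json holds the acquisition
# metadata (full double precision, round-trips bit-exactly) and
# <stem>.fid.csv holds the complex FID, one row per point, re/im printed
# with %.17g so every IEEE double survives the round trip.

.acqToList <- function(acq) {
  list(matrixSize = acq@matrixSize, fov = acq@fov,
       sliceThickness = acq@sliceThickness, flipAngle = acq@flipAngle,
       nPulses = acq@nPulses, repetitionTime = acq@repetitionTime,
       acqTime = acq@acqTime, echoTime = acq@echoTime,
       frameInterval = acq@frameInterval, nFrames = acq@nFrames,
       delayToFirstFrame = acq@delayToFirstFrame,
       frequencyMHz = acq@frequencyMHz, spectralWidth = acq@spectralWidth,
       offsetPPM = acq@offsetPPM, timingTolerance = acq@timingTolerance)
}

.acqFromList <- function(x) {
  do.call(AcquisitionParams, x)
}

#' Persist a CSI dataset as a plain-text container
#'
#' Writes \code{<stem>.meta.json} (acquisition metadata, noise level, seed;
#' format tag \code{hpMRSI-csi-v1}) and \code{<stem>.fid.csv} (columns
#' \code{frame}, \code{row}, \code{col}, \code{point}, \code{re}, \code{im};
#' indices 1-based, doubles printed with 17 significant digits so the array
#' round-trips bit-exactly).
#'
#' @param dataset a \linkS4class{CSIDataset}.
#' @param stem path stem (without extension).
#' @return the stem, invisibly.
#' @export
writeCSIDataset <- function(dataset, stem) {
  meta <- list(format = "hpMRSI-csi-v1",
               acq = .acqToList(dataset@acq),
               noiseSd = dataset@noiseSd,
               seed = if (is.na(dataset@seed)) NULL else dataset@seed)
  jsonlite::write_json(meta, paste0(stem, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  d <- dim(dataset@fid)
  idx <- expand.grid(point = seq_len(d[4]), col = seq_len(d[3]),
                     row = seq_len(d[2]), frame = seq_len(d[1]))
  v <- aperm(dataset@fid, c(4, 3, 2, 1))
  con <- file(paste0(stem, ".fid.csv"), "w")
  on.exit(close(con))
  writeLines("frame,row,col,point,re,im", con)
  writeLines(sprintf("%d,%d,%d,%d,%.17g,%.17g", idx$frame, idx$row,
                     idx$col, idx$point, Re(v), Im(v)), con)
  invisible(stem)
}

#' Read a CSI dataset written by \code{\link{writeCSIDataset}}
#'
#' @param stem path stem used at write time.
#' @return a \linkS4class{CSIDataset}.
#' @export
readCSIDataset <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, "hpMRSI-csi-v1"))
    stop("not an hpMRSI CSI container")
  acq <- .acqFromList(meta$acq)
  df <- utils::read.csv(paste0(stem, ".fid.csv"))
  d <- c(acq@nFrames, acq@matrixSize[1], acq@matrixSize[2],
         spectralPoints(acq))
  fid <- array(0 + 0i, dim = d)
  fid[cbind(df$frame, df$row, df$col, df$point)] <-
    complex(real = df$re, imaginary = df$im)
  new("CSIDataset", fid = fid, acq = acq, noiseSd = meta$noiseSd,
      seed = if (is.null(meta$seed)) NA_integer_ else as.integer(meta$seed))
}

#' Export chamber spectra to tidy CSV
#'
#' One row per (frame, chamber, ppm): columns \code{frame}, \code{time},
#' \code{chamber}, \code{ppm}, \code{magnitude}.
#'
#' @param series a \linkS4class{ChamberSpectraSeries}.
#' @param path output CSV.
#' @export
writeSpectraCSV <- function(series, path) {
  d <- dim(series@spectra)
  df <- expand.grid(ppm = series@ppm, chamber = seq_len(d[2]),
                    frame = seq_len(d[1]))
  df$time <- series@frameTimes[df$frame]
  df$magnitude <- as.vector(aperm(series@spectra, c(3, 2, 1)))
  utils::write.csv(df[, c("frame", "time", "chamber", "ppm", "magnitude")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a peak series to tidy CSV
#'
#' @param peaks a \linkS4class{PeakSeries}.
#' @param path output CSV.
#' @export
writePeaksCSV <- function(peaks, path) {
  utils::write.csv(peakTable(peaks), path, row.names = FALSE)
  invisible(path)
}

#' Export a concentration series to tidy CSV
#'
#' @param conc a \linkS4class{ConcentrationSeries}.
#' @param path output CSV.
#' @export
writeConcentrationCSV <- function(conc, path) {
  utils::write.csv(concentrationTable(conc), path, row.names = FALSE)
  invisible(path)
}

# FNV-1a hash of a string, returned as 8 hex digits; used only to label run
# manifests (the manifest embeds the full configuration anyway).
.fnv1a <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    # 32-bit modular multiply in doubles, split to stay within 2^53
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
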