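#' Chemical-shift-imaging acquisition parameters
#'
#' \code{AcquisitionParams} bundles the parameters of the CSI pulse sequence
#' used to image the multiwell device: an \eqn{8 \times 8} voxel matrix over a
#' 40 mm field of view (5 mm in-plane voxels, 12 mm slice), a 15 degree flip
#' angle, 64 phase-encoding pulses per frame at a repetition time of
#' 66.907 ms, a 51.2 ms acquisition window per FID, and one spectroscopic
#' frame every 4 s starting 25 s after dissolution.
#'
#' The number of complex points per FID is \code{round(acqTime *
#' spectralWidth)}; with the defaults (51.2 ms, 20 kHz) this gives 1024 points
#' and a spectral resolution of \code{1/acqTime} (about 19.5 Hz, 0.61 ppm at
#' 32.13 MHz).
#'
#' Note that 64 pulses at the default repetition time occupy 4.282 s, slightly
#' more than the nominal 4 s frame interval; the validity check allows this
#' overrun (up to \code{timingTolerance}), and per-pulse simulation modes space
#' frames at \code{max(frameInterval, nPulses * repetitionTime)}.
#'
#' @slot matrixSize integer length-2, voxels along (row = y, col = x).
#' @slot fov numeric, field of view in mm (square).
#' @slot sliceThickness numeric, mm.
#' @slot flipAngle numeric, RF excitation angle in degrees.
#' @slot nPulses integer, RF pulses (phase-encoding steps) per frame.
#' @slot repetitionTime numeric, pulse repetition time in seconds.
#' @slot acqTime numeric, FID acquisition window in seconds.
#' @slot echoTime numeric, seconds.
#' @slot frameInterval numeric, nominal time between frames in seconds.
#' @slot nFrames integer, number of spectroscopic frames.
#' @slot delayToFirstFrame numeric, seconds between dissolution and the first
#'   frame (transfer plus injection).
#' @slot frequencyMHz numeric, 13C spectrometer frequency in MHz.
#' @slot spectralWidth numeric, Hz.
#' @slot offsetPPM numeric, ppm value at the centre of the spectral band.
#' @slot timingTolerance numeric, allowed overrun of the pulse train past the
#'   frame interval, seconds.
#'
#' @export
setClass("AcquisitionParams",
  representation(
    matrixSize = "integer",
    fov = "numeric",
    sliceThickness = "numeric",
    flipAngle = "numeric",
    nPulses = "integer",
    repetitionTime = "numeric",
    acqTime = "numeric",
    echoTime = "numeric",
    frameInterval = "numeric",
    nFrames = "integer",
    delayToFirstFrame = "numeric",
    frequencyMHz = "numeric",
    spectralWidth = "numeric",
    offsetPPM = "numeric",
    timingTolerance = "numeric"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (length(object@matrixSize) != 2L || any(object@matrixSize < 1L))
    msg <- c(msg, "matrixSize must be two positive integers")
  if (object@fov <= 0) msg <- c(msg, "fov must be positive")
  if (object@flipAngle < 0 || object@flipAngle > 90)
    msg <- c(msg, "flipAngle must lie in [0, 90] degrees")
  if (object@nPulses < 1L) msg <- c(msg, "nPulses must be >= 1")
  if (object@repetitionTime <= 0 || object@acqTime <= 0 ||
      object@frameInterval <= 0)
    msg <- c(msg, "repetitionTime, acqTime and frameInterval must be positive")
  if (object@nPulses * object@repetitionTime >
      object@frameInterval + object@timingTolerance)
    msg <- c(msg, sprintf(
      "pulse train (%.3f s) exceeds frame interval + tolerance (%.3f s)",
      object@nPulses * object@repetitionTime,
      object@frameInterval + object@timingTolerance))
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (object@delayToFirstFrame < 0) msg <- c(msg, "delayToFirstFrame must be >= 0")
  if (object@frequencyMHz <= 0) msg <- c(msg, "frequencyMHz must be positive")
  if (object@spectralWidth <= 0) msg <- c(msg, "spectralWidth must be positive")
  np <- object@acqTime * object@spectralWidth
  if (abs(np - round(np)) > 1e-6)
    msg <- c(msg, "acqTime * spectralWidth must be an integer number of points")
  if (length(msg)) msg else TRUE
})

#' Construct acquisition parameters
#'
#' All arguments default to the values of the multiwell CSI protocol (see
#' \linkS4class{AcquisitionParams}).
#'
#' @param matrixSize voxels per dimension, length 2 (rows, cols).
#' @param fov field of view, mm.
#' @param sliceThickness slice thickness, mm.
#' @param flipAngle degrees.
#' @param nPulses RF pulses per frame.
#' @param repetitionTime seconds.
#' @param acqTime FID window, seconds.
#' @param echoTime seconds.
#' @param frameInterval seconds between frames.
#' @param nFrames number of frames.
#' @param delayToFirstFrame seconds of pre-acquisition evolution.
#' @param frequencyMHz 13C frequency, MHz.
#' @param spectralWidth Hz.
#' @param offsetPPM centre of the spectral band, ppm.
#' @param timingTolerance allowed pulse-train overrun, seconds.
#' @return an \linkS4class{AcquisitionParams} object.
#' @examples
#' acq <- AcquisitionParams(nFrames = 10L)
#' spectralPoints(acq)
#' @export
AcquisitionParams <- function(matrixSize = c(8L, 8L), fov = 40,
                              sliceThickness = 12, flipAngle = 15,
                              nPulses = 64L, repetitionTime = 0.066907,
                              acqTime = 0.0512, echoTime = 0.00149,
                              frameInterval = 4, nFrames = 10L,
                              delayToFirstFrame = 25, frequencyMHz = 32.13,
                              spectralWidth = 20000, offsetPPM = 170,
                              timingTolerance = 0.5) {
  new("AcquisitionParams",
      matrixSize = as.integer(matrixSize), fov = fov,
      sliceThickness = sliceThickness, flipAngle = flipAngle,
      nPulses = as.integer(nPulses), repetitionTime = repetitionTime,
      acqTime = acqTime, echoTime = echoTime, frameInterval = frameInterval,
      nFrames = as.integer(nFrames), delayToFirstFrame = delayToFirstFrame,
      frequencyMHz = frequencyMHz, spectralWidth = spectralWidth,
      offsetPPM = offsetPPM, timingTolerance = timingTolerance)
}

#' @describeIn AcquisitionParams number of complex points per FID.
#' @param x an \code{AcquisitionParams} object.
#' @export
setMethod("spectralPoints", "AcquisitionParams", function(x) {
  as.integer(round(x@acqTime * x@spectralWidth))
})

#' Chemical-shift axis of the reconstructed spectrum
#'
#' Returns the ppm value of each spectral point after Fourier transform and
#' frequency shift, in ascending ppm order. Conventionally NMR spectra are
#' displayed with ppm decreasing to the right; the axis returned here is
#' strictly increasing and plotting order is left to the caller.
#'
#' @param x an \linkS4class{AcquisitionParams} object.
#' @param zeroFill integer zero-filling factor (>= 1).
#' @return numeric vector of ppm values, length \code{spectralPoints(x) * zeroFill}.
#' @export
setMethod("ppmAxis", "AcquisitionParams", function(x, zeroFill = 1L) {
  n <- spectralPoints(x) * as.integer(zeroFill)
  df <- x@spectralWidth / n
  freq <- (seq_len(n) - 1L - n %/% 2L) * df
  x@offsetPPM + freq / x@frequencyMHz
})

#' Frame sampling times
#'
#' Times of the first pulse of each frame, in seconds, with \code{t = 0} at
#' the first frame (the pre-acquisition delay is modelled separately). In
#' \code{"per-pulse"} mode frames are spaced by the full pulse-train duration
#' when it exceeds the nominal frame interval.
#'
#' @param x an \linkS4class{AcquisitionParams} object.
#' @param mode \code{"frame-lumped"} or \code{"per-pulse"}.
#' @return numeric vector of length \code{nFrames}.
#' @export
acqFrameTimes <- function(x, mode = c("frame-lumped", "per-pulse")) {
  mode <- match.arg(mode)
  spacing <- if (mode == "per-pulse")
    max(x@frameInterval, x@nPulses * x@repetitionTime)
  else x@frameInterval
  (seq_len(x@nFrames) - 1L) * spacing
}

setMethod("show", "AcquisitionParams", function(object) {
  cat("AcquisitionParams\n")
  cat(sprintf("  matrix %d x %d, FOV %g mm, voxel %g mm, slice %g mm\n",
              object@matrixSize[1], object@matrixSize[2], object@fov,
              object@fov / object@matrixSize[2], object@sliceThickness))
  cat(sprintf("  flip %g deg, %d pulses/frame, RT %.3f ms, Tacq %.1f ms\n",
              object@flipAngle, object@nPulses,
              1e3 * object@repetitionTime, 1e3 * object@acqTime))
  cat(sprintf("  %d frames every %g s, first frame at %g s post dissolution\n",
              object@nFrames, object@frameInterval, object@delayToFirstFrame))
  cat(sprintf("  %d points, SW %g Hz, %.2f MHz, offset %g ppm\n",
              spectralPoints(object), object@spectralWidth,
              object@frequencyMHz, object@offsetPPM))
})
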