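#' Fluidic volume calibration of the multiwell device
#'
#' \code{VolumeCalibration} holds the fit of the volume-distribution model
#' \deqn{V_w = (V_t - V_d) / 8,} where \eqn{V_w} is the volume delivered per
#' well, \eqn{V_t} the total injected volume and \eqn{V_d} the dead volume
#' retained in the injection tubing and channels. The slope is fixed at 1/8
#' (the device splits the sample eight ways); a free-slope least-squares fit
#' is retained as a diagnostic together with its \eqn{R^2}.
#'
#' @slot deadVolume numeric, fitted dead volume in microlitres.
#' @slot slope numeric, slope of the constrained model (1/8).
#' @slot rSquared numeric, coefficient of determination of the free-slope
#'   diagnostic fit.
#' @slot residuals numeric, per-observation residuals of the constrained
#'   model (observed minus predicted chamber volume, microlitres).
#' @slot freeSlope numeric, slope of the diagnostic free fit.
#' @slot freeIntercept numeric, intercept of the diagnostic free fit
#'   (microlitres).
#' @slot negativeDeadVolume logical, flags a fitted dead volume below zero.
#' @export
setClass("VolumeCalibration",
  representation(
    deadVolume = "numeric",
    slope = "numeric",
    rSquared = "numeric",
    residuals = "numeric",
    freeSlope = "numeric",
    freeIntercept = "numeric",
    negativeDeadVolume = "logical"
  )
)

setValidity("VolumeCalibration", function(object) {
  msg <- character()
  if (!is.finite(object@deadVolume)) msg <- c(msg, "deadVolume must be finite")
  if (is.finite(object@rSquared) && object@rSquared > 1 + 1e-12)
    msg <- c(msg, "rSquared must be <= 1")
  if (length(msg)) msg else TRUE
})

#' Fit the dead volume of the injection path
#'
#' Least-squares fit of the constrained volume-distribution model
#' \eqn{V_w = (V_t - V_d)/8} to observed (total injected volume, mean chamber
#' volume) pairs. With the slope fixed at 1/8 the least-squares dead volume
#' has the closed form \eqn{V_d = \mathrm{mean}(V_t - 8 V_w)}, which is what
#' is returned; an unconstrained linear regression of \eqn{V_w} on \eqn{V_t}
#' is reported alongside as a diagnostic, with its \eqn{R^2}.
#'
#' @param pairs a 2-column matrix or data frame: total injected volume and
#'   mean chamber volume, both in microlitres; at least two rows.
#' @return a \linkS4class{VolumeCalibration}.
#' @examples
#' cal <- fitDeadVolume(cbind(c(1000, 1400, 1800, 2200), c(59, 108, 154, 191)))
#' deadVolume(cal)  # 576 uL
#' @export
fitDeadVolume <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 2L)
    stop("calibration-insufficient: need at least 2 (injected, chamber) pairs")
  if (!is.numeric(pairs) || !all(is.finite(pairs)))
    stop("validation error: volumes must be finite numbers")
  if (any(pairs <= 0))
    stop("validation error: volumes must be positive")
  vt <- pairs[, 1]; vw <- pairs[, 2]
  vd <- mean(vt - 8 * vw)
  res <- vw - (vt - vd) / 8
  fit <- stats::lm(vw ~ vt)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are fine here
  neg <- vd < 0
  if (neg) warning("fitted dead volume is negative")
  new("VolumeCalibration", deadVolume = vd, slope = 1 / 8, rSquared = r2,
      residuals = as.numeric(res),
      freeSlope = unname(stats::coef(fit)[2]),
      freeIntercept = unname(stats::coef(fit)[1]),
      negativeDeadVolume = neg)
}

#' @describeIn VolumeCalibration fitted dead volume, microlitres.
#' @param x a \code{VolumeCalibration}.
#' @export
setMethod("deadVolume", "VolumeCalibration", function(x) x@deadVolume)

#' @describeIn VolumeCalibration \eqn{R^2} of the free-slope diagnostic fit.
#' @export
setMethod("rSquared", "VolumeCalibration", function(x) x@rSquared)

setMethod("show", "VolumeCalibration", function(object) {
  cat(sprintf("VolumeCalibration: Vd = %.1f uL (slope fixed 1/8)\n",
              object@deadVolume))
  cat(sprintf("  diagnostic free fit: slope %.4f, intercept %.1f uL, R2 %.4f\n",
              object@freeSlope, object@freeIntercept, object@rSquared))
  if (object@negativeDeadVolume) cat("  WARNING: negative dead volume\n")
})

#' Predict the volume delivered per chamber
#'
#' Applies the calibrated model \eqn{V_w = (V_t - V_d)/8}. Injections not
#' exceeding the dead volume deliver nothing; the prediction is floored at
#' zero with a warning.
#'
#' @param totalInjected total injected volume, microlitres.
#' @param calibration a \linkS4class{VolumeCalibration}, or a numeric dead
#'   volume in microlitres.
#' @return predicted chamber volume, microlitres (never negative).
#' @examples
#' predictChamberVolume(1600, 576)  # 128 uL
#' @export
predictChamberVolume <- function(totalInjected, calibration) {
  vd <- if (is(calibration, "VolumeCalibration")) deadVolume(calibration)
        else as.numeric(calibration)
  if (!all(is.finite(totalInjected)) || !is.finite(vd))
    stop("validation error: volumes must be finite")
  vw <- (totalInjected - vd) / 8
  if (any(vw < 0)) {
    warning("injected volume below dead volume; predicting 0 uL")
    vw <- pmax(0, vw)
  }
  vw
}
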