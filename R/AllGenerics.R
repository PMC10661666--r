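#' @import methods
NULL

#' @export
setGeneric("chamberCenters", function(x) standardGeneric("chamberCenters"))

#' @export
setGeneric("chamberRoles", function(x) standardGeneric("chamberRoles"))

#' @export
setGeneric("nChambers", function(x) standardGeneric("nChambers"))

#' @export
setGeneric("deadVolume", function(x) standardGeneric("deadVolume"))

#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @export
setGeneric("spectralPoints", function(x) standardGeneric("spectralPoints"))

#' @export
setGeneric("ppmAxis", function(x, ...) standardGeneric("ppmAxis"))

#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @export
setGeneric("speciesTable", function(x) standardGeneric("speciesTable"))

#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @export
setGeneric("rateMatrix", function(x, ...) standardGeneric("rateMatrix"))

#' @export
setGeneric("trajectoryTimes", function(x) standardGeneric("trajectoryTimes"))

#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @export
setGeneric("fidArray", function(x) standardGeneric("fidArray"))

#' @export
setGeneric("spectraArray", function(x) standardGeneric("spectraArray"))

#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @export
setGeneric("peakTable", function(x) standardGeneric("peakTable"))

#' @export
setGeneric("concentrationTable", function(x) standardGeneric("concentrationTable"))

#' @export
setGeneric("decayRate", function(x) standardGeneric("decayRate"))

#' @export
setGeneric("decayAmplitude", function(x) standardGeneric("decayAmplitude"))

#' @export
setGeneric("timeConstant", function(x) standardGeneric("timeConstant"))
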