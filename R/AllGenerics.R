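#' @include AllClasses.R
NULL

#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @export
setGeneric("zReal", function(x) standardGeneric("zReal"))

#' @export
setGeneric("zImag", function(x) standardGeneric("zImag"))

#' @export
setGeneric("zMod", function(x) standardGeneric("zMod"))

#' @export
setGeneric("zPhase", function(x) standardGeneric("zPhase"))

#' @export
setGeneric("Rb", function(x) standardGeneric("Rb"))

#' @export
setGeneric("Rct", function(x) standardGeneric("Rct"))

#' @export
setGeneric("cpeQ", function(x) standardGeneric("cpeQ"))

#' @export
setGeneric("cpeAlpha", function(x) standardGeneric("cpeAlpha"))

#' @export
setGeneric("mineralContent", function(x) standardGeneric("mineralContent"))

#' @export
setGeneric("trueParams", function(x) standardGeneric("trueParams"))

#' @export
setGeneric("fittedParams", function(x) standardGeneric("fittedParams"))

#' @export
setGeneric("fitObjective", function(x) standardGeneric("fitObjective"))

#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' Goodness of fit of a circuit model
#'
#' For an [ImpedanceSpectrum] and [CircuitParams], computes the coefficient of
#' determination of the circuit prediction over the concatenated real and
#' imaginary impedance components (each centred on its own mean). For a
#' [FitResult] it is an accessor for the stored value.
#'
#' @param spectrum an [ImpedanceSpectrum], or a [FitResult] (accessor form).
#' @param params a [CircuitParams] object (omitted in the accessor form).
#' @return a number in (-Inf, 1]; 1 means the model reproduces the spectrum
#'   exactly.
#' @export
setGeneric("rSquared", function(spectrum, params) standardGeneric("rSquared"))

#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @export
setGeneric("precisionScore", function(x, average = c("weighted", "macro"))
  standardGeneric("precisionScore"))

#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))

#' @export
setGeneric("pcaLoadings", function(x) standardGeneric("pcaLoadings"))

#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @export
setGeneric("featureMode", function(x) standardGeneric("featureMode"))
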