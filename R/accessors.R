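#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn CircuitParams-class bulk resistance (Ohm).
#' @param x object.
#' @export
setMethod("Rb", "CircuitParams", function(x) x@Rb)

#' @describeIn CircuitParams-class charge-transfer resistance (Ohm).
#' @export
setMethod("Rct", "CircuitParams", function(x) x@Rct)

#' @describeIn CircuitParams-class CPE magnitude (S s^alpha).
#' @export
setMethod("cpeQ", "CircuitParams", function(x) x@Q)

#' @describeIn CircuitParams-class CPE exponent.
#' @export
setMethod("cpeAlpha", "CircuitParams", function(x) x@alpha)

setMethod("show", "CircuitParams", function(object) {
  cat(sprintf(
    "CircuitParams: Rb = %.4g Ohm, Rct = %.4g Ohm, Q = %.4g S.s^alpha, alpha = %.4g\n",
    object@Rb, object@Rct, object@Q, object@alpha))
})

#' @describeIn ImpedanceSpectrum-class frequency grid (Hz).
#' @param x object.
#' @export
setMethod("frequencies", "ImpedanceSpectrum", function(x) x@frequencies)

#' @describeIn ImpedanceSpectrum-class real impedance component (Ohm).
#' @export
setMethod("zReal", "ImpedanceSpectrum", function(x) x@zReal)

#' @describeIn ImpedanceSpectrum-class imaginary impedance component (Ohm).
#' @export
setMethod("zImag", "ImpedanceSpectrum", function(x) x@zImag)

#' @describeIn ImpedanceSpectrum-class impedance modulus |Z| (Ohm).
#' @export
setMethod("zMod", "ImpedanceSpectrum", function(x)
  sqrt(x@zReal^2 + x@zImag^2))

#' @describeIn ImpedanceSpectrum-class signed phase angle in degrees
#'   (negative = capacitive).
#' @export
setMethod("zPhase", "ImpedanceSpectrum", function(x)
  atan2(x@zImag, x@zReal) * 180 / pi)

setMethod("show", "ImpedanceSpectrum", function(object) {
  f <- object@frequencies
  cat(sprintf("ImpedanceSpectrum: %d frequencies, %.3g - %.3g Hz\n",
              length(f), min(f), max(f)))
  cat(sprintf("  |Z| range: %.4g - %.4g Ohm; phase range: %.1f to %.1f deg\n",
              min(zMod(object)), max(zMod(object)),
              min(zPhase(object)), max(zPhase(object))))
})

#' @describeIn EISExperiment-class frequency grid (Hz).
#' @param x object.
#' @export
setMethod("frequencies", "EISExperiment", function(x)
  SummarizedExperiment::rowData(x)$frequency_hz)

#' @describeIn EISExperiment-class mineral-content class labels (wt%).
#' @export
setMethod("mineralContent", "EISExperiment", function(x)
  SummarizedExperiment::colData(x)$label_wt_percent)

#' @describeIn EISExperiment-class generating circuit parameters as a
#'   data.frame (columns Rb, Rct, Q, alpha), or NULL when absent.
#' @export
setMethod("trueParams", "EISExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  need <- c("true_Rb", "true_Rct", "true_Q", "true_alpha")
  if (!all(need %in% colnames(cd))) return(NULL)
  data.frame(Rb = cd$true_Rb, Rct = cd$true_Rct, Q = cd$true_Q,
             alpha = cd$true_alpha, row.names = rownames(cd))
})

#' Extract one spectrum from a dataset
#'
#' @param x an [EISExperiment].
#' @param i column index or sample id.
#' @return an [ImpedanceSpectrum].
#' @export
getSpectrum <- function(x, i) {
  stopifnot(is(x, "EISExperiment"), length(i) == 1L)
  impedanceSpectrum(frequencies(x),
                    SummarizedExperiment::assay(x, "zReal")[, i],
                    SummarizedExperiment::assay(x, "zImag")[, i])
}

setMethod("show", "EISExperiment", function(object) {
  callNextMethod()
  lab <- mineralContent(object)
  cat("mineral content classes (wt%):\n")
  print(table(lab))
})

#' @describeIn FitResult-class fitted circuit parameters.
#' @param x object.
#' @export
setMethod("fittedParams", "FitResult", function(x) x@params)

#' @describeIn FitResult-class weighted residual sum of squares at optimum.
#' @export
setMethod("fitObjective", "FitResult", function(x) x@objective)

#' @describeIn FitResult-class convergence flag of the best restart.
#' @export
setMethod("isConverged", "FitResult", function(x) x@converged)

#' @describeIn FitResult-class stored goodness of fit.
#' @param spectrum a [FitResult] (accessor form of [rSquared()]).
#' @param params unused in the accessor form.
#' @export
setMethod("rSquared", signature("FitResult", "missing"),
          function(spectrum, params) spectrum@rSquared)

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (R^2 = %.6f, converged = %s, restarts = %d)\n",
              object@rSquared, object@converged, object@restartsUsed))
  show(object@params)
})

#' @describeIn PCAModel-class orthonormal loading matrix.
#' @param x object.
#' @export
setMethod("pcaLoadings", "PCAModel", function(x) x@loadings)

#' @describeIn PCAModel-class explained-variance fractions per component.
#' @export
setMethod("explainedVariance", "PCAModel", function(x) x@varianceRatios)

#' @describeIn PCAModel-class number of selected components.
#' @export
setMethod("nComponents", "PCAModel", function(x) x@nSelected)

setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel: %d features, %d component(s) selected\n",
              nrow(object@loadings), object@nSelected))
  k <- min(5L, length(object@varianceRatios))
  cat("  leading variance fractions:",
      paste(sprintf("%.3f", object@varianceRatios[seq_len(k)]),
            collapse = " "), "\n")
})

#' @describeIn FeatureMatrix-class samples x features matrix.
#' @param x object.
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @describeIn FeatureMatrix-class class label (wt%) per row.
#' @export
setMethod("mineralContent", "FeatureMatrix", function(x) x@labels)

#' @describeIn FeatureMatrix-class feature-set mode.
#' @export
setMethod("featureMode", "FeatureMatrix", function(x) x@mode)

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix (%s): %d samples x %d features\n",
              object@mode, nrow(object@values), ncol(object@values)))
})

#' @describeIn EvaluationReport-class fraction of correct predictions.
#' @param x object.
#' @export
setMethod("accuracy", "EvaluationReport", function(x) x@accuracy)

#' @describeIn EvaluationReport-class averaged per-class precision;
#'   \code{average = "weighted"} (default) weights by actual class size,
#'   \code{"macro"} averages uniformly.
#' @param average averaging convention.
#' @export
setMethod("precisionScore", "EvaluationReport",
          function(x, average = c("weighted", "macro")) {
  average <- match.arg(average)
  if (average == "weighted") x@precisionWeighted else x@precisionMacro
})

#' @describeIn EvaluationReport-class confusion matrix (rows = actual).
#' @export
setMethod("confusionMatrix", "EvaluationReport", function(x) x@confusion)

#' @describeIn EvaluationReport-class per-class precision and recall.
#' @export
setMethod("perClassMetrics", "EvaluationReport", function(x) x@perClass)

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: accuracy %.3f, weighted precision %.3f\n",
              object@accuracy, object@precisionWeighted))
  print(object@confusion)
})
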