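#' Equivalent-circuit parameters for a bone impedance spectrum
#'
#' The four-parameter state of the series R-(R||CPE) circuit used to model a
#' bone sample between two plate electrodes: the bulk bone resistance
#' \code{Rb} (Ohm), the bone--electrode interfacial charge-transfer resistance
#' \code{Rct} (Ohm), and the constant-phase-element (CPE) pseudo-capacitance
#' with magnitude \code{Q} (S s^alpha) and exponent \code{alpha}
#' (dimensionless, 1 = ideal capacitor).
#'
#' @slot Rb bulk resistance in Ohm, positive.
#' @slot Rct charge-transfer resistance in Ohm, positive.
#' @slot Q CPE magnitude in S s^alpha, positive.
#' @slot alpha CPE exponent in (0, 1].
#' @export
setClass("CircuitParams",
  representation(Rb = "numeric", Rct = "numeric", Q = "numeric",
                 alpha = "numeric"))

setValidity("CircuitParams", function(object) {
  msg <- character()
  for (nm in c("Rb", "Rct", "Q", "alpha")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", nm))
  }
  if (length(msg) == 0L) {
    if (object@Rb <= 0) msg <- c(msg, "'Rb' must be > 0")
    if (object@Rct <= 0) msg <- c(msg, "'Rct' must be > 0")
    if (object@Q <= 0) msg <- c(msg, "'Q' must be > 0")
    if (object@alpha <= 0 || object@alpha > 1)
      msg <- c(msg, "'alpha' must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct circuit parameters
#'
#' @param Rb bulk bone resistance (Ohm).
#' @param Rct interfacial charge-transfer resistance (Ohm).
#' @param Q CPE magnitude (S s^alpha).
#' @param alpha CPE exponent in (0, 1].
#' @return a [CircuitParams] object.
#' @examples
#' circuitParams(Rb = 3.16e5, Rct = 2e7, Q = 2.4e-7, alpha = 0.9)
#' @export
circuitParams <- function(Rb, Rct, Q, alpha) {
  new("CircuitParams", Rb = as.numeric(Rb), Rct = as.numeric(Rct),
      Q = as.numeric(Q), alpha = as.numeric(alpha))
}

#' A single impedance spectrum
#'
#' Complex impedance measured (or simulated) on an ascending frequency grid.
#' The rectangular components are stored; modulus and signed phase (degrees,
#' negative = capacitive) are derived views.
#'
#' @slot frequencies frequency grid in Hz, positive and strictly ascending.
#' @slot zReal real part of the impedance, Ohm.
#' @slot zImag imaginary part of the impedance, Ohm.
#' @export
setClass("ImpedanceSpectrum",
  representation(frequencies = "numeric", zReal = "numeric",
                 zImag = "numeric"))

setValidity("ImpedanceSpectrum", function(object) {
  f <- object@frequencies
  msg <- character()
  if (length(f) < 1L) msg <- c(msg, "empty frequency grid")
  if (any(!is.finite(f)) || any(f <= 0))
    msg <- c(msg, "frequencies must be finite and > 0")
  if (length(f) > 1L && any(diff(f) <= 0))
    msg <- c(msg, "frequencies must be strictly ascending")
  if (length(object@zReal) != length(f) || length(object@zImag) != length(f))
    msg <- c(msg, "zReal and zImag must match the grid length")
  if (any(!is.finite(object@zReal)) || any(!is.finite(object@zImag)))
    msg <- c(msg, "impedance values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an impedance spectrum
#'
#' @param frequencies frequency grid in Hz (strictly ascending, positive).
#' @param zReal,zImag rectangular impedance components in Ohm, one value per
#'   frequency.
#' @return an [ImpedanceSpectrum].
#' @examples
#' s <- impedanceSpectrum(c(1, 10, 100), c(3, 2, 1), c(-3, -2, -1))
#' zMod(s)
#' @export
impedanceSpectrum <- function(frequencies, zReal, zImag) {
  new("ImpedanceSpectrum", frequencies = as.numeric(frequencies),
      zReal = as.numeric(zReal), zImag = as.numeric(zImag))
}

#' Labeled collection of bone impedance spectra
#'
#' An \linkS4class{SummarizedExperiment} whose assays \code{zReal} and
#' \code{zImag} hold the rectangular impedance components (rows = frequencies,
#' columns = samples), with the frequency grid in \code{rowData()$frequency_hz}
#' and the mineral-content class label (wt%) in
#' \code{colData()$label_wt_percent}. Datasets produced by
#' [generateDataset()] additionally carry the generating circuit parameters in
#' colData columns \code{true_Rb}, \code{true_Rct}, \code{true_Q},
#' \code{true_alpha}.
#'
#' @export
setClass("EISExperiment", contains = "SummarizedExperiment")

setValidity("EISExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("zReal", "zImag") %in% an))
    msg <- c(msg, "assays 'zReal' and 'zImag' are required")
  rd <- SummarizedExperiment::rowData(object)
  if (!"frequency_hz" %in% colnames(rd)) {
    msg <- c(msg, "rowData column 'frequency_hz' is required")
  } else {
    f <- rd$frequency_hz
    if (any(!is.finite(f)) || any(f <= 0) ||
        (length(f) > 1L && any(diff(f) <= 0)))
      msg <- c(msg, "'frequency_hz' must be positive and strictly ascending")
  }
  if (!"label_wt_percent" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'label_wt_percent' is required")
  if (length(msg)) msg else TRUE
})

#' Assemble an EISExperiment from spectra
#'
#' @param spectra list of [ImpedanceSpectrum] objects sharing one grid.
#' @param labels mineral-content class labels (wt%), one per spectrum.
#' @param sampleIds sample identifiers; defaults to \code{sample_1, ...}.
#' @param trueParams optional list of [CircuitParams] (one per spectrum) to
#'   store as ground truth.
#' @return an [EISExperiment].
#' @export
EISExperiment <- function(spectra, labels,
                          sampleIds = sprintf("sample_%d", seq_along(spectra)),
                          trueParams = NULL) {
  stopifnot(length(spectra) >= 1L, length(labels) == length(spectra),
            length(sampleIds) == length(spectra))
  if (anyDuplicated(sampleIds))
    stop("sample ids must be unique")
  grid <- frequencies(spectra[[1L]])
  same <- vapply(spectra, function(s)
    length(frequencies(s)) == length(grid) &&
      isTRUE(all.equal(frequencies(s), grid)), logical(1))
  if (!all(same))
    stop("all spectra must share one frequency grid; offending samples: ",
         paste(sampleIds[!same], collapse = ", "))
  zr <- vapply(spectra, zReal, numeric(length(grid)))
  zi <- vapply(spectra, zImag, numeric(length(grid)))
  dimnames(zr) <- dimnames(zi) <- list(NULL, sampleIds)
  cd <- S4Vectors::DataFrame(label_wt_percent = as.numeric(labels),
                             row.names = sampleIds)
  if (!is.null(trueParams)) {
    stopifnot(length(trueParams) == length(spectra))
    cd$true_Rb <- vapply(trueParams, Rb, numeric(1))
    cd$true_Rct <- vapply(trueParams, Rct, numeric(1))
    cd$true_Q <- vapply(trueParams, cpeQ, numeric(1))
    cd$true_alpha <- vapply(trueParams, cpeAlpha, numeric(1))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(zReal = zr, zImag = zi),
    rowData = S4Vectors::DataFrame(frequency_hz = grid),
    colData = cd)
  new("EISExperiment", se)
}

#' Result of fitting the equivalent circuit to one spectrum
#'
#' @slot params fitted [CircuitParams].
#' @slot rSquared coefficient of determination over concatenated real and
#'   imaginary components.
#' @slot objective weighted residual sum of squares at the optimum.
#' @slot converged whether the best Nelder-Mead start reported convergence.
#' @slot restartsUsed number of multistart runs performed.
#' @export
setClass("FitResult",
  representation(params = "CircuitParams", rSquared = "numeric",
                 objective = "numeric", converged = "logical",
                 restartsUsed = "integer"))

setValidity("FitResult", function(object) {
  msg <- character()
  if (object@objective < 0) msg <- c(msg, "'objective' must be >= 0")
  if (object@rSquared > 1 + 1e-12) msg <- c(msg, "'rSquared' cannot exceed 1")
  if (object@restartsUsed < 1L) msg <- c(msg, "'restartsUsed' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Principal component model for spectral feature matrices
#'
#' Loadings are eigenvectors of the sample covariance of the (already
#' standardized) training matrix, ordered by decreasing eigenvalue, with each
#' column's sign flipped so its largest-magnitude entry is positive. The
#' z-scoring statistics used upstream may be carried along so the model is
#' self-contained.
#'
#' @slot loadings features x components orthonormal matrix.
#' @slot varianceRatios fraction of variance per component (sums to 1).
#' @slot nSelected number of leading components selected.
#' @slot center per-feature means removed before projection.
#' @slot stdCenter,stdScale optional z-scoring statistics of the upstream
#'   standardization (empty when standardization is handled by the caller).
#' @export
setClass("PCAModel",
  representation(loadings = "matrix", varianceRatios = "numeric",
                 nSelected = "integer", center = "numeric",
                 stdCenter = "numeric", stdScale = "numeric"))

setValidity("PCAModel", function(object) {
  msg <- character()
  r <- object@varianceRatios
  if (any(r < -1e-12)) msg <- c(msg, "variance ratios must be non-negative")
  if (any(diff(r) > 1e-8)) msg <- c(msg, "variance ratios must be non-increasing")
  if (abs(sum(r) - 1) > 1e-6) msg <- c(msg, "variance ratios must sum to 1")
  if (object@nSelected < 1L) msg <- c(msg, "'nSelected' must be >= 1")
  if (object@nSelected > ncol(object@loadings))
    msg <- c(msg, "'nSelected' exceeds the number of components")
  if (length(msg)) msg else TRUE
})

#' Feature matrix for classification
#'
#' Rows are samples, columns are features: \code{log10|Z|} at each grid
#' frequency, optionally followed by the four fitted circuit-parameter
#' features \code{log10_Rb}, \code{log10_Rct}, \code{log10_Q}, \code{alpha}.
#'
#' @slot values samples x features numeric matrix, finite.
#' @slot labels mineral-content class label (wt%) per row.
#' @slot mode \code{"impedance_only"} or \code{"combined"}.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", labels = "numeric", mode = "character"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!object@mode %in% c("impedance_only", "combined"))
    msg <- c(msg, "mode must be 'impedance_only' or 'combined'")
  if (nrow(object@values) != length(object@labels))
    msg <- c(msg, "one label per row is required")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "feature values must be finite")
  if (length(msg)) msg else TRUE
})

#' Classifier evaluation on a labeled test set
#'
#' @slot accuracy fraction of correct predictions.
#' @slot precisionWeighted per-class precision averaged with weights equal to
#'   the actual class sizes.
#' @slot precisionMacro unweighted mean of per-class precisions.
#' @slot confusion class x class count matrix, rows = actual, columns =
#'   predicted.
#' @slot perClass data.frame with per-class precision and recall.
#' @export
setClass("EvaluationReport",
  representation(accuracy = "numeric", precisionWeighted = "numeric",
                 precisionMacro = "numeric", confusion = "matrix",
                 perClass = "data.frame"))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  cm <- object@confusion
  if (nrow(cm) != ncol(cm)) msg <- c(msg, "confusion matrix must be square")
  total <- sum(cm)
  if (total > 0 && abs(object@accuracy - sum(diag(cm)) / total) > 1e-12)
    msg <- c(msg, "accuracy must equal trace/total of the confusion matrix")
  if (length(msg)) msg else TRUE
})
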