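#' Build the classification feature matrix
#'
#' Impedance features are \code{log10|Z(f)|} at each grid frequency, in grid
#' order (the moduli span several decades, so the log scale keeps every
#' frequency informative after z-scoring). In \code{"combined"} mode the four
#' fitted circuit-parameter features \code{log10(Rb)}, \code{log10(Rct)},
#' \code{log10(Q)} and \code{alpha} are appended.
#'
#' @param experiment an [EISExperiment].
#' @param fits list of [FitResult] (one per sample, in column order or named
#'   by sample id); required for \code{mode = "combined"}.
#' @param mode feature-set mode.
#' @return a [FeatureMatrix].
#' @examples
#' ds <- generateDataset(generatorConfig(nPerClass = rep(2, 6)))
#' dim(featureValues(buildFeatures(ds)))   # 12 x 60
#' @export
buildFeatures <- function(experiment, fits = NULL,
                          mode = c("impedance_only", "combined")) {
  mode <- match.arg(mode)
  stopifnot(is(experiment, "EISExperiment"))
  zr <- SummarizedExperiment::assay(experiment, "zReal")
  zi <- SummarizedExperiment::assay(experiment, "zImag")
  x <- t(log10(sqrt(zr^2 + zi^2)))
  colnames(x) <- sprintf("log10Zmod_%.6g_hz", frequencies(experiment))
  if (mode == "combined") {
    if (is.null(fits) || length(fits) != ncol(experiment))
      stop("combined mode requires one fit per sample")
    if (!is.null(names(fits))) {
      missing <- setdiff(colnames(experiment), names(fits))
      if (length(missing))
        stop("missing fits for samples: ", paste(missing, collapse = ", "))
      fits <- fits[colnames(experiment)]
    }
    pm <- cbind(
      log10_Rb = vapply(fits, function(f) log10(Rb(fittedParams(f))), numeric(1)),
      log10_Rct = vapply(fits, function(f) log10(Rct(fittedParams(f))), numeric(1)),
      log10_Q = vapply(fits, function(f) log10(cpeQ(fittedParams(f))), numeric(1)),
      alpha = vapply(fits, function(f) cpeAlpha(fittedParams(f)), numeric(1)))
    x <- cbind(x, pm)
  }
  rownames(x) <- colnames(experiment)
  new("FeatureMatrix", values = x, labels = mineralContent(experiment),
      mode = mode)
}

#' Column standardization fitted on training rows
#'
#' \code{standardizeFit} computes per-column means and standard deviations;
#' \code{standardizeApply} z-scores a matrix with those statistics.
#' Zero-variance columns get unit scale, so training rows of a constant
#' column map to exactly 0.
#'
#' @param x numeric matrix (training rows for the fit).
#' @return \code{standardizeFit}: list with \code{center} and \code{scale};
#'   \code{standardizeApply}: the standardized matrix.
#' @export
standardizeFit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

#' @rdname standardizeFit
#' @param stats statistics from \code{standardizeFit}.
#' @export
standardizeApply <- function(x, stats) {
  sweep(sweep(x, 2L, stats$center, "-"), 2L, stats$scale, "/")
}

#' Principal component analysis with variance-threshold selection
#'
#' Components are the eigenvectors of the sample covariance of the input
#' (which is expected to be standardized already), ordered by decreasing
#' eigenvalue. The number of retained components is the smallest k whose
#' cumulative explained-variance fraction reaches \code{varianceThreshold},
#' floored at \code{minComponents}. Each loading vector is sign-flipped so
#' its largest-magnitude entry is positive, making scores deterministic.
#'
#' @param x standardized samples x features matrix with at least 2 rows.
#' @param varianceThreshold cumulative explained-variance target in (0, 1].
#' @param minComponents lower bound on the number of components.
#' @return a [PCAModel].
#' @export
pcaFit <- function(x, varianceThreshold = 0.90, minComponents = 1) {
  if (nrow(x) < 2L) stop("insufficient data: at least 2 rows are required")
  if (varianceThreshold <= 0 || varianceThreshold > 1)
    stop("varianceThreshold must lie in (0, 1]")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ratios <- ev / sum(ev)
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  k <- which(cumsum(ratios) >= varianceThreshold - 1e-12)[1L]
  if (is.na(k)) k <- length(ratios)
  k <- max(k, as.integer(minComponents))
  new("PCAModel", loadings = rot, varianceRatios = ratios,
      nSelected = as.integer(k), center = pc$center,
      stdCenter = numeric(0), stdScale = numeric(0))
}

#' Project a matrix onto the selected principal components
#'
#' @param x matrix with the same feature columns as the training matrix.
#' @param model a [PCAModel].
#' @return scores matrix, one column per selected component.
#' @export
pcaTransform <- function(x, model) {
  stopifnot(is(model, "PCAModel"))
  if (ncol(x) != nrow(model@loadings))
    stop("feature count does not match the PCA model")
  k <- model@nSelected
  s <- sweep(x, 2L, model@center, "-") %*% model@loadings[, seq_len(k), drop = FALSE]
  colnames(s) <- sprintf("PC%d", seq_len(k))
  s
}
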