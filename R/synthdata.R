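#' Configuration of the synthetic bone-spectrum generator
#'
#' Defines the simulated study: six mineral-content classes with the
#' per-class sample counts of the measured dataset (91 spectra in total),
#' lognormal inter-sample variability of the circuit parameters, and
#' multiplicative Gaussian measurement noise on the rectangular impedance
#' components.
#'
#' Class-mean circuit parameters follow the fitted-parameter trends of the
#' bone study: the bulk resistance Rb rises log-linearly with mineral content
#' (demineralization removes the resistive mineral phase), while the
#' interfacial parameters are two-plateau steps -- Rct high for nearly intact
#' bone (>= \code{plateauWt} wt%) and dropping to a demineralized steady
#' state, Q moving the opposite (slightly larger) way. The CPE exponent is
#' held fixed across classes.
#'
#' @param classLabels mineral-content classes in wt%.
#' @param nPerClass samples per class; defaults sum to 91.
#' @param paramCV inter-sample coefficient of variation of Rb, Rct and Q.
#' @param noiseSD standard deviation of the multiplicative spectral noise.
#' @param grid frequency grid (Hz).
#' @param seed generator seed.
#' @param rbLog10Range log10 Rb (Ohm) at 0 and 100 wt%; interpolated linearly
#'   in wt%.
#' @param rctPlateau named vector \code{c(low=, high=)}, Rct (Ohm) below/at-or-
#'   above \code{plateauWt}.
#' @param qPlateau named vector \code{c(low=, high=)}, Q (S s^alpha)
#'   below/at-or-above \code{plateauWt}.
#' @param alpha CPE exponent, constant across classes.
#' @param plateauWt wt% threshold separating the two interface plateaus.
#' @return a list of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(classLabels = c(0, 20, 40, 60, 80, 100),
                            nPerClass = c(16, 16, 16, 15, 12, 16),
                            paramCV = 0.10,
                            noiseSD = 0.02,
                            grid = makeGrid(),
                            seed = 42,
                            rbLog10Range = c(4, 5.5),
                            rctPlateau = c(low = 4e6, high = 2e7),
                            qPlateau = c(low = 3.6e-7, high = 2.4e-7),
                            alpha = 0.9,
                            plateauWt = 80) {
  stopifnot(length(classLabels) == length(nPerClass), all(nPerClass >= 1),
            paramCV >= 0, noiseSD >= 0,
            all(c("low", "high") %in% names(rctPlateau)),
            all(c("low", "high") %in% names(qPlateau)))
  structure(list(classLabels = classLabels, nPerClass = as.integer(nPerClass),
                 paramCV = paramCV, noiseSD = noiseSD, grid = grid,
                 seed = seed, rbLog10Range = rbLog10Range,
                 rctPlateau = rctPlateau, qPlateau = qPlateau, alpha = alpha,
                 plateauWt = plateauWt),
            class = "GeneratorConfig")
}

#' Class-mean circuit parameters for a mineral content
#'
#' @param wtPercent mineral content in [0, 100].
#' @param config a [generatorConfig()].
#' @return a [CircuitParams] with the class-mean values.
#' @examples
#' Rb(classMeanParams(100)) > Rb(classMeanParams(0))   # TRUE
#' @export
classMeanParams <- function(wtPercent, config = generatorConfig()) {
  if (!is.numeric(wtPercent) || length(wtPercent) != 1L ||
      wtPercent < 0 || wtPercent > 100)
    stop("wtPercent must lie in [0, 100]")
  r <- config$rbLog10Range
  hi <- wtPercent >= config$plateauWt
  circuitParams(
    Rb = 10^(r[1] + (r[2] - r[1]) * wtPercent / 100),
    Rct = unname(if (hi) config$rctPlateau["high"] else config$rctPlateau["low"]),
    Q = unname(if (hi) config$qPlateau["high"] else config$qPlateau["low"]),
    alpha = config$alpha)
}

#' Draw one synthetic spectrum
#'
#' Rb, Rct and Q are drawn lognormally around the class means with
#' coefficient of variation \code{paramCV} (the lognormal mean equals the
#' class mean; alpha is held fixed); the noiseless spectrum comes from
#' [circuitImpedance()]; multiplicative Gaussian noise \code{(1 + eps)},
#' \code{eps ~ N(0, noiseSD^2)}, is applied independently to the real and
#' imaginary components at each frequency, and the imaginary part is clamped
#' to be non-positive (the circuit is capacitive).
#'
#' Uses the current RNG state; seed upstream (as [generateDataset()] does)
#' for reproducibility.
#'
#' @param config a [generatorConfig()].
#' @param wtPercent class label in wt%.
#' @return list with \code{params} ([CircuitParams] actually used) and
#'   \code{spectrum} ([ImpedanceSpectrum]).
#' @export
sampleSpectrum <- function(config, wtPercent) {
  mp <- classMeanParams(wtPercent, config)
  cv <- config$paramCV
  sdlog <- sqrt(log(1 + cv^2))
  draw <- function(mean) {
    if (cv == 0) mean else stats::rlnorm(1, log(mean) - sdlog^2 / 2, sdlog)
  }
  p <- circuitParams(Rb = draw(Rb(mp)), Rct = draw(Rct(mp)),
                     Q = draw(cpeQ(mp)), alpha = cpeAlpha(mp))
  s <- circuitImpedance(p, config$grid)
  n <- length(config$grid)
  zr <- zReal(s)
  zi <- zImag(s)
  if (config$noiseSD > 0) {
    zr <- zr * (1 + stats::rnorm(n, 0, config$noiseSD))
    zi <- zi * (1 + stats::rnorm(n, 0, config$noiseSD))
  }
  zi <- pmin(zi, 0)
  list(params = p, spectrum = impedanceSpectrum(config$grid, zr, zi))
}

#' Generate a labeled synthetic bone EIS dataset
#'
#' Produces \code{nPerClass[i]} spectra for each class label under the seeded
#' noise model of [sampleSpectrum()]; the generating circuit parameters are
#' retained in the colData for parameter-recovery studies. Identical
#' configuration and seed give a bit-identical dataset.
#'
#' @param config a [generatorConfig()].
#' @return an [EISExperiment] with \code{sum(nPerClass)} samples.
#' @examples
#' ncol(generateDataset(generatorConfig(nPerClass = rep(1, 6))))   # 6
#' @export
generateDataset <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "GeneratorConfig"))
  withSeed(config$seed, {
    spectra <- list()
    params <- list()
    labels <- numeric(0)
    ids <- character(0)
    for (i in seq_along(config$classLabels)) {
      wt <- config$classLabels[i]
      for (k in seq_len(config$nPerClass[i])) {
        d <- sampleSpectrum(config, wt)
        spectra[[length(spectra) + 1L]] <- d$spectrum
        params[[length(params) + 1L]] <- d$params
        labels <- c(labels, wt)
        ids <- c(ids, sprintf("wt%03d_%02d", wt, k))
      }
    }
    EISExperiment(spectra, labels, sampleIds = ids, trueParams = params)
  })
}
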