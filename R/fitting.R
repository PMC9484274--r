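#' Options for circuit fitting
#'
#' @param nRestarts number of Nelder-Mead starts (first from
#'   [initialGuess()], the rest jittered).
#' @param maxIterations iteration cap per start.
#' @param relTol relative convergence tolerance on the objective.
#' @param weighting \code{"modulus"} (residuals scaled by 1/|Z_obs|^2, the
#'   default, so all decades of the spectrum contribute) or \code{"unit"}.
#' @param seed seed for the restart jitter.
#' @return a list of class \code{"FitOptions"}.
#' @export
fitOptions <- function(nRestarts = 8, maxIterations = 2000, relTol = 1e-10,
                       weighting = c("modulus", "unit"), seed = 1) {
  weighting <- match.arg(weighting)
  stopifnot(nRestarts >= 1, maxIterations >= 1, relTol > 0)
  structure(list(nRestarts = as.integer(nRestarts),
                 maxIterations = as.integer(maxIterations),
                 relTol = relTol, weighting = weighting, seed = seed),
            class = "FitOptions")
}

#' Heuristic starting parameters for a spectrum
#'
#' Reads the circuit elements off the spectrum shape: Rb from the
#' high-frequency modulus (where the CPE shorts the interface), alpha from
#' the low-frequency phase (CPE-dominated limit, phase -> -alpha * 90 deg), Q
#' from the low-frequency modulus after removing Rb, and Rct as a large
#' multiple of the low-frequency modulus (weakly identified when no
#' low-frequency plateau is visible).
#'
#' @param spectrum an [ImpedanceSpectrum] with at least 4 frequencies.
#' @return a [CircuitParams] start value.
#' @export
initialGuess <- function(spectrum) {
  stopifnot(is(spectrum, "ImpedanceSpectrum"))
  n <- length(frequencies(spectrum))
  if (n < 4L) stop("insufficient data: at least 4 frequencies are required")
  m <- zMod(spectrum)
  ph <- zPhase(spectrum)
  f <- frequencies(spectrum)
  rb <- max(m[n], .Machine$double.eps)
  alpha <- min(max(abs(ph[1L]) / 90, 0.05), 1)
  zlow <- max(m[1L] - rb, m[1L] * 1e-3)
  q <- 1 / (zlow * (2 * pi * f[1L])^alpha)
  circuitParams(Rb = rb, Rct = 100 * m[1L], Q = q, alpha = alpha)
}

# Weighted complex least-squares objective on the (log10 Rb, log10 Rct,
# log10 Q, alpha) scale. Out-of-range alpha is repelled by a penalty so the
# unconstrained simplex respects the physical box.
.fitObjective <- function(theta, zr, zi, w, grid) {
  alpha <- theta[4L]
  if (!is.finite(alpha) || alpha <= 0.01 || alpha > 1)
    return(1e12 * (1 + abs(alpha)))
  if (any(!is.finite(theta)) || any(abs(theta[1:3]) > 15))
    return(1e12)
  z <- 10^theta[1L] +
    1 / (10^-theta[2L] + 10^theta[3L] * (1i * 2 * pi * grid)^alpha)
  sum(w * ((Re(z) - zr)^2 + (Im(z) - zi)^2))
}

#' Fit the equivalent circuit to a spectrum
#'
#' Complex nonlinear least squares: minimizes the weighted sum of squared
#' rectangular residuals with the derivative-free Nelder-Mead simplex,
#' optimizing over \code{log10(Rb)}, \code{log10(Rct)}, \code{log10(Q)} and
#' \code{alpha} so positivity holds by construction. The first start is
#' [initialGuess()]; further starts jitter the log-parameters by up to
#' +-0.5 and alpha by +-0.1. The best objective over all restarts is
#' returned; failure to converge is reported through the \code{converged}
#' flag, not an error.
#'
#' @param spectrum an [ImpedanceSpectrum].
#' @param options a [fitOptions()] list.
#' @return a [FitResult].
#' @examples
#' truth <- circuitParams(1e4, 1e6, 1e-7, 0.8)
#' fit <- fitSpectrum(circuitImpedance(truth, makeGrid(1, 1e5, 30)))
#' rSquared(fit)
#' @export
fitSpectrum <- function(spectrum, options = fitOptions()) {
  stopifnot(is(spectrum, "ImpedanceSpectrum"),
            inherits(options, "FitOptions"))
  zr <- zReal(spectrum)
  zi <- zImag(spectrum)
  if (any(!is.finite(zr)) || any(!is.finite(zi)))
    stop("invalid data: non-finite impedance values")
  grid <- frequencies(spectrum)
  w <- switch(options$weighting,
              modulus = 1 / pmax(zr^2 + zi^2, .Machine$double.xmin),
              unit = rep(1, length(grid)))
  g <- initialGuess(spectrum)
  theta0 <- c(log10(Rb(g)), log10(Rct(g)), log10(cpeQ(g)), cpeAlpha(g))
  jitters <- withSeed(options$seed, {
    lapply(seq_len(options$nRestarts - 1L), function(i)
      c(stats::runif(3, -0.5, 0.5), stats::runif(1, -0.1, 0.1)))
  })
  best <- NULL
  for (r in seq_len(options$nRestarts)) {
    th <- theta0
    if (r > 1L) {
      th <- theta0 + c(jitters[[r - 1L]][1:3], 0)
      th[4L] <- min(max(theta0[4L] + jitters[[r - 1L]][4L], 0.05), 1)
    }
    res <- stats::optim(th, .fitObjective, zr = zr, zi = zi, w = w,
                        grid = grid, method = "Nelder-Mead",
                        control = list(maxit = options$maxIterations,
                                       reltol = options$relTol))
    if (is.null(best) || res$value < best$value) best <- res
  }
  p <- circuitParams(Rb = 10^best$par[1L], Rct = 10^best$par[2L],
                     Q = 10^best$par[3L], alpha = min(max(best$par[4L], 1e-6), 1))
  new("FitResult", params = p, rSquared = rSquared(spectrum, p),
      objective = best$value, converged = best$convergence == 0L,
      restartsUsed = options$nRestarts)
}

#' @describeIn rSquared coefficient of determination of a circuit model
#'   against a measured spectrum, computed over the concatenated real and
#'   imaginary components with each component centred on its own mean.
#' @export
setMethod("rSquared", signature("ImpedanceSpectrum", "CircuitParams"),
          function(spectrum, params) {
  pred <- circuitImpedance(params, frequencies(spectrum))
  zr <- zReal(spectrum); zi <- zImag(spectrum)
  ssTot <- sum((zr - mean(zr))^2) + sum((zi - mean(zi))^2)
  if (ssTot == 0)
    stop("degenerate data: observed impedance is constant")
  ssRes <- sum((zReal(pred) - zr)^2) + sum((zImag(pred) - zi)^2)
  1 - ssRes / ssTot
})

#' Fit the circuit to every sample of a dataset
#'
#' @param experiment an [EISExperiment].
#' @param options a [fitOptions()] list; the per-sample jitter seed is offset
#'   by the sample index so restarts differ across samples yet remain
#'   reproducible.
#' @return named list of [FitResult], one per sample.
#' @export
fitDataset <- function(experiment, options = fitOptions()) {
  stopifnot(is(experiment, "EISExperiment"))
  ids <- colnames(experiment)
  out <- lapply(seq_along(ids), function(i) {
    opts <- options
    opts$seed <- (options$seed + i) %% 2147483647
    fitSpectrum(getSpectrum(experiment, i), opts)
  })
  names(out) <- ids
  out
}

#' Tabulate fitted parameters
#'
#' @param fits list of [FitResult] from [fitDataset()].
#' @return data.frame with columns Rb, Rct, Q, alpha, r_squared, converged.
#' @export
fitTable <- function(fits) {
  data.frame(
    Rb = vapply(fits, function(f) Rb(fittedParams(f)), numeric(1)),
    Rct = vapply(fits, function(f) Rct(fittedParams(f)), numeric(1)),
    Q = vapply(fits, function(f) cpeQ(fittedParams(f)), numeric(1)),
    alpha = vapply(fits, function(f) cpeAlpha(fittedParams(f)), numeric(1)),
    r_squared = vapply(fits, rSquared, numeric(1)),
    converged = vapply(fits, isConverged, logical(1)),
    row.names = names(fits))
}
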