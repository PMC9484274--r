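#' Logarithmic frequency grid
#'
#' Builds the measurement grid: \code{nPoints} log-equispaced frequencies from
#' \code{fMin} to \code{fMax} inclusive. The default reproduces the
#' measurement protocol of 60 frequencies spanning 1 Hz to 100 kHz.
#'
#' @param fMin,fMax grid bounds in Hz, \code{0 < fMin < fMax}.
#' @param nPoints number of frequencies, at least 2.
#' @return numeric vector of frequencies in Hz, strictly ascending.
#' @examples
#' length(makeGrid())            # 60
#' makeGrid(1, 100, 3)           # 1, 10, 100
#' @export
makeGrid <- function(fMin = 1, fMax = 1e5, nPoints = 60) {
  if (!is.numeric(fMin) || !is.numeric(fMax) || fMin <= 0 || fMax <= fMin)
    stop("invalid bounds: need 0 < fMin < fMax")
  if (nPoints < 2) stop("nPoints must be >= 2")
  f <- 10^seq(log10(fMin), log10(fMax), length.out = nPoints)
  f[1] <- fMin
  f[nPoints] <- fMax
  f
}

#' Constant-phase-element impedance
#'
#' The CPE generalizes an ideal capacitor: Z_CPE(f) = 1 / (Q (j 2 pi f)^alpha).
#' Its phase is -alpha * 90 degrees at every frequency; alpha = 1 recovers
#' 1/(j omega C).
#'
#' @param Q CPE magnitude in S s^alpha, positive.
#' @param alpha CPE exponent in (0, 1].
#' @param f frequency (Hz), may be a vector.
#' @return complex impedance in Ohm, one value per frequency.
#' @examples
#' Arg(cpeImpedance(1e-6, 1, 10)) * 180 / pi   # -90
#' @export
cpeImpedance <- function(Q, alpha, f) {
  if (!is.numeric(Q) || length(Q) != 1L || Q <= 0)
    stop("Q must be a single positive number")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  if (any(f <= 0)) stop("frequencies must be > 0")
  1 / (Q * (1i * 2 * pi * f)^alpha)
}

#' Forward model of the bone equivalent circuit
#'
#' Impedance of the two-layer bone model: the bulk resistance in series with
#' the parallel combination of the charge-transfer resistance and the CPE,
#' \deqn{Z(f) = R_b + \frac{1}{1/R_{Ct} + Q (j 2\pi f)^\alpha}.}
#' At high frequency the CPE shorts the interface and Z tends to \code{Rb};
#' at low frequency the CPE blocks and Z tends to \code{Rb + Rct}.
#'
#' @param params a [CircuitParams] object.
#' @param grid frequency grid in Hz (see [makeGrid()]).
#' @return an [ImpedanceSpectrum].
#' @examples
#' s <- circuitImpedance(circuitParams(1e4, 1e6, 1e-7, 0.9), makeGrid())
#' zPhase(s)[1]
#' @export
circuitImpedance <- function(params, grid = makeGrid()) {
  stopifnot(is(params, "CircuitParams"))
  validObject(params)
  z <- params@Rb +
    1 / (1 / params@Rct + params@Q * (1i * 2 * pi * grid)^params@alpha)
  impedanceSpectrum(grid, Re(z), Im(z))
}

#' Rectangular/polar conversions
#'
#' \code{toPolar} converts a spectrum (or rectangular components) to modulus
#' (Ohm) and signed phase (degrees); \code{toRectangular} inverts it. The
#' round trip reproduces the input to floating-point accuracy.
#'
#' @param spectrum an [ImpedanceSpectrum], or a numeric vector of real parts
#'   when \code{zImag} is supplied.
#' @param zImag imaginary parts, required when \code{spectrum} is numeric.
#' @return \code{toPolar}: list with \code{modulus} and \code{phaseDeg};
#'   \code{toRectangular}: list with \code{zReal} and \code{zImag}.
#' @examples
#' toPolar(0, -1)                   # modulus 1, phase -90
#' @export
toPolar <- function(spectrum, zImag = NULL) {
  if (is(spectrum, "ImpedanceSpectrum"))
    return(list(modulus = zMod(spectrum), phaseDeg = zPhase(spectrum)))
  zr <- spectrum
  if (is.null(zImag)) stop("zImag is required for numeric input")
  if (length(zr) != length(zImag)) stop("length mismatch")
  list(modulus = sqrt(zr^2 + zImag^2),
       phaseDeg = atan2(zImag, zr) * 180 / pi)
}

#' @rdname toPolar
#' @param modulus impedance modulus in Ohm.
#' @param phaseDeg signed phase in degrees.
#' @export
toRectangular <- function(modulus, phaseDeg) {
  if (length(modulus) != length(phaseDeg)) stop("length mismatch")
  th <- phaseDeg * pi / 180
  list(zReal = modulus * cos(th), zImag = modulus * sin(th))
}
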