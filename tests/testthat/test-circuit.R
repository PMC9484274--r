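test_that("makeGrid spans the requested range log-uniformly", {
  g <- makeGrid()
  expect_length(g, 60)
  expect_identical(g[1], 1)
  expect_identical(g[60], 1e5)
  expect_true(all(diff(g) > 0))
  expect_equal(diff(log10(g)), rep(5 / 59, 59))

  expect_equal(makeGrid(1, 10, 2), c(1, 10))
  expect_equal(makeGrid(1, 100, 3), c(1, 10, 100))

  expect_error(makeGrid(-1, 10), "bounds")
  expect_error(makeGrid(10, 1), "bounds")
  expect_error(makeGrid(1, 10, 1), "nPoints")
})

test_that("CPE impedance has constant phase -alpha*90 and the closed-form modulus", {
  # ideal capacitor limit
  z <- cpeImpedance(1e-6, 1, c(1, 10, 1e3))
  expect_equal(Arg(z) * 180 / pi, rep(-90, 3))
  expect_equal(Mod(z), 1 / (1e-6 * 2 * pi * c(1, 10, 1e3)))

  # phase equals -alpha*90 degrees for arbitrary valid parameters
  for (alpha in c(0.3, 2 / 3, 0.9)) {
    z <- cpeImpedance(3e-7, alpha, makeGrid(1, 1e5, 7))
    expect_equal(Arg(z) * 180 / pi, rep(-alpha * 90, 7), tolerance = 1e-12)
  }

  # frozen value from an independent complex-arithmetic evaluation of
  # 1/(Q (j 2 pi f)^alpha) at Q = 1e-7, alpha = 2/3, f = 1
  expect_equal(Mod(cpeImpedance(1e-7, 2 / 3, 1)), 2936838.655,
               tolerance = 1e-9)

  expect_error(cpeImpedance(1e-7, 1.2, 1), "alpha")
  expect_error(cpeImpedance(1e-7, 0, 1), "alpha")
  expect_error(cpeImpedance(-1e-7, 0.5, 1), "Q")
})

test_that("circuit impedance matches an independent oracle and its limits", {
  p <- circuitParams(1e4, 2e6, 1.5e-7, 0.8)
  g <- makeGrid(1, 1e5, 25)
  s <- circuitImpedance(p, g)
  zo <- oracleCircuitZ(1e4, 2e6, 1.5e-7, 0.8, g)
  expect_equal(zReal(s), Re(zo), tolerance = 1e-12)
  expect_equal(zImag(s), Im(zo), tolerance = 1e-12)

  # high-frequency limit: CPE shorts the interface, Z -> Rb, phase -> 0
  hi <- circuitImpedance(p, c(1e8, 1e9))
  expect_equal(zMod(hi)[2], 1e4, tolerance = 1e-3)
  expect_lt(abs(zPhase(hi)[2]), 0.5)

  # zero-frequency limit: CPE blocks, Z -> Rb + Rct, phase -> 0
  lo <- circuitImpedance(p, c(1e-8, 1e-7))
  expect_equal(zMod(lo)[1], 1e4 + 2e6, tolerance = 1e-3)
  expect_gt(zPhase(lo)[1], -0.5)
})

test_that("alpha = 1 reduces to the analytic RC semicircle", {
  Rb <- 5e3; Rct <- 2e5; Q <- 2e-8
  s <- circuitImpedance(circuitParams(Rb, Rct, Q, 1), makeGrid(1e-3, 1e8, 4000))
  # Nyquist locus: (x - Rb - Rct/2)^2 + y^2 = (Rct/2)^2
  d <- sqrt((zReal(s) - Rb - Rct / 2)^2 + zImag(s)^2)
  expect_equal(d, rep(Rct / 2, 4000), tolerance = 1e-9)
  # apex: min of zImag equals -Rct/2 at omega = 1/(Rct Q)
  i <- which.min(zImag(s))
  expect_equal(zImag(s)[i], -Rct / 2, tolerance = 1e-4)
  expect_equal(2 * pi * frequencies(s)[i], 1 / (Rct * Q), tolerance = 0.02)
})

test_that("forward-model modulus decreases with frequency; z_imag stays <= 0", {
  set.seed(101)
  g <- makeGrid(1, 1e5, 200)
  for (i in 1:25) {
    p <- circuitParams(10^runif(1, 2, 6), 10^runif(1, 4, 9),
                       10^runif(1, -9, -5), runif(1, 0.1, 1))
    s <- circuitImpedance(p, g)
    expect_true(all(diff(zMod(s)) < 0))
    expect_true(all(zImag(s) <= 0))
  }
})

test_that("polar/rectangular conversions round-trip and match known points", {
  expect_equal(toPolar(1, 0), list(modulus = 1, phaseDeg = 0))
  expect_equal(toPolar(0, -1), list(modulus = 1, phaseDeg = -90))

  set.seed(7)
  zr <- rnorm(40, sd = 1e3); zi <- -abs(rnorm(40, sd = 1e3))
  p <- toPolar(zr, zi)
  r <- toRectangular(p$modulus, p$phaseDeg)
  expect_equal(r$zReal, zr, tolerance = 1e-12)
  expect_equal(r$zImag, zi, tolerance = 1e-12)

  s <- circuitImpedance(circuitParams(1e4, 1e6, 1e-7, 0.9))
  p <- toPolar(s)
  r <- toRectangular(p$modulus, p$phaseDeg)
  expect_equal(r$zReal, zReal(s), tolerance = 1e-12)

  expect_error(toPolar(1:3, 1:2), "length mismatch")
  expect_error(toRectangular(1:3, 1:2), "length mismatch")
})

test_that("spectrum validity rejects malformed grids", {
  expect_error(impedanceSpectrum(c(1, 1, 2), rep(1, 3), rep(0, 3)),
               "ascending")
  expect_error(impedanceSpectrum(c(-1, 2), c(1, 1), c(0, 0)), "> 0")
  expect_error(impedanceSpectrum(c(1, 2), 1, c(0, 0)), "match")
})
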