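test_that("initial guess reads plausible parameters off the spectrum", {
  # noiseless class-mean spectra with a visible high-frequency plateau
  for (wt in c(0, 40, 100)) {
    truth <- classMeanParams(wt)
    g <- initialGuess(circuitImpedance(truth))
    expect_lt(abs(Rb(g) - Rb(truth)) / Rb(truth), 0.05)
  }
  # ideal capacitor: phase at 1 Hz is deep, so the alpha guess is high
  s <- circuitImpedance(circuitParams(1e4, 1e7, 2.4e-7, 1))
  expect_gte(cpeAlpha(initialGuess(s)), 0.9)

  expect_error(initialGuess(impedanceSpectrum(c(1, 10, 100),
                                              c(3, 2, 1), c(-1, -1, -1))),
               "insufficient")
})

test_that("noiseless spectra are recovered within 0.1% with R^2 = 1", {
  set.seed(42)
  for (i in 1:20) {
    truth <- randomIdentifiableParams()
    s <- circuitImpedance(truth, makeGrid())
    fit <- fitSpectrum(s, fitOptions(seed = i))
    p <- fittedParams(fit)
    expect_lt(abs(Rb(p) - Rb(truth)) / Rb(truth), 1e-3)
    expect_lt(abs(Rct(p) - Rct(truth)) / Rct(truth), 1e-3)
    expect_lt(abs(cpeQ(p) - cpeQ(truth)) / cpeQ(truth), 1e-3)
    expect_lt(abs(cpeAlpha(p) - cpeAlpha(truth)), 1e-3)
    expect_gte(rSquared(fit), 0.9999)
  }
})

test_that("Rb is recovered to 10% median error at 2% spectral noise", {
  cfg <- generatorConfig(seed = 314, nPerClass = c(9, 8, 8, 8, 8, 9))
  ds <- generateDataset(cfg)  # 50 spectra across all classes
  fits <- fitDataset(ds, fitOptions(seed = 314))
  tab <- fitTable(fits)
  tp <- trueParams(ds)
  relErr <- abs(tab$Rb - tp$Rb) / tp$Rb
  expect_lte(median(relErr), 0.10)
  expect_gte(median(tab$r_squared), 0.99)
})

test_that("the reported objective equals an independent residual computation", {
  truth <- circuitParams(2e4, 5e5, 2e-7, 0.85)
  cfg <- generatorConfig(seed = 8)
  set.seed(8)
  s <- sampleSpectrum(cfg, 60)$spectrum

  # brute-force modulus-weighted sum of squares at pinned parameters
  zo <- oracleCircuitZ(Rb(truth), Rct(truth), cpeQ(truth), cpeAlpha(truth),
                       frequencies(s))
  w <- 1 / zMod(s)^2
  oracle <- sum(w * ((Re(zo) - zReal(s))^2 + (Im(zo) - zImag(s))^2))

  pinned <- boneEIS:::.fitObjective(
    c(log10(Rb(truth)), log10(Rct(truth)), log10(cpeQ(truth)),
      cpeAlpha(truth)),
    zReal(s), zImag(s), w, frequencies(s))
  expect_equal(pinned, oracle, tolerance = 1e-12)

  # and the fitter can only do at least as well as the truth
  fit <- fitSpectrum(s)
  expect_lte(fitObjective(fit), oracle)
})

test_that("objective never increases with additional restarts", {
  set.seed(5)
  s <- sampleSpectrum(generatorConfig(), 40)$spectrum
  objs <- vapply(c(1, 2, 4, 8), function(k)
    fitObjective(fitSpectrum(s, fitOptions(nRestarts = k, seed = 3))),
    numeric(1))
  expect_true(all(diff(objs) <= 1e-12))
})

test_that("unit-weighted fit agrees with a coarse grid-search oracle", {
  truth <- circuitParams(1e5, 3e5, 5e-8, 1)
  s <- circuitImpedance(truth, makeGrid(1, 1e5, 40))
  fit <- fitSpectrum(s, fitOptions(weighting = "unit"))

  # exhaustive 20^3 search over (log10 Rb, log10 Rct, log10 Q), alpha = 1
  lg <- function(x, half = 0.5) seq(log10(x) - half, log10(x) + half,
                                    length.out = 20)
  gridRb <- lg(1e5); gridRct <- lg(3e5); gridQ <- lg(5e-8)
  best <- c(NA, NA, NA); bestVal <- Inf
  for (a in gridRb) for (b in gridRct) for (q in gridQ) {
    zo <- oracleCircuitZ(10^a, 10^b, 10^q, 1, frequencies(s))
    v <- sum((Re(zo) - zReal(s))^2 + (Im(zo) - zImag(s))^2)
    if (v < bestVal) { bestVal <- v; best <- c(a, b, q) }
  }
  res <- diff(gridRb)[1]
  p <- fittedParams(fit)
  expect_lt(abs(log10(Rb(p)) - best[1]), res)
  expect_lt(abs(log10(Rct(p)) - best[2]), res)
  expect_lt(abs(log10(cpeQ(p)) - best[3]), res)
  expect_gt(cpeAlpha(p), 0.999)
})

test_that("R^2 follows its definition over concatenated components", {
  truth <- circuitParams(1e4, 1e6, 1e-7, 0.9)
  s <- circuitImpedance(truth)
  expect_equal(rSquared(s, truth), 1)

  # a parameter set predicting the per-component means scores ~0; any real
  # circuit differs, so check the definition algebraically instead
  off <- circuitParams(2e4, 2e6, 2e-7, 0.8)
  pred <- circuitImpedance(off, frequencies(s))
  ssRes <- sum((zReal(pred) - zReal(s))^2) + sum((zImag(pred) - zImag(s))^2)
  ssTot <- sum((zReal(s) - mean(zReal(s)))^2) +
    sum((zImag(s) - mean(zImag(s)))^2)
  expect_equal(rSquared(s, off), 1 - ssRes / ssTot)

  set.seed(12)
  noisy <- sampleSpectrum(generatorConfig(), 80)$spectrum
  expect_gte(rSquared(fitSpectrum(noisy)), 0.99)

  flat <- impedanceSpectrum(c(1, 2, 3, 4), rep(5, 4), rep(0, 4))
  expect_error(rSquared(flat, truth), "degenerate")
})

test_that("non-finite spectra are rejected", {
  s <- circuitImpedance(classMeanParams(50))
  zr <- zReal(s); zr[5] <- NA
  expect_error(impedanceSpectrum(frequencies(s), zr, zImag(s)), "finite")
})
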