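# Shared fixtures for the suite. Small datasets are built in code; the one
# default-size dataset and the seed-7 pipeline run are cached per session
# because several files assert on them.

tinyConfig <- function(seed = 11, nPerClass = rep(2L, 6), noiseSD = 0.02)
  generatorConfig(nPerClass = nPerClass, seed = seed, noiseSD = noiseSD)

defaultDataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateDataset(generatorConfig())
    cache
  }
})

pipelineSeed7 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- runPipeline(seed = 7, classifiers = c("logistic", "v_svm",
                                                      "neural_network",
                                                      "random_forest"))
    cache
  }
})

# Independent forward evaluation used as an oracle against circuitImpedance.
oracleCircuitZ <- function(Rb, Rct, Q, alpha, f) {
  w <- 2 * pi * f
  jw <- complex(modulus = w^alpha, argument = alpha * pi / 2)
  Rb + 1 / (1 / Rct + Q * jw)
}

randomIdentifiableParams <- function() {
  # geometries with both plateaus inside the 1 Hz - 100 kHz window
  rb <- 10^stats::runif(1, 3.5, 5)
  rct <- rb * 10^stats::runif(1, 1, 2)
  alpha <- stats::runif(1, 0.6, 0.95)
  zc <- rb * 10^stats::runif(1, 0.5, 1.5)  # |Z_CPE| at 1 Hz
  q <- 1 / (zc * (2 * pi)^alpha)
  circuitParams(rb, rct, q, alpha)
}
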