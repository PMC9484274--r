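Package: boneEIS
Title: Bone Mineral Content from Electrochemical Impedance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Equivalent-circuit analysis and machine-learning classification
    of bone electrochemical impedance spectra. Implements the series
    R-(R||CPE) forward model for cortical bone between plate electrodes,
    complex nonlinear least-squares fitting of the circuit by multistart
    Nelder-Mead, the wet-weight mass-balance estimate of mineral lost during
    demineralization, a seeded generator of labeled synthetic bone spectra,
    PCA feature reduction, and a comparison of nu-SVM, neural-network,
    random-forest and multinomial-logistic classifiers of mineral content.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    nnet,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'boneEIS-package.R'
    'circuit.R'
    'features.R'
    'fitting.R'
    'io.R'
    'mineral.R'
    'mlpipe.R'
    'synthdata.R'
    'utils.R'
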