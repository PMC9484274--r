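# boneEIS

Quantifying bone mineral content from electrochemical impedance spectra.

Bone healing is hard to monitor: radiography and CT are insensitive to
mineral content, costly, and carry radiation exposure. Electrochemical
impedance spectroscopy (EIS) offers a non-destructive electrical readout —
the complex impedance Z(f) of a bone sample clamped between plate
electrodes, swept over 1 Hz–100 kHz — that tracks the resistive mineral
(hydroxyapatite) phase. **boneEIS** implements the full analysis chain that
turns such spectra into a mineral-content classification, for
bioimpedance/biosensor researchers and for method development on simulated
data:

1. **Forward model** — the two-layer equivalent circuit

   Z(f) = R_b + 1 / ( 1/R_Ct + Q (j 2πf)^α )

   with bulk bone resistance R_b in series with the bone–electrode
   interface: charge-transfer resistance R_Ct in parallel with a constant
   phase element (CPE), Z_CPE = 1/(Q (jω)^α).
2. **Mineral mass balance** — wet-weight change during decalcifier
   treatment converted to mineral loss,
   W_M,lost = ρ_M ΔW_wet / (ρ_W − ρ_M), and to wt% labels.
3. **Circuit fitting** — complex nonlinear least squares (modulus-weighted)
   by multistart Nelder–Mead over log-parameters, with R² goodness of fit.
4. **Synthetic data** — a seeded generator of labeled 6-class bone spectra
   (91 samples by default) whose circuit parameters follow the measured
   trends of demineralized bone.
5. **Detection pipeline** — log10|Z| (± fitted-parameter) features,
   train-only z-scoring, PCA at a 90% variance threshold, stratified 70/21
   split, and ν-SVM / neural-network / random-forest / logistic
   classification with confusion-matrix evaluation.

## Worked example

```r
library(boneEIS)

## intact-bone class means and their spectrum
p <- classMeanParams(100)
p
#> CircuitParams: Rb = 3.162e+05 Ohm, Rct = 2e+07 Ohm, Q = 2.4e-07 S.s^alpha, alpha = 0.9
s <- circuitImpedance(p, makeGrid())
round(zPhase(s)[1], 2)   # phase at 1 Hz, degrees
#> -58.78

## fit the circuit back from the spectrum
fitSpectrum(s)
#> FitResult (R^2 = 1.000000, converged = TRUE, restarts = 8)
#> CircuitParams: Rb = 3.162e+05 Ohm, Rct = 2.001e+07 Ohm, Q = 2.4e-07 S.s^alpha, alpha = 0.9

## full pipeline: simulate 91 spectra, fit all, featurize, PCA, classify
res <- runPipeline(seed = 7)
print(res$comparison, digits = 3)
#>             mode          model accuracy precision_weighted n_components
#> 1 impedance_only       logistic    1.000              1.000            1
#> 2 impedance_only          v_svm    0.952              0.962            1
#> 3 impedance_only neural_network    1.000              1.000            1
#> 4 impedance_only  random_forest    0.952              0.962            1
#> 5       combined       logistic    1.000              1.000            1
#> 6       combined          v_svm    0.952              0.962            1
#> 7       combined neural_network    1.000              1.000            1
#> 8       combined  random_forest    0.952              0.962            1
confusionMatrix(res$reports$combined$v_svm)
#>       predicted
#> actual 0 20 40 60 80 100
#>    0   3  1  0  0  0   0
#>    20  0  4  0  0  0   0
#>    40  0  0  4  0  0   0
#>    60  0  0  0  3  0   0
#>    80  0  0  0  0  3   0
#>    100 0  0  0  0  0   3
```

The comparison table is the per-model test-set performance on the 21
held-out spectra (rows = actual class in the confusion matrix): here the
combined-feature ν-SVM classifies 20/21 test samples correctly (95.2%
accuracy, 96.2% weighted precision), with the one error between the two
most demineralized neighboring classes.

The mass-balance side:

```r
mineralLost(-0.216)          # 0.216 g wet-weight drop
#> $vLost 0.1   $wLost 0.316   # cm^3 and g of mineral lost
mineralContentPercent(0.316, 0.79)
#> 60                          # wt% remaining
```

A thin command-line front end over the same functions lives at
`inst/scripts/boneeis.R` (subcommands `simulate`, `mineral`, `fit`,
`featurize`, `classify`, `pipeline`).

See the vignette (`vignettes/bone-eis-methods.Rmd`) for the model
assumptions, generator calibration, and numerical design choices.

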