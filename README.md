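# lfnmr

Quantitative metabolomics for low-field (60 MHz) benchtop ¹H NMR
spectroscopy of biofluids — with a physics-based synthetic spectrum and
cohort generator, so the entire analysis protocol runs and is testable
without an instrument.

Benchtop NMR spectrometers bring metabolite quantification to the
point of care, but at 60 MHz chemical-shift dispersion is 6.7× smaller
than at 400 MHz: multiplets expand across the ppm axis, second-order
coupling distorts intensities, water presaturation attenuates nearby
analyte signals, and unequal T1 relaxation biases integrals. This
package implements the full analysis chain that copes with those
effects, for analytical chemists and metabolomics researchers working
with (or evaluating) low-field instruments:

* **Spectrum simulation** — exact diagonalisation of the isotropic spin
  Hamiltonian *H* = Σ νᵢI<sub>zi</sub> + Σ J<sub>ij</sub> **I**ᵢ·**I**ⱼ
  for small spin systems at any field, with presaturation attenuation
  (calibrated to 42% retention 18 Hz from the water carrier at 60 MHz),
  Ernst/saturation-recovery T1 factors and √n-scans noise scaling.
* **Preprocessing** — apodisation, Fourier transform, auto-phasing,
  baseline correction (constant / polynomial / asymmetric least
  squares), TSP chemical-shift referencing.
* **Quantification** — 27-bucket trapezoidal integration with exclusion
  regions, TSP / constant-sum / creatinine normalisation, SNR-based
  LOD/LOQ with a ≥10% water-overlap criterion (total-glucose LOQ
  8.0 mmol/L, i.e. 2.88 mmol/L in α-anomer units), and anomer-corrected
  glucose concentrations via the factor 100/36 = 2.78.
* **Chemometrics** — glog and Pareto transforms with an enforced
  pipeline order, FDR/Holm-corrected t tests, varimax PCA, OPLS-DA with
  10-fold Q² and permutation testing, Monte Carlo cross-validated
  linear-SVM ROC analysis, random forests.
* **Method agreement** — balanced two-way variance-components ANOVA
  (methods fixed, participants random), Tukey HSD, and agreement
  regressions with slope/intercept CI coverage flags.
* **Synthetic data** — calibration series, diabetic/control urine
  cohorts matching published group statistics, and four-method
  measurement tables, all seed-deterministic.

## Worked example

Calibrate glucose quantification on a synthetic 60 MHz series, then
discriminate a synthetic type 2 diabetic cohort from controls:

```r
library(lfnmr)

cfg <- acquisition_config()          # 60 MHz, 64 scans, presat at 4.95 ppm
ser <- generate_calibration_series(
  "glucose", c(2, 5, 8, 10, 20, 50, 100, 200, 400, 600), cfg, seed = 1)
model <- calibration_from_series(ser)
model
#> <calibration_model> glucose slope 0.075482, intercept 0.14051, r 0.9999
#>   LOD 2, LOQ 8 mmol/L (SNR-only LOQ 5)

quantify_from_calibration(3.5, model)
#>   concentration below_loq clamped
#> 1      44.50722     FALSE   FALSE
```

The fitted line is tightly linear (r = 0.9999). The LOQ is 8 mmol/L
total glucose: below that, the residual presaturated water signal
contributes ≥10% of the α-C1-H integration window even though the SNR
criterion alone would allow 5 mmol/L. A TSP-normalised ratio of 3.5
corresponds to 44.5 mmol/L total glucose, well above the LOQ.

```r
co <- generate_cohort(diabetes_cohort_spec(), cfg, seed = 1)
fm <- normalize_features(build_feature_matrix(co$spectra), "tsp")

m <- oplsda_fit(pareto_scale(glog_transform(fm)), co$groups)
m$Q2 <- cv_q2(pareto_scale(glog_transform(fm)), co$groups, seed = 2)
m
#> <oplsda> 1 predictive + 1 orthogonal; R2X 0.587, R2Y 0.969, Q2 0.904

mccv_svm_roc(fm, co$groups, n_features = 10, n_splits = 100, seed = 3)
#> <mccv_roc> 100 balanced splits, positive class 'diabetic'
#>  n_features    auroc   lower95 upper95
#>          10 0.976875 0.7109375       1
```

The OPLS-DA model separates the groups far above the conventional
Q² ≥ 0.40 cut-off, and the 10-feature MCCV-SVM classifier reaches a mean
held-out AUROC of 0.977 on this cohort (1.0 = perfect separation,
0.5 = none).

`run_pipeline(list(seed = 1))` executes the whole chain (simulate →
quantify → statistics) and writes CSV/JSON artefacts plus a manifest of
parameter values and output hashes; reruns with the same seed are
byte-identical.

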