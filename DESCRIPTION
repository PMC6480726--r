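Package: lfnmr
Title: Low-Field Benchtop NMR Metabolomics: Simulation, Quantification
    and Chemometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative biofluid metabolomics on low-field
    (60 MHz) benchtop proton NMR spectrometers. Simulates field-dependent
    1D spectra of small spin systems by exact Hamiltonian diagonalisation,
    models instrument effects (water-presaturation attenuation, T1
    saturation, noise versus scan number), and generates synthetic
    calibration series, urine cohorts and multi-method measurement tables
    with realistic statistical structure. Implements the downstream
    analysis protocol: FID preprocessing (apodisation, Fourier transform,
    phase and baseline correction, chemical-shift referencing), bucket
    integration with internal-standard and constant-sum normalisation,
    LOD/LOQ estimation, anomer-corrected glucose quantification,
    generalised-log and Pareto transforms, PCA, OPLS-DA with
    cross-validation and permutation testing, Monte Carlo cross-validated
    SVM ROC analysis, random-forest classification, and variance-component
    method-agreement analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    e1071,
    randomForest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
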