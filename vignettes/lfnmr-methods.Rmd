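---
title: "Low-field benchtop NMR metabolomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-field benchtop NMR metabolomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfnmr)
```

# Scope

lfnmr implements a complete quantitative metabolomics workflow for
low-field (60 MHz) benchtop ^1^H NMR analysis of biofluids, together with
a physics-based synthetic-spectrum and cohort generator that stands in for
instrument data. Every stage of the protocol — spectrum simulation,
FID preprocessing, bucket integration and internal-standard
quantification, LOD/LOQ determination, anomer-corrected glucose
estimation, multivariate discrimination, and multi-method agreement
analysis — is an exported, tested function, so the whole pipeline can be
exercised end to end on one CPU in minutes without a spectrometer.

# The spectrum model

## Spin physics

A metabolite is described as one or more small spin systems: groups of
equivalent protons with chemical shifts $\delta_i$ (ppm), proton counts,
relaxation times, and a symmetric scalar-coupling matrix $J_{ij}$ (Hz).
`compute_transitions()` diagonalises the isotropic liquid-state
Hamiltonian exactly,

$$H = \sum_i \nu_i I_{zi} + \sum_{i<j} J_{ij}\, \mathbf{I}_i \cdot \mathbf{I}_j,
\qquad \nu_i = \delta_i \cdot f_0,$$

with $f_0$ the spectrometer frequency in MHz, working in the full
$2^N$-dimensional product basis of each coupling-connected block of spins.
Line intensities are squared matrix elements of total $I_x$ between
eigenstates, rescaled so total intensity equals the proton count.
Because chemical-shift differences in Hz shrink with $f_0$ while $J$ does
not, second-order (strong-coupling) distortions and multiplet crowding at
60 MHz emerge from the model rather than being painted on; the simulator
reproduces the closed-form AB solution exactly and converges to binomial
first-order multiplets in the weak-coupling limit.

Blocks are capped at 8 expanded spins. Glucose is therefore modelled per
anomer as a coupled C1-H/C2-H pair (α: 5.25 ppm, $J$ = 3.8 Hz; β:
4.65 ppm, $J$ = 8.0 Hz, literature couplings) plus an uncoupled bulk
ring-proton envelope spread over 3.2–3.9 ppm, with the equilibrium
36:64 α:β anomer abundance applied by the generator. Only the C1-H
doublets and the 3.14–3.99 ppm bulk region are quantified, so this
simplification does not affect any reported quantity.

## Lineshapes and instrument effects

`render_spectrum()` places a unit-area Lorentzian of configurable FWHM
(default 0.55 Hz, the benchtop shim criterion) at each transition;
intensities are densities per ppm so trapezoidal bucket integrals are in
concentration × proton units. Three instrument effects multiply each
line:

* **Presaturation attenuation.** Continuous irradiation at the water
  frequency (4.95 ppm at 60 MHz, 4.80 ppm at 400 MHz) attenuates nearby
  analyte resonances. The retained fraction is modelled as a full-depth
  Gaussian dip, $f(\Delta) = 1 - e^{-(\Delta/w)^2}$, with width $w$
  calibrated per field/power anchor: 42% retention 18 Hz from the carrier
  at the 60 MHz default power (58 dB), and ~42% retention at the β-C1-H
  offset (60 Hz) with ~99% at the α-C1-H offset (180 Hz) for the 400 MHz
  default (50 dB) — the attenuation pattern implied by an observed 57:43
  anomeric intensity ratio against the true 36:64 equilibrium. A
  Lorentzian-shaped dip was considered and rejected: no Lorentzian
  depth/width pair can simultaneously give ~0.42 at 60 Hz and >0.99 at
  180 Hz, while the Gaussian form satisfies both anchors and the 60 MHz
  anchor exactly. Between power settings the width scales as
  $10^{-\Delta\mathrm{dB}/20}$ (6 dB per factor of two in irradiation
  amplitude), exposed as a calibration table for users with different
  instruments.
* **T1 saturation.** With repetition time $TR$ and 90° pulses each scan
  recovers $1 - e^{-TR/T_1}$ of the equilibrium magnetisation (the Ernst
  steady state is used for other pulse angles). Resonances with long
  $T_1$ are differentially suppressed: alanine's α-CH ($T_1$ = 6.94 s)
  against its CH~3~ (1.51 s) at a 6 s repetition drops the α-CH integral
  to 59% while the CH~3~ keeps 98%, breaking the nominal 1:3
  stoichiometry — a worked warning against short repetition times.
* **Noise.** Additive white Gaussian noise on the spectrum with standard
  deviation `noise_sigma`/√`n_scans`, so SNR scales with the square root
  of the scan count.

`synthesize_fid()` produces the matching complex time-domain signal (sum
of damped exponentials relative to a carrier at the centre of the
spectral window); its Fourier transform agrees with the direct rendering
within 2%, which the tests assert as a round-trip invariant.

# The synthetic-sample generators

## Preparation chemistry

`tsp_final_concentration()` does the dilution bookkeeping for the two
standard recipes: the biofluid preparation (450 µL supernatant + 50 µL
buffer + 50 µL ²H₂O with 0.05% w/v TSP) delivers 264 µmol/L TSP, and the
calibration-standard preparation (500 + 50 + 50 + 50 µL) delivers
223 µmol/L, using 172.26 g/mol for the TSP-d4 sodium salt.

## Calibration series

`generate_calibration_series()` renders one spectrum per analyte
concentration containing the analyte, TSP at the recipe concentration,
and a residual water resonance at the presaturation carrier. Two
generator constants are calibrated once against protocol-level anchors
and documented here:

* the residual water area (3.87 concentration × proton units, 6 Hz wide)
  places the ≥10% water-overlap interference threshold for the
  α-glucose-C1-H integration window between 7.5 and 8.0 mmol/L total
  glucose, so the quantification limit determined by
  `fit_calibration()` is 8.0 mmol/L total (2.88 mmol/L in α-anomer
  units);
* the per-scan noise σ of 20 gives the 8 mmol/L standard a flank-method
  SNR in the low tens at 64 scans, the order reported for that standard.

With presaturation enabled and no noise, the fitted TSP-normalised
calibration slope is 42% of the slope predicted from concentrations and
proton counts alone — the end-to-end consequence of the attenuation
anchor — and with presaturation disabled the slope matches proton
bookkeeping within 2%.

## Cohorts

`diabetes_cohort_spec()` transcribes the printed case-study group
statistics: 3-hydroxybutyrate 3.12 ± 0.99 (SEM, n = 10) versus
0.24 ± 0.06 (SEM, n = 14) mmol/L; creatinine 20.86 ± 10.56 versus
6.30 ± 0.99 mmol/L; and glucose detectable in 6/10 diabetic samples with
mean 155 ± 56 mmol/L among detectable samples (hence ≈93 mmol/L across
all ten). SEMs are converted to SDs with the printed group sizes.
Concentrations are drawn from moment-matched log-normal distributions:
at the large CVs these statistics imply (0.6–1.6), a zero-truncated
normal would inflate group means by 20–60% and break the printed
arithmetic, while the log-normal preserves mean and SD exactly and never
emits negative concentrations. A truncated-normal option is retained per
metabolite. Zero-inflation (the 0.6 glucose detection fraction) is a
Bernoulli mask applied after the positive draw.

Buckets whose group means are never printed (citrate, acetate,
hippurate, indoxyl sulphate, and others) carry literature-typical levels
flagged unanchored; only their reported direction of change is honoured,
and their within-group SDs are set to 0.6 × mean, the variability range
the anchored statistics themselves imply. A panel of background urine
metabolites (choline, betaine, TMAO, taurine, glycine, creatine,
succinate, glycolate) at identical levels in both groups keeps every
bucket non-empty.

## What the generator does not emulate

Samples are independent, shifts are fixed (no pH- or ionic-strength-
driven chemical-shift wander), lineshapes are pure Lorentzians (no shim
artefacts), there is no baseline drift or peak misalignment between
samples, and no drug metabolites or dietary xenobiotics. Passing tests
therefore demonstrate that the analysis chain is correct and well
calibrated on data matching the printed statistical structure; they do
not certify performance on real urine, where those artefacts dominate
the hard cases. One visible consequence: on synthetic cohorts the
discriminant models are close to saturated (Q² ≈ 0.8–0.9 against ≈0.63
reported for the real data), so removing the two glucose buckets — a
removal that markedly degraded the real-data model — changes the
synthetic Q² by less than replicate noise. The corresponding directional
check is kept in the acceptance suite and documented as a known
limitation of a moment-matched generator.

# Quantification protocol

`default_bucket_table()` ships the 27-bucket layout spanning
1.03–8.52 ppm: twelve resonance-anchored buckets (citrate 2.53–2.70,
N-acetyl 1.99–2.13, lactate 1.25–1.34, alanine 1.44–1.52, creatinine
2.98–3.14, acetone 2.14–2.29, acetate 1.87–1.99, 3-hydroxybutyrate
1.14–1.25, indoxyl sulphate 7.15–7.33, hippurate 7.55–7.71, glucose bulk
3.14–3.99 and α-C1-H 5.17–5.36 ppm) plus unanchored filler buckets
tiling the remaining unexcluded span. The exclusion list (residual
water 4.41–5.16 ppm and nine signal-free regions) is enforced at
construction: a bucket intersecting an exclusion is rejected.

Bucket integration is trapezoidal on the native grid over closed
intervals, with interpolated end values so adjacent buckets partition
their union exactly. SNR uses either the mean absolute value of ten
points flanking the peak window on each side, or the mean of the ten
largest-magnitude points in a designated noise region (9.0–9.5 ppm,
signal-free by construction); the extreme-value estimator is never the
larger of the two. LOD and LOQ are the lowest calibration concentrations
reaching SNR 3 and 10, with the LOQ additionally raised until the
residual-water contribution to the integration window falls below 10% of
its area (area, not height, is used — the protocol wording leaves this
open and area matches the integral-based quantification). α-anomer
concentrations convert to total glucose by the factor 100/36 = 2.78.

Normalisation is either to the TSP internal standard or constant-sum;
creatinine normalisation is additionally provided with a feasibility
check that warns at ≤100 MHz when the glucose bulk envelope (which abuts
the creatinine bucket at 3.14 ppm) exceeds the creatinine signal, the
situation that defeats creatinine normalisation of diabetic urine at
60 MHz.

# Preprocessing

The FID chain is apodisation → Fourier transform → phase correction →
baseline correction → TSP referencing, and is order-stable and
idempotent at its fixed point. Numerical choices: zero-filling to twice
the next power of two; first-point halving for a trapezoid-consistent
discrete transform; auto-phasing by Nelder–Mead minimisation of squared
negative intensity (recovering injected zero-order errors within 1°);
baseline modes `constant` (median), `poly` (OLS polynomial, exact for
offset/drift-only traces) and `als`, an asymmetric-least-squares
Whittaker smoother (λ = 10⁷, p = 10⁻³, 15 reweighting iterations)
followed by a peak-masked symmetric pass that interpolates under points
more than 3σ above the provisional baseline. The ALS mode follows slow
baseline curvature to within 5% of its amplitude; on extremely narrow
noise-free Lorentzians it can still clip a few percent of peak area via
the tails, so quantification of clean synthetic spectra should use the
exact polynomial/constant modes. TSP referencing finds the axis maximum
within ±0.3 ppm of zero (quadratic apex interpolation) and errors, with
an instruction to reference manually, if no candidate peak clears five
times the median absolute intensity.

# Chemometrics

The transform pipeline enforces the protocol order through state tags on
the feature matrix: normalise (TSP or CSN) → exclusion filtering → glog →
Pareto → model; calling a stage out of order raises an error. The
generalised logarithm $g(x) = \ln\{(x + \sqrt{x^2+\lambda})/2\}$ uses
λ = (median absolute intensity)² by default — a noise-scale proxy chosen
because the protocol names the transform but no parameter. Pareto
scaling divides centred columns by $\sqrt{s}$, leaving variance equal to
the original standard deviation.

Univariate screening is per-bucket two-sample t tests with
Benjamini–Hochberg FDR control by default (step-down Holm available);
under a simulated global null the realised false-discovery rate stays at
its nominal 5%. PCA retains components to a cumulative
explained-variance criterion (default 80%) with optional varimax
rotation under Kaiser normalisation (tolerance 10⁻⁸).

OPLS-DA is implemented as NIPALS orthogonal signal correction: the
default single class-orthogonal component is stripped before one
predictive PLS component is extracted (the number of orthogonal
components in the original analysis is unstated; one is the
conventional choice and it is configurable). Orthogonal scores are
uncorrelated with class membership by construction. Predictive ability
is Q² = 1 − PRESS/TSS over stratified 10-fold cross-validation, with
≥0.40 as the conventional cut-off; label permutation (p = (1 + #{perm ≥
obs})/(1 + B)) validates both Q² and R²Y. VIP scores are reported from
the predictive component; a PLS-DA VIP variant is available through the
same weights.

MCCV-SVM ROC analysis performs repeated balanced subsampling (2/3 of the
minority class per class for training, 100 splits — both unstated in the
protocol and fixed here), ranks features by training-set |t| only, fits
a linear-kernel maximum-margin classifier, and averages held-out AUROC
(rank-based, cross-checked against an independent ROC implementation)
with a 95% percentile interval. Random-forest classification uses the
protocol defaults of 500 trees and seven variables per node and reports
out-of-bag accuracy and confusion counts.

# Method agreement

`generate_method_comparison()` emulates the four-method urinary glucose
comparison (60 MHz NMR, 400 MHz NMR, enzymatic spectrophotometry,
colourimetric dipstick) as $y_{ij} = \mu_j b_i (1 + e_{ij})$ with
log-normal participant concentrations, method biases in the ratio of the
reported method means (92.9 : 82.0 : 98.8 : 128.7), and per-method CVs
defaulting to 8% (within-method analytical CVs are not reported; this is
a configuration value, not a transcribed fact).
`variance_components_anova()` fits the balanced two-way model
$y_{ijk} = \mu + M_i + P_j + e_{ijk}$ (method fixed, participant random)
by closed-form expected mean squares, truncating negative participant
components at zero with a flag; unbalanced tables are directed to the
regression path (a REML mixed model via lme4 is the natural extension
but is out of scope while the design stays balanced). Tukey HSD compares
method means; pairwise agreement uses ordinary least squares with
t-based 95% CIs and coverage flags for slope 1 and intercept 0 — OLS
because the reported gradient CIs are OLS-style; a Deming option would
acknowledge error in both methods but is not needed to reproduce the
reported analysis. Coverage is calibrated: across 1000 simulations the
slope CI covers the truth 95% ± 2%.

# Reproducibility and problem sizes

Every stochastic function takes an explicit seed and restores the
caller's RNG state; `run_pipeline()` derives per-stage child seeds from
one master seed and writes a manifest with MD5 hashes of every artefact,
so reruns are byte-identical. The shipped analyses use desk-scale sizes
chosen to keep the full suite in the minutes range: 10 001-point spectra
(0.001 ppm grid over −1 to 10.5 ppm), cohorts of 10 + 14 samples,
100 MCCV splits, 10-fold cross-validation, and 20 cohort replicates for
headline summaries; distributional checks use 10 000 concentration draws
without rendering spectra.
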