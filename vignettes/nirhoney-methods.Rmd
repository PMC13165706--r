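---
title: "Methods: honey NIR calibration, wavelength selection and botanical classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: honey NIR calibration, wavelength selection and botanical classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nirhoney` implements a complete chemometric pipeline for near-infrared
(NIR) spectra of honey: simulation of reference chemistry and
multi-instrument absorbance spectra, spectral pre-processing, a partial
least squares (PLS) engine with wavelength-importance diagnostics,
wavelength (band) selection, and multi-algorithm calibration and
botanical-origin classification under Venetian-blind cross-validation and
bootstrap resampling. This vignette is the package's account of the
underlying models, the tunable parameters and their defaults, and the
design decisions taken where several reasonable options existed.

## The scientific setting

Honey is a concentrated sugar matrix (roughly 60–70% glucose + fructose,
17–18% water) whose composition varies with botanical origin. Its NIR
spectrum between 850 and 2500 nm is dominated by O–H and C–H overtone and
combination bands of water and carbohydrates; minor constituents
(hydroxymethylfurfural, enzymes such as diastase) absorb weakly if at all.
Chestnut honey (CH) and polyfloral honey (PF) differ systematically in
glucose, reducing sugars, electrical conductivity, pH and HMF; a pooled
multifloral class (MF) is compositionally intermediate and heterogeneous.
The practical questions the pipeline addresses are (i) how well
physicochemical traits can be calibrated from spectra recorded on
instruments of very different range, resolution and noise, (ii) whether
restricting models to selected wavelength bands preserves accuracy while
improving parsimony, and (iii) how reliably botanical origin can be
classified.

## The synthetic-data generator

Because the pipeline must be testable without external data, the
`synthetic_data` module is first-class, tested code that generates both the
reference chemistry and the spectra, with planted ground truth that the
selection machinery can be scored against.

### Reference chemistry

`sample_composition()` draws per-sample traits from truncated normal
distributions. Class means for CH and PF are the package's composition
parameters (`composition_params()`); spreads are reconstructed from
per-variable standard errors of the mean at a group size of 30
(SD = SEM·√30). Key conventions:

* **Reducing sugars** are the exact sum of glucose and fructose in every
  record — a generator identity, used as a conservation test.
* **Electrical conductivity and pH** both reflect mineral/organic-acid
  content rather than a dedicated NIR chromophore, so both are driven by a
  single latent "mineral" level: the latent equals conductivity (mS/cm)
  and pH is the fixed line through the two class means
  (pH = 3.394 + 0.894·EC). The line's slope and intercept are solved from
  the CH and PF means, so class direction (CH higher in both) is built in.
* **MF** is a 50/50 mixture of the CH and PF parameter sets with 1.5×
  inflated SDs — a deliberately heterogeneous, intermediate class.
* Draws are truncated at ±4 SD and at physical bounds (all traits
  positive; moisture restricted to 13–25%, the operating range of
  refractometric moisture determination). Truncation at zero visibly
  raises the realised CH mean of HMF (configured 5.87 mg/kg, realised
  ≈ 7.3–8.4 mg/kg, SD 5.5): the distribution is asymmetric near the
  bound. The CH < PF direction of HMF is unaffected, which is what the
  composition tests assert.

### Spectra

`simulate_spectra()` builds clean absorbance as a Beer–Lambert sum of
Gaussian analyte bands,

$$A_i(\lambda) = s_i \cdot \ell \sum_a c_{ia} \sum_b
  \alpha_{ab}\, e^{-(\lambda - \mu_{ab})^2 / 2\sigma_{ab}^2}
  \; + \; \beta_0 + \beta_1 \lambda + \delta_{class(i)}
  \; + \; \varepsilon_i(\lambda),$$

with concentration $c$, effective pathlength $\ell$, per-scan scatter
factor $s_i \sim N(1, 0.02)$, linear instrument baseline, class-dependent
additive offset $\delta$, and detector noise
$\varepsilon \sim N(0, \text{noise\_sd})$. Two modelling choices matter:

* **The scatter factor multiplies the analyte absorption term only.** It
  represents effective-pathlength variation (sample presentation,
  scattering by sugar crystals); the additive baseline is an instrument
  property and is not scattered. Under whole-spectrum scatter, a
  full-spectrum model can re-estimate each scan's factor from any
  out-of-band region, so every band-restricted model would be
  systematically worse than full spectrum and no wavelength selection
  could ever be competitive — contrary to the well-established empirical
  finding that band-selected models are comparable. With scatter confined
  to the analyte term, the information about an analyte is carried by its
  band, and selection is a well-posed problem.
* **Band assignments are chosen to be identifiable.** Moisture carries
  the two water bands (1440 nm, σ = 20; 1920 nm, σ = 15); glucose carries
  the carbohydrate C–H combination band at 2100 nm (σ = 25, so its
  two-sigma informative set is exactly 2050–2150 nm); fructose carries a
  first-overtone band at 1460 nm (σ = 15) and a separated combination
  band at 2270 nm (σ = 30); HMF has a single band at 2150 nm with
  near-zero amplitude and diastatic activity has none, making both poorly
  predictable *by construction*; the mineral latent has one very broad,
  weak band at 1700 nm. An earlier design gave glucose a second band at
  1450 nm, 10 nm from the fructose and moisture bands; the three Gaussians
  were nearly collinear there, the region carried no information beyond
  the 2100 nm band, and greedy interval selection — correctly — refused to
  keep it. A generator whose planted truth cannot be recovered by a
  correct algorithm defeats its own purpose, so the informative sets were
  separated.

`informative_mask()` exposes the ground truth: the grid points within two
sigmas of any positive-amplitude band of the analyte(s) of interest.

### Instrument profiles

Three built-in profiles mirror the analytical configurations of interest:

| profile | range (nm) | step | mode | path | noise SD | saturation |
|---|---|---|---|---|---|---|
| `benchtop` | 850–2500 | 0.5 | transflectance | 1 | 0.005 | — |
| `wide_portable` | 1350–2500 | 16 | transflectance | 1 | 0.02 | — |
| `narrow_portable` | 1102–1600 | 2 | transmittance | 3 | 0.01 | 2.0 |

The narrow-range profile's long transmittance path (path multiplier 3)
drives clean absorbance above 2 in the strong 1400–1600 nm water/sugar
region; wherever the clean spectrum exceeds the saturation threshold the
noise SD is inflated 5-fold, reproducing the noisy high-absorbance
artefact seen with over-long cuvettes. The pathlength multipliers and
noise SDs are generator constants chosen to give the benchtop profile the
best signal-to-noise ratio and the portables realistic handicaps (coarse
16 nm sampling; range truncation plus saturation noise).

### What the generator does and does not emulate

It reproduces: class-dependent composition with realistic spreads;
duplicate scans per sample; the dominant honey absorption features; the
mean-absorbance ordering PF > MF > CH at every wavelength (via the class
offsets 0 / 0.09 / 0.18 plus composition); instrument-specific resolution,
noise and the narrow-range saturation artefact. It does **not** emulate
crystallisation kinetics, temperature effects, baseline drift over time,
wavelength-calibration error, or non-Gaussian band shapes, and the
class-offset mechanism is a stand-in for the complex scattering physics
that separates real floral classes. Consequently, passing recovery and
ordering tests demonstrates the *pipeline's* correctness under a known
truth — not that any particular accuracy will be attained on real honey.

## Pre-processing

`preprocess_spec()` fixes the operator order **scatter correction →
detrending → Savitzky–Golay → scaling**, the order in which combined
treatments are conventionally reported. Operators:

* **SNV** standardises each spectrum to mean 0, sample SD 1 (n − 1
  denominator).
* **MSC** regresses each spectrum on a reference (`x ≈ a + b·ref`) and
  returns `(x − a)/b`; the reference is the calibration-mean spectrum.
* **Linear detrending** removes each row's least-squares line over the
  wavelength index.
* **Savitzky–Golay** filtering (window 3–21, polynomial order 2–3,
  derivative 0–2) delegates to `signal::sgolayfilt`, which fits the local
  polynomial at the edges (same-length output, exact on polynomials of
  degree ≤ order) and scales derivatives by `1/step^deriv` so they are in
  absorbance per nm and comparable across instrument grids. Window 1 means
  no filtering and forces derivative 0.
* **Scaling**: mean centring or autoscaling (the notation
  "mean centring + scaling" denotes autoscaling).

`preprocess_fit_apply()` estimates every data-dependent statistic (MSC
reference, column means/SDs) on calibration rows only and reuses them on
validation rows; a dedicated test mutates the validation set and asserts
the calibration output is unchanged. `enumerate_preprocess_grid()` spans
the full chain space — 3 scatter × 2 detrend × 58 Savitzky–Golay
combinations × 3 scalings = 1044 chains — each with a stable
human-readable id.

## PLS engine and diagnostics

`fit_pls()` is classical univariate NIPALS with X-deflation only
(y-loadings recomputed per component), convergence tolerance 1e-10 and a
500-iteration inner cap (the inner loop converges immediately for a single
response; the loop is kept for the general contract). Components stop
early if the response residual is numerically exhausted. At full rank
(`n_lv = min(n − 1, p)`) the model reproduces ordinary least squares,
which the tests verify against `lm()`. Coefficients are stored per
component count, so reduced-rank predictions need no refit. One point
worth knowing: PLS does *not* generally fit an exactly linear target with
fewer components than the predictor rank — exactness requires the solution
to lie in the Krylov space spanned by the extracted components — so
exact-fit tests are pinned at full rank.

Since the VIP and Selectivity Ratio formulas are not uniquely fixed by
name, the standard literature definitions are used:

* **VIP**: $\mathrm{VIP}_j = \sqrt{p \sum_a SS_a (w_{ja}/\lVert w_a\rVert)^2 / \sum_a SS_a}$,
  with $SS_a$ the response sum of squares explained by component $a$. The
  squared VIPs average to exactly 1, which every fitted model in the test
  suite asserts.
* **SR** (target projection): predictors are projected onto the normalised
  regression vector; SR of a variable is its explained sum of squares
  divided by its residual sum of squares. Variables with numerically zero
  residual variance receive the maximum finite SR (logged), keeping the
  profile finite.

`rmsecv()` pools all held-out residuals before squaring and averaging, so
its value is invariant to fold relabelling; an internal multi-component
variant computes the whole 1..A profile from one fit per fold.

## Wavelength selection

The cascade is: full-spectrum PLS → VIP/SR candidacy mask → interval
construction → greedy interval combination (siPLS) → optional CARS-PLS
refinement.

* **Candidacy**: a wavelength is a candidate when VIP ≥ 1.0 *and* its SR
  exceeds the 0.75 quantile of the SR profile. If the joint mask is empty
  the rule falls back to VIP alone (logged); if still empty, the error
  instructs full-spectrum use. Runs of candidates separated by ≤ 2
  non-candidates are merged and runs shorter than 5 grid points are
  discarded; both constants are package defaults chosen to bridge noise
  speckle without inventing intervals (neither is externally prescribed).
* **siPLS** (`sipls_search()`): forward greedy search over the candidate
  intervals. Each step evaluates the RMSECV of the current selection plus
  one more interval, with the latent-variable count chosen from 1..10 by
  inner minimum; the interval with the largest decrease is accepted while
  the relative improvement is at least 0.5%. Ties break toward the lower
  start index, making the search deterministic; the RMSECV trajectory is
  non-increasing by construction.
* **CARS-PLS** (`cars_pls()`): the single stated decay rate is read as a
  per-iteration retention ratio, $r_i = \max(\mathrm{round}(p\,·\,0.9^i),\,30)$
  over 30 iterations (the classical two-parameter exponential is *not*
  used, because only one rate is specified). Each iteration fits PLS on a
  random 80% sample subset restricted to the surviving variables, keeps
  the top $r_i$ by |coefficient| (enforced selection), then thins by
  adaptive reweighted sampling — $r_i$ draws with replacement with
  probability ∝ |coefficient|, keeping unique draws and topping back up
  with the highest-|b| survivors if the unique count falls below the
  30-variable floor, so the retention invariant always holds. The
  iteration with minimal RMSECV defines the selection; everything is
  reproducible from the seed. CARS operates on single wavelengths
  (standard practice) and is applied after siPLS as a refinement.

## Model evaluation

* **Venetian-blind folds**: row *j* in stable sample order goes to fold
  (j − 1) mod k, k = 5 by default.
* **Learners**: PLS (in-package), kNN (in-package; Euclidean or Manhattan,
  neighbour-mean regression / majority-vote classification with
  distance-then-alphabetical tie-breaks), random forests (`ranger`,
  200–500 trees, depth 10–20, seeded), SVM/SVC (`e1071`; linear,
  polynomial, RBF, sigmoid). kNN, RF and SVM operate on PCA scores
  (`pca_compress()`, components estimated on calibration rows only); PLS
  projects for itself. Default hyperparameter grids are package choices:
  PLS latent variables {2,4,6,8,10}, kNN k = 5, RF 300 trees / depth 15,
  SVM cost 1, 8 principal components.
* **Metrics**: regression R² (about the mean of the observed response),
  RMSE, MAE; classification accuracy, balanced accuracy (mean class-wise
  recall), macro-F1 (undefined per-class F1 set to 0, logged), and MCC.
  For more than two classes the MCC is the correlation-coefficient
  generalisation over the C×C confusion matrix, which reduces exactly to
  the familiar binary formula at C = 2; the tests verify both against a
  per-sample counting oracle. Balanced accuracy equals accuracy under
  class balance and falls below it for majority-vote behaviour under
  imbalance — the constructed 74/26 example reproduces accuracy 0.74
  against balanced accuracy 0.50.
* **Validation schemes**: Venetian-blind 5-fold with pooled held-out
  predictions, or bootstrap (100 iterations by default) scoring
  out-of-bag rows with pre-processing and PCA refitted inside every
  iteration and per-iteration metrics averaged (dispersion retained).
* **Grid search**: exhaustive over chains × models; tuning criterion RMSE
  (regression) or macro-F1 (classification), ties broken by fewer latent
  variables / components, then lexicographic chain id. Where a "best"
  model must be reported by R² instead, the leaderboard retains every
  combination so either criterion can be applied; RMSE is the default
  because it is the tuning criterion.

A regression test constructs a dataset with gross fold-wise scale
heterogeneity and verifies that honest per-fold refitting differs from a
leaky variant that transforms all rows once — i.e. the pipeline cannot
silently leak validation information.

## Workflow layer and composition ANOVA

`run_workflow()` chains simulation (or CSV input) → replicate averaging →
alignment → optional band selection → grid search, logging one line per
stage, and is byte-reproducible given the config. Band selection is
performed once per target on the first candidate chain's pre-processed
spectra, and the selected mask is applied for all grid candidates — a
deliberate economy: re-selecting per chain would multiply cost with little
benefit at these problem sizes. `compare_workflows()` reports the metric
delta and the variable-count delta per target with a ±0.02 neutrality
margin.

`composition_anova()` compares CH and PF trait by trait with one-way
ANOVA (MF excluded: a pooled multifloral class is not a homogeneous
group), reports group means, the F-test p-value, and a single pooled SEM
per trait computed as √(MSE/n) with n the per-group size — the convention
matching a table that prints one SEM per variable. Shapiro–Wilk normality
p-values on the residuals are reported but not gating, since no remedial
action is prescribed. With two groups the F-test equals the squared
pooled t-test, which the tests assert.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data at
the package's default study size: 78 samples (30 CH / 30 PF / 18 MF),
duplicate scans, 3301-point benchtop spectra. Stochastic properties use
10 seeds (band-selection recovery), 100 runs (CARS survival, ANOVA
direction, VIP/SR rank simulations), or 5 seeds × 3 levels (noise
monotonicity). Numerical tolerances: SNV/detrend exactness 1e-12;
Savitzky–Golay polynomial exactness 1e-8 (edges included); PLS-vs-OLS
1e-6; metric-oracle agreement 1e-10; CSV round-trip 1e-12. Degenerate
inputs (zero-variance rows or responses, empty folds, out-of-range
components, sub-floor CARS dimensions) raise informative errors rather
than producing silent results.

## Known limitations

* Cross-validated grid-search performance is an optimistic estimate of
  generalisation; there is no nested CV or external validation set.
* The generator's class-offset mechanism is a simplification of
  scattering physics; absolute synthetic accuracies (e.g. glucose
  R² ≈ 0.99 on the benchtop profile) exceed what real honey data yield
  and should be read only through the *comparisons* the tests make
  (instrument ordering, selection recovery, direction of composition
  contrasts).
* PLS is univariate (one response at a time); no PLS2, kernel PLS or
  O-PLS.
* No vendor binary spectra formats and no wavelength interpolation
  between instruments; spectra exchange uses the package's wide CSV
  dialect.
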