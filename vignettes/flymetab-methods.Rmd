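---
title: "Models and methods behind flymetab"
author: "flymetab authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flymetab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flymetab)
```

# The problem

Untargeted LC-MS metabolomics of an inbred fly panel produces a table of
thousands of m/z features (each defined by mass-to-charge ratio, retention
time, and ion intensity) measured across a factorial design: genotype
lines crossed with sex and a ladder of collection ages, with replicate
pools of a few flies per cell, on two chromatography columns whose feature
sets partially overlap. The questions such a design can answer — which
features change with age and in which direction, which differ between the
sexes, how much intensity variation is heritable, whether the metabolome
predicts age and sex, and which metabolic pathways are over-represented in
each answer — all require statistical machinery whose behaviour should be
verified before it touches real data. flymetab packages that machinery
together with a synthetic-data generator that emulates the design with
*known* planted structure, so every stage is testable by parameter
recovery rather than by eyeballing.

# The synthetic-data generator

`generate_table()` simulates log-normal intensities: on the log scale the
per-feature signal is

$$y_{is} = b_i + a_i z(\mathrm{age}_s) + c_i x(\mathrm{sex}_s)
  + u_{i,\ell(s)} + \text{interactions} + \varepsilon_{is},$$

with baseline $b_i \sim N(13.8, 1.5^2)$ (a wide instrument-scale dynamic
range), an age trend that is linear in the *rank* of the age level (the
ladder is ordered but unevenly spaced; a non-monotone "hump" mode is
provided to exercise the ordered-factor tests), a signed sex shift, line
effects $u_{i\ell} \sim N(0, \sigma^2_B)$ for the genotype-carrying
features, sex-specific age slopes, line-specific age slopes, line-specific
sex shifts, and residual noise of variance $\sigma^2_W$ (default 1,
i.e. a raw-scale coefficient of variation of about 130%, which is what
biological replicate pools of whole flies typically show). Raw intensities
are the exponentiated signal. The defaults — 15 lines, both sexes, ages
3–81 d, two replicate pools of three flies, 3091 + 3714 features with a
30% overlap of underlying chemicals between columns — mirror the design
the package targets. Chemicals shared between columns carry identical
ground truth and baseline but independent residual noise, since the two
chromatographies measure the same molecule with unrelated technical error.

Planted effect *fractions* default to values in the range such factorial
screens report (a few percent of features per age direction, tens of
percent for sex, about ten percent for genotype and the age-by-genotype
interaction), and effect magnitudes are log-normal around one log unit.
The per-feature ground truth records every planted sign, magnitude,
per-line shift, and the true intraclass correlation
$\sigma^2_B/(\sigma^2_B+\sigma^2_W)$, and is the oracle all recovery tests
compare against.

Missingness is left-censoring-like: the probability that a cell goes
missing is a decreasing logistic in log intensity, centred at a
detection-threshold quantile (default 5%) with steepness 10 per log unit.
At infinite steepness exactly the lowest quantile is censored; at
steepness 0 the rate is flat and independent of intensity. MS non-detects
are intensity-driven, hence the default; missing cells are encoded as
absent values, never zero.

`plant_pathways()` additionally assigns synthetic compounds (random
monoisotopic masses) to a subset of features, rewrites those features' m/z
to the protonated-adduct mass of their compound so annotation can recover
them, and groups the compounds into pathways — optionally concentrating
one pathway's compounds on age-affected features to create a truly
enriched pathway. It operates on the table as well as the ground truth
because planting a compound is only meaningful if the feature's observed
m/z matches it.

What the generator does *not* emulate: raw spectra, chromatographic drift,
batch effects, technical duplicate injections, or correlated feature
blocks from shared adducts/isotopes of one compound. Passing recovery
tests therefore demonstrate the statistics are correct under the stated
model, not that real data meet the model.

# Quality control

`run_qc()` applies six steps in a fixed order: signal-to-noise filtering
on raw intensities, log transform, sex-wise missingness filtering,
least-squares imputation, m/z filtering, and per-sample mean centering.
The order matters and is guarded by a test: imputing before the
missingness filter would rescue features that are mostly absent in one
sex, and centering requires a complete table.

* **SNR** is mean over sample standard deviation of a feature's observed
  raw intensities; the threshold is inclusive (`>= 15` keeps by default)
  and constant features (SD 0) are kept but flagged, since zero observed
  noise is no evidence against a feature. Features with fewer than two
  observed cells have no defined SD and are removed. One caveat matters in
  practice: an SNR threshold of 15 corresponds to a raw-scale CV below 7%,
  which technical replicates can achieve but biological samples essentially
  never do — any log-normal feature with $\sigma_W = 1$ has CV ≈ 131% and
  SNR ≈ 0.76 no matter how strong its signal. The standalone
  `qc_config()` keeps 15 as its default for technical-replicate-style
  input; the *pipeline* default pairs the generator with a threshold of
  0.3, which removes only features whose variance has run away (it loses
  under 2% of planted effects at the default effect-size distribution).
* **Sex-wise missingness** removes a feature only when its missing
  fraction *exceeds* 5% in either sex — a feature at exactly the bound is
  kept. This filter systematically under-counts sex effects (features
  present in one sex only are discarded), which is a property of the
  design, not of the implementation.
* **Imputation** is the gene-wise least-squares variant: for each feature
  with missing cells, the K = 10 most correlated features (absolute
  Pearson correlation over jointly observed samples) provide
  single-regressor least-squares predictions, combined with weights
  proportional to $r^2$, using only neighbours observed at the target
  sample; the feature mean is the logged fallback. Observed cells are
  never altered, and a mask-and-recover benchmark against mean imputation
  is part of the acceptance suite.
* **m/z filter** keeps features strictly below 900 (acquisition optimised
  for the low-mass range), and **centering** sets every sample's mean over
  features to zero, the scale on which the factorial models operate.

# Per-feature factorial models

Each QC'd feature is fit by ordinary least squares on
age + sex + genotype + age:sex + age:genotype + sex:genotype (the
three-way term is available behind `model_spec(three_way = TRUE)`; neither
configuration is asserted as canonical). Age is an ordered factor with
orthogonal polynomial contrasts — categorical in spirit, but ordered so a
linear trend contrast exists; sex and genotype use sum contrasts. The
latest age (81 d) is dropped by default: late-age cells are incomplete in
real panels of this kind. Fits are vectorised across features through a
shared QR decomposition.

Age, sex and age:sex are tested by drop-term F-tests. Genotype and the
genotype-containing interactions are tested by likelihood-ratio tests of
nested OLS fits. One numerical point deserves emphasis: in a Gaussian
linear model the likelihood-ratio statistic $n\log(\mathrm{RSS}_r /
\mathrm{RSS}_f)$ is an exact monotone function of the drop-term F
statistic, so the two tests are the *same* test — provided the reference
distribution is the exact F. The asymptotic $\chi^2$ reference usually
quoted for likelihood-ratio tests is badly anticonservative at this
design's dimensions (110 fixed-effect columns against 360 samples: about
44% of null p-values fall below 0.05 for the age:genotype term), which
would wreck any false-discovery guarantee. flymetab therefore computes
likelihood-ratio p-values from the exact F reference and reports the
asymptotic $\chi^2$ p-value alongside (`p_chisq` in `fit_feature()`
output) for comparison with classical `lrtest`-style output.

Significance is controlled per factor by Benjamini–Hochberg at FDR 1%,
applied across all features separately for each factor and chromatography
column (the columns are never merged — the same chemical elutes and
ionises differently on each). Direction labels come from the sign of the
degree-1 polynomial contrast (age) and the sex contrast; a coefficient
within $10^{-10}$ of zero relative to the response scale is labelled flat
and excluded from both direction counts. The acceptance suite verifies
exact null calibration (mean realized false-discovery proportion at the
nominal level over repeated null simulations), ≥ 80% detection of planted
two-sigma effects per factor, and ≥ 95% direction agreement.

# Heritability

Each feature's log intensity is decomposed into between-line and
within-line variance under a mixed model with age and sex fixed and line
as a random intercept. The default estimator is REML (via `nlme::lme`); an
ANOVA method-of-moments estimator — equating between/within mean squares
of fixed-effect-adjusted residuals, with negative between-line estimates
truncated to zero and flagged — is implemented independently and serves as
the cross-check oracle in tests. The reported quantity is the intraclass
correlation $t = \sigma^2_B/(\sigma^2_B+\sigma^2_W)$, a heritability proxy
for line-structured data; a within-sample variant
$\sigma^2_B/(\sigma^2_B+\sigma^2_W/n)$ with $n$ the pooled flies per
sample is available behind `icc(per_individual = TRUE)` because the
placement of the pool size in such formulas varies across the literature —
the plain ICC is the default and the only reported form, and no conversion
to narrow-sense heritability is attempted. The screen ranks features by
$t$ within column, flags $t \ge 0.05$, and hands the 150 most heritable
features per column to enrichment. Acceptance checks recover planted ICC
levels {0, 0.1, 0.25, 0.4} to within ±0.05 on 200 features each (truncation
inflates the null group slightly; the bound accommodates that bias).

# Multivariate prediction

`pls_fit()` is a from-scratch NIPALS implementation: per component a
unit-norm X-weight vector, scores, X- and Y-loadings, and rank-one
deflation of both blocks. NIPALS was chosen over SIMPLS for transparency;
its correctness oracle is the least-squares limit (at the full rank of X,
PLS prediction equals ordinary least squares, asserted to $10^{-8}$), and
the dense model is additionally cross-checked against an independent PLS
implementation in the test suite. Scores are mutually orthogonal to
$10^{-8}$ by construction.

`spls_fit()` adds keepX-style sparsity — per component the weight vector
is truncated to its `keep` largest absolute entries (ties broken by index)
and renormalised before scores are computed — and classifies by nearest
training-class centroid in latent score space (a deliberate, documented
artifact choice; discriminant implementations differ here). Age is treated
as continuous days for regression and as one class per age level (hence
classes − 1 components) for discriminant analysis.

Validation follows three patterns:

* **Sparsity selection**: stratified ten-fold cross-validation over a
  kept-feature grid (default 1, 2, 3, 4, 5, 10, 25, 50), minimising the
  classification error rate; ties go to the sparsest value.
* **Train/test R²**: repeated random 2/3–1/3 splits (default 20 repeats);
  the component count is chosen by ten-fold CV inside each training set
  (capped at 10), and performance is the squared correlation between
  predicted and observed age on the held-out third.
* **Permutation nulls**: labels or ages are permuted without replacement
  and the *entire* selection-plus-fitting pipeline is re-run per
  permutation. One subtlety is handled explicitly: the grid-minimum CV
  error is an optimistically biased statistic, and under permutation it
  sits visibly below chance (≈ 0.43–0.46 for balanced classes) because
  hyperparameter selection exploits dataset-level spurious correlations
  that any same-dataset re-evaluation shares. `permutation_null()`
  therefore defaults to nested cross-validation — sparsity selected by
  inner CV within each outer training set, scored on the untouched outer
  fold — which is unbiased at chance (0.5); the `evaluation = "selection"`
  option reports the biased grid-minimum statistic instead, which is the
  right choice when comparing against an observed grid-minimum error, and
  is what the pipeline stage uses so its observed and permuted values are
  like-for-like. The acceptance suite runs the nested guard with 2000
  noise features against 100 samples: permuted-label error within 3
  standard errors of 0.5 and permuted-age R² below 0.05.

# Annotation and pathway enrichment

`annotate()` matches observed m/z values against a compound database under
positive-mode adduct rules (M+H, M+Na, M+K, M+H−H₂O; shifts include the
electron mass) within a relative tolerance of 10 ppm — a figure consistent
with a high-resolution instrument, and configurable. A feature may match
several compounds; that ambiguity is inherent to one-step annotation.

`enrich()` deliberately does *not* attempt network-based candidate
resolution (the route taken by network-aware annotation tools). Instead,
the observed statistic per pathway is simply the number of selected
features with at least one candidate compound in the pathway, and the null
distribution re-computes the same statistic on random same-size draws from
the feature universe. Because annotation ambiguity flows through observed
and null statistics identically, the empirical p-value
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{perm})$ stays
calibrated without resolving candidates — the add-one form avoids zero
p-values at finite permutation counts. A hypergeometric p-value on
annotated-feature counts is reported alongside as the parametric
reference. Selections come from `select_top()`: per column the 250
smallest-p features among positively and among negatively associated ones
for directed factors, or the 250 smallest-p features regardless of sign
for likelihood-ratio-tested interactions; ties break by feature id. The
heritability screen's top-150 list feeds the same machinery. Acceptance
checks that a planted enriched pathway ranks first at p ≤ 0.01 with 999
permutations, and that pathway p-values are uniform under uniform
assignment (the Kolmogorov–Smirnov check uses pathways of mixed sizes and
multi-adduct matching so the discrete p-value support is dense enough for
the test to be meaningful; permutation p-values on small pathways are
unavoidably discrete).

The bundled database (`synthetic_compound_db()`) is a small fixture of
common metabolites with genuine monoisotopic masses and synthetic pathway
groupings; it exists for examples and tests and is not a curated metabolic
model. User-supplied compound/pathway TSVs load through
`read_compound_db()`.

# Pipeline, configuration, and reproducibility

`run_pipeline()` chains simulate → qc → univariate → heritability →
multivariate → enrich, with every stage reading and writing tab-separated
UTF-8 artifacts (missing cells as empty fields) so stages re-run
independently; a JSON manifest records the configuration hash, the seed
and every file written. A single global seed deterministically derives an
independent substream per stage and per randomised operation, which makes
whole-pipeline runs byte-identical under a fixed seed — asserted in the
acceptance suite. Configuration is one nested YAML file with full
defaults; unknown keys are rejected rather than ignored.

The simulated sizes used by the automated checks are deliberately modest —
200 features per heritability level, 20 null simulations of 150 features
for calibration, 600 features for effect recovery, 2000 noise features for
the leakage guard, 800 features for enrichment recovery — chosen so each
property is measured with adequate precision while a full verification run
completes in a few minutes on one core. One statistical caveat is worth
recording: the null false-discovery check averages a small number of
highly variable realized proportions (any null simulation with a single
rejection contributes a proportion of 1), so at 20 simulations its
sampling noise is of the same order as the margin between the nominal
level and the bound; larger replications show the procedure calibrated at
the nominal level.

# Known limitations

* The generator's independence assumptions (features independent given the
  design; no batch or drift structure) make recovery results a statement
  about the statistics, not about robustness to real-data artifacts.
* The SNR filter's biological-sample form is only meaningful with a
  threshold matched to the intensity variance structure (see above);
  technical-replicate SNR is not simulated.
* Sparse PLS-DA selection is per component by hard truncation; no
  optimality claim is made relative to penalised formulations.
* Enrichment treats pathways marginally; overlapping pathways are tested
  separately and no cross-pathway adjustment beyond the empirical null is
  applied.
* Standard errors for the intraclass correlation are not provided; the
  screen is a ranking device, not an inferential endpoint.
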