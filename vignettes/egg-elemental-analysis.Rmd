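---
title: "Elemental profiling, risk scoring and chemometric classification of egg components"
author: "ovorisk"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: egg elemental analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`ovorisk` analyses wide multi-element concentration tables from chicken egg
components. The central container, `ElementExperiment`, extends
`SummarizedExperiment`: rows are the 64 elements of the analytical panel
(`elementPanel()`), columns are samples (one egg component each), and two
assays carry the concentrations (mg/kg dry weight) and the logical
non-detect mask. Column metadata pins the egg identifier, the component
(`white`, `yolk`, `shell`) and the hen rearing system (`home`,
`commercial`). Validity rules enforce non-negative concentrations, the
declared metadata vocabulary, panel membership and unique (egg, part)
pairs, so every downstream function can assume a well-formed table.

The panel groups the five macro-minerals, fifteen heavy/trace metals, six
alkaline and alkaline-earth metals, sixteen rare earth elements, six
technology-critical elements, six platinum-group elements, nine transition
and post-transition metals, and thorium. Published egg ICP-MS panels
name 61 of these symbols consistently and vary in the remainder of the
heavy/trace group; we complete it with Fe, Se and Ag, three trace
elements routinely quantified in egg surveys. Their calibration values are
marked `synthetic` in `defaultCalibration()`.

# Concentration conversion and non-detects

Digest measurements convert as `Ct = Cs * Vs / Wt` (µg/g dry weight, which
is numerically mg/kg). Units are pinned end to end — solution µg/L, volume
L, mass g — and the conversion lives in a single function,
`convertConcentration()`, which is linear in `Cs`, inversely proportional
to `Wt`, and propagates non-detects.

Left-censored cells must be resolved before statistics
(`substituteNondetects()`). Three policies are exposed because reported
summary tables rarely state their treatment: `zero` (the default for risk
scoring — a conservative under-count, since censored values are by
definition small and setting them to zero can only lower a hazard
quotient), `half_lod` (the common LOD/2 imputation, requiring an explicit
per-element LOD map), and `drop` (exclusion from summaries, which changes
the per-cell n). Substitution provenance is logged in the object metadata.
CSV parsing is strict: `"."` decimal separator, `ND`/empty cells as
non-detect flags, and thousands separators rejected rather than silently
mangled; writing uses 17 significant digits so a read–write–read round
trip is value-exact.

# Health-risk model

For a metal at concentration $C$ (mg/kg) in the consumed food, the Target
Hazard Quotient is

$$THQ = \frac{EF \cdot ED \cdot IR \cdot C}{BW \cdot AT \cdot RfD},$$

with exposure frequency $EF = 365$ d/yr, exposure duration $ED = 75.88$ yr
(average adult lifetime), intake rate $IR = 0.0328$ kg/person/day for
eggs, body weight $BW = 70$ kg, averaging time $AT = 365 \times 75.88$ d,
and the oral reference dose $RfD$ (stored in µg/kg/day exactly as
tabulated — Al 1000, Cr 1500, Mn 140, Co 43, Ni 20, Cu 40, Zn 300,
As 0.304, Cd 1, Sn 0.3, Hg 0.571, Pb 3.57 — and converted to mg/kg/day
once, inside `computeTHQ()`). With the defaults the time factor
$EF \cdot ED / AT$ cancels to exactly 1, so $THQ = C \cdot IR / (BW \cdot
RfD)$; the test suite asserts this cancellation. The TTHQ is the plain sum
over metals, with risk flagged if and only if TTHQ > 1.

`riskByGroup()` scores each egg on its edible fraction. The default
combination is the unweighted mean of the white and yolk concentrations —
the simplest reading of an "egg white + yolk" aggregate — with a
mass-weighted alternative (`whiteMassFrac`, default 0.3, approximating the
dry-matter split between white and yolk). The shell is excluded by
default: it is not eaten. Metals with no concentration data are skipped
with a warning, never imputed. Concentrations enter on the dry-weight
basis as given, with the intake rate as tabulated; no moisture correction
is applied, and users comparing against fresh-weight intake figures should
be aware of that mismatch.

One limitation worth stating: summing hazard quotients computed from
literature mean concentrations (bundled as
`referenceEdibleConcentrations()`) gives a TTHQ around 0.32, dominated by
Pb, Ni and Hg. Published per-egg TTHQ distributions for the same matrices
tend to centre lower; mean-based and per-sample aggregates, and
dry-versus-fresh-weight bases, do not commute. The package therefore
treats the TTHQ ≤ 1 safety bound — which holds comfortably either way —
as the quantitative claim, not any particular TTHQ magnitude.

# PCA with explicit outlier trimming

`pcaFit()` works on the auto-scaled (centred, unit-variance) matrix — the
standard choice for element data spanning five orders of magnitude, where
unscaled PCA would be a calcium/sodium plot. The decomposition is a plain
SVD for numerical stability; eigenvalues use the n−1 divisor; loadings are
unit-norm; and each component's sign is fixed so its largest-magnitude
loading is positive, making outputs deterministic. Contributions of
variable $j$ to dimension $k$ are $100\,w_{jk}^2$ (columns sum to 100),
with `topContributions()` exporting ranked tables against the
expected-average reference $100/p$. Variable coordinates (loading ×
component SD) are correlations when the input is standardised, hence
bounded by 1. A zero-variance column under scaling is an error naming the
column.

Exploratory egg studies typically trim a handful of visually obvious
outliers before refitting. `flagOutliers()` makes that step explicit and
automatic: the squared Mahalanobis distance on the first `dims` (default
2) score dimensions — sums of squared eigenvalue-standardised scores —
compared against the $\chi^2_{dims}$ quantile (default 0.999). On a
homogeneous Gaussian cloud of 100 samples this flags $n(1-q) = 0.1$
samples in expectation, which the tests confirm; spiked samples injected
by the generator at 10 SD are recovered exactly. For reproducing a
specific published trimming, `removeOutliers()` also accepts any
hand-specified report. Note one subtlety: trimming shrinks the leading
eigenvalues, so standardised distances of the survivors can *increase*
after a refit; the meaningful post-condition, asserted in the tests, is
that the trimmed cloud no longer triggers the flagging rule.

# Sparse PLS-DA

The discrimination engine is written from first principles. The class
factor becomes a one-hot indicator matrix, column-centred; X is
auto-scaled. Each NIPALS round alternates

1. $w \propto X^\top u$, normalised;
2. keepX selection: soft-threshold $w$ at its (keepX+1)-th largest
   absolute entry — e.g. $(0.9, 0.5, 0.1)$ with keepX = 2 becomes
   $(0.8, 0.4, 0)$ — then renormalise, so exactly keepX variables carry
   weight;
3. $t = Xw$, $c \propto Y^\top t$, $u \propto Yc$;

until $w$ converges (tolerance $10^{-9}$, cap 500 iterations). X is then
deflated by regression on $t$; Y is not deflated, which for PLS2 is
algebraically equivalent because the deflated part of Y is orthogonal to
all later scores — predictions use the accumulated coefficients
$W(P^\top W)^{-1} C^\top$. Weight signs follow the same
largest-entry-positive convention as the PCA. Scores are pairwise
orthogonal and weights unit-norm by construction; both are asserted after
every fit in the tests, and the full-keepX model is checked against an
independent eigen/SVD PLS2 oracle (and against mixOmics) to $10^{-6}$.

Prediction offers the three standard distance rules: `max` (argmax of the
predicted indicator response), `centroid` (nearest class centroid in
score space, Euclidean) and `mahalanobis` (nearest centroid under the
pooled within-class score covariance). Exact ties break deterministically
toward the first class in level order, with a warning.

`crossValidate()` tunes (ncomp, keepX, distance) by stratified k-fold
cross-validation (default 5 folds × 10 repeats), refitting scaling and
selection inside every training fold so nothing leaks from the held-out
fold. Both the overall error rate and the balanced error rate (the
unweighted mean of per-class error rates, insensitive to the 55:15 class
imbalance of the rearing systems) are reported per grid point; selection
minimises mean BER with ties broken toward fewer components, then smaller
keepX, then distance order — the most parsimonious of the equally good
models, since the selection rule itself is rarely reported in applied
work. The default keepX grid {1..10, 15, 17, 20, 30, 50} covers the
small-model and moderate-model regimes without exhaustive search.
`evaluateHoldout()` fits a chosen configuration on a stratified 70%
shuffle and reports the confusion matrix, accuracy, and macro-averaged
sensitivity/specificity (for two classes: the recalls of the first and
second class) on the 30% test set.

# The synthetic generator

`generateEggData()` stands in for an undeposited 70-egg survey. Its
defaults *are* the study design: 55 home-grown plus 15 commercial eggs,
three component samples each (210 rows), 64 elements.

**Marginals.** Concentrations are positive and right-skewed (reported
max/mean ratios up to ~3), so each (element, part, system) cell is
lognormal. Where a min–max envelope is reported, the log-scale SD is set
so ~99% of the mass falls inside the printed range
($\sigma = (\log\max - \log\min) / (2 \cdot 2.576)$); elements with only
a mean get a default geometric SD of 1.8, a typical trace-element spread,
documented as an assumption. The location parameter is always solved so
the distribution mean hits the target exactly
($\mu = \log m - \sigma^2/2$); the tests verify 2% recovery of the
egg-white zinc mean at 5000 eggs. Calibration rows resolve by
specificity: (element, part, system) over (element, part) over (element,
system) over (element).

**Correlation.** Within-sample dependence uses a single-factor Gaussian
copula per block on the latent normals: members load on a shared factor
with loading $\lambda$ and per-element signs, giving pairwise latent
correlation $\pm\lambda^2$. Defaults stay deliberately sparse — only the
relationships the exploratory analyses of such data describe: a
near-perfect negative Cu–Mg pair ($\lambda = 0.95$), a positive
{Rh, Sr, Ca, Ti, Cs} block and a positive light-REE block
($\lambda = 0.8$). Mg is described in the literature both as part of the
positive block and as Cu's near-perfect negative partner; both cannot
hold strongly, so Mg is kept in the (stronger) Cu–Mg pair.

**Rearing-system signal.** Seventeen elements are informative for the
system (`informativeElements()`): fourteen markers receive a log-scale
mean shift of `markerShift` SD units (default 0.75, half up for the
elevated system, half down for the other — a moderate, realistic
husbandry effect that yields held-out system accuracy in the low 80s
rather than a trivially separable cohort), and Al and Cr discriminate
through system-specific calibration means. `injectStructure()` applies
such shifts to any existing table (estimating per-part log-SDs from the
data), so the null case (`shift = 0`) and stronger effects are one call
away.

**Censoring and outliers.** Elements with a configured non-detect rate
(default 5% for Mn and Cr, whose reported ranges start at ND) are
left-censored at exactly that rate via the latent normal quantile. Three
outlier samples (the count such surveys typically remove) are spiked at
10 column SDs on five shared elements — a common contamination signature,
which is what makes them recoverable as a group by the score-distance
rule; count, magnitude, signature size and target part are configurable.

**What the generator does not emulate** — and hence what passing tests do
not show about measured data: instrument error structure (drift, isobaric
interference), digestion recovery variation, geographic provenance
effects, and the true 64 × 64 covariance beyond the named blocks. Tests
passing on this generator demonstrate the correctness and calibration of
the *methods*; they are not evidence about any particular real cohort.

# Pipeline and reproducibility

`reproduceStudy()` chains the stages — generate/load, summarise, full
PCA, outlier flagging, trimmed PCA, risk scoring, egg-part PLS-DA
(2 components, keepX (2, 1)), rearing-system PLS-DA (3 components,
keepX 17) — into a plain output directory with a JSON manifest recording
the package version, seed and MD5 of every file. Every random step is
seeded from the single master seed, so identical (input, config, seed)
reproduce identical hashes; a failing stage halts with an error naming
the stage while preserving completed outputs. A workflow engine would be
overkill at desk scale; a hashed manifest gives the same auditability.

# Numerical and testing choices

* Deterministic sign conventions (largest-magnitude entry positive) for
  both PCA loadings and PLS weights; deterministic tie-breaks with
  warnings.
* Oracles in the test suite are independent routes: `prcomp` for the PCA,
  a hand-written eigen/SVD PLS2 for the engine, mixOmics as an external
  cross-check only.
* Degenerate inputs fail loudly with named offenders: zero-variance
  columns, unknown metals (listing the known registry), missing LODs,
  column mismatches at prediction, classes smaller than the fold count.
* Problem sizes in the tests are chosen for tightness per unit time:
  property loops use n ≤ 50, p ≤ 10 instances; calibration convergence
  uses 5000 eggs; statistical properties (null BER near 0.5, marker
  recovery in at least half the runs) aggregate over 10–20 seeds.
* Stochastic assertions state their expected sampling error (e.g. the 2%
  zinc tolerance corresponds to more than two standard errors of a
  lognormal mean with geometric SD 1.8 at n = 5000).

# Known limitations

* The dry-weight/intake-rate mismatch in the risk model is inherited from
  the tabulated inputs and left uncorrected by default.
* Which metals enter a published TTHQ is often ambiguous (reference doses
  exist for metals without reported concentrations); the registry and the
  metal set are therefore explicit arguments everywhere.
* PCA variance fractions of a synthetic cohort need not match any
  published figure: they depend on the unobservable full covariance, and
  only the block structure is calibrated.
* The sparse selection on calibrated data is data-driven: Mg and Cd
  legitimately separate egg parts in the calibrated distributions, so the
  selected macro trio can be {Na, Mg, K} rather than {Na, K, Ca} on some
  draws; the classification itself is robustly near-perfect.
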