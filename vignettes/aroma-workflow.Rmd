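---
title: "From GC-MS peak tables to key odorants and cellar markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From GC-MS peak tables to key odorants and cellar markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aromakit)
```

aromakit implements the analysis chain used in untargeted aroma profiling of
fermented beverages by headspace solid-phase microextraction GC-MS
(HS-SPME-GC-MS): integrated peak tables go in; retention-index annotation,
internal-standard semi-quantification, odor-activity scoring and supervised
chemometrics come out. This vignette explains the models behind each stage,
the parameters that matter, and the choices made where the methodology is
genuinely open.

## The measurement model

An integrated peak table contains, per replicate injection, retention times
(minutes) and detector peak areas. Three identities connect these raw
numbers to interpretable quantities.

**Retention index (van den Dool-Kratz).** Under a linear oven-temperature
program, a peak eluting between the n-alkanes with carbon numbers $Z$ and
$Z+1$ gets the column-independent index

$$\mathrm{RI} = 100 \left( Z + \frac{RT - RT_Z}{RT_{Z+1} - RT_Z} \right),$$

computed against an alkane-ladder calibration (typically C7-C30).
`compute_ri()` uses the bracketing rung pair; retention times outside the
ladder span are linearly extrapolated from the end pair and flagged, since
columns are routinely run past the last calibrated alkane. A sparse ladder
(missing rungs) is handled by scaling the interpolation with the actual
carbon-number step. Annotation (`annotate_peaks()`) assigns each peak the
library compound with the nearest reference index, within a tolerance of 10
index units by default — common practice for 5%-phenyl-type columns; the
tolerance is a parameter because it trades recall against misassignment.
Within a replicate, assignments are injective (best pair wins), and an exact
distance tie leaves the peak unannotated with a warning: with no mass
spectra in this data model there is no evidence to break such a tie.

**Semi-quantification.** With an internal standard (IS; 2-octanol at a
final concentration of 328.8 µg/L in the reference design) spiked into
every vial, the analyte concentration estimate is

$$C = \frac{A_c}{A_{is}} \cdot C_{is},$$

the analyte/IS area ratio scaled by the spiked concentration. The ratio
cancels any factor that multiplies all areas of one injection equally
(extraction efficiency, injection volume, detector drift); it assumes equal
response factors across compounds, which is why the result is a
*semi*-quantification. Replicates aggregate to wine-level means and sample
standard deviations over the replicates in which a compound was detected;
a compound seen in a single replicate is reported with SD 0 and flagged
`low_support` rather than silently dropped, because the tables this package
mirrors apply no replicate-consensus filter.

**Odor activity.** The relative odor activity value divides the
concentration by the compound's odor threshold in the tasting medium,

$$\mathrm{ROAV} = C / T,$$

and compounds with ROAV strictly greater than 1 are flagged as key
odorants. Thresholds are reference data supplied by the user (or the
packaged table); compounds whose thresholds have not been described are
reported as *unevaluable* rather than being given a pseudo-threshold.
Reported ROAVs are rounded half-up to two decimals for display; the
key-odorant comparison always uses the unrounded value.

## The packaged reference panel

`load_paper_fixture()` returns a transcribed nine-wine survey: 128 volatile
compounds (acids, alcohols, aldehydes, esters, and a mixed "other" class)
semi-quantified in three aged rice wines (YJ, JJ, NEH), four modern rice
wines (GLS, SKM, KJS, XH) and two grape wines (CC, ZY), three replicate
injections per wine, plus odor thresholds for the 38 compounds with
described thresholds. Missing cells mean "not detected" and stay missing —
they are never zero-filled on input. The files are checksummed at load
time.

```{r fixture}
fx <- load_paper_fixture()
rec <- compute_roav(fx$concentrations, fx$thresholds)
sapply(select_key_odorants(rec), nrow)
```

The transcription was validated two ways: every per-class concentration
total was checked against the printed class totals (38 of the 45
wine-by-class cells agree within ±0.05 µg/L; the handful that cannot be
reconciled under any reading of the source tables are documented in the
test suite), and every printed odor-activity cell was checked against the
recomputed concentration/threshold quotient at its printed precision.

## Chemometrics

The multivariate stage works on a samples-by-compounds matrix in which
replicate injections enter as independent rows — group separation is then
judged against replicate-level variability, not wine means.

* **Imputation** (`impute_missing()`): missing cells become 1/5 of the
  column's minimum positive value, the usual stand-in for concentrations
  censored below the detection limit. Columns observed in no sample are
  dropped and reported.
* **Quotient normalization** (`normalize_to_reference()`): each row is
  divided by the median of its element-wise quotients against a designated
  reference sample, correcting dilution-like effects.
* **Pareto scaling** (`pareto_scale()`): columns are centered and divided
  by the square root of their standard deviation — a compromise that keeps
  abundant esters from drowning out trace compounds without inflating pure
  noise the way unit-variance scaling does. Scaling is applied after
  imputation and normalization.
* **Unsupervised views**: `spearman_matrix()` (rank correlations between
  samples, ties by average ranks) and `pcoa()` (classical metric
  multidimensional scaling: Gower double-centering of squared distances,
  eigendecomposition, coordinates scaled by the root eigenvalues). The
  default distance is Bray-Curtis on the imputed concentrations, with
  Euclidean and the other `vegan::vegdist()` measures available; on
  Euclidean distances of a centered matrix PCoA reproduces PCA scores
  exactly, which the test suite asserts. Negative eigenvalues of
  non-Euclidean dissimilarities are reported and their axes dropped.

**PLS-DA** (`fit_plsda()`) fits the one-hot encoded, centered class matrix
on the centered feature matrix by NIPALS with deflation of both blocks,
giving mutually orthogonal score vectors. Weight vectors are sign-fixed so
their largest-magnitude element is positive, making score plots
reproducible. Two numerical guards matter in practice: a component whose
X-Y covariance is numerically zero, and an exhausted (low-rank) block,
both truncate the model with a warning instead of iterating on rounding
noise — a situation that real noiseless or near-duplicate designs do
produce inside cross-validation loops.

**OPLS-DA** (`fit_oplsda()`, two classes only) removes a requested number
of components that are structured in X but exactly uncorrelated with the
class before fitting a single predictive component, concentrating all
between-group separation on one axis. With zero orthogonal components it
coincides with one-component PLS-DA.

**VIP** (`compute_vip()`) summarizes each variable's contribution as

$$\mathrm{VIP}_j = \sqrt{p \cdot \frac{\sum_a SS_a \, (w_{ja}/\lVert w_a \rVert)^2}{\sum_a SS_a}},$$

with $SS_a$ the Y-variance explained by component $a$ (only the predictive
component for OPLS-DA). Squared VIPs average to one, so the conventional
VIP > 1 cutoff (strict, as for ROAV) flags above-average contributors.

**Validation.** `cross_validate()` reports $R^2 = 1 - RSS/TSS$ on the full
fit and $Q^2 = 1 - PRESS/TSS$ with prediction errors accumulated over
stratified k-fold splits (default 5 folds; stratification is required —
losing a class from a training split is an error, not a silent skip).
`permutation_test()` refits under label shufflings and reports the add-one
estimate $p = (1 + \#\{Q^2_{perm} \ge Q^2_{obs}\})/(1 + B)$ with $B = 100$
permutations by default, so $p$ can never undercut $1/(B+1)$. Both are
deterministic given their seed.

## What the synthetic generator emulates — and what it does not

`generate_panel()` draws replicate-level panels with known ground truth,
mirroring the reference design: wines in comparison groups, three
replicate injections per wine, an IS at 328.8 µg/L, and ~46-minute
retention times. Per replicate it draws the IS peak area log-normally (5%
CV, so the area-ratio invariance of semi-quantification is actually
exercised), true concentrations log-normally around the wine means with a
configurable coefficient of variation (concentrations are positive and the
reference tables' SDs scale roughly with their means, which is exactly the
log-normal regime), censors below a detection floor, and jitters retention
times by 0.02 min around an affine map from the reference index — small
enough that annotation at the default tolerance is solvable, large enough
to be nonzero. `plant_markers()` multiplies chosen compounds' means in one
group, and `fixture_spec()` seeds a generator from the packaged panel
(per-cell CV = sd/mean, defaulting to 0.1 where undefined; reference
indices are synthetic, evenly spaced, because the source tables print
none).

The generator does **not** simulate chromatography: no peak shapes,
co-elution, spectral similarity, response-factor differences between
compounds, or batch drift. Passing tests therefore demonstrate that the
pipeline's algebra and statistics are right, not that annotation or
quantification would be error-free on real chromatograms.

Test problem sizes were chosen to probe each property at the smallest
scale where it is meaningful: marker recovery uses 13 planted markers at
4-fold change among 60 null compounds, 25% CV, three replicates per group
(the planted-marker count mirrors the cellar-marker comparison the
reference study reports); the permutation-calibration check uses 200 null
simulations of 12 samples by 8 variables with 19 permutations each; the
separation check uses 18 samples with 8-fold change, 10% CV and 100
permutations.

## Design choices and limitations

* Whether published per-class totals average over detected replicates or
  all replicates is unstated in the sources this package mirrors; the
  package reports means over detected replicates and treats missing as
  absent.
* The exact cross-validation fold count and PCoA distance metric behind
  published figures are typically unstated; both are explicit, seeded
  parameters here rather than asserted conventions.
* Thresholds depend on the medium (aqueous vs ethanol); the package takes
  them as given and performs no medium correction.
* OPLS-DA is restricted to two classes by construction; multi-class
  questions belong to PLS-DA.
* The number of PLS components is a user decision (capped by
  `min(n - 1, p)`); models self-truncate when a block is exhausted.
* An end-to-end run is available as `run_pipeline()` on a
  `pipeline_config()`; the configuration hash and seed recorded in the
  output manifest make reruns byte-reproducible. The package's functions
  are the intended interface — the pipeline wrapper exists for scripted,
  manifest-tracked runs, not as a substitute for the API.
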