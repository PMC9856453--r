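---
title: "Methods: dose-response analysis of Cell Painting profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response analysis of Cell Painting profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cell Painting is a high-content assay in which cells are stained with five
fluorescent probes (nuclei/DNA, actin-Golgi-plasma membrane "AGP",
endoplasmic reticulum, RNA/nucleoli, mitochondria) and imaged at scale;
CellProfiler-style software then extracts on the order of a thousand
morphological features per cell. In a dose-response design — here modeled
on an exposure study of metal additive-manufacturing particles in U-2 OS
cells — each of three 96-well microplates carries ten exposure
concentrations (0 to 100 µg/mL) in six replicate wells, nine imaged fields
per well, and roughly 200–250 segmented cells per field.

`morphodose` implements the downstream analysis of such an experiment as a
tested, reusable pipeline: quality control, robust normalization against
unexposed controls, cross-plate batch correction, aggregation to image-,
well- and treatment-level profiles, a per-feature concentration screen,
low-dimensional embedding, sparse classification with plate-wise
cross-validation, and the companion differential-abundance statistics for
targeted lipidomics/metabolomics tables. Because studies of this kind
often deposit no raw data, the package includes a first-class synthetic
generator with known ground truth, so every stage is verifiable end to
end.

## Data model

Profiles live in a `profile_frame`: a tibble whose metadata columns key the
profile (plate, well, field, cell, concentration, depending on the level)
and whose single `features` column is a numeric matrix. The matrix backing
matters: a full simulated experiment has ~360,000 cells × hundreds of
features, and normalization/aggregation are then column-kernel operations
(implemented in C++ where R-level loops would dominate) rather than
million-row data-frame scans. `profile_wide()` and `profile_long()`
convert to ordinary tibbles for interactive work and ggplot2.

Feature names follow CellProfiler's underscore-token convention
(`Cells_Correlation_Overlap_AGP_ER`); `parse_feature_name()` is total —
any string parses, with `unknown`/`other` fallbacks — and assigns
compartment, feature group, fluorescent channels, measurement tokens and
numeric scale suffixes. Both `Cells_Correlation_…` and the display
spelling `Cells Correlation_…` are accepted because published feature
references mix the two.

## The processing chain

**Quality control.** Wells with fewer than 500 cells are removed first,
then images with fewer than 30 cells (`qc_filter()`, thresholds
configurable). The order matters for bookkeeping: a sparse well is one
defect, not six image defects. `drop_cells_and_features()` then applies a
feature block-list before discarding cells with missing values, so a
missing value confined to a block-listed feature does not cost the cell.
Which exact block-list to use is an input, not a package decision: the
published Cell Painting block-list format (one name per line) is read by
`read_blocklist()`.

**Control-based normalization.** Per feature and per plate, values are
centered by the median of the unexposed-control (0 µg/mL) cells and scaled
by the median absolute deviation of the same cells:
`x' = (x − median_ctrl) / MAD_ctrl`. The MAD is deliberately *unscaled* —
no 1.4826 normal-consistency factor — so control cells sit at exactly
median 0, MAD 1 afterwards; a `mad_scale` flag restores the factor for
users who want normal-consistent units. Features whose control MAD is zero
in any plate carry no usable scale; they are dropped and reported rather
than regularized, which keeps the normalized units interpretable. Both
median and MAD are robust to the heavy-tailed single-cell outliers that
segmentation errors produce (the generator's `noise = "t5"` option exists
to exercise exactly this).

**Batch correction.** Plate-to-plate shifts are removed with the
parametric empirical-Bayes location-scale model (ComBat): standardize each
feature to its pooled moments, estimate per-batch location (γ̂) and scale
(δ̂²) on the standardized data, shrink them toward feature-wise priors
(normal for locations, inverse-gamma for scales, hyperparameters by method
of moments), adjust, and rescale. The EB fixed point is iterated to a
relative tolerance of 1e-6 with a 200-iteration cap — standard practice
for this estimator; it converges in a handful of iterations on real-sized
inputs. `shrink = FALSE` gives the direct location-scale adjustment, which
equalizes per-batch means and variances exactly and serves as the oracle
in the test suite (together with a cross-check against the reference
Bioconductor implementation). Contracts at the edges: a single batch is an
identity, a singleton batch is an error, a zero-variance feature passes
through unchanged and is reported. The operation is level-agnostic; the
pipeline applies it at image level before the regression and
classification analyses, and can apply it at cell level instead
(`batch_level = "cell"`), matching the two placements used in practice.

**Aggregation.** Image- and well-level profiles are medians of their
contributing rows (robust, breakdown point 50%); treatment-level profiles
are means of same-concentration wells within a plate, then unweighted
means across plates. A concentration absent from one plate triggers a
warning and is averaged over the remaining plates.

**Heatmap construction.** `heatmap_matrix()` arranges treatment-level
profiles for display: rows are the nine nonzero concentrations in
descending order; columns are one compartment's features ordered by group
(Correlation, Intensity, RadialDistribution, Texture), then channel (DNA,
AGP, ER, RNA, Mito), then name. Granularity and Location features are
computed throughout the pipeline but excluded from the default display,
mirroring common practice for these summary figures; `include_all_groups`
overrides.

## The concentration screen

`ancova_screen()` fits, per feature at image level, ordinary least squares
of the profile value on the transformed dose plus a plate factor, and
tests the dose slope with a two-sided t test. The plate factor absorbs any
additive per-plate shift exactly (the test suite asserts invariance to
per-plate constants to machine precision). Raw p-values get the Bonferroni
correction over the family of all tested features
(`p_adjusted = min(1, m·p)`), with the family size m equal to the number
of features actually tested.

The dose covariate defaults to `log10(conc + c0/2)` with `c0` the smallest
nonzero concentration: the design spans three orders of magnitude, a raw
linear covariate would let the 100 µg/mL arm dominate the fit, and the
half-minimum offset maps the 0 µg/mL control to a finite value one octave
below the lowest dose. The identity scale is available (`dose_scale =
"identity"`) since the appropriate scale is ultimately a modeling choice.

`fwer_simulation()` is the verification harness: it repeats
generate-null → QC → normalize → aggregate → batch-correct → screen and
reports the fraction of replicates with at least one Bonferroni rejection.
Under the global null this must not exceed the nominal family-wise level
(up to Monte-Carlo error), which is the package's headline acceptance
check.

## Multivariate analyses

**Sparse PLS-DA.** `fit_splsda()` implements the soft-thresholding
formulation directly: classes are one-hot encoded and centered; for each
of K components the leading left singular vector of `t(X) %*% Y` is
soft-thresholded at `eta × max|w|` (so `eta` is the fraction of the
largest absolute coefficient below which weights die), renormalized, used
to score X, and X is deflated. Soft-thresholding the cross-product vector
is what makes the selection embedded: features whose class covariance is
small relative to the strongest feature get exactly zero weight, and the
selected set is the union of nonzero weights across components. `eta = 0`
is the dense PLS-DA limit — the suite checks equality of scores and
predictions against an independently coded dense oracle — and selection
size is monotone non-increasing in `eta`.

The discriminant rule on the latent scores is nearest class centroid, with
ties broken toward the lower concentration class; it is deliberately
simple, stated here because the choice is not forced by the sPLS-DA
formulation, and swappable in principle without touching the direction
vectors. Prediction aligns columns by feature name, so column order cannot
silently corrupt results.

**Cross-validation.** `crossvalidate_leave_one_plate()` holds out each
plate in turn — the only split that honors the batch structure, since
random splits would leak plate identity — fits on the rest, predicts the
held-out plate's ten-way concentration class, and only then binarizes both
truth and prediction at 1.25 µg/mL into "small" vs "large". Binarizing
after multiclass prediction (rather than training a binary classifier)
matches how such predictions are usually reported: a class-by-class
prediction table (`cv_prediction_table()`) plus binary sensitivity —
defined over the *large* class — specificity, and balanced accuracy,
summarized as mean ± SD over the three runs together with the per-run
selected-feature counts and their across-run intersection. `K` and `eta`
have defaults (2, 0.5) chosen for the simulated designs in the test suite;
for real data they should be tuned on training folds only, never on the
held-out plate.

**UMAP.** `umap_embed()` wraps the uwot implementation (the embedding is
an established algorithm; re-deriving it is not this package's job) with
200 neighbors by default — a broad neighborhood appropriate when the
interesting structure is the global dose gradient across ~1600 images
rather than fine local clusters. The embedding is exploratory and feeds no
downstream statistic; determinism under a fixed seed is guaranteed by
single-threaded SGD.

## Omics differential abundance

`anova_tukey()` runs, per analyte, a one-way ANOVA across exposure groups
followed by Tukey's HSD on log2 abundances. Technical replicates are
averaged into their biological replicate first (default, switchable):
treating technical repeats as independent observations would
pseudo-replicate and overstate degrees of freedom. `volcano_classify()`
computes fold changes as ratios of geometric means (differences of log2
means), takes the two-group p-value from the Tukey pair by default (a
Welch t-test alternative exists, since reporting conventions differ), and
gates significance at p < 0.05 and fold change > 2 (or < 1/2 for
down-regulation). `cluster_heatmap()` selects the top 25 analytes by
ANOVA p (ties alphabetical), z-scores each analyte's log2 abundances
across samples, and clusters rows with Ward linkage on Euclidean
distances — the defaults of the common web tools for such figures; all
three choices are arguments.

## The synthetic generator

`generate_experiment()` draws cell value
`x = baseline_j + s_j·g(conc) + γ_pj + δ_pj·ε` with per-feature baselines,
a configurable fraction of features carrying a dose slope on the
transformed scale, additive (γ) and multiplicative (δ) plate effects drawn
once per (plate, feature) — the same location-scale form the correction
stage assumes — and unit Gaussian or rescaled t(5) cell noise. Defaults
mirror the emulated study design: 3 plates, the ten-concentration series,
6 wells × 9 fields, 200–250 cells per field. Where the emulated study
fixes no value the defaults are chosen once as plausible for this assay
class: 30% affected features at half a noise-SD per decade of dose, plate
offsets of SD 0.5 and scale factors of SD 0.2 on the log scale —
batch effects comparable to, but not overwhelming, the biology. QC-defect
injection (wells or images downsampled to fixed cell counts) is exact by
construction, so QC removal counts can be asserted, and everything is
bit-reproducible under a fixed seed.

What the generator does *not* emulate — and hence what green tests do not
certify about real data: feature-feature correlation structure (real
morphological features are heavily correlated; here they are independent
given the design), non-linear or saturating dose-response shapes,
spatial/edge well effects, segmentation artifacts beyond symmetric heavy
tails, and drift within a plate. Conclusions from the simulator are about
the correctness and calibration of the *procedures*, not about biology.

`generate_analyte_table()` produces log-normal abundances with nested
biological (SD 0.35 log2 units) and technical (SD 0.15) variance
components for 3 × 2 replicates per group, and applies programmed fold
changes multiplicatively; the nulls calibrate the ANOVA's size and the
planted effects its fold-change recovery.

## Numerical and edge-case decisions

- Medians use R's convention (mean of the two middle order statistics);
  the C++ kernels reproduce it exactly and drop NAs per (group, feature).
- The EB iteration tolerance is 1e-6 (relative), capped at 200 iterations.
- Constant features: undefined t statistics are flagged and never
  significant; zero-variance features pass through batch correction
  unchanged; zero-MAD features are dropped at normalization with a record.
- Ties in nearest-centroid prediction go to the lower concentration class
  (distances compared after rounding at 1e-12 to make exact symmetry
  deterministic).
- Histogram bins in `size_summary()` are exactly equal-width over the
  observed range (not pretty-rounded), with the rightmost edge closed.
- All pipeline randomness flows from one root seed; the FWER harness uses
  `seed + replicate` so replicates are independent but reproducible.

## Problem sizes used by the shipped checks

The test suite and the reproduction script exercise the full plate layout
(1620 images; ~360,000 cells at 200–250 cells per field) for the
family-wise error-rate simulation (200 null replicates at 100 features)
and the layout count, and deliberately small designs (2 wells × 2 fields,
tens of cells, 10–30 features) everywhere a property does not depend on
scale. The EB-convergence check uses two batches of 250,000 rows, where
the shrinkage correction provably approaches the direct adjustment.

## Known limitations

- Nonparametric ComBat is not implemented; plates with genuinely
  non-Gaussian batch effects are outside the parametric model.
- The ANCOVA is a linear trend test on the chosen dose scale; it has no
  power against non-monotone dose-response shapes and is not a
  mixed-effects model (wells are not modeled as random effects).
- sPLS-DA feature selection inherits the instability of all sparse
  methods under strong feature correlation; the across-run selection
  intersection is reported precisely because single-run selections
  overstate certainty.
- The volcano p-value convention (Tukey pair vs plain t-test) changes
  which analytes clear the gate; both are exposed because published
  analyses are often ambiguous about it.
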