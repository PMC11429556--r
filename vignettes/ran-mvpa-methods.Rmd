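---
title: "Longitudinal MVPA of rapid automatized naming fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal MVPA of rapid automatized naming fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ranmvpa)
```

## The analysis in one paragraph

`ranmvpa` implements a longitudinal multivariate pattern analysis of
block-design rapid automatized naming (RAN) fMRI. Per subject and visit, a
voxel-wise **Letter > Color** contrast is formed by temporal averaging of the
BOLD signal over letter-naming blocks minus color-naming blocks. Contrasts
are spatially averaged within the regions of an integer-labeled parcellation;
a two-class **Fisher criterion** scores each region's survivor-vs-control
separability per visit; regions meeting a threshold at **any** of the three
visits survive, and the threshold is chosen from the grid 0.16–0.26 (step
0.02) by maximizing mean leave-one-out SVM accuracy across visits. A linear
SVM (C = 1) is then cross-validated per visit on the voxel features of the
selected regions, with Monte Carlo permutation inference on its accuracy.
Full-sample SVM weight vectors are projected back into voxel space and
thresholded by magnitude (|w| ≥ 0.02) and cluster extent (≥ 50 voxels).
Finally, cluster-averaged contrasts are compared between groups per visit
(Welch's t), including the contralateral homolog cluster, and within patients
each of seven standardized reading scores defines a high/low stratification
(cutoff 100) that is classified from the same voxel features.

## The contrast model

A RAN run is a fixed schedule: 10 s lead-in, three cycles of
NULL/COLOR/NUMBER/LETTER blocks of 20 s each, and a 20 s tail — 270 s and,
at TR = 2 s, 135 volumes:

```{r}
tl <- build_timeline()
tl
```

The contrast is plain block averaging: per voxel, the mean over letter-block
volumes minus the mean over color-block volumes. There is deliberately **no
HRF convolution and no GLM**; the operation is a temporal average, which
keeps the contrast linear in the data (a property the test suite asserts to
1e-10). Because BOLD lags stimulus onset by several seconds, block windows
are shifted forward by `hrf_shift_volumes` (default 2 volumes = 4 s,
configurable down to 0). Whether block edges should instead be discarded is
genuinely underdetermined for this design; both behaviors are expressible
through the shift parameter, and every result that depends on it states it.
Volume indexing is 0-based and block windows are half-open `[onset, offset)`;
a volume belongs to the block during which its acquisition starts. Indices
shifted past the end of the run are dropped; a shift larger than one block
intentionally reaches into the following block, since that is what a fixed
hemodynamic delay does physically.

NULL and NUMBER blocks are carried in the data model but unused by the
default contrast: only Letter > Color is analyzed.

## Region features and the Fisher filter

Region means are arithmetic means over a region's voxels; background
(label 0) never contributes, and a region with no voxels yields a *missing*
value, never a silent zero. Voxel features within a region set are ordered
lexicographically by (i, j, k), so weight maps are reproducible across runs
regardless of how the regions were listed.

The Fisher score for a region is the standard two-class criterion

$$F = \frac{(\mu_1 - \mu_2)^2}{\sigma_1^2 + \sigma_2^2},$$

with unbiased variances. The methodological literature also uses a
class-size-weighted denominator; that variant is available via
`fisher_score(..., weighted = TRUE)` but is not the default, since with the
near-balanced groups of this design the two coincide up to a constant. If
both variances vanish the score is `Inf` for unequal means and 0 otherwise.

Two decisions here deserve emphasis:

* **Survival rule.** A region survives a threshold if its score meets it at
  *any* of the three visits. Thresholds are swept over 0.16–0.26 in steps of
  0.02, and the chosen threshold maximizes the mean LOO accuracy across
  visits; exact ties go to the *largest* tied threshold (the most selective
  region set), and every tie is logged.
* **Circularity.** Scores are computed on the full sample at each visit and
  the same data are then cross-validated — selection is not nested inside
  the CV folds. This is a known source of optimism, reproduced here
  deliberately as the default mode because it is the analysis being
  re-implemented; the package structure (selection operates on a score list,
  classification on a feature matrix) makes a nested variant
  straightforward for users who want unbiased accuracy estimates, and the
  synthetic-data suite quantifies the optimism empirically (it is visible as
  a ~1–2 point elevation of TP1 accuracy over chance).

## The classifier and its inference

The classifier everywhere is a linear soft-margin SVM with C = 1. The
C-SVC dual is solved by sequential minimal optimization (maximal violating
pair working-set selection, KKT-gap stopping rule at 1e-3) over a
**precomputed Gram matrix**, implemented in compiled code. The kernel-matrix
formulation is what makes the inference loop tractable: all n leave-one-out
folds and all B label permutations share one Gram matrix, so a permutation
test costs (B+1)·n small dual solves and no repeated kernel evaluations.
The solver is cross-checked in the test suite against an independent SVM
implementation (libsvm via e1071): full-sample weight vectors and intercepts
agree to the convergence tolerance, and held-out LOO predictions agree on
≥ 99% of samples (the residue being points whose decision value is within
solver tolerance of zero).

Features are **not standardized** by default. The weight-map threshold
|w| ≥ 0.02 is a statement about raw weights, which is only meaningful when
the features keep their natural scale; within-training-fold z-scoring is
available as a config option for users who want it.

Leave-one-out CV holds out exactly one subject-visit sample per fold. A
training fold that degenerates to a single class (possible only when a class
has one sample) predicts the majority class and is logged. Exact decision
ties (possible with constant features) resolve to the first class in the
canonical ordering — factor levels if the labels are a factor, sorted order
otherwise — and are logged.

Classification quality is summarized as accuracy, sensitivity and
specificity on the declared positive class (survivors, or high performers),
and balanced accuracy = (sensitivity + specificity)/2.

The Monte Carlo permutation p-value reruns the full LOO analysis on B
permutations of the label vector (group sizes preserved by construction) and
reports p = k/B, where k counts shuffles whose accuracy is at least the
observed one. The observed labeling is **not** included in the count — the
published counts of 1/1000 would be impossible otherwise, since the identity
permutation always ties itself — and the bias-corrected (k+1)/(B+1)
estimator is reported alongside for users who prefer a strictly positive
p-value. All shuffles are driven by an explicit seed.

## Weight maps and clusters

A full-sample SVM fit yields one signed weight per feature voxel, placed at
its coordinate (zero elsewhere); positive weights are associated with the
positive class. Clusters are formed by binarizing |w| at the magnitude
threshold (default 0.02), labeling connected components, and keeping those
with at least the minimum extent (default 50 voxels), sorted by size.
Two choices are deliberately configurable because the convention is not
universal:

* **Connectivity** defaults to 26 (faces, edges, corners — the most
  inclusive and the common choice for voxel clusters), with 6 and 18
  available.
* **Sign handling**: thresholding on magnitude means a cluster may mix
  positive and negative weights; the per-cluster dominant sign is reported.
  A `split_sign` mode clusters each sign separately for users who render
  signed maps as separate overlays.

Raising either threshold can only shrink the total surviving voxel count — a
monotonicity property the test suite checks, along with exact agreement of
component labeling against a flood-fill oracle.

One caveat worth knowing: weight magnitudes depend on the feature scale and
the sample size (for a well-separated problem the weight norm is inversely
proportional to the class-mean distance, which grows with the number of
informative voxels). On the synthetic cohort the per-voxel weights peak
around 0.02, so the default thresholds usually return an *empty* cluster
list there — an honest reflection of the scale, not a failure; the
clustering machinery itself is validated on constructed weight maps with
known components.

## Cohort statistics

The group-level comparison spatially averages each subject's contrast over
the voxels of the selected-region cluster and tests survivors against
controls per visit. The published analysis does not name its test; the
package defaults to **Welch's two-sample two-sided t-test** (unequal
variances are the safe assumption for patient-vs-control comparisons), with
the pooled-variance test available via `var_equal = TRUE`. When both groups
are constant and equal the p-value is defined as 1. The contralateral
analysis is the *same code path* run on the homolog region set obtained from
the parcellation's symmetric homolog links.

Performer stratification splits survivor visits (all three visits pooled, so
one subject contributes up to three samples) at a standardized score of 100;
a score of exactly 100 is a high performer. Missing scores drop the sample
for that test only, so per-test sample sizes differ exactly by missingness.
Pooling visits treats repeated visits as independent samples — a
within-subject dependence that is accepted deliberately for fidelity to the
published sample sizes (e.g. 89 pooled samples from 50 patients), and
documented here rather than "fixed", since correcting it would change the
analysis being reproduced. The features used are the voxels of the regions
selected by the survivor-vs-control analysis; the source text does not state
this explicitly, and it is flagged as an assumption.

## The synthetic cohort generator

No imaging data accompany this package (the study data are private), so the
generator is a first-class module that emulates the statistical structure
the analysis assumes, making every stage testable end-to-end:

* **Design**: 50/50 survivors/controls at TP1, nested attrition to 36/36 and
  21/21 (later visits are exact subsets, dropping the last-enrolled
  subjects).
* **Parcellation**: 30 rectangular regions as 15 mirrored left/right homolog
  pairs (120 voxels each) on a 32×32×32 grid; the first four right-hemisphere
  regions play the roles of the right superior/middle/inferior occipital
  gyri and occipital pole.
* **Planted effect**: survivors' contrasts are shifted inside those four
  regions by 0, 0.4 and 0.8 voxel-noise SDs at TP1/TP2/TP3 — near-zero
  early, largest at the last visit.
* **Noise**: i.i.d. N(0, σ²) per voxel plus a per-subject, *per-region*
  random offset (SD 0.6σ, drawn once per subject and held fixed across
  visits). The per-region structure matters: it models stable individual
  differences in regional responsiveness, it is what limits classification
  accuracy (the effective subject-level separation is d ≈ 2·δ/subject_sd
  with four planted regions, giving expected LOO accuracy ≈ 0.50 / 0.75 /
  0.91 across visits — the qualitative trajectory of the published 57→75→79%
  divergence), and it keeps region scores independent so that false-positive
  selections behave like independent χ² tails. A single global offset per
  subject would instead be removable by the classifier through
  between-region contrasts and would correlate all Fisher scores.
* **Scores**: seven standardized tests at 100 ± 15; sound awareness, reading
  fluency and word attack are linked to the standardized planted-region
  signal with ρ = 0.5, the other four are pure noise; 5% of scores are
  missing at random.
* **Reproducibility**: everything flows from one master seed; identical
  seeds give byte-identical cohorts.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: spatial autocorrelation of fMRI noise,
physiological drift and motion residuals, lesion/resection geometry,
age/sex structure, and any relationship between attrition and disease
severity (drop-out is by enrollment order, not outcome). The effect sizes
are calibration choices that reproduce the published accuracy *trajectory*
qualitatively; they are not estimates of the real effect.

An optional mode (`simulate_bold_series()`) emits full 135-volume series in
which letter blocks carry the target contrast as a block amplitude, so the
temporal-averaging stage is exercised end-to-end; with zero noise the
contrast is recovered exactly.

## Numerical choices and problem sizes

* SMO stopping tolerance 1e-3 on the KKT violation gap (the conventional
  default for SMO solvers); α snapped to exact
  box bounds within 1e-12·C to keep working-set membership consistent.
* Fisher scores of zero-variance degenerate columns use an `Inf` sentinel so
  they sort above any threshold rather than producing NaN.
* Region means over empty regions are `NA` by design.
* Threshold-sweep ties: largest threshold wins; logged.
* The test suite runs the full default cohort (214 maps of 32³ voxels) for
  20 seeds in the property suites, and the permutation-calibration suite
  uses n = 40, B = 99 over 200 repetitions; both sizes were chosen so the
  whole suite completes in minutes on one CPU while keeping the binomial
  bands of the assertions meaningful.
* `scripts/acceptance.R` runs the full pipeline once at the default study
  conditions with B = 199 shuffles per permutation test (the package default
  is B = 1000, matching the published analysis).

## Known limitations

* The paper-faithful selection mode is circular (see above); accuracy
  estimates inherit its optimism by design.
* Pooled performer samples violate independence across repeated visits.
* The SMO solver is specialized to the two-class linear kernel with
  precomputed Gram matrices; nonlinear kernels and multi-class problems are
  out of scope.
* Published p-values and Fisher scores from the real cohort cannot be
  reproduced (data unavailable); the package validates against printed-table
  arithmetic and recovers planted effects in synthetic cohorts instead.
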