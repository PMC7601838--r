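---
title: "Multiparametric radiomics and informatics for imaging-based risk stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric radiomics and informatics for imaging-based risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiris)
```

## The problem

OncotypeDX-style recurrence scores stratify ER-positive breast cancer into
low (score <= 17), intermediate (18-30) and high (>= 31) recurrence-risk
groups, but the assay is invasive and costly. Multiparametric MRI (T2, DWI
with its apparent-diffusion-coefficient map, and dynamic contrast-enhanced
imaging with pharmacokinetic metrics) captures cellularity, vascularity and
morphology non-invasively. This package implements an integrated
radiomics-informatics system that fuses quantitative imaging, radiomic
texture descriptors and clinical/histological variables, and asks how well
that fusion recovers the gene-assay risk bands: an unsupervised
multi-subspace embedding model with a heatmap visualization, a parameter
interaction network with hub analysis, and a hybrid Isomap + SVM classifier
evaluated by leave-one-out cross-validation.

No patient imaging is distributed. A synthetic phantom cohort generator
encodes the study conditions — three risk groups of 19/49/12 patients with
the group statistics of a representative 80-lesion ER-positive clinical
cohort — so every stage of the
pipeline is runnable and testable end to end.

## Single-parameter radiomics

All texture features operate on an ROI quantized by equal-width min-max
binning into `G = 64` gray levels (`quantize()`); a zero-range ROI maps to
level 1, and all entropies use log base 2.

* **First-order statistics** (14): mean, median, SD, variance, skewness,
  kurtosis, energy (sum of squared intensities), histogram entropy and
  uniformity, min, max, range, mean absolute deviation, RMS. SD and
  variance use the `n - 1` denominator; skewness and kurtosis use
  population moments (kurtosis is not excess-corrected).
* **GLCM** (18): symmetric co-occurrence matrices at distance 1 voxel over
  the four in-plane directions (0/45/90/135 degrees), computed slice-wise
  and pooled across slices per direction; features are evaluated per
  direction and averaged, which makes them invariant to 90-degree
  rotations. The correlation of a single-level ROI is defined as 1 (the
  0/0 limit of a perfectly homogeneous field). IDN and IDMN normalize the
  level difference by `G`.
* **GLRLM** (11): runs of equal level along the same four directions,
  slice-wise, a mask gap breaking a run; the 11 Galloway/Chu statistics are
  averaged across directions.
* **NGTDM** (5): Amadasun-King coarseness, contrast, busyness, complexity
  and strength over the 8-neighborhood (2-D slice-wise default; a
  26-neighborhood 3-D mode is available). Only voxels whose complete
  neighborhood lies inside the ROI contribute. A single-level ROI has zero
  contrast and busyness and infinite coarseness; this degenerate value is
  deliberate and documented rather than clamped.
* **Fractal** (2): box-counting slopes. The boundary dimension counts
  occupied boxes over the 4-connectivity boundary voxels (box sizes from 1
  up to half the in-plane extent, log-spaced); a discretized circle scores
  close to 1. The intensity dimension uses differential box counting on
  the quantized relief, starting at box size 2 because a single-voxel box
  carries no intensity span.
* **Convexity** (1): ROI voxels over convex-hull voxels, computed
  slice-wise (2-D hull of voxel centers, rasterized by point-in-polygon
  membership), clipped to (0, 1]. A slice-wise hull was chosen because the
  lesions are quasi-convex blobs per slice and no compiled 3-D hull is
  needed; for strongly re-entrant 3-D shapes it overestimates convexity
  relative to a true 3-D hull, which is a documented limitation.
* **Radiomic feature maps (RFM)**: any first-order or GLCM feature
  recomputed in a sliding in-plane window (default 5 x 5) centered on each
  ROI voxel, using the ROI-wide quantization so windows are comparable
  across the lesion, plus a 3 x 3 Laplacian and a Laplacian-of-Gaussian
  (sigma = 1 voxel) filter map. The scalar reported per map is the ROI
  mean (mean absolute response for the two filters, whose signed mean is
  close to zero by construction). All FOS and GLCM maps can be computed;
  the entropy/uniformity/energy maps plus the two filters are the headline
  set and the pipeline default.

## Multiparametric tissue-signature radiomics

The tissue signature at a voxel is the length-N vector of intensities
across the N co-registered channels. Channels are z-score standardized over
the ROI before binning, so every multiparametric feature is invariant to
positive affine rescaling of any channel — important because the channels
carry unrelated physical units.

* **TSPM**: the N-dimensional probability array over per-channel bins
  (`B = 8` per channel by default). B is a compromise: `B^N` cells must
  remain populated at lesion sizes of a few hundred voxels while still
  resolving the marginal distributions; at N = 4 and ~500 voxels, 8 bins
  per channel leave the occupied-cell histogram well populated. Features:
  entropy, uniformity, and mutual information defined as the mean over
  channel pairs of the MI of their 2-D bin marginals (a definition chosen
  because the N-channel MI has no canonical binary form; a single channel
  yields 0).
* **TSFOS**: the 14 first-order statistics of the pooled standardized
  sample (all N x voxels values together), with a 64-bin histogram for
  entropy/uniformity. Pooling standardized intensities (rather than
  signature magnitudes) keeps the statistic interpretable as "the
  distribution of voxel intensities across all imaging parameters". A
  consequence worth noting: the pooled energy statistic is nearly constant
  across patients (the z-scores sum to ~n per channel), so discrimination
  comes from the shape statistics, not energy.
* **TSCM**: occupied signature cells are ranked by the mean of their bin
  tuple (ties broken lexicographically) into ordinal codewords 1..L — the
  co-occurrence statistics with an "autocorrelation/variance" flavour need
  an ordinal level index, and the tuple mean orders codewords from "all
  channels low" to "all channels high". Codeword co-occurrence is then
  accumulated exactly like a GLCM (distance 1, four in-plane directions,
  symmetrized, direction-averaged). The "-I" feature variants are the
  first standard formula (contrast-I = sum (i-j)^2 p etc.), homogeneity-II
  is the inverse difference moment, and inverse variance is
  sum_{i != j} p/(i-j)^2. With a single channel and all levels occupied
  the TSCM reduces exactly to the GLCM, which the tests exploit.

## The multi-subspace embedding model

`radiris()` enumerates every 1-, 2- and 3-parameter subspace of the
patient-space matrix (C(D,1) + C(D,2) + C(D,3) subspaces), embeds each to
one dimension with Isomap (k-nearest-neighbor graph on z-scored columns,
geodesic distances, first classical-MDS coordinate; `k_nldr = 10` by
default), and retains embeddings whose Pearson correlation with the
continuous risk score satisfies |R| >= 0.5. Pearson is the default
reading of "correlation coefficient" here; the absolute value
plus a sign flip handles the arbitrary sign of a 1-D embedding. Subspaces
whose neighborhood graph disconnects are recorded and skipped. For D above
25, enumeration is restricted to the 25 highest-variance parameters to cap
the C(D,3) growth.

The retained embeddings, min-max scaled to [0,1], form the heatmap matrix:
columns (embeddings) cluster by average linkage on correlation distance
(1 - r), exposing redundant embeddings as zero-height merges; rows
(patients) cluster by average linkage on Euclidean distance, and cutting
the row tree into three groups gives the patient risk clusters. New
patients are embedded per subspace with the stored out-of-sample transform
and assigned to the nearest cluster centroid (ties to the lower-index
cluster).

Missing tabular values are median-imputed before embedding — the simplest
imputation that does not distort the k-NN geometry with artificial
variance.

## The parameter interaction network

Each parameter is first mapped to a risk-prediction score on [0,1] by
min-max normalization, oriented by the sign of its correlation with the
risk score so 1 always means high risk. Edge weights are
`1 - corr(z_i, z_j)` (Pearson; weights in [0,2] act as distances); each
vertex keeps edges to its k = 3 nearest neighbors and the digraph is
union-symmetrized, the convention that keeps a k = 3 graph connected most
often. Metrics: weighted average path length and diameter over all pairs,
unweighted average local clustering coefficient against the matched
Erdos-Renyi baseline (its edge density), and degree, weighted betweenness
and harmonic centralities. The integrated centrality — a summary for which several reasonable
definitions exist — is defined here as the mean of the three centralities
after per-metric min-max normalization to [0,1]; it is isolated in one
function so a different definition can be substituted, and hub ranking
sorts by it with alphabetical tie-breaks.

## The Isomap + SVM classifier

`isosvm()` standardizes the features, embeds them to `d_iso = 10`
dimensions with Isomap (`k_iso = 60`, capped at n - 2 so subgroup models
stay feasible), and trains an RBF-kernel SVM (linear available) on the
embedding, multiplying the penalty of the minority class by the imbalance
`ratio` (default 2, as in a 2:1 penalty). Four inter-group comparisons are
wired: low vs intermediate, low vs high, intermediate vs high, and low vs
(intermediate + high).

Out-of-sample points are embedded by a Nystrom-style extension: geodesic
distances from the new point are approximated through its k nearest
training neighbors and projected with the stored MDS eigensystem; a
training point re-transformed reproduces its own embedding exactly, and a
point with no training neighbor within the largest training k-NN edge
length falls back (flagged) to its nearest neighbor's embedding.

Evaluation is leave-one-out cross-validation: each sample held out, the
model refitted, the held-out decision value recorded. Two details matter:

* The class receiving the imbalance penalty is fixed once on the full
  label vector. Re-deriving the minority class inside each fold ties the
  penalty to the held-out sample's own class and produces spuriously
  perfect AUCs on random labels — a leakage mode the test suite guards
  against explicitly.
* Pooled LOOCV decision values carry the known pessimistic bias of
  leave-one-out scoring under class imbalance, so chance-level performance
  sits somewhat below AUC 0.5 for a fixed configuration. Hyperparameters
  are therefore tuned by LOOCV AUC over a small grid (which contains the
  (k_iso 60, d_iso 10, ratio 2) configuration), and permutation nulls are
  scored by the same tuned procedure, keeping real and permuted labels
  symmetric.

ROC curves are empirical; AUC is the trapezoid rule (identical to the
scaled Mann-Whitney statistic, which the tests assert on arbitrary
inputs); confidence intervals come from a stratified bootstrap (2000
resamples, seeded, percentile method); sensitivity and specificity are
reported at the Youden-optimal threshold; curves are compared with the
DeLong test. Group comparisons elsewhere in the pipeline use Welch's
unpaired two-sided t-test with significance at p <= 0.05 and no
multiple-testing correction by default (a Benjamini-Hochberg option
exists but is off, the convention this kind of exploratory analysis
uses).

## The synthetic phantom cohort

`cohort_spec()` encodes the study conditions; `generate_cohort()` is
deterministic given the seed and restores the caller's RNG state.

* **Counts and bands**: 19 low / 49 intermediate / 12 high; score bands
  <= 17, 18-30, >= 31 with nearest-integer rounding inside the gaps.
* **Channel statistics** (group means low/int/high): lesion ADC
  1.49/1.18/1.14 x 1e-3 mm^2/s with glandular ADC 2.15 in every group;
  Ktrans 0.30/0.46/0.49 min^-1; peak DCE enhancement 503/461/468 a.u. with
  SDs 33/24/31; lesion size 1.9/1.7/2.9 cm with SDs 1.3/1.4/1.7; Ki-67
  15/30/45 % with SDs 8/12/15 (the mixture gives an overall 29 +- 16%,
  typical of such cohorts; the per-group split and the remaining SDs are
  configuration defaults). T2 is non-discriminative by design. The
  intermediate-group ADC (1.18) sits close to the high value, reflecting
  that intermediate and high lesions show similarly reduced diffusion
  (near 1.14) against 1.49 for low.
* **Geometry**: spherical lesions (radius 5 voxels on a 28 x 28 x 14
  grid) and a disjoint spherical glandular ROI; voxel counts match the
  analytic ball volume within surface-order discretization error.
* **Heterogeneity**: a smooth multiplicative texture field (coarse-lattice
  Gaussian value noise, trilinear interpolation, clipped at +-2 SD) with
  per-group amplitude 0.50/0.35/0.25, plus a mean-preserving focal
  high-signal core (radius half the lesion radius; gains 0/0.8/1.1)
  emulating necrotic / hyper-enhancing foci. The core is what moves the
  min-max-binned histogram statistics: amplitude alone cannot (the
  binning is scale-invariant), while range-stretching outliers lower
  entropy and raise uniformity. Gains rise with risk, and the
  intermediate and high gains sit close together, so heterogeneity is
  highest in the low-risk group, the intermediate and high groups show
  nearly identical texture statistics, and the intermediate-vs-high
  comparison is the hardest classification — the structure the cohort is
  designed to emulate.
* **Risk score**: a logistic-scaled linear combination of the
  standardized drivers — ADC (weight -1), Ktrans (+1), Ki-67 (+1),
  realized texture amplitude (-1) — plus N(0, 0.5) noise. The logistic is
  rescaled within each group's score band (low [3,17], intermediate
  [18,30], high [31,60]), which keeps the stated group counts exact and
  the score-derived risk group identical to the generating group while
  preserving the monotone feature link. The negative texture weight
  matches the entropy direction described above.
* **Categoricals**: BI-RADS-style morphology classes 1-6 and kinetic
  curve types 1-3 from group-specific multinomials (low risk favouring
  circumscribed masses and persistent kinetics, high risk spiculated
  masses and washout).

What the phantoms do **not** emulate: MR physics (no k-space, coil or
bias-field effects), registration error between channels, irregular lesion
shapes, scanner- or site-level batch effects, and any real correlation
structure between clinical codes and imaging beyond the group-level
design. Passing tests therefore demonstrate algorithmic correctness and
sensitivity under the designed effect directions — not clinical
performance on real mpMRI.

## Numerical choices and degenerate inputs

Zero-range quantization maps to level 1; 0 log 0 terms are dropped from
every entropy; the GLCM correlation of a constant ROI is 1; NGTDM
coarseness of a constant ROI is infinite; zero-variance embeddings are
excluded from the correlation gate; constant parameters are rejected by
the risk normalization; perfectly correlated parameters (edge weight 0)
keep their edge through a 1e-12 weight floor because the graph library
drops zero-weight edges; eigenvector signs in the MDS step are fixed by
making the largest-magnitude loading positive, which makes embeddings
deterministic; centroid ties assign to the lower-index cluster; hub ties
break alphabetically.

## Problem sizes

The test suite and the acceptance script run the full pipeline at the
emulated cohort size (n = 80) for the classification stage, 200 patients
per group for generator-convergence checks, 1000 random 6 x 6 ROIs for the
texture-oracle equivalence, and 200 random <= 10-vertex graphs for the
network oracles. These sizes were chosen so each check has enough
statistical resolution to detect a real defect while the whole suite stays
interactive.

## Known limitations

* The integrated-centrality summary and the exact RFM headline roster
  admit several reasonable definitions; the ones here are documented
  above and isolated behind single functions.
* Slice-wise (2-D) texture directions are the default; the 13-direction
  3-D mode exists only for NGTDM's neighborhood choice, not for GLCM/GLRLM.
* The out-of-sample Isomap extension is approximate off the training
  manifold; its fallback is nearest-neighbor, which is crude but flagged.
* LOOCV AUC inherits the pessimistic pooling bias discussed above;
  leave-pair-out scoring would remove it but is quadratic in n.
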