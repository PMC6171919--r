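---
title: "Radiomics feature reliability under tumor segmentation variability"
author: "radsegvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomics feature reliability under tumor segmentation variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsegvar)
```

## The problem

Radiomics pipelines compute quantitative features (shape, intensity
histogram, texture) from a delineated tumor volume and use them as imaging
biomarkers. The delineation itself is uncertain: the same tumor contoured
twice by one observer, by different observers, or with different software
tools yields different masks, and that variability propagates into every
downstream feature. Before a feature can be trusted as a biomarker one has
to know how reliable it is under each of those three sources of variation:

* **intra-observer** — repeat contours by the same observer with the same
  tool (repeatability),
* **inter-observer** — different observers using the same tool
  (reproducibility across people),
* **inter-software** — the same observer using different tools
  (reproducibility across tools).

`radsegvar` implements the complete analysis as a reproducible pipeline:
synthetic CT tumor phantoms with families of perturbed contours whose
variance components are controllable, segmentation agreement metrics (Dice,
Hausdorff, group-consensus masks), a three-category radiomics feature
engine, informative-feature reduction, ANOVA-based intraclass-correlation
reliability analysis with confidence intervals and a four-tier
classification, Lin's concordance coefficient, and a normalized
feature-range analysis.

Real studies of this design use private patient CT data. The synthetic
module stands in for such a cohort so every stage of the statistics can be
exercised, validated against known ground truth, and stress-tested — it is
first-class, tested code, not a fixture.

## The synthetic cohort

### Phantoms

`generatePhantom()` builds one tumor per patient: a mildly anisotropic
ellipsoid (axis ratios within about ±16%) whose radius is modulated by a
smooth random field of relative amplitude `lumpiness`, voxelized on a
CT-like grid (defaults: 0.8 × 0.8 mm transverse pixels, 2.5 mm slices —
typical helical chest CT reconstruction values). The global scale is set by
bisection so the voxelized volume matches the target within a fraction of a
voxel; tumor volumes in the default study span 1.15–10.53 cm³, the range a
small lung-tumor cohort exhibits. Intensities are lung background (−800 HU)
plus an elevated tumor compartment (+20 HU by default) carrying spatially
correlated texture (SD 40 HU, correlation length ~3 mm), a partial-volume
soft edge (≈1 mm), an optional chest-wall slab, and white acquisition
noise.

A ten-patient cohort with identical texture statistics would make texture
features uninformative (no between-patient variance, hence no reliability
to measure), so the default `studyDesign()` draws per-patient phantom
parameters uniformly from documented ranges: tumor mean −20…60 HU, texture
SD 25–55 HU, texture correlation length 2–5 mm, lumpiness 0.08–0.25. This
emulates the variety of tumor appearances in a real cohort. What the
generator does **not** emulate: real anatomy (airways, vessels, lobes),
respiratory motion, scanner-specific noise texture, or the actual level-set
/ region-growing segmentation algorithms — contours are *simulated* as
boundary perturbations, never computed by re-implemented segmenters.
Passing tests therefore demonstrate that the statistical machinery behaves
correctly under a controlled, plausibly CT-like data-generating process;
they do not certify feature values on clinical data.

### Contour perturbation model

Observers disagree smoothly, not voxel-by-voxel. `simulateContour()`
displaces the true boundary along its normal by a Gaussian random field
with ~5 mm spatial correlation length, of scale
`sqrt(toolSdMm² + runSdMm²)`, plus a constant radial offset
(`observerBiasMm`). The displacement is implemented by re-thresholding the
signed distance transform of the truth at the offset field; the signed
distance is measured to the explicit interface (the midpoints of
inside/outside voxel pairs, resolved on a 2× lattice), which makes a +2 mm
offset dilate a sphere by 2 mm to within voxelization accuracy. A tool's
boundary smoothing (`smoothingMm`) is applied to the continuous level-set
field before thresholding, so smoothed boundaries remain
sub-voxel-consistent between runs. With every scale at zero the output
equals the truth bit-for-bit.

In a full study (`generateStudy()`) the variance components are assigned
hierarchically from one master seed:

* each (tool, observer) pair draws a systematic radial bias from
  N(0, `observerBiasMm`) — observers over- or under-contour consistently;
* each (patient, tool, observer) draws one stable boundary field of scale
  `toolSdMm` shared by both runs — an observer's idiosyncratic reading of
  one tumor with one tool;
* each run adds an independent field of scale `runSdMm`.

Runs of one observer therefore agree more than different observers, who
agree more than different tools, which is exactly the ordering the three
reliability families measure. Extreme erosions are floored at half the
maximal interior depth so a simulated observer can shrink a contour to a
core but never annihilate it (the single-contour API keeps the strict
error instead).

### Default tool presets

The four bundled presets encode the qualitative finding the study design
exists to probe — the low-interaction level-set-like tool perturbs least,
the region-growing tool more, the two manual tools most:

| tool | toolSd (mm) | biasSd (mm) | runSd (mm) | smoothing (mm) |
|---|---|---|---|---|
| LSTK-like | 0.3 | 0.4 | 0.3 | 1.0 |
| GrowCut-like | 0.5 | 0.8 | 0.8 | 0.5 |
| MIM-like | 0.6 | 1.2 | 1.5 | 0 |
| Slicer-like | 0.7 | 1.2 | 1.7 | 0 |

No published per-tool variability magnitudes exist, so these are plausible
stand-ins chosen once and fully user-configurable. Two deliberate
qualitative properties: manual run-to-run jitter dominates the stable
per-tumor component (repeat manual contours a year apart differ
substantially, and a large *stable* component would spuriously inflate
between-tumor variance and with it the manual tools' intra-observer ICC),
and only the semi-automatic tools smooth their boundaries (level sets and
edited region growing produce smooth surfaces; slice-wise paintbrush
contours do not).

## Feature engine

The catalog has three categories, 83 features in the default profile:

* **SHP (12)** — volume, surface area, surface-to-volume ratio, sphericity
  `π^(1/3)·(6V)^(2/3)/A`, two compactness variants, spherical
  disproportion, roundness, maximum 3D diameter, major axis length,
  elongation, flatness. Surface area comes from a marching-tetrahedra
  triangulation of the lightly smoothed mask indicator (σ = 0.75 voxel),
  with coarse-slice grids linearly upsampled along z before meshing; on
  analytic spheres of radii 5–13.5 mm this lands within ~3% of the true
  area, whereas voxel-face counting overestimates curved surfaces by ~50%
  and would wreck sphericity.
* **HIS (21)** — first-order statistics of the raw in-mask intensities
  (population-variance convention; entropy/uniformity on a 64-bin
  histogram over the in-mask range). No air/bone exclusion, no resampling,
  no smoothing: features must reflect the segmentation exactly as given,
  because the segmentation is the quantity under study.
* **TXT (25 × 2 distances)** — gray-level co-occurrence features at
  in-plane offsets of 1 and 2 voxels. The GLCM quantizes in-mask
  intensities to 64 equal-width bins over the in-mask min–max range,
  accumulates symmetric pairs within each transverse slice in the four
  in-plane directions (0°, 45°, 90°, 135°), pools across slices,
  normalizes, and averages each statistic over the four directions to
  remove directional bias. Logs are base 2.

A documented 40-feature reduced profile (`featureCatalog("reduced40")`:
12 SHP + 12 HIS + 16 distance-1 TXT) mirrors the size of a typical
non-redundant feature set after reduction. Both catalogs reproduce the
*structure* of the classic IBEX-era feature sets, not any tool's bit-exact
definitions, which are not public.

Degenerate statistics follow one convention throughout: quantities
undefined on constant input (skewness, kurtosis, GLCM correlation, the
information measures' normalizer) are reported as 0, so every feature
vector is finite and downstream matrices stay complete.

## Feature reduction

Two sequential steps, in fixed order:

1. **Normalized dynamic range.** Feature values are averaged per patient,
   the patient averages are z-scored (sample SD, n−1 — the two-patient
   closed form is √2, the witness for the convention), and
   NDR = max − min of the z-scores. NDR is affine-invariant and 0 exactly
   when a feature cannot distinguish patients. The default cutoff is 0
   (report-only): published cutoffs are acknowledged to be arbitrary, so
   filtering strength is a user decision; 2.4 is a typical empirical floor
   for informative CT features in small cohorts.
2. **Spearman redundancy pruning.** Pairwise Spearman correlations over
   all contour rows (computing over patient averages instead is a
   configuration choice); while any pair has |ρ| > 0.95 the pair with the
   largest |ρ| loses the member with the larger mean absolute correlation
   to everything else. The published rule is order-ambiguous; processing
   violating pairs in descending |ρ| with the mean-|ρ| and then
   lexicographic tie-break makes runs deterministic. After pruning, no
   retained pair exceeds the threshold — asserted, not hoped.

Significance flags on the correlation matrix (two-sided t approximation,
p < 0.05, uncorrected) are annotation only; they never filter.

## Reliability analysis

Every reliability family reduces to n × k measurement matrices (rows =
tumors, columns = runs / observers / tools) analyzed by crossed ANOVA:

* intra-observer, per (tool, observer): one-way random-effects
  single-measure absolute-agreement
  ICC(1) = (MS_R − MS_W) / (MS_R + (k − 1)·MS_W);
* inter-observer, per (tool, run), and inter-software, per (arm, observer,
  run): two-way mixed single-measure absolute-agreement
  ICC(A,1) = (MS_R − MS_E) / (MS_R + (k − 1)·MS_E + (k/n)(MS_C − MS_E)).

The default design yields 12 intra-observer, 8 inter-observer and 12
inter-software groups. Confidence intervals use the McGraw–Wong forms: the
exact F interval for the one-way model and the Satterthwaite-approximate F
interval for absolute agreement — the interval coverage is verified by
simulation (92–98% empirical coverage at n = 30, k = 3 over true ICC 0.2,
0.5, 0.8, 1000 replicates per cell, in the acceptance suite). Perfect
agreement matrices get the interval [1, 1]; otherwise-degenerate mean
squares yield the widest valid interval [−1, 1] with a flag. Negative ICC
estimates are reported as computed, never truncated: they are an expected
small-sample phenomenon.

Classification uses the conventional tiers — poor < 0.4, fair [0.4, 0.6),
good [0.6, 0.75), excellent ≥ 0.75 (closed lower bounds) — applied by
default to the lower 95% confidence bound, the conservative convention for
claiming reliability; the point-estimate basis is available for summary
tables.

Lin's CCC (population moments; for k > 2 columns the mean of pairwise
CCCs — the overall-CCC generalization is noted but not implemented) is
computed alongside every ICC, and the per-relationship Spearman correlation
and linear-fit R² between the two metrics quantify whether they rank
features the same way. Category comparisons use two-sided Wilcoxon
rank-sum tests per group (exact null when the combined size is ≤ 20 and
untied, normal approximation with continuity correction otherwise — a
40-feature set split three ways straddles that boundary).

One printed-source subtlety: the one-way ICC denominator is sometimes
printed as MS_R + (k + 1)·MS_W; that form breaks the identical-columns ⇒
ICC = 1 identity and contradicts the McGraw–Wong definitions it cites, so
this package uses (k − 1), under which all identities hold and are tested.

## Feature ranges

`normalizePerPatient()` z-scores each feature within each patient over all
of that patient's contours, both arms pooled — pooled normalization is the
only reading under which manual and semi-automatic ranges are comparable on
one axis. `rangeByMethod()` then records min/max per feature for each arm
and each tool (both groupings are emitted because either could be the
published one), plus overlap/containment flags between the manual and
semi-automatic ranges. Zero-SD cells (all contours of a patient agree)
normalize to 0 with a flag, which keeps the degenerate zero-perturbation
study well-defined: every range is then exactly [0, 0].

## Numerical and design choices

* Arrays are indexed (x, y, z) with spacing in the same order in mm,
  matching R's NIfTI tooling; the transverse plane is a fixed z.
* Volumes and masks are NIfTI-1 (masks as uint8 0/1); feature tables are
  CSV with a JSON category sidecar; reports are CSV + JSON.
* Hausdorff distance is the classic max–max form over boundary-voxel
  centers (boundary = mask voxel with a face-adjacent background
  neighbor), in cm; surface-mesh distances and percentile variants are out
  of scope. Voxel-center distances carry up to one voxel diagonal of
  discretization slack, and tests allow exactly that.
* The group-consensus mask is a voxel-wise majority vote, by default
  ⌈(m + 2)/2⌉ of the m manual first-run contours — the 4-of-6 rule at the
  default design's numbers.
* All randomness flows from one master seed through deterministic
  per-(patient, tool, observer, run) child seeds (polynomial string hash
  modulo 2³¹ − 1), so studies are bit-reproducible and independent across
  cells.
* Problem sizes in the test suite: the directional reproduction runs 50
  replicate 10-patient studies on the 40-feature profile; estimator
  recovery uses n = 2000 matrices (bias) and n = 30 (coverage, 1000
  replicates per cell); the feature-engine fuzz covers 1000 random
  phantoms across the full volume, lumpiness and noise ranges.

## Known limitations

* Phantom texture is stationary Gaussian; real intratumoral texture is
  neither, so absolute texture-feature values are not clinically
  meaningful — only their response to contour variation is.
* The boundary-perturbation model cannot produce topology changes an
  interactive segmenter might (split contours, internal holes): the
  largest connected component is kept by construction.
* GLCM min–max quantization ties texture features to the in-mask intensity
  extremes; features are accordingly sensitive to boundary voxels that mix
  with lung. This mirrors the behavior of min–max-quantizing extractors
  and is part of what the reliability analysis measures.
* ICC magnitudes depend on cohort heterogeneity (more heterogeneous
  cohorts give higher ICCs), so only orderings and classifications —
  not absolute ICC values — transfer between cohorts, synthetic or real.
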