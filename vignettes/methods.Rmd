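---
title: "Morphological classification of multimodal prostate histology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological classification of multimodal prostate histology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Prostate cancer diagnosis rests on glandular architecture in H&E-stained
sections: benign glands are large, irregular lumens ringed by a thin,
ordered epithelial layer; carcinoma shows small rounded lumens, dense and
enlarged epithelial nuclei, and epithelium infiltrating the stroma away
from any lumen. The difficulty for automated analysis is that H&E alone
does not identify *which* pixels are epithelium — stain variability makes
that unreliable. `histomorph` therefore consumes a second modality: a
cell-type label map derived from infrared spectroscopic imaging of a
serial section, where each coarse pixel is already classified as
epithelium, stroma, other or background. The package fuses the two images
and classifies each tissue sample (one microarray core) as cancer or
benign from purely morphological features.

The pipeline is: **register** the label map onto the H&E grid →
**segment** lumens and epithelial nuclei → **extract** a 67-dimensional
feature vector → **select** features (mRMR + SFFS) → **classify** with a
cost-balanced RBF-SVM under repeated stratified cross-validation.

# Registration

Only the macroscopic outline and the lumens are shared between the two
modalities, so both images are reduced to binary tissue masks
(`binarize_he`: a pixel is empty white space when *all three* channels
exceed 200; `binarize_ir`: any non-background label). The transform is
affine with translation $(t_x, t_y)$, rotation $\theta$ and isotropic
scale $s$; the objective is the summed absolute mask difference
(symmetric-difference pixel count), minimised by Nelder–Mead downhill
simplex. Because the masks are binary, no intensity transformation is
needed.

Design choices the model itself leaves open:

* **Pivot.** The rotation/scale centre is fixed at the *target* mask
  centroid. A corner-origin pivot couples rotation and translation so
  strongly that the simplex routinely stalls; the centroid pivot makes the
  parameters nearly orthogonal.
* **Initialisation.** $s_0 = \sqrt{A_\mathrm{ref}/A_\mathrm{tgt}}$ (mask
  true-areas), translation aligning centroids, $\theta_0 = 0$. When
  physical pixel sizes are known the scale starts near their ratio
  ($6.25/0.9636 \approx 6.49$).
* **Restarts.** Five simplex starts perturbing $\theta_0$ by
  $\{0, \pm 0.1, \pm 0.2\}$ rad; best objective wins, ties broken towards
  the smallest $|\theta|$. The objective is piecewise constant in the
  rotation at pixel granularity, and restarts are the cheapest insurance
  against its local minima.
* **Termination.** Absolute objective change below 0.5 px or the
  iteration cap (500 per restart).
* **Resolution bridging.** `register_pair` registers the label-map mask
  against the H&E mask *downsampled* by the integer factor nearest the
  pixel-size ratio, then rescales the fitted parameters exactly to the
  fine grid (`scale_affine_params`, including the half-pixel offset of
  block centres). At the label map's ~6.5 px granularity nothing is
  gained by evaluating the objective on the full H&E grid, and the coarse
  objective is ~40× cheaper. The standalone `register` operates at full
  resolution.

The recovery contract (tested): for transforms within $|t| \le 20$ px,
$|\theta| \le 0.3$ rad, $s \in [0.8, 1.2]$ of the auto-initialisation,
parameters are recovered within (2 px, 2 px, 0.02 rad, 2%) in at least
18 of 20 random mask pairs.

# Segmentation

**Lumens** are empty white spaces (all channels > 200) adjacent to
epithelium-rich areas. *Complete* lumens are interior white components —
not connected to the border background — retained when (a) the fraction
of their dilated boundary ring (width 3 px) overlapping the mapped
epithelium is at least 0.3, (b) their area is within [30, 50000] px, and
(c) solidity (area over convex-image area) is at least 0.7. *Incomplete*
lumens sit at the tissue edge: the sample is modelled as the minimum
enclosing circle of the tissue mask and white components between the
tissue boundary and the circle that touch the tissue are candidates,
filtered by the same size/adjacency rules. Crescent-shaped slivers caused
by the circle fit itself are rejected when the component centroid lies
near the rim (centroid distance / radius > 0.85) *and* the component is a
thin arc (radial extent below 0.2 of the radius). Whether the tissue
circle should be a least-squares or minimum enclosing fit is not dictated
by the method; the minimum enclosing circle is used because it guarantees
the candidates lie between tissue and circle.

**Nuclei** are dark, approximately elliptical, and only meaningful inside
epithelium. The detector: Gaussian smoothing (σ = 1 px) → contrast-limited
adaptive histogram equalisation (tile ≈ 64 px, clip limit 2 in EBImage's
parameterisation) → per-pixel colour score $|R + G - B|$, which is *low*
on blue nuclei (B high, R and G low) and high on pink cytoplasm and white
lumens → Otsu threshold computed on the within-epithelium score histogram
(parameter-free, robust to stain shifts) keeping pixels *below* the cut →
morphological closing (disc radius 1) and hole filling → watershed on the
distance transform with seed separation 3 px → filters: area in
[15, 500] px, eccentricity ≤ 0.97, mean score below the cut, and centroid
inside the epithelium restriction mask.

Two constants deserve explanation. The closing radius is 1 because
epithelial nuclei sit close together; radius 2 fuses neighbours faster
than the watershed can separate them. The watershed seed separation is
3 px — below the typical nucleus radius (~4 px) — because any larger
separation suppresses one of two seeds in touching pairs. The epithelium
restriction mask is the mapped label dilated by 3 px: the label grid is
~6.5× coarser than the H&E grid, so the mapped mask carries about half a
label-pixel of boundary quantisation; without the dilation, genuinely
epithelial nuclei at the ring edge are discarded for being a few pixels
"outside". Consequently the guaranteed invariant is that every nucleus
centroid lies inside the *dilated* epithelium mask.

# Feature extraction

Seventeen quantity categories are measured per sample — eight epithelial
(epithelium area; nucleus areas; nucleus count; per-nucleus distance to
the nearest lumen; per-nucleus distance to the epithelium boundary;
isolated-nucleus count, i.e. no neighbouring centroid within 30 px;
count of nuclei farther than 80 px from any lumen; normalised spatial
entropy of nucleus centroids) and nine lumen-based (area; count;
roundness; distortion; minimum-bounding-circle ratio; convex-hull ratio;
boundary and area symmetry indices; spatial association with
cytoplasm-rich epithelium).

They are summarised twice. **Global** features aggregate over the whole
sample with AVG, STD and (for counts and sizes) TOT. **Local** features
slide a 100 × 100 px window with stride 50 px (half-overlap; windows with
tissue coverage under 0.2 are excluded), compute a within-window AVG or
TOT, and reduce over window positions with STD, MIN or MAX — these
capture focal disease that a whole-sample average dilutes. The default
registry (`feature_registry()`) assigns aggregators so the total is
exactly 67 features: 29 global and 38 local, every category represented
in both scopes; the assignment ships as data and can be swapped via a
JSON registry file. For local lumen area, only the part of a lumen inside
the window is counted.

Definitions worth pinning down:

* **Roundness** is implemented literally as
  $L_\mathrm{peri}^2 / (L_\mathrm{area} \cdot r)$ with
  $r = \sqrt{L_\mathrm{area}/\pi}$. Note this is *scale-dependent*: a
  perfect disc of radius $R$ scores $4\pi/R$, so smaller discs score
  higher. The anomaly is retained rather than "fixed" because downstream
  selection only needs a consistent measure.
* **Perimeter** uses the 8-connected contour chain with the classical
  calibrated step weights (0.948 axis, 1.340 diagonal), which removes the
  ~5% systematic overestimate of raw chain length on smooth boundaries —
  roundness is quite sensitive to this choice.
* **Distortion** is STD/AVG of centroid-to-boundary-pixel distances;
  single-pixel objects return 0 by convention.
* **Convex-hull ratio** uses the convex-image convention (pixels whose
  centres fall in the hull of the set's pixel centres), which is exactly
  1 for convex rasters and always ≥ 1. The **minimum-bounding-circle
  ratio** uses the exact minimum enclosing circle of the pixel *corners*
  (found by convex minimisation of the maximum distance), so it is always
  at least the hull ratio.
* **Symmetry indices** are package-defined surrogates: the pixel set (and
  its boundary set) is reflected across the principal axis through the
  centroid and the normalised symmetric difference is reported — 0 for
  perfect mirror symmetry, both indices in [0, 1].
* **Spatial association with cytoplasm** is the fraction of the lumen's
  dilated boundary ring occupied by epithelial pixels that are pink
  (R > B) rather than nuclear-blue; functional polarisation of benign
  epithelium puts cytoplasm next to the lumen, so benign lumens score
  near 1.
* **Spatial entropy** is Shannon entropy of nucleus-centroid counts on a
  g × g grid (g = 8) over the tissue bounding box, normalised by the log
  of the occupied-cell capacity (the number of grid cells intersecting
  tissue, capped by the nucleus count); a uniform spread scores 1, a
  single cluster 0.
* **Missing policy.** A sample with no lumens (or no valid windows) has
  undefined AVG/STD aggregates; these become the neutral sentinel 0 and
  the vector is flagged (`missing_policy_applied`). TOT aggregates of an
  empty set are genuine zeros, not missing.

# Feature selection

Stage one ranks all features by the minimum-redundancy-maximal-relevance
criterion in the MID (difference) form on 3-bin discretised features
(bins at mean ± SD): the first feature maximises $I(f; y)$, each next
maximises $I(f;y) - \frac{1}{|S|}\sum_{g \in S} I(f;g)$, ties broken
towards the lower column index. Candidate prefixes of length 1..30 are
scored by cross-validated AUC and the best prefix (ties towards smaller)
becomes the candidate set. Stage two is sequential floating forward
selection: repeatedly add the feature whose inclusion maximises the AUC,
then conditionally delete features as long as a deletion strictly
improves the best AUC seen; stop at AUC 1.0 or after 20 additions plus
deletions, returning the best set encountered. The internal criterion is
a 5-fold stratified cross-validated AUC at a fixed seed, so that set
scores are comparable across steps; the SFFS pool is all features, not
just the original candidates.

# Classification and evaluation

The classifier is an RBF-kernel SVM
($K(x_i, x_j) = \exp(-\gamma \lVert x_i - x_j \rVert^2)$, default
$\gamma = 1$, grid {10, 1, 0.1, 0.01, 0.001} exposed in config) with two
cost factors: the positive-class cost is scaled by
$C_+/C_- = \#\mathrm{neg} / \#\mathrm{pos}$ so the potential total cost
of false positives equals that of false negatives. Features are z-scored
by training statistics before the kernel — morphological features mix
pixel counts, distances and dimensionless ratios, and an unscaled RBF
distance would be dominated by whichever has the largest numeric range.
This standardisation is a deliberate, load-bearing addition.

Evaluation is repeated stratified K-fold cross-validation (K = 10). In
every fold the *entire* two-stage selection runs on the training split
only; held-out scores are pooled per repeat into one ROC; the rank-based
(Mann–Whitney) AUC and specificities at 90/95/99% sensitivity (highest
threshold reaching each sensitivity) are averaged over repeats. The
held-out fold can never influence selection, standardisation or training
— this leakage guard is a tested contract, as is transfer evaluation
(`train_test_transfer`: selection and standardisation from the training
cohort only).

# The synthetic tissue generator

Real TMA cohorts are not distributable, so benchmarking uses
`render_sample`/`render_cohort`: paired H&E-like RGB images and coarse
label maps with exact ground truth. A 256² canvas holds a tissue disc;
glands are non-overlapping distorted discs (lumen radius benign
20 ± 4 px clamped at 12, cancer 8 ± 1.5 px; radial harmonics give benign
lumens distortion 0.25, cancer 0.08), each ringed by epithelium (benign
10 px — one to two cell layers at ~1 µm/px — cancer 14 px, plus
infiltrative epithelial foci without lumens in cancer). Elliptical
nuclei (radius 3.4 vs 4.0 px; 6 vs 10 per 1000 px² of epithelium) are
placed in the epithelium without overlapping lumens or each other.
Gaussian pixel noise (SD 8) and an optional stain shift complete the
image. The label map is rendered at the true 6.25/0.9636 pixel-size
ratio and then given a small random affine jitter (±1.5 label px,
±0.03 rad, ±2% scale) so registration is genuinely exercised end to end.

What the generator does *not* emulate: texture inside nuclei and stroma,
chromatic stain interactions, out-of-focus blur, folded or torn tissue,
and touching-gland architecture. Passing segmentation and classification
tests on these images therefore demonstrates the pipeline's mechanics
and its sensitivity to the modelled morphological contrasts — not
performance on real stained tissue.

Problem sizes used by the test-suite and the acceptance script (chosen
as the smallest cohorts at which the contrasts and error rates
stabilise): 20 mask pairs for registration recovery; 20 rendered samples
for segmentation recovery; 50 simulated 8-feature tables for the
selection oracle; a 60 + 60 cohort with 10-fold cross-validation, two
repeats. The permuted-label null is reported as the mean over three
label permutations (single repeats each): one permutation draw of the
pooled AUC has a standard deviation near 0.1 at this cohort size —
selection on permuted labels overfits training noise, which both widens
the null and centres it slightly below 0.5 — so a single draw is too
noisy to summarise the null.

# Degenerate inputs and numerical conventions

Coordinates are 0-based, row-major (row, col), pixel centres; all
geometry is in H&E pixel units. Empty masks are an error for
registration; tissue under 50 px is an error for edge-lumen detection;
samples whose label map has ≤ 100 epithelial pixels are excluded at the
pipeline level with reason `insufficient_epithelium`, so cohort
accounting stays auditable. Single-class label vectors are errors for
the cost ratio, AUC and cross-validation. Zero-variance features
standardise with unit scale. All stochastic steps (folds, generator,
simplex restarts are deterministic) derive from explicit seeds, and
repeated runs with the same seed are bit-identical.

# Known limitations

* The mapped epithelium mask inherits the label map's ~6.5 px
  granularity; nucleus-level epithelium membership is only accurate to
  that scale.
* The exact 67-feature table of the original method is not public; the
  registry here is a faithful reconstruction of the documented counts
  (67 = 29 global + 38 local over 17 categories) with a documented
  default assignment, not a guaranteed feature-for-feature match.
* Symmetry indices, cytoplasm association and spatial entropy are
  package-defined surrogates for quantities whose exact published
  definitions are unavailable.
* SFFS is greedy; on signals visible only through high-order feature
  interactions (e.g. pure parity) it can miss the optimum. The tested
  contract is agreement with exhaustive search on additive signals.
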