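# histomorph

Morphology-based cancer classification of multimodal prostate histology.

Prostate cancer diagnosis rests on glandular architecture: benign glands
are large, irregularly shaped lumens ringed by a thin ordered layer of
epithelium, while carcinoma shows small rounded lumens, dense enlarged
epithelial nuclei, and epithelium infiltrating away from any lumen. The
hard part of automating this readout is knowing *which* pixels are
epithelium — H&E staining alone is too variable. `histomorph` consumes a
second modality per tissue sample: a cell-type label map (epithelium /
stroma / other / background) derived from infrared spectroscopic imaging
of a serial section, at ~6.25 µm/px against the H&E image's ~0.96 µm/px.

For whom: image-analysis and computational-pathology researchers who
want a transparent, fully scripted pipeline from paired images to a
cross-validated cancer/benign classifier, with a synthetic ground-truth
generator for benchmarking every stage.

## The method

1. **Registration.** Both images are reduced to binary tissue masks and
   aligned by an affine transform — translation (t_x, t_y), rotation θ,
   isotropic scale s, pivoted at the target-mask centroid — minimising
   the summed absolute mask difference with Nelder–Mead downhill simplex
   (5 rotation restarts, area-ratio scale initialisation).
2. **Segmentation.** Lumens are white components (all RGB channels
   > 200) adjacent to epithelium, detected both inside the tissue and at
   its edge (tissue modelled as its minimum enclosing circle; crescent
   artifacts of the circle fit rejected). Nuclei are found inside the
   mapped epithelium by smoothing, adaptive histogram equalisation, a
   per-pixel |R + G − B| colour score (low on blue nuclei), Otsu
   thresholding, morphological closing and a distance-transform
   watershed, then filtered by size, eccentricity and mean score.
3. **Features.** 17 categories of epithelial and lumen quantities
   (sizes, counts, nucleus–lumen distances, spatial entropy, lumen
   roundness L²_peri/(L_area·r), distortion STD/AVG of centre-boundary
   distances, bounding-circle and convex-hull ratios, symmetry indices,
   lumen–cytoplasm association) summarised as 29 global (AVG/STD/TOT)
   plus 38 local features (STD/MIN/MAX over 100×100 px sliding windows)
   — 67 features in all.
4. **Selection.** mRMR ranking (MID form, 3-bin discretisation), best
   prefix of at most 30 features by cross-validated AUC, then sequential
   floating forward selection with a 20-step add/remove budget.
5. **Classification.** RBF-kernel SVM (default γ = 1) with the
   positive-class cost scaled by C+/C− = #neg/#pos, features z-scored by
   training statistics; evaluated by repeated stratified 10-fold
   cross-validation with nested selection, reporting pooled rank AUC and
   specificity at 90/95/99% sensitivity.

## Worked example

Generate a small synthetic cohort with ground truth, run the full
pipeline, and evaluate:

```r
library(histomorph)

dir <- tempfile("cohort")
render_cohort(n_benign = 60, n_cancer = 60, out_dir = dir, seed = 7)

cfg <- pipeline_config(seed = 7, clf = classifier_config(n_repeats = 2))
res <- run_pipeline(file.path(dir, "manifest.csv"), cfg,
                    out_dir = file.path(dir, "out"))
print(res$report)
```

```
Cross-validated evaluation: AUC 1.000 (sd 0.0000) over 2 repeat(s), 10 fold(s)
  specificity at 90% sensitivity: 100.00% (sd 0.00)
  specificity at 95% sensitivity: 100.00% (sd 0.00)
  specificity at 99% sensitivity: 100.00% (sd 0.00)
```

The synthetic presets separate cleanly by design — benign samples have
few large irregular lumens with sparse nuclei, cancerous samples many
small round lumens with dense nuclei — so a correct pipeline should
reach AUC ≈ 1 here, and permuting the labels should (and does) drop the
AUC to ≈ 0.5. A single sample can be inspected step by step:

```r
smp <- render_sample(tissue_params("cancer", seed = 2))
reg <- register_pair(smp$pair)        # params on the H&E grid
seg <- segment_sample(smp$pair, reg)  # lumens + nuclei + masks
fv  <- extract_features(seg, smp$pair$he)
length(seg$nuclei)     # e.g. 74 detected nuclei
fv$values["G_TOT_lumen_count"]
```

A thin command-line front end wraps the same functions
(`exec/histomorph`): subcommands `synth`, `register`, `segment`,
`extract`, `select`, `evaluate`, `run-all`.

## Layout

- `R/` — imaging core, registration, segmentation, features, selection,
  classification, synthetic generator, pipeline, CLI.
- `tests/testthat/` — unit, property and acceptance tests (fixtures are
  generated in code).
- `vignettes/methods.Rmd` — the model, its assumptions, every tunable
  constant with its rationale, and known limitations.
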