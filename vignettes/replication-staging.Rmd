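---
title: "Methods: staging DNA replication from nuclear images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staging DNA replication from nuclear images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, parameter choices, and statistical design
behind `replistage`. Code chunks are illustrative and not evaluated when the
vignette is built; the README contains a fully executed example.

## 1. Biological model

DNA replication proceeds through a reproducible spatial program. Pulse-labeling
nascent DNA with EdU produces a focal pattern whose morphology indicates
position within S phase:

| class | foci | size | placement |
|---|---|---|---|
| early | many (~100+) | small | diffuse through euchromatin |
| early-mid | many | small–medium | diffuse + chromocenter rims |
| mid | moderate | medium | chromocenters and nuclear periphery |
| mid-late | few | large | chromocenters and interior clusters |
| late | very few | largest | large heterochromatin blocks, not chromocenter rims |
| G1/G2 | none | — | EdU-negative background only |

The package treats this six-way labeling as the supervised target, and the
continuous progression through it as the signal the self-supervised embedding
should recover.

## 2. Synthetic microscopy generator

`generate_nucleus` renders one nucleus on an 80 × 80 px native crop
(0.1625 µm/px scale convention):

- **Nucleus shape**: an ellipse with semi-major axis drawn in (29, 33) px and
  axis ratio in (0.84, 0.95) — sized so that area, axis and eccentricity all
  sit comfortably inside the mESC filter window, since the generator's clean
  output is required to pass quality control at ≥ 95%.
- **DAPI texture**: base nuclear signal plus 5–8 chromocenters (radius
  3.8–4.8 px) of elevated intensity; background offset 150 grey levels.
- **EdU foci**: `n_foci` Gaussian spots with per-class σ (1.2 px early →
  3.0 px late), placed by the class's placement mixture (diffuse,
  chromocenter, periphery, non-chromocenter interior). Total EdU mass is
  scaled to a target mean (3200 for S-phase classes; 300, i.e. below the
  1000-threshold, for G1/G2).
- **Noise**: Poisson shot noise on 16-bit intensities, clipped at 65535.

Class invariants are enforced at the pattern level: G1/G2 nuclei are
EdU-negative by the filter's definition (mean < 1000), early patterns are
purely diffuse, late patterns avoid chromocenter placement. These mirror the
qualitative biology; absolute intensities, focus counts, and σ values are the
package's own desk-scale choices, selected once so that (a) clean nuclei pass
the quality filters and (b) a pixel-level oracle statistic (the fraction of
EdU mass inside the chromocenter mask, `edu_chromocenter_fraction`) perfectly
separates early from late — i.e. the classes carry learnable signal. They are
study conditions, not tuning knobs: no generator parameter is adjusted to the
outcome of any downstream learning experiment.

`condition_effect` models perturbations: `early_like_shift` (probability that
a non-early S nucleus is re-rendered with a diffuse, early-like pattern),
`focus_count_multiplier`, and `artifact_rate`. `generate_field` places
non-overlapping nuclei in a 512 × 512 field by rejection sampling;
`generate_dataset` writes multi-field, multi-condition TIFF datasets with a
manifest and a completion marker.

**What the generator does *not* emulate**: optical PSF anisotropy, chromatic
aberration, bleaching, stage drift, cell-cycle-correlated nucleus size, and
real chromatin texture. It is a validation harness, not a microscope
simulator.

## 3. Segmentation

DAPI → Otsu threshold (exhaustive between-class-variance maximization over
observed grey levels) → hole filling → removal of sub-200 px debris →
Euclidean distance map, Gaussian-smoothed (σ = 4) → local-maximum seeds with
a minimum separation → Voronoi-style propagation within the foreground mask.
Touching nuclei are split by their distance-map basins. `extract_records`
produces one `nucleus_record` per label: a fixed-size crop (zero-padded at
field borders), its binary mask, moment-based region properties (area,
centroid, axis lengths via √eigenvalues of the second-moment matrix,
eccentricity), and a border flag.

## 4. Quality filtering

`compute_qc` computes, per channel: whole-crop mean, mean of the central
10 × 10 window, a blur metric (one minus the ratio of re-blurred to original
high-frequency content, computed per axis with uniform 11-tap smoothing;
1 = featureless), gradient sharpness (mean Sobel magnitude), and a
low-contrast flag (1st–99th percentile span below 5% of dtype range).

`filter_profile` bundles thresholds into named dialects:

- **mESC** (DAPI + EdU): area 2000–10000 px², minor axis ≥ 40 px, major axis
  ≤ 120 px, eccentricity ≤ 0.7, EdU whole and center mean ≥ 1000, blur ≤ 0.75
  (DAPI) / 0.7 (EdU).
- **U2OS** (DAPI + EdU + PCNA): area ≤ 25000 px², major axis ≤ 250 px,
  eccentricity ≤ 0.8, EdU mean ≥ 2000, PCNA whole and center mean ≥ 500,
  blur ≤ 0.75/0.7/0.7, sharpness ≥ 100 (EdU) / 50 (PCNA), and EdU
  low-contrast exclusion.

`apply_filters` evaluates every criterion independently and returns a named
per-criterion report — a record fails with a list of reasons, never silently.
The engine is verified against a brute-force per-criterion oracle on 1000
randomized records.

## 5. Supervised staging classifier

A small 4-block CNN (3 × 3 convolutions, ReLU, 2 × 2 average pooling, global
average pooling, linear head) implemented directly on BLAS matrix products
(im2col); every layer's gradient is verified by finite differences to
rel. error < 1e-6. Training: SGD with momentum 0.9, cosine-annealed learning
rate with warm restarts (period 20 epochs, 1e-2 → 0), batch 32,
inverse-class-frequency weighted resampling, early stopping on validation
accuracy. Splits are 60:20:20, stratified per class with largest-remainder
rounding (each stratum within ±1 of its exact share). A ResNet-50 option is
config-selectable but intentionally not implemented in this desk-scale
package; the recipe, not the parameter count, is what the package embodies.
Inputs are resized to a declared side (default 224, acceptance experiments
use 32), scaled from 16-bit to [0, 1], and channel-standardized with
training-set statistics.

## 6. Self-supervised BYOL embedder

Two augmented views (horizontal flip / vertical flip) pass through an online
network (encoder → projector → predictor) and a target network (encoder →
projector). The loss is the symmetrized cosine distance
`2 − 2·cos(pred_online, proj_target)` with a stop-gradient on the target;
target parameters follow the online ones by exponential moving average with
constant τ = 0.99. Optimizer: Adam, lr 3e-4, β₁ = 0.9, β₂ = 0.999, trained
from scratch. Projector/predictor are 2-layer MLPs with batch
normalization (defaults 256-d output, 4096-d hidden; acceptance experiments
use 32/128). Embeddings are taken at the global-average-pool layer. The
implementation asserts the stop-gradient numerically: target gradient norms
are identically zero throughout training.

## 7. Embedding analysis and statistics

- **Common PC space**: PCA is fit once on a reference condition
  (`fit_pca`; sign convention: largest-magnitude loading positive) and all
  conditions are projected into it, so coordinates are comparable across
  groups.
- **Density maps**: 2-D KDE (`MASS::kde2d`) on a 200 × 200 grid, bandwidth =
  normal reference rule × 2, evaluation range extended 3 bandwidths beyond
  the data, contours from 10% of peak density.
- **Threshold proportions**: a rule such as `PC1 > t` (fixed by the user or
  derived from a reference quantile via `quantile_threshold_rule`) converts
  each group to a binomial count; groups are compared with the pooled
  two-proportion Z test, and per-group uncertainty uses the normal
  approximation `p̂ ± 1.96·√(p̂(1−p̂)/n)` (bounds clamped to [0, 1]).
- **Outlier accounting**: `axis_outlier_counts` applies axis limits in order
  with first-match attribution so per-rule counts are disjoint and sum to the
  total excluded.
- **Class composition**: `class_distribution_report` gives per-group
  proportions with CIs, an overall chi-squared homogeneity test, and pairwise
  Z tests.

### Design of the shift-detection experiment

The end-to-end validation plants a `condition_effect` and asks the embedding
pipeline to detect it via the threshold-proportion Z test at p < 0.01, while
100 matched null comparisons (two groups from the identical generative
distribution) must reject at no more than the nominal rate. Because the
uncorrected pooled Z test is slightly anti-conservative for moderate
proportions, the experiment's exact size was computed by exhaustive binomial
enumeration: with balanced groups of 80 and a tail proportion near 0.25
(reference-quantile threshold q = 0.75), the exact size at α = 0.01 is
0.0098 — at or below nominal — whereas designs with p ≈ 0.4 exceed it. The
q = 0.75 / n = 80 / α = 0.01 design is therefore fixed in the acceptance
tests.

## 8. Pipeline and provenance

`run_pipeline` executes simulate → segment → filter → embed → analyze →
report, journaling each stage in `pipeline_status.yaml` (a failure marks the
stage `failed` and leaves later stages `pending`). `provenance.json` records
the MD5 hash of the canonicalized config, the master seed, and per-stage
derived seeds. All stochastic steps derive their streams from one master seed
via a deterministic `child_seed` map, so identical configs reproduce all
tabular outputs bit for bit. Every row in the final report traces back
through filter report and segmentation label to its source field and
ground-truth nucleus id.

## 9. Limitations

- The synthetic generator validates algorithms; results do not transfer
  quantitatively to real microscopy without retraining and re-tuning filter
  dialects.
- The pure-R network engine is desk-scale: suitable for ~10³–10⁴ small
  images, not for 224 px ResNet-scale training.
- The two-proportion Z test is asymptotic; for very small groups or extreme
  thresholds use the exact-enumeration reasoning of Section 7 before trusting
  nominal levels.
- Chromocenter ground truth is only available for synthetic data; on real
  images the placement mixture is latent.
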