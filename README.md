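# replistage

Quantifying the spatiotemporal dynamics of DNA replication from multi-channel
fluorescence images of nuclei.

During S phase, the spatial pattern of active replication foci changes in a
stereotyped progression: many small foci spread through the nuclear interior
(early), signal accumulating at chromocenters and the nuclear periphery (mid),
and a few large clusters on late-replicating heterochromatin (late). Labeling
nascent DNA with EdU (or marking replisomes with PCNA) therefore timestamps a
nucleus within S phase from a single snapshot. `replistage` implements the
full analysis chain for such data:

1. **Synthetic microscopy** (`generate_nucleus`, `generate_field`,
   `generate_dataset`) — a seeded renderer for the five S-phase pattern
   classes (early, early-mid, mid, mid-late, late), EdU-negative G1/G2
   nuclei, imaging artifacts (blur, abnormal morphology, mis-segmentation),
   and configurable condition effects, so every downstream stage can be
   exercised and validated at desk scale without microscope data.
2. **Segmentation** (`segment_field`, `extract_records`) — Otsu thresholding
   of the DAPI channel, hole filling, distance-map seeded watershed to split
   touching nuclei, and per-nucleus crop extraction with region properties.
3. **Quality filtering** (`compute_qc`, `filter_profile`, `apply_filters`) —
   a transparent per-criterion filter engine (area, axis lengths,
   eccentricity, whole-crop and nucleus-center intensities, wavelet-free blur
   metric, gradient sharpness, low-contrast flag) with mESC and U2OS
   threshold dialects; every rejection names the criterion that failed.
4. **Supervised staging** (`train_classifier`, `evaluate_classifier`) — a
   small CNN trained with inverse-class-frequency resampling and
   cosine-annealed warm-restart SGD; 60:20:20 stratified splits with
   largest-remainder rounding.
5. **Self-supervised embedding** (`train_byol`, `embed_images`) — a
   from-scratch BYOL implementation (online/target networks, predictor,
   EMA target updates, stop-gradient, horizontal/vertical-flip views) with a
   pure-R/BLAS conv-net engine; no GPU or deep-learning framework required.
6. **Embedding analysis** (`fit_pca`, `project_embeddings`, `kde_map`,
   `threshold_proportions`, `axis_outlier_counts`) — common principal
   component space across conditions, kernel-density maps, threshold-rule
   proportions with two-proportion Z tests, and first-match axis-limit
   outlier accounting.
7. **Statistics & reporting** (`proportion_ci`, `chi2_homogeneity`,
   `class_distribution_report`) and a **pipeline runner/CLI**
   (`run_pipeline`, `pipeline_cli`) with YAML configs, stage journaling,
   provenance hashes, and bit-reproducible tabular outputs.

## Worked example

```r
library(replistage)

## 1. Simulate a field of nuclei and segment it from the DAPI channel
field <- generate_field(n_nuclei = 8,
                        class_mixture = c(early = 0.3, mid = 0.4, late = 0.3),
                        rng_seed = 1)
labels <- segment_field(field$field)
records <- extract_records(field$field, labels, crop_size_px = 80,
                           field_id = "f001")
cat("segmented nuclei:", length(records), "\n")
#> segmented nuclei: 8

## 2. Quality-control filtering with the mESC threshold dialect
records <- lapply(records, compute_qc)
res <- filter_records(records, filter_profile("mESC"))
print(res[, c("field_id", "label", "pass")])
#>   field_id label pass
#> 1     f001     1 TRUE
#> 2     f001     2 TRUE
#> 3     f001     3 TRUE
#> 4     f001     4 TRUE
#> 5     f001     5 TRUE
#> 6     f001     6 TRUE
#> 7     f001     7 TRUE
#> 8     f001     8 TRUE

## 3. Train a supervised stage classifier on synthetic nuclei
g <- generate_nuclei(300, c(early = 0.5, g1g2 = 0.5), rng_seed = 1)
sp <- stratified_split(g$manifest$s_class, seed = 1)
cfg <- train_config(max_epochs = 6, patience = 6, seed = 1)
m <- train_classifier(g$images[, , , sp$train, drop = FALSE],
                      g$manifest$s_class[sp$train],
                      g$images[, , , sp$val, drop = FALSE],
                      g$manifest$s_class[sp$val], cfg)
ev <- evaluate_classifier(m, g$images[, , , sp$test, drop = FALSE],
                          g$manifest$s_class[sp$test])
print(ev$confusion)
#>        predicted
#> true    early g1g2
#>   early    28    0
#>   g1g2      0   32
cat(sprintf("held-out accuracy: %.3f\n", ev$accuracy))
#> held-out accuracy: 1.000

## 4. Self-supervised embedding and condition-shift detection
mix <- c(early = 0.2, early_mid = 0.2, mid = 0.2, mid_late = 0.2, late = 0.2)
pool <- generate_nuclei(100, mix, rng_seed = 2)
enc <- train_byol(pool$images, byol_config(input_side = 32,
                                           projection_size = 32,
                                           projection_hidden_size = 128,
                                           steps = 100, seed = 1))
basis <- fit_pca(embed_images(enc, pool$images))
treated <- generate_nuclei(60, mix, rng_seed = 3,
                           effect = condition_effect(early_like_shift = 0.9,
                                                     focus_count_multiplier = 2))
control <- generate_nuclei(60, mix, rng_seed = 4)
pc <- project_embeddings(rbind(embed_images(enc, control$images),
                               embed_images(enc, treated$images)), basis)
rule <- quantile_threshold_rule(
  project_embeddings(embed_images(enc, pool$images), basis), "PC1", 0.75)
shift <- threshold_proportions(pc, rep(c("control", "treated"), each = 60), rule)
print(shift$proportions)
#>     group  n  k proportion   ci_lower  ci_upper
#> 1 control 60 10  0.1666667 0.07236612 0.2609672
#> 2 treated 60  3  0.0500000 0.00000000 0.1051477
print(shift$tests)
#>    group1  group2        z    p_value
#> 1 control treated 2.056009 0.03978161
```

Even at this deliberately tiny scale (100 training nuclei, 100 BYOL steps,
60 nuclei per group), the embedding separates the perturbed condition from
its control at p < 0.05; the package's acceptance experiment, at a modestly
larger scale, detects the planted effect at p < 0.01 while 100 matched null
comparisons reject at no more than the nominal rate.

## The end-to-end pipeline

A single YAML config drives simulation → segmentation → filtering →
embedding → analysis → report:

```sh
Rscript inst/cli/replistage.R run --config analysis.yaml
```

Each run directory contains `segmentation.csv`, `filter_results.csv`,
`embeddings.csv`, `pc_coordinates.csv`, `analysis.json`, `class_report.csv`,
a `pipeline_status.yaml` stage journal, and `provenance.json` with the config
hash and all derived seeds. Re-running an identical config reproduces every
tabular output byte for byte.

## License

MIT. See `LICENSE`.
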