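# histotex

Texture- and colour-based grading of H&E-stained prostate tissue patches in
R.

Histological grading of prostate carcinoma (Gleason benign / grade 3 /
grade 4 / grade 5) is driven by two visual cues in a stained section: the
spatial texture of glands and nuclei, and the colour balance of the
haematoxylin (blue, nuclei) and eosin (pink, stroma) stains. `histotex`
implements a complete patch-classification pipeline around those cues:

1. **Haar wavelet decomposition.** Each 256 × 256 patch is converted to
   grayscale and decomposed with the orthonormal 2-D Haar transform
   (low-pass `(1,1)/√2`, high-pass `(1,−1)/√2`, rows then columns) into
   level-1 sub-bands `LL1, LH1, HL1, HH1` (128²) and, from `LL1`, level-2
   sub-bands (64²).
2. **GLCM texture features.** For each sub-band of a level, the gray-level
   co-occurrence matrix p(i, j) is formed at unit distance in the four
   directions 0°, 45°, 90°, 135° (offsets (0,1), (−1,1), (−1,0), (−1,−1)),
   with G = 128 gray levels at level 1 and 64 at level 2. Six Haralick
   statistics — contrast Σ|i−j|²p, homogeneity Σp/(1+(i−j)²), correlation
   Σp(i−μx)(j−μy)/(σxσy), energy Σp², entropy −Σp log p, dissimilarity
   Σ|i−j|p — are averaged over the 16 band × direction combinations.
3. **Colour moment features.** Per RGB channel, population moments in root
   form — mean, standard deviation, variance, signed cube root of the third
   central moment (skewness), fourth root of the fourth (kurtosis) —
   averaged over channels: 5 features, joining the 6 texture statistics in
   an 11-feature record per image per level.
4. **MANOVA screen.** One-way MANOVA (Pillai's trace, Wilks' lambda
   alongside) plus per-feature one-way ANOVA across the four grade groups;
   features with P < α are flagged (and optionally dropped).
5. **MLP classification.** A from-scratch 11–4–3–2 sigmoid multilayer
   perceptron, trained by per-sample stochastic gradient descent with
   momentum (squared-error loss, η = 0.3, m = 0.2, 500 epochs by default)
   on a stratified 7:3 split, applied to the five standard binary
   contrasts: benign vs malignant, benign vs grade 3 / 4 / 5, and grade 3
   vs grades 4/5. Performance is reported as accuracy, sensitivity,
   specificity, F1 and Matthews correlation coefficient (MCC), in percent.

Clinical image sets of this kind are generally not public, so the package
ships a seeded synthetic H&E-like patch generator
(`generate_cohort()`) whose grade parameters (gland size, nuclei density,
stain colours) vary monotonically across grades, making every downstream
stage testable and reproducible offline. `infer_confusion()` additionally
recovers integer confusion matrices from published
accuracy/sensitivity/specificity triples, for auditing printed performance
tables.

## Worked example

```r
library(histotex)
library(dplyr)

# a small synthetic cohort: 8 patches per grade, 64 px, fixed seed
cohort <- generate_cohort(cohort_spec(images_per_grade = 8,
                                      image_size = 64, seed = 2024))
feats <- extract_features(cohort, levels = c(1, 2), glcm_levels = c(32, 16))

screen <- feature_screen(feats)
glance(screen)
#> # A tibble: 2 × 4
#>   level pillai approx_f  p_value
#>   <int>  <dbl>    <dbl>    <dbl>
#> 1     1   2.45     8.18 1.81e-12
#> 2     2   2.40     7.35 1.82e-11

fit <- mlp_fit(feats, "benign_vs_grade5",
               mlp_config(seed = 4, epochs = 300), level = 1)
fit
#> MLP fit: benign_vs_grade5
#>   architecture: 11-4-3-2  epochs: 300  eta: 0.3  momentum: 0.2
#>   train/test: 12 / 4
#>   test accuracy 100.0%, sensitivity 100.0%, specificity 100.0%
```

The Pillai traces near their maximum (min(groups − 1, features) = 3) with
vanishing P-values say the four synthetic grades differ strongly in the
joint 11-feature distribution at both wavelet levels; the fitted contrast
then separates benign from grade-5 patches perfectly on its held-out split.
At the full study size (100 images per grade, 256 px) the same call chain
runs through `run_pipeline()`, which also emits the per-level metric tables
and the level comparison:

```r
run <- run_pipeline(cohort_spec(seed = 1), mlp_config(seed = 1))
run$metrics      # 5 contrasts x 2 levels x 5 metrics
plot_level_comparison(run$metrics)
```

Auditing a printed table row (accuracy 98.3, sensitivity 100.0,
specificity 96.8 on 60 test samples):

```r
infer_confusion(98.3, 100.0, 96.8, total = 60)
#>      tp    fn    fp    tn accuracy sensitivity specificity    f1   mcc
#>      29     0     1    30     98.3         100        96.8  98.3  96.7
```

The recovered matrix is unique, and the recomputed F1 (98.3) and MCC (96.7)
match the printed row.

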