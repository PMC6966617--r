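---
title: "Wavelet texture and colour-moment grading: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet texture and colour-moment grading: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histotex)
library(dplyr)
```

## The problem and the model

Gleason grading of prostate carcinoma is read off H&E-stained sections:
benign tissue shows large, well-formed glands with sparse nuclei; with
increasing grade the glands shrink and fragment while nuclei density rises.
Two feature families capture this quantitatively. *Texture*: the gray-level
co-occurrence matrix (GLCM) of a patch, computed over Haar wavelet
sub-bands so that both coarse (approximation) and fine (detail) spatial
scales contribute. *Colour*: the moment structure of the RGB intensity
distributions, which tracks the haematoxylin/eosin balance.

The pipeline is: RGB patch → grayscale (luma weights 0.299/0.587/0.114) →
two-level Haar decomposition → per-sub-band GLCMs in four directions → six
averaged Haralick statistics per level; in parallel, per-channel colour
moments averaged over channels → five colour features. The resulting
11-feature records are screened by one-way MANOVA/ANOVA across the four
grade groups and classified with a small sigmoid multilayer perceptron
(11–4–3–2) on five binary grade contrasts, reporting accuracy,
sensitivity, specificity, F1 and MCC on a stratified 7:3 hold-out.

## Haar normalization and band naming

Two-tap Haar filters come in two common normalizations: the orthonormal
pair $(1,1)/\sqrt2$, $(1,-1)/\sqrt2$ and the running-average pair
$(1,1)/2$, $(1,-1)/2$. We default to the orthonormal form because it makes
the transform an isometry — perfect reconstruction and Parseval energy
conservation hold to machine precision, which the test suite asserts at
relative tolerance $10^{-9}$ — and therefore keeps sub-band magnitudes
comparable across levels when they are re-quantized for the GLCM. The
averaging variant is exposed (`normalization = "average"`) for
compatibility with texts that define the approximation band as a running
mean. Band letters record the (row filter, column filter) pair: `LH` is
row-high/column-low. Texts disagree on which of `LH`/`HL` to call
"horizontal"; we avoid the adjectives in code and document the convention
here instead.

Patches must have dyadic-compatible sizes (divisible by $2^{levels}$);
non-conforming inputs are rejected rather than padded, since padding
policies silently change texture statistics at the boundary.

## GLCM construction

The stated GLCM sizes (128² at level 1, 64² at level 2) are read as the
number of quantization levels equalling the sub-band side length of a
256-pixel patch — the only reading under which a GLCM of those dimensions
exists. Each sub-band is quantized from its *own* min–max range (detail
bands contain negatives), linearly onto bins $0..G-1$; a constant band maps
to bin 0. Pairs are *ordered* (asymmetric matrix) at unit distance with
offsets $(0,1), (-1,1), (-1,0), (-1,-1)$ for 0°, 45°, 90°, 135°;
out-of-bounds neighbours are dropped and counts normalized to sum to one.
A symmetric option exists but is off by default, matching the directional
offset definitions.

Three statistics as commonly printed contain typographic slips, which we
correct to the standard Haralick forms: contrast and dissimilarity weight
$p(i,j)$ (not "$p(i-j)$"), homogeneity divides by $1+(i-j)^2$ (a $(i+j)^2$
denominator would not be a similarity measure), and correlation pairs
$(i-\mu_x)$ with $(j-\mu_y)$. Entropy uses the natural log (configurable);
$0\log 0 = 0$. When a marginal standard deviation vanishes the correlation
is undefined and surfaces as `NA` — never as a silent 0 — and is excluded
from the 16-combination average; if a record still lacks a defined
correlation it is imputed with the per-class mean and flagged.

Averaging each statistic over the 4 sub-bands × 4 directions of a level is
what reduces the texture block to 6 features so the final vector has the
stated 11 dimensions. Whether the original analysis averaged or
concatenated-then-screened is not recorded anywhere we could verify; the
per-band, per-direction long table remains available
(`texture_features(..., detail = TRUE)`) for either analysis.

## Colour features

Colour percentages are implemented as intensity-mass shares
($100\sum_c p_c / \sum p$), which always sum to 100; the alternative
dominant-channel pixel count is available behind `method = "dominant"`.
The five moments follow the root-form definitions — standard deviation and
variance from the population second moment, skewness as the *signed cube
root* of the third central moment, kurtosis as the fourth root of the
fourth — rather than the dimensionless standardized moments; the
standardized variants are available via `standardized = TRUE`. Root-form
kurtosis is always non-negative and bounded by the largest absolute
deviation, both of which are property-tested. Averaging the moments over
R, G, B yields the 5 colour features; the per-channel table is retained.

## The significance screen

`feature_screen()` fits a one-way MANOVA across the four grades and
reports Pillai's trace (robust near singular within-group covariance) with
Wilks' lambda alongside, plus a univariate one-way ANOVA per feature. The
univariate F is the quantity tested against a brute-force sum-of-squares
oracle and the $F = t^2$ identity. Because no surviving-feature list is
recoverable from published work of this design — all 11 features appear to
be used downstream — the default screens but does not drop
(`select = FALSE`); setting `select = TRUE` restricts the classifier to
features with $P < \alpha$ (default 0.05). No multiple-testing correction
is applied, matching the screen's descriptive role. MANOVA failure (e.g.
singular covariance) falls back to the univariate screen with a warning.

## The classifier

The 11–4–3–2 network uses sigmoid activations throughout and one-hot
binary targets. A perceptron-style weight update alone cannot train hidden
layers, so training is full backpropagation of the squared error
$L = \tfrac12\|a - y\|^2$, per-sample stochastic gradient descent with a
momentum buffer $v \leftarrow mv - \eta\nabla$, $w \leftarrow w + v$.
Gradients are verified against central differences at relative $10^{-6}$.
Defaults $\eta = 0.3$, $m = 0.2$, 500 epochs are the WEKA MLP defaults;
per-contrast tuned values used in prior studies are unrecoverable, so the
defaults are fixed and exposed in `mlp_config()`.

Two paper-silent choices were necessary and are deliberate:

* **Standardization.** GLCM contrast and colour variance differ by orders
  of magnitude; unscaled inputs saturate the sigmoids. Features are
  z-scored with training-split statistics (never test statistics).
* **Class balancing.** The benign-vs-malignant contrast is 100 vs 300 at
  the default cohort size; the majority class is subsampled to balance
  before the stratified split (consistent with ≈30+30 test splits implied
  by published n = 60 rows). `balance = FALSE` restores full-data
  training.

The positive class of every contrast is the higher-grade side. Prediction
is argmax over the two output scores with ties resolved toward the
positive class. Weight initialization is uniform$(-0.5, 0.5)$ from the
seed; the split, balancing, shuffling and initialization all derive from
`mlp_config(seed = )`, and `run_pipeline()` fans one master seed out to
cohort synthesis and per-contrast sub-seeds, so a single integer
reproduces a full study bit-identically.

## The synthetic cohort

No clinical image set of this design is deposited, so the generator
targets the *statistical contract* the pipeline assumes rather than visual
realism: pink stroma, near-white elliptical gland lumina whose mean radius
decreases with grade (24 → 14 → 8 → 4 px), dark nuclei discs whose density
increases (0.8 → 1.8 → 2.8 → 4.0 per 1000 px²), slightly darkening stroma,
and additive Gaussian noise (sd 8) clipped to [0, 255]. These defaults are
calibration choices fixed once — no quantitative texture statistics of any
real cohort of this design are published to match — and chosen so classes
are separable but adjacent grades overlap more than extreme ones. The
default cohort is 400 images, 100 per grade, 256 × 256 × 24-bit, matching
the usual study size.

What passing tests on this cohort do show: the pipeline's stages transform
separable inputs into separable features and a trainable classifier, with
every numeric stage verified against independent oracles. What they do not
show: performance on real tissue, where stain variability, artefacts and
morphological complexity dominate; synthetic accuracies (≈99% on the
easiest contrasts) exceed realistic clinical figures precisely because the
generator honours the separability contract so cleanly.

Per-image seeds are hashes of (cohort seed, class index, replicate index),
so replicate $k$ of a grade is identical regardless of cohort size — a
property the test suite checks.

## Auditing printed performance tables

`infer_confusion()` inverts the printed (accuracy, sensitivity,
specificity) triple of a table row by exhaustive search over integer
confusion matrices of a given total. Under round-half-away-from-zero to
one decimal, six of the ten published per-contrast rows of this study
design resolve uniquely at $n = 60$ and their recomputed F1/MCC agree with
print to the printed precision; two rows are consistent only under
truncation toward zero (both conventions are supported, half-away being
the default), and the two grade-3 vs grade-4/5 rows admit *no* integer
matrix at $n = 60$ under either — the audit documents, rather than
resolves, that inconsistency, which also blocks reconciling the stated
level-1 weighted-average accuracy. Degenerate inputs (e.g. all metrics
100) return the full candidate set flagged non-unique.

## Numerical and scale choices

* Wavelet tests use 16×16 random matrices (100 replicates) for
  reconstruction/Parseval and ≤16×16 for the explicit block-sum oracle;
  GLCM oracles use 8×8 random matrices at tolerance $10^{-12}$.
* The shared test cohort is 8 images/grade at 64 px with 32/16 gray
  levels — small enough for fast property tests, large enough for
  Cohen's $|d| > 1$ class contrast. The end-to-end learning checks use
  the full default cohort (100/grade, 256 px) for the benign-vs-grade-5
  contrast and a label-shuffled null.
* Rounding for table display is half away from zero to one decimal
  (`format_metrics()`), the convention under which the most published
  rows are self-consistent.
* `run_pipeline()` writes features, significance report, metric tables,
  level comparison, and a manifest with the seed and per-file MD5
  checksums; reruns are byte-identical.

## Known limitations

* The generator does not model stain deconvolution physics, gland
  morphology beyond ellipses, whole-slide context, or scanner variation.
* Only the Haar family and two decomposition levels are supported.
* The MLP is intentionally minimal (no cross-validation, early stopping,
  or alternative losses); it is the reference learner for this feature
  set, not a competitive classifier.
* MANOVA assumes multivariate normality within groups; with strongly
  separated synthetic classes its P-values are effectively zero and serve
  as a screen, not as calibrated inference.
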