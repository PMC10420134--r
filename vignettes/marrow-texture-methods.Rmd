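---
title: "Methods: vertebral bone-marrow texture and adjacent annular fissures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vertebral bone-marrow texture and adjacent annular fissures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Outer annular fissures — tears of the annulus fibrosus reaching its outer
third, DDD (Dallas Discogram Description) grade 2–3 — are a candidate pain
generator in chronic low back pain, but their reference diagnosis
(CT-discography) is invasive. `marrowtex` implements the hypothesis that the
*bone marrow of the adjacent vertebral halves* carries an MRI-visible texture
signature of the fissure: each disc is flanked by two "vertebral units" (the
inferior half of the vertebra above, the superior half of the vertebra
below), and quantitative texture descriptors of those units on routine T1-
and T2-weighted images are used to classify the disc's fissure status. The
clinical comparator is the Modic-change (MC) marker: predict a fissure
whenever the unit shows any endplate marrow signal change (types 1–3). That
marker is highly specific but insensitive, so the package's head-to-head
evaluation asks whether a texture model beats it in paired accuracy.

# The model in one page

For each vertebral unit the package computes 93 features per modality (186
per unit): 18 first-order statistics and the GLCM (24), GLRLM (16), GLSZM
(16), GLDM (14) and NGTDM (5) texture families, with pyradiomics-style names
such as `glszm_SmallAreaLowGrayLevelEmphasis_t1w`. No shape and no
filtered-image features are included: units are near-boxes of similar size,
so shape carries no class information, and filtered images would multiply
the feature count without a matching increase in units.

The fitting function `fissure_radiomics()` then runs a fixed reduction
ladder:

1. **Robustness (ICC)**: every feature is recomputed under two
   perturbations — a one-voxel 26-connected mask erosion, and extraction on
   a 1.1 mm instead of 1.0 mm isotropic grid. Features whose ICC(1,1)
   between original and perturbed values falls below 0.5 under either
   perturbation are excluded. ICC(1,1) is the one-way random-effects,
   single-rater form `(MSB − MSW) / (MSB + (k−1) MSW)`.
2. **Standardization**: surviving features are z-scored (sample SD);
   zero-variance columns are excluded with a recorded reason.
3. **Correlation pruning**: among pairs with `|R| > 0.9` (Pearson,
   processed in descending `|R|`), the member less correlated with the
   fissure label (point-biserial) is excluded.
4. **Sequential backward selection (SBS)**: starting from all survivors,
   the feature whose removal maximizes mean 5-fold stratified
   cross-validated *balanced* accuracy is removed, down to 5 features, once
   per classifier — a multilayer perceptron, a random forest, and
   5-nearest-neighbours. All three share the same seeded folds. Balanced
   accuracy (mean of sensitivity and specificity) is used because the
   cohort is ~80/20 imbalanced and raw accuracy would reward the trivial
   all-positive rule.
5. **Aggregation**: the union of the three top-5 sets, ranked by number of
   models voting for a feature, is the candidate set.
6. **Backward-elimination logistic regression**: candidates enter a
   binomial GLM; the feature with the largest Wald p-value above 0.05 is
   dropped iteratively. Coefficients are reported with standard errors,
   odds ratios and 95% CIs.
7. **Evaluation**: predicted probabilities are thresholded at the
   accuracy-maximizing cut (scanned over score midpoints, ties to the
   lowest threshold), giving a confusion matrix; AUC comes from the
   rank (Mann–Whitney) formulation; the MC marker is evaluated on the same
   units; and the two classifiers are compared with an exact mid-p McNemar
   test on their discordant classifications.

The result is a classed S3 object with `print()`, `summary()`, `coef()`,
`predict()` and `plot()` methods, plus `write_report()` for a JSON/CSV
bundle.

# Preprocessing choices

* **Resampling.** Native sagittal lumbar MRI is strongly anisotropic
  (≈0.6 × 0.6 mm in-plane, ≈4.4 mm through-plane). Texture matrices assume
  isotropic neighbourhoods, so volumes are trilinearly resampled to 1.0 mm;
  masks use nearest-neighbour to preserve labels. Voxel centres sit at
  `index * spacing`, and the output grid has `floor((n−1)·sp/t) + 1`
  samples per axis, so no output voxel is extrapolated.
* **Normalization.** `x' = scale · (x − μ) / σ` over the whole volume with
  `scale = 100`, then truncation at ±3·scale. MRI intensities are
  scanner-arbitrary, so some standardization is mandatory; the scale of 100
  with the fixed bin width below places typical marrow ROIs in the 32–128
  occupied-gray-level band that texture features are usually computed over.
* **Discretization.** Fixed bin *width* (3 normalized units), not fixed bin
  count: `level = floor((x − min_ROI)/w) + 1`. With per-ROI minima this
  keeps a given contrast step the same number of levels apart in every
  unit, which matters for cross-unit comparability of gray-level–weighted
  features.
* **Units.** `split_vertebra()` cuts each vertebral mask at its centroid
  slice perpendicular to the cranio-caudal axis; the centroid slice joins
  the superior half. `contract_mask()` (the ICC perturbation) erodes with
  the full 3×3×3 (26-connected) structuring element.

# Texture implementation notes

* All matrix builders are small C++ kernels; each is checked in the test
  suite against brute-force R enumerations (per-voxel neighbour loops,
  BFS connected components, explicit run walks) on batches of random ROIs.
* GLCM: symmetric co-occurrences at distance 1 along the 13 unique 3D
  directions; features are computed per direction and averaged.
* GLCM MCC (maximal correlation coefficient): rather than forming the
  O(N³) similarity matrix Q, we use the identity that Q is similar to
  `B²` with `B(a,b) = p(a,b)/sqrt(px(a)·px(b))`, a symmetric matrix whose
  largest eigenvalue is exactly 1; MCC is therefore the second-largest
  absolute eigenvalue of `B`, obtained from a single symmetric
  eigendecomposition. This is both faster and numerically cleaner.
* GLCM information measures: for a symmetric GLCM, HXY1 and HXY2 both
  reduce to `HX + HY`, so IMC1 = −MI/max(HX, HY) and
  IMC2 = sqrt(1 − exp(−2·MI)) with MI clamped at 0 against floating-point
  negatives.
* GLSZM zones are 26-connected components of equal level; GLDM dependence
  is `1 +` the number of 26-neighbours within `alpha = 0` levels; NGTDM
  Coarseness is capped at 1e6 for zero-contrast ROIs.
* First-order Entropy/Uniformity use the discretized histogram; quantiles
  are type 7.

# The synthetic cohort generator

Patient images cannot ship with a package, so `generate_cohort()` produces
cohorts whose *statistical shape* matches the targeted study design:
61 patients, 2–4 examined discs each (mean 2.9, hence ~177 discs and ~354
units in expectation), an 80/20 fissure imbalance, Modic changes in ~12% of
units and — by default — only adjacent to fissured discs, which reproduces
the 100%-specific/insensitive regime of the MC marker.

The forward model is deliberately simple but designed around two
principles. First, *family specificity*: the class signal must live
where the package claims it does — in the equal-level neighbourhood and
zone statistics read by the GLDM/GLSZM families — and not leak into
histogram moments or broad co-occurrence moments. The planted mechanism
is the **coherence of the T1W fat-island structure**: every unit, both
classes alike, receives marrow heterogeneity of the same amplitude,
*terraced* into discrete plateaus of the same level quantum and rescaled
to the same spread. The classes differ only in the coherence length of
the field being terraced — away from fissures the plateaus form large
coherent fat islands (3.0 mm), adjacent to a fissured disc the same
structure is finely fragmented (1.2 mm). Because amplitude, quantum and
spread are identical, first-order statistics and broad co-occurrence
moments are closely matched. Pairwise statistics do still see coherence
— the same-level *pair rate* at distance 1 grows linearly with the
coherence length, which is what `glcm_Imc1` and the run-length features
read — but equal-level *patch sizes* grow with its square, so the GLDM
dependence counts and GLSZM zone statistics gain quadratically from the
same contrast and carry the strongest signal by a clear margin. The
coherence ratio is therefore chosen wide (2.5×) and overall
discriminability is moderated instead by class-independent nuisance
(lesion load and acquisition noise), which degrades every family
equally. (Several earlier designs failed in
instructive ways: lesions planted only in the fissure class made the
logistic stage separate perfectly; a lesion-burden amplitude difference
leaked into first-order features; and a small-foci-versus-large-blobs
granularity difference, however carefully histogram-matched, was always
read most efficiently by co-occurrence features such as Correlation,
Imc1 and ClusterShade, which displaced the zone features during backward
elimination. Geometric granularity is visible to every second-order
family; level-coherence with a wide ratio is the regime where the zone
and dependence families' quadratic read dominates.)

Second, *overlap*: every unit also draws the same exponentially
distributed load of focal nuisance lesions — a half-and-half mix of
small foci and large blobs, identically distributed in both classes — so
within-class texture variability is substantial and single features
separate the classes imperfectly (the strongest feature-label
correlations sit around 0.6), a discriminable but far from separable
regime rather than a trivial phantom. Fat islands and foci are fat-contrast effects:
visible on T1W, inconspicuous on fluid-weighted T2W, so the planted
signal is T1W-specific — mirroring where marrow texture is usually
read. The T2W channel is a monotone decreasing transform of the shared
latent background with its own smooth component and noise. Modic
changes are painted as diffuse latent shifts over the endplate-adjacent
third of a unit (types 1 and 3 darken, type 2 brightens T1W). Setting
`texture_effect = 0` removes the class-conditional difference entirely,
giving a null generator for calibration checks.

What a passing run on synthetic data shows: that the *pipeline* —
extraction, robustness screening, selection, modelling, paired testing —
recovers a known planted texture association of realistic effect size and
correctly ranks the texture model against the MC marker. What it cannot
show: that real vertebral marrow carries such a signature; that claim needs
patient data.

# Numerical and algorithmic choices

* **MLP**: one hidden layer of 100 ReLU units trained full-batch with Adam
  (learning rate 0.01, weight decay 1e-4, 18 epochs), implemented as a
  small C++ routine over BLAS `dgemm`. A quasi-Newton optimizer would
  build a dense Hessian over >3000 weights at every SBS candidate
  evaluation; the fixed-budget Adam trainer is ~50× faster at equal
  selection quality, which is what makes sequential backward selection
  with an MLP tractable at all. Weights are drawn from R's RNG so the
  whole fit is reproducible from one seed.
* **Random forest**: `ranger`, 45 trees, class-balanced case weights,
  single-threaded, seeded per fold.
* **kNN**: `class::knn`, k = 5, on the standardized features.
* **Seeding**: every stochastic step derives its seed deterministically
  from the configured seed (per SBS step and fold), so identical
  config + seed yields a bit-identical report bundle.
* **Threshold rule**: candidate thresholds are the midpoints of
  consecutive sorted unique scores plus sentinels below the minimum and
  above the maximum, so the all-positive and all-negative rules are
  reachable; ties go to the lowest threshold.
* **AUC**: midrank Mann–Whitney form, cross-checked in the tests against a
  threshold-sweep trapezoid and all-pairs concordance.
* **mid-p McNemar**: `2·P(X ≤ min(b,c)) − P(X = min(b,c))`,
  `X ~ Binomial(b+c, ½)`; exact, appropriate for small discordant counts,
  and less conservative than the exact test.

# Problem sizes and runtime

On one CPU core a full default cohort (~61 patients, ~340 units) generates
in ~10 s; feature extraction over the three conditions (original,
contracted mask, perturbed voxel size) takes ~50 s; the three SBS runs
~60 s; the complete `fissure_radiomics()` call about 2–2.5 minutes. Memory
stays well under 1 GB. The unit tests run the texture kernels against
brute-force oracles on ~100 small random ROIs in seconds; end-to-end tests
use 5–6-patient cohorts.

# Limitations

* The generator is a phantom: box-shaped vertebrae, stationary Gaussian
  fields, lesions as circular foci. It validates the machinery, not the
  biology.
* Threshold selection and evaluation happen on the same units (apparent
  performance), as is common in association-focused radiomics reports; the
  CV in SBS protects feature *selection*, not the final error estimate.
* The logistic stage assumes the candidate set is small relative to the
  unit count; with very small cohorts backward elimination can meet
  separation, which the fit reports as an error rather than silently
  returning unstable coefficients.
* ICC(1,1) treats the two perturbation conditions as interchangeable
  raters; that is the standard robustness screen, but it is a
  repeatability, not a validity, measure.
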