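---
title: "Methods: machine scoring of tumor-infiltrating lymphocytes on H&E tiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: machine scoring of tumor-infiltrating lymphocytes on H&E tiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Tumor-infiltrating lymphocytes (TILs) are a prognostic biomarker in
melanoma, but pathologist-read TIL scores (the TIL-WG stromal percentage,
the ordinal Clark brisk/nonbrisk/sparse grades) suffer substantial
interobserver variability. `tilquant` implements a machine-scoring
pipeline over tile-scale H&E images — stain normalization, nucleus
detection, cell classification, and a panel of five "electronic TIL"
ratios — together with the statistics used to establish the analytical
validity (operator concordance) and clinical validity (survival
association) of such scores. Every input the pipeline needs can be
simulated, so all of its behavior is testable without any image
downloads.

This vignette records the models, the parameters that matter, the
numerical conventions, and the design choices that were genuinely open.

## Optics: Beer–Lambert mixing and stain normalization

A pixel's transmitted 8-bit intensity relates to stain concentrations
through the Beer–Lambert law in base-10 optical density (OD),

$$\mathrm{OD}_c = -\log_{10}\!\frac{\max(I_c, 1)}{I_o}, \qquad
  \mathrm{OD} = S\,c,$$

where $S$ is the 3×2 matrix of unit stain vectors (hematoxylin, eosin)
and $c \ge 0$ the per-pixel stain concentrations. Zero pixels are mapped
to 1 before the logarithm so the transform stays finite and invertible up
to quantization (`rgb_to_od()` / `od_to_rgb()`).

`estimate_stain_vectors()` is Macenko-style estimation: foreground pixels
(OD Euclidean norm above β, default **β = 0.15 OD**) are projected onto
the top-2 eigenplane of their OD covariance; the in-plane direction
angles at percentiles α and 100−α (default **α = 1**) are mapped back to
OD space, clamped to the non-negative orthant and unit-normalized.
Per-stain concentration scales are the 99th-percentile foreground
concentrations. `normalize_image()` re-renders concentrations through a
fixed reference model after matching the 99th-percentile scales, which is
how a batch of tiles is brought to one uniform stain appearance.

Conventions worth stating:

* **Stain assignment.** Hematoxylin is the estimated vector with the
  larger red:blue OD ratio. Hematoxylin-stained chromatin appears
  blue-violet because it absorbs red light most strongly (its reference
  OD vector is (0.65, 0.70, 0.29)), while eosin absorbs mostly green;
  the red:blue ratio separates the two robustly. The reference vectors
  are the standard stain-deconvolution values; `default_stain_model()`
  holds them.
* **Foreground subsampling.** Above 200,000 foreground pixels a fixed
  stride subsample is used, so the estimate is deterministic without an
  RNG.
* **β versus noise.** β's role is to exclude background; it must sit
  above the background OD magnitude. At the default generator noise
  (OD sd 0.01) β = 0.15 is ample. In experiments with heavy noise the
  background norm distribution (χ₃-like, scale = noise sd) crosses 0.15,
  and β should be raised accordingly.
* **Estimator assumptions.** The percentile-angle rule assumes the tile
  contains a dense continuum of stain mixtures including near-pure pixels
  of each stain. Sparse, lightly stained cell tiles violate this: at high
  noise the extreme-angle percentile lands in the angular noise tail of
  the weakest-stained nuclei (angular sd ≈ noise/concentration), and the
  error is dominated by that tail rather than by the estimator. Recovery
  experiments therefore use `render_stain_phantom()` — a dense uniform
  two-stain concentration field — where recovery is ≈0.7° noiseless and
  ≈2.5° at OD noise 0.05; on noiseless cell tiles it is ≈0.03°.
* **Quantization dithering.** Angular error is not monotone in noise near
  zero: 8-bit quantization contributes a small bias at zero noise that
  tiny noise dithers away. Monotonicity tests compare noise levels in the
  noise-dominated regime.

## Cell detection, features, classification

`detect_nuclei()` operates on the hematoxylin concentration channel:
Gaussian smoothing (**σ = 1.5 µm**), threshold (**0.10**), hole filling,
then a distance-transform watershed (tolerance 1 px) to split touching
nuclei, and an area filter (**5–400 µm²**). These are desk-standard
values in the QuPath tradition; σ should be reduced below the expected
nucleus separation when splitting small touching nuclei (the tests use
σ = 0.5 µm for a 5-µm-separation fixture). `expand_cells()` grows nuclei
by a distance-limited Voronoi propagation (**radius 5 µm**), so cell
territories never overlap and each contains its nucleus.

`extract_features()` computes a fixed, ordered schema per cell
(`til_feature_names()`): nucleus area, perimeter, circularity
$4\pi A/P^2$ (capped at 1; rasterized perimeters underestimate length),
eccentricity, max-caliper length, cell area, nucleus/cell ratio, and
mean/min/max hematoxylin and eosin concentrations in the nucleus and in
the cytoplasm ring. One-pixel masks get a one-pixel perimeter floor and a
`degenerate` flag.

`train_classifier()` is a one-hidden-layer perceptron (**32 units,
≤500 epochs, weight decay 1e-4**, softmax output) over z-scored features;
the scaling constants and class levels are stored with the network, and
training is seeded. The architecture is deliberately small: with the
morphology defaults below the classes are separable by construction, and
held-out macro-F1 on default synthetic tiles is ≈0.97.

`evaluate_classification()` matches predictions to ground truth by
greedy closest-first centroid pairing within **5 µm**; a matched pair is
correct iff labels agree, unmatched truth is a false negative, unmatched
prediction a false positive. Per-class precision/recall/F1 (harmonic
mean, 0 when both are 0) plus macro averages are reported. A pure
label-agreement mode (`classification_report()`) is also provided for
settings where the truth segmentation is reused, since evaluation
protocols differ between studies.

## The five electronic TIL variables

Within an operator-annotated region (centroid-in-polygon membership,
boundary inclusive):

$$\mathrm{eTILs\%} = \frac{100\,n_i}{n_i + n_t},\quad
  \mathrm{etTILs\%} = \frac{100\,n_i}{n_i+n_t+n_s+n_o},\quad
  \mathrm{esTILs\%} = \frac{100\,n_i}{n_i+n_s},$$

$$\mathrm{eaTILs} = \frac{a_i}{A},\qquad
  \mathrm{easTILs\%} = \frac{100\,a_i}{A - a_t},$$

with $n$ counts, $a$ summed cell areas (mm²) by class
(i = immune, t = tumor, s = stromal, o = other) and $A$ the analyzed
region area (mm²). eaTILs is immune area per mm² of analyzed region;
easTILs uses region-minus-tumor-area as a stroma proxy, mirroring the
pathologist's stromal-TIL denominator. These two denominators follow the
variables' originating publications; each lives in one line of
`compute_til_panel()` for easy revision. A score whose denominator is
zero or negative is **flagged undefined (`NA`), never reported as 0**.

Cohort QC (`qc_filter()`) excludes a slide iff analyzed area < 0.5 mm² or
tumor-cell fraction < 0.50, boundaries inclusive ("less than" excludes
strictly below). Dichotomization (`dichotomize()`) labels a case high iff
score ≥ cutoff, with the cutoff either the cohort median or an absolute
value (16.6 for eTILs%; 10 and 30 for manual stromal-TIL percentages).

## Concordance statistics

ICC uses two-way ANOVA mean squares on the complete-case matrix
(case-wise deletion, count of dropped rows reported). The default form is
**ICC(2,1)** — two-way random effects, absolute agreement, single rater:

$$\widehat{\mathrm{ICC}}(2,1) =
  \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

with 95% CIs by the F-distribution method (Satterthwaite degrees of
freedom for the rater term). Because published reports rarely state which
of the six Shrout–Fleiss forms their software produced, `icc()` returns
all six with CIs so any choice can be matched post hoc. Scores are
typically log-transformed first (`log_transform()`, natural log with
**offset 1** so 0% scores stay defined; the transform is monotone, so
rankings are unchanged).

Kendall's W uses within-rater mid-ranks and the tie correction
$T_j=\sum(t^3-t)$:

$$W = \frac{12 S}{m^2(n^3-n) - m\sum_j T_j}.$$

If every rater is constant, W is undefined and an error is raised.
Reliability bands follow the printed intervals: < 0.40 poor (below the
lowest published band), [0.40, 0.60] moderate, (0.60, 0.80] good,
> 0.80 excellent — so 0.60 is moderate, 0.44 moderate, 0.94 excellent.
The per-case coefficient of variation is sample sd/mean, with a missing
CV for zero-mean cases and the median across cases as the summary.

## Survival statistics

`km_logrank()` produces Kaplan–Meier curves and the two-group log-rank
test; `cox_fit()` maximizes the partial likelihood with **Efron** tie
handling (convergence tightened to 1e-12 so estimating-equation
identities hold to numerical precision in tests); the adjusted model is
group + sex + age + stage with **stage I as reference** (three dummy
contrasts). Non-convergence or a monotone likelihood (perfect
separation) raises an explicit error rather than returning an unstable
estimate. `schoenfeld_test()` regresses scaled Schoenfeld residuals on
KM-transformed time, per covariate and globally. Two-sided α = 0.05
throughout; no multiplicity correction is applied anywhere, matching the
single-comparison design the statistics serve.

A note on an invariance used in testing: duplicating every record leaves
the Breslow partial likelihood's maximizer exactly unchanged (risk-set
sums simply double), while Efron's within-tie correction makes the
invariance approximate; the tests assert both at their appropriate
tolerances.

## The synthetic-data generator

`sim_config()` fixes the study conditions; the defaults are chosen once
to mirror the design the statistics are meant for, not tuned per
experiment:

* **Geometry.** Pixel size 0.4986 µm; 60 cases; 38 AI-arm raters and 29
  manual-arm raters; testing cohort n = 111.
* **Tiles.** Poisson cell counts at class densities (per mm²) tumor 400,
  stromal 400, immune 600, other 200 — an immune-rich but plausible
  tile mix; neither density nor class balance of any real cohort is
  published, so these are a modeling choice. Morphology: immune nuclei
  2.5–4 µm, near-circular, hematoxylin-dense (concentration 1.10); tumor
  5–10 µm (0.65) with a wide eosinophilic cytoplasm; stromal elongated
  (axis ratio 2.5–4, 0.55) in eosin-rich tissue (cytoplasm eosin 0.55);
  "other" small weak blobs (0.35). Nuclei carry hematoxylin and
  cytoplasm eosin, so tiles contain near-pure pixels of both stains.
  Rendering inverts the Beer–Lambert model with Gaussian OD noise
  (default sd 0.01) and 8-bit quantization; background renders exactly at
  $I_o$.
* **Score matrices.** $x_{ij}=\mu+b_i+r_j+e_{ij}$ with variance
  components set so the case share equals the target ICC (default 0.94;
  total variance 25 on a TIL% scale with mean 20; 30% of the non-case
  variance is systematic rater effect). Estimated ICC(2,1) recovers the
  target to ±0.005 in expectation at 60×38.
* **Clark matrices.** The same latent model (latent ICC default 0.50, the
  moderate-agreement regime of manual grading) thresholded at the latent
  1/3 and 2/3 quantiles into grades 1–3. No generative model for ordinal
  grading is published; thresholding a latent Gaussian is the standard
  choice. The resulting Kendall W at the default is ≈0.45–0.48.
* **Survival.** Exponential event times with hazard
  $\lambda_0 e^{\beta\,\mathrm{high}}$, $\lambda_0 = 0.015$/month,
  true HR 0.45, independent Uniform(0, 150 months) censoring — together
  giving ≈50% events, the regime of a mature melanoma cohort. Sex ≈1:1,
  age ≈ Normal(61, 12) truncated to 25–87, stage I-heavy
  (50/25/15/10%). Covariate effects default to zero so univariable
  recovery is clean; they can be switched on for adjusted-model
  experiments.

What the generator does *not* emulate: tissue architecture (tumor nests,
pigment, necrosis), out-of-focus blur, scanner-specific color response,
annotation ambiguity, or operator region-selection variability — the
dominant real-world source of inter-operator spread in AI-assisted
scoring. Passing tests therefore demonstrate the correctness of the
computations and the internal consistency of the pipeline under its
stated optical model, not clinical performance on real slides.

## Problem sizes used by the test and acceptance runs

Chosen as comfortable desk-scale sizes: classifier experiments use ten
0.49-mm² tiles (≈2200 labeled cells; held-out 40%); concordance recovery
averages 100–200 simulated 60×38 matrices; survival recovery averages
100–200 cohorts of n = 111; the log-rank null uses 500 replicates; stain
recovery uses three 150×150-px phantoms per noise level.

## Known limitations

* Tile-scale only; no whole-slide tiling, stitching, or SVS reading.
* The watershed splits nuclei by distance-map geometry; heavily
  overlapping nuclei (separation well below the smoothing scale) merge.
* Greedy nearest matching is order-independent but not globally optimal;
  at 5 µm radius on realistic densities the difference is negligible.
* The MLP is trained per study on its own reference-normalized features;
  no pretrained weights are shipped, and no claim is made that the
  feature set transfers to real melanoma slides with pigment.
* easTILs' stroma proxy (region minus tumor area) can be negative in
  tumor-dense regions; the score is then undefined and flagged, which is
  the honest outcome for a stroma-based ratio without stroma.
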