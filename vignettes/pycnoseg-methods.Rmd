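---
title: "Counting pycnotic nuclei in slice-culture stacks: models and design choices"
author: "pycnoseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting pycnotic nuclei in slice-culture stacks: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pycnoseg)
```

## The problem

Excitotoxically lesioned organotypic hippocampal slice cultures (OHSC) are a
standard model of neuronal damage. Dead and degenerating cells take up
propidium iodide (PI), and the readout is the number of PI-positive pycnotic
nuclei in a confocal z-stack: bright, compact, roughly circular objects
5–15 px across (at 0.52 µm/px), sitting on a diffuse background whose level
varies within and between slices. Manual counting is slow and
rater-dependent; global thresholds and cumulative intensity measures fail on
noisy, region-dependent background. `pycnoseg` implements a trainable
pixel-classification pipeline that imitates the manual count: spatial
features → PCA → ranked-feature classifiers → whole-stack damage gating →
morphological post-processing → false-positive filtering → circular Hough
splitting of overlapping nuclei. The final output per stack is a dead-cell
count.

Because no reference microscopy data are distributed with the package, a
synthetic stack generator reproduces the statistical structure the pipeline
assumes; every stage is developed and tested against it.

## The feature bank

Stacks are first normalized to $[0,1]$ (min–max over the whole stack), which
makes all downstream features invariant to global intensity scaling. Stacks
whose pixel size deviates by more than 5 % from the 0.52 µm reference are
resampled, since all size parameters below are in pixels at that resolution.

The bank has exactly 116 channels:

* **Gaussian derivatives** at scales $\sigma \in \{1, 3, 6\}$ px: first and
  second derivatives along $x$, $y$, $z$, plus the mixed $x\&y$ and
  $x\&y\&z$ derivatives at first and second order per axis — 10 directions
  × 3 scales = 30 channels. Kernel support follows
  $\mathrm{Size} = \sigma\,(3 + 0.25\,o - 2.5\,(o-6)/((o-6)^2+(o-9)^2))$
  for derivative order $o$, rounded up to the next odd integer so kernels
  stay centered. The formula is isolated behind `gaussian_filter_size()` so
  an alternative reading can be swapped in one place.
* **Laguerre–Gauss filters (LGF)**, a blob-sensitive family indexed by
  radial order $p$ and azimuthal order $l$. With $u = \rho s$ the kernel is
  $\exp(-u^2/q)\, u^{l/q} \left[\cos\!\big(l(\theta + 2\pi r/\max(2l,1))\big)\,
  L_p(u \arctan u)\right]^{3-q}$, evaluated on a 21 × 21 grid with
  $s = 0.5$, $q = 2$, $r = 0$ and $p, l \in \{0, 1, 2\}$. Since pycnotic
  nuclei are point-symmetric, rotated copies ($r \ne 0$) add little and are
  rejected in strict mode. Channels: the 9 responses, their first and second
  Gaussian derivatives ($\sigma = 1$ px) along $x$, $y$ and $z$ (54), and
  the 9 LGF responses of the coherency image — 72 channels.
* **Structure-tensor coherency** $C = ((\lambda_1-\lambda_2)/(\lambda_1+\lambda_2))^2$
  from the eigenvalues of the Gaussian-smoothed gradient outer product
  (gradient scale 1 px, integration scale 3 px, per z-slice), with $C = 0$
  where the trace vanishes. $C$ enters the bank through the LGF responses
  above.
* **White top-hat transforms** with disc diameters
  $\{3, 4, 5, 7, 9, 13, 15, 18\}$ px and **local entropy filters** with
  windows $\{3, 5, 7, 9, 13, 17\}$ px (on a 64-level quantized copy) —
  14 channels. The sizes bracket the 5–15 px nucleus range with a margin.

The channel registry (`feature_registry()`) names every channel with its
generating bank and parameters; the 116 total is asserted at build time.
The decomposition across banks — in particular that the LGF derivative set
is first/second order along each of $x$, $y$, $z$ — is this package's
documented reading; it is fixed so the registry totals exactly 116.

Feature computation is voxel-wise 3D. In-plane kernels are separable 1D
convolutions (compiled, reflective boundary); z-kernels shrink with a
warning when their half-width would exceed the stack's z extent, which is
routine for desk-scale 8-slice stacks at $\sigma = 6$. Single-slice inputs
get zero-valued z-derivative channels.

## Labels from expert clicks

Training labels are sparse: an expert clicks some (not all) positive nuclei
and outlines polygonal negative regions. Clicks rarely hit the intensity
peak, so each click is snapped to the nearest *significant* maximum: the
h-maxima transform (grayscale reconstruction of $f - h$ under $f$,
$h = 0.1$ on the normalized scale) suppresses maxima shallower than $h$,
and the voxels where $f$ still exceeds the reconstruction form compact
"domes" around each surviving peak. A click moves to the brightest voxel of
the dome component nearest to it within a 5 px search radius, by
hill-climbing until a fixed point — so refinement is idempotent. Clicks
with no dome in range are flagged, never silently dropped.

The positive region of a seed is its dome component, clipped to a 15 px
ball; this yields per-nucleus pixel sets of a few dozen voxels, the same
order as published positive-pixel-per-cell ratios. Negative polygons are
rasterized with the even-odd rule on pixel centers (boundary excluded).
A voxel claimed by both classes resolves to positive with a warning: clicks
are deliberate point statements, polygons are coarse regions. Everything
else stays unlabeled and is excluded from training and evaluation. The
choice of $h$ and both radii are exposed in `pipeline_config()`.

## Classification

PCA (centered, unit-scaled, fitted on the pooled labeled voxels of the
training stacks, subsampled to at most $5 \times 10^5$ rows) de-correlates
the bank; components replace raw channels everywhere downstream.
Components are ranked by two-sided Wilcoxon rank-sum tests of positive
against negative voxels (exact via `wilcox.test` up to $n = 200$, otherwise
the tie- and continuity-corrected normal approximation), ties in $p$ broken
by component index. The number of components is either selected by
cross-validation (`select_feature_count_cv()`: a stratified 30 % holdout
fixed per run, 10 folds resampling the remaining 70 % for training,
accuracy measured on the holdout, smallest $k$ at the maximal mean) or set
from the PCA spectrum (`components_for_variance()`; the pipeline default is
the 99 %-variance count, typically 40–60 components on synthetic cohorts).

Four classifier families are provided with fixed reference
hyperparameters: Gaussian naive Bayes; quadratic discriminant analysis
(`MASS::qda`, falling back to a ridge-regularized Gaussian discriminant
when a class covariance is singular, with the ridge recorded); random
forest (100 trees, minimum terminal node 100 — split predictors are chosen
by standard impurity search, as the platform-specific interaction-curvature
split test has no portable equivalent and tree count/leaf size dominate
behavior); and a multilayer perceptron with one hidden layer of 100 units
and L2 penalty $10^{-4}$. The MLP is trained by full-batch quasi-Newton
optimization on standardized inputs (`nnet`), so stochastic-gradient
settings (batch size, learning-rate schedule) do not apply; they are kept
in the spec record for provenance. "100 hidden layers" in the source
description is read as one hidden layer of 100 units — a 100-layer
perceptron is implausible under the stated training settings. Training
subsample caps (30 000 rows for RF, 20 000 for the MLP, 30 optimizer
iterations) keep a 12-fold evaluation inside minutes on one CPU; on the
synthetic conditions, halving or doubling them does not change the ranking
of the models. Class imbalance is left unweighted, and probabilistic
outputs are thresholded at 0.5.

Evaluation is leave-one-stack-out: PCA and ranking are refitted on each
training pool (the held-out stack never influences feature extraction),
and confusion counts run over the held-out stack's labeled voxels only.

## The damage gate

Stacks differ strongly in overall damage; a whole-stack gate routes each
stack to a classifier trained on its own regime. The gate is a bag of
visual words: dense patch descriptors (8-bin gradient-orientation
histograms plus patch mean, SD, max and bright-pixel fraction) on the
maximum-intensity z-projection, quantized against a 100-word k-means
vocabulary, histogrammed per stack (L1-normalized) and classified by a
linear SVM. The descriptor, vocabulary size and kernel are configuration
choices — only the representation ("bag of visual words") is inherited.
Gate quality is estimated by 200 stratified 70/30 splits with the class
ratio preserved; the vocabulary is refitted inside every split. A bypass
topology (one model trained on all stacks, no gating) is selectable in
`pipeline_config(topology = "single")`.

## Post-processing and counting

Predicted masks are cleaned in a fixed order: voxels strictly below
0.1 × the stack's maximal intensity are set negative; a morphological
closing (3 × 3 square, one iteration, per z-slice — the element and
iteration count are this package's choice) bridges one-pixel gaps; and
connected components smaller than 30 voxels (strict) are removed.
Because the dim cut is deterministic, `count_nuclei()` only classifies
voxels at or above it — the final mask is identical and segmentation of a
full stack takes seconds instead of minutes.

Object-level analysis is planar, on the maximum-intensity projection of
the 3D mask: the descriptors (perimeter, eccentricity, ...) and the
circular Hough transform are 2D concepts, while classification stays
voxel-wise. Each 8-connected object carries ten descriptors: area, convex
area (hull of the pixel squares, so convex shapes have solidity exactly 1),
eccentricity and axis lengths from second central moments (with the 1/12
pixel-variance term), equivalent diameter, extent, perimeter (chain-code
length of the outer contour plus $\pi$, the offset of the half-pixel
silhouette boundary — a rasterized 11 px disc then has circularity
$4\pi A/P^2$ within 10 % of 1), solidity and circularity.

Objects are matched to manual annotations by greedy nearest-first
assignment with a strict < 10 px rule (10.000 px is "not closer than" and
does not match); each manual point is consumed once, and an exact
positive/negative distance tie resolves positive. Matched objects train a
radial-basis SVM on the ten standardized descriptors; the assumed outlier
fraction of 0.05 is realized as a ν-SVM slack budget (ν capped below the
class-balance feasibility bound when false positives are rare). With fewer
than two false positives the filter degenerates to the identity with a
warning — precisely the regime a good upstream classifier produces, where
sensitivity stays near 1 and specificity is low.

Overlapping nuclei merge into one mask component and would be undercounted,
so a circular Hough transform splits them. The design departs from a
textbook full-ring accumulator in four ways, each forced by the ragged
masks a pixel classifier actually produces:

* **Gradient-directed voting.** Each edge pixel of the projection votes
  only along its inward boundary normal, over radii 2.5–9 px in 0.5 px
  steps — votes converge onto a point only where boundary curvature
  matches the candidate radius, which removes the spurious off-center
  peaks of full-ring voting. The radius grid extends past the nominal
  7.5 px pycnotic maximum because the segmentation mask dilates a nucleus
  by 1–1.5 px; without the extension the largest nuclei get
  systematically under-sized circles.
* **Per-layer peaks, circumference-normalized.** Candidate centers are
  the local maxima of each radius layer (radius-pooled center maps pull
  the peaks of touching circles toward each other), and scores divide the
  vote mass by $2\pi r$ so small nuclei compete fairly with large ones.
  Only a mild relative threshold (0.2 of the best candidate) is applied.
* **Boundary verification.** A candidate survives only if at least half
  of its circumference lies within 1.5 px of a mask boundary pixel. This
  is what separates real circles from phantoms in the interior of large
  ragged objects — the two have overlapping vote scores, but a touching
  nucleus still exposes about two thirds of its outline while an interior
  phantom exposes far less.
* **Overlap-aware suppression.** Accepted circles (in order of
  score × support) suppress candidates closer than 2.5 px or 0.85 of
  their radius, and any candidate disc overlapping an accepted disc by
  more than 0.3 intersection-over-union — a duplicate detection of the
  same nucleus, whereas two genuinely touching nuclei one radius apart
  overlap by only about 0.24.

On the overlap cohort (30 % touching pairs) this raises object recall
from 0.83 before splitting to 0.97–1.00 after, with total counts within
two of the true nucleus number; a textbook 0.5-of-maximum cut instead
rejects exactly the overlaps the transform exists to resolve. Recall
against manual positives is computed with the same strict 10 px,
consume-once rule. Only recall is assessed at this stage — the simulated
expert, like a real one, does not mark every positive nucleus, so
precision against clicks is not meaningful.

## The synthetic data model

`synth_config()`/`generate_stack()` emulate what the pipeline assumes about
PI-stained OHSC stacks, not the optics: nuclei are ellipsoidal indicator
volumes (in-plane radius from the 5–15 px diameter range, axial semi-axis
scaled by the 0.52/2 µm pixel/z-step ratio) convolved with a small Gaussian
(σ = 1 px in-plane), giving the bright, compact, smooth maxima that
h-maxima refinement expects; the background is a low-order 2D polynomial
field per slice (mildly modulated along z) plus Gaussian pixel noise; a
configurable fraction of nuclei is placed as touching pairs at
0.8–1.2 × mean radius, so single nuclei still roughly resemble circles; and
the simulated expert clicks only `label_fraction` of the nuclei, jittered
by up to 2 px. Damage classes follow presets — "high": 50 nuclei per
256 × 256 slice area with background amplitude 0.20 and noise SD 0.03;
"low": 30 nuclei, 0.08 and 0.02; peak intensities 0.6–1.0 for both. No
quantitative background statistics are published for the original data, so
these levels are free parameters chosen to give a clear but not trivial
separation (nucleus interiors above the 95th background percentile, which
is asserted per stack); they are exposed in `SynthConfig`, not calibrated.

The default desk-scale shape is 8 × 256 × 256 (pixel metadata still
0.52 µm/px, so size thresholds transfer unchanged); cohorts of 12 such
stacks with ~30–50 nuclei each are the study conditions for the evaluation
suite, chosen so the full leave-one-stack-out run of all four models
completes in minutes on one CPU. What passing tests show is that the
pipeline recovers known ground truth under this model — bright compact
blobs on smooth backgrounds with incomplete labels. What they cannot show
is robustness to real tissue: autofluorescence texture, anisotropic PSF,
staining artifacts, large accumulations of overlapping signals (explicitly
out of scope for the circle-based splitter) and genuinely ambiguous
intermediate damage are absent from the generator.

## Numerical choices and degenerate inputs

* Constant stacks normalize to all zeros with a warning; constant feature
  channels get unit scale in the PCA.
* Coherency is 0 where the tensor trace is below $10^{-12}$; roundoff
  above 1 is clipped.
* `wilcox.test` p-ties break by ascending component index; accuracy ties in
  feature-count selection take the smallest count.
* Stratified folding errors out when a class has fewer than two samples;
  the gate requires at least two stacks per class.
* R's vector-heap GC trigger grows slowly, so the full-volume feature
  builder reserves its expected working set once up front; without this,
  nearly every filter allocation forces a full collection once a large
  output matrix is live.
* All randomness (placement, jitter, subsampling, fold assignment, forest
  bootstrap, MLP initialization, k-means) is derived from explicit seeds;
  rerunning a pipeline from its manifest is bit-identical.

## Known limitations

The approach is resolution-dependent by construction (hence the resampling
rule), and more broadly domain-dependent: a model trained on stacks with
one background field scale overcounts on stacks with another, even at the
same nominal pixel size, so training and application data must share
acquisition conditions. The Hough splitter handles pairwise overlap of roughly circular
nuclei only. The false-positive SVM is data-starved whenever the upstream
classifier is good — its specificity on rare false positives should be read
as descriptive, not as a usable operating point. The gate presets model two
clearly separated damage regimes; stacks of intermediate character are the
expected error mode, and no third class is provided. The synthetic
evaluation bounds what can be claimed: performance numbers from this
package characterize the implementation, not any real OHSC dataset.
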