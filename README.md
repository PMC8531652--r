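# pycnoseg

Counting dead cells in brain slice cultures, the way an expert would — but
reproducibly.

In organotypic hippocampal slice cultures (OHSC), neuronal damage is read
out by counting propidium-iodide (PI) positive pycnotic nuclei in confocal
z-stacks: bright, compact, roughly circular objects 5–15 px across
(0.52 µm/px) on a diffuse, region-dependent background. Manual counting is
slow and rater-dependent; intensity thresholds fail on noisy backgrounds.
`pycnoseg` implements a trainable pixel-classification pipeline that
imitates the manual count and returns a per-stack number of dead cells.

The pipeline:

1. **Spatial feature bank** (116 channels): Gaussian derivatives at
   σ ∈ {1, 3, 6} px with support
   `Size = σ·(3 + 0.25·o − 2.5(o−6)/((o−6)² + (o−9)²))`;
   Laguerre–Gauss filters (s = 0.5, q = 2, r = 0, p, l ∈ {0, 1, 2}) with
   their Gaussian derivatives and their responses on the structure-tensor
   coherency image C = ((λ₁−λ₂)/(λ₁+λ₂))²; white top-hat (3–18 px discs)
   and local-entropy (3–17 px windows) transforms.
2. **PCA** de-correlates the bank; components are ranked by Wilcoxon
   rank-sum tests of positive vs negative training voxels.
3. **Pixel classifiers**: naive Bayes, quadratic discriminant analysis,
   random forest (100 trees, min leaf 100) and a multilayer perceptron
   (100 hidden units, L2 = 1e-4), evaluated leave-one-stack-out.
4. **Damage gate**: a bag-of-visual-words linear SVM classifies whole
   stacks into "high"/"low" damage and routes them to class-specific
   models (or a single all-data model in the bypass topology).
5. **Post-processing**: dim-pixel cut (< 0.1 × max), morphological
   closing, removal of components < 30 px, a morphology-feature RBF-SVM
   that rejects false-positive objects, and a gradient-directed circular
   Hough transform that splits touching nuclei (radii 2.5–7.5 px);
   detections are matched to manual marks by a strict < 10 px rule.

Expert annotations are point clicks (snapped to h-maxima intensity peaks)
plus polygonal negative regions; the expert is not assumed to mark every
positive nucleus. Since no microscopy data ship with the package, a
synthetic stack generator (`generate_stack()`, `generate_cohort()`)
reproduces the assumed image structure — smooth bright nuclei, polynomial
background fields, touching pairs, incomplete labels — and drives the
entire test suite.

## Worked example

Simulate a labeled cohort, train the single-topology pipeline, and count
nuclei on a held-out stack:

```r
library(pycnoseg)

config <- pipeline_config(topology = "single",
                          classifier = classifier_spec("rf"),
                          seed = 71)
cohort <- generate_cohort(4, 0.5, synth_config(seed = 71, label_fraction = 1))
tsets <- lapply(cohort, function(el)
  prepare_training_data(el$stack, el$annotations, config, damage = el$damage))
registry <- train_segmentation_models(tsets, config)

held_out <- generate_stack(synth_config(seed = 999, damage_class = "low"))
res <- run_pipeline(config, list(held_out$stack), registry)
res$counts
#>        stack_id damage count   ok
#> 1 synth_seed999    all    30 TRUE
nrow(held_out$truth$nuclei)   # ground truth
#> [1] 30
head(res$details[[1]]$circles, 3)
#>     x   y radius     score support
#> 1 201 127      3 0.1947537       1
#> 2 206 220      4 0.1853134       1
#> 3  12 208      4 0.1840587       1
```

The run takes about two minutes (most of it feature extraction on the four
training stacks). `res$details[[1]]` carries the cleaned mask, the object
table with all ten morphological descriptors, and the Hough circles;
`write_manifest()` stores a JSON manifest from which a rerun is
bit-identical. Counts are only reliable when training and application
stacks share the acquisition scale and background statistics — a model
trained on small test-sized stacks overcounts on full-sized ones.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/pycnoseg.R simulate --out cohort/ --seed 1 --n-stacks 12
Rscript inst/scripts/pycnoseg.R count --dir cohort/ --out counts.csv
```

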