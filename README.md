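# iomil

Weakly supervised recognition of focal lesions in grayscale abdominal
CT-like images, for researchers who have image-level labels ("this scan
contains a cancer" / "this one does not") but no region annotations.
`iomil` implements an instance-optimized multi-instance learning (MIL)
pipeline: each image is a **bag**, each equal-size square block tiled from
it is an **instance**, and a bag is positive iff at least one instance
contains lesion tissue — so no tumor segmentation is ever required.

## The method

For an image normalized to 339 × 339 and equalized, blocks of side `l`
(default 113) are cut on a `k × k` grid, `k = round(339 / l)`. Each block
is described by gray-level co-occurrence matrix (GLCM) statistics at
distances d ∈ {1, 2} and directions θ ∈ {0°, 45°, 90°, 135°}:

- ASM = Σᵢⱼ I(i,j)² (uniformity), ENT = −Σᵢⱼ I(i,j) log I(i,j),
  CON = Σᵢⱼ (i−j)² I(i,j), COR = [Σᵢⱼ ij·I(i,j) − uₓu_y] / (σₓσ_y),

taking the mean and variance of each statistic over the four directions,
per distance (16 features). Two instance-optimization stages build the
training set: (1) blocks with ASM = 1 are uniform background and are
discarded; (2) instances are scored by bag-level cross-validated RBF SVMs
(every instance inherits its bag's label), and the correctly classified
instances of high-accuracy bags — the *key instances* — are retained. The
SVM hyperparameters (C, g) are tuned by particle swarm optimization plus a
coordinate line search (CPSO) on cross-validated accuracy. A test bag with
a fraction `r` of its reserved instances predicted negative is called
negative iff `r > P` (default P = 0.86). Performance is reported as
ACC/SEN/SPE averaged over a five-group validation protocol.

A synthetic phantom generator (elliptical organ with correlated Gaussian
texture; cancer-, cirrhosis- and cyst-like classes with ground-truth
lesion masks) makes the whole pipeline testable without clinical data, and
three baselines are included for comparison: a traditional whole-image
SVM, Citation-kNN with minimum Hausdorff bag distance, and a
bag-dissolution ("WEMISVM-style") SVM.

## Worked example

```r
library(iomil)

# 20 cancer / 30 normal phantoms with high lesion contrast
ds <- generate_dataset(c(cancer = 20, normal = 30),
                       config_overrides = list(lesion_contrast = -70,
                                               lesion_texture_std = 25),
                       master_seed = 11)
features <- phantom_instance_table(ds)   # 450 instances x 26 columns

report <- five_group_validation(
  features,
  pso = pso_config(swarm_size = 8, iterations = 10, fitness_folds = 3, seed = 2),
  lo  = lo_config(C_step = 0.25, g_step = 0.25, C_halfwidth = 1, g_halfwidth = 2),
  seed = 7)
report
#> <five_group_report> mean of 5 groups: ACC 0.960, SEN 1.000, SPE 0.933

glance(report$classifier)
#> # A tibble: 1 x 7
#>       C      g     P n_key_instances n_excellent_bags n_support_vectors ...
#> 1   127 0.0625  0.86             114               13                26
```

The report says: on the held-out half of the 50 bags, dealt into five
stratified groups, the classifier recognized every cancer bag
(SEN = 1.000) and 93.3% of normal bags (SPE = 0.933), for a mean accuracy
of 0.960. The classifier itself kept 114 key instances from the 13
highest-accuracy bags and tuned the SVM to C = 127, g = 0.0625.
`tidy(report)` returns the per-group confusion counts;
`autoplot(report)` plots them.

Lower-level entry points mirror the pipeline stages:
`generate_phantom()`, `preprocess_image()`, `extract_instances()`,
`instance_features()` / `featurize_bags()`,
`first_instance_optimization()`, `score_instances()`,
`second_instance_optimization()`, `build_classifier()`, `predict_bags()`,
`evaluate_predictions()`; baselines via `single_instance_svm_baseline()`,
`citation_knn_predict()`, `wemisvm_train()`/`wemisvm_predict()`; parameter
studies via `sweep_parameter()` and a YAML-driven `run_experiment()`
(see also the thin CLI at `inst/scripts/iomil-cli.R`).

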