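# aclnet

Three-class chest-radiograph classification (COVID-19 vs. healthy vs.
pneumonia) with marker-controlled watershed preprocessing and a hybrid
attention-CNN-LSTM network, for researchers who want a fully
inspectable, dependency-light reimplementation of this family of
pipelines — every stage from pixels to per-class metrics is plain R (plus
a few compiled kernels), testable on built-in synthetic radiographs
without downloading any clinical data.

## The method

**Preprocessing.** Opacities in a radiograph are blob-like regions of
elevated intensity. Each image is reduced to grayscale and its Sobel
gradient magnitude `|∇f| = sqrt(Gx² + Gy²)` computed; foreground
markers are the h-maxima-suppressed regional maxima of
opening/closing-by-reconstruction, background markers the
distance-transform ridge lines of the thresholded dark region; the
gradient surface is then flooded from the markers alone
(marker-controlled watershed). Every marker component becomes one
catchment basin; pixels where basins meet are watershed ridge lines.
The segmentation is rendered back onto the image (by default the
original intensities with ridges highlighted) and resized to the
network input, 100 × 100 × 3.

**Classifier.** The "ACL" network is a 28-layer graph: two
conv(16, 3×3)/batch-norm/ReLU/max-pool(3×3) stages, a
conv/ReLU/conv/max-pool trunk, an attention branch whose sigmoid output
`α ∈ (0,1)` gates the trunk by element-wise multiplication
(`out = α × x`), and a head of flatten → LSTM(100 hidden units, one
step per image) → FC(100) → ReLU → 40% dropout → FC(3) → softmax
`S_k = exp(x_k)/Σ exp(x_i)`. The LSTM gates act on `[x_t, h_{t−1},
C_{t−1}]` with `C_t = f·C_{t−1} + i·tanh(W_c z + b_c)` and
`h_t = o·tanh(C_t)`. Training is SGDM (`v ← γv − η∇; θ ← θ + v`) on
cross-entropy at η = 0.001, γ = 0.9, 5 epochs, minibatch 32, at
training-test splits 70-30, 80-20 and 90-10.

**Evaluation and ablation.** From the confusion matrix (rows = true),
each class gets one-vs-rest sensitivity `Se = TP/(TP+FN)`, specificity
`Sp = TN/(TN+FP)`, precision `Pr = TP/(TP+FP)`, `F = 2TP/(2TP+FP+FN)`
and a one-vs-rest ROC/AUC; `run_ablation()` trains the four variants —
case1 (plain CNN), case2 (+LSTM), case3 (+attention), full — on
identical splits.

See `vignettes/acl-pipeline.Rmd` for the model details, parameter
semantics and design decisions.

## Worked example

```r
library(aclnet)

# 20 images per class of synthetic lung-field radiographs, 3 classes
ds <- generate_dataset(synth_config(n_per_class = 20, seed = 1))
pp <- preprocess_dataset(ds, preprocess_params())   # MCW + resize to 100x100x3

sp <- stratified_split(pp, "80-20", seed = 1)
model <- build_acl("full", c(100L, 100L, 3L), n_classes = 3, seed = 1)
model
#> <acl_model> variant 'full', 28 layers, 47,437,315 parameters, seed 1

fit <- train_model(model, sp$train, train_config(split_ratio = "80-20", seed = 1),
                   validation = sp$test)
evaluate_model(fit$model, sp$test)
```

On this 60-image run the report prints:

```
#> <metrics_report> accuracy 0.6667
#>      class Se    Sp     Pr F_score    AUC
#>      covid  1 0.625 0.5714  0.7273 0.9062
#>     normal  1 0.875 0.8000  0.8889 1.0000
#>  pneumonia  0 1.000     NA  0.0000 0.8125
```

i.e. per-class sensitivity/specificity/precision/F-score/AUC plus
overall accuracy on the 12 held-out images (`NA` marks a
zero-denominator metric — no pneumonia predictions were made — rather
than a silent 0). Accuracy on such a small run is limited by the
handful of gradient steps five epochs allow: 48 training images at
minibatch 32 give just 10 updates. The vignette discusses this
optimization budget; training the same pipeline to ~150 updates (the
update count the 5-epoch protocol implies at the published dataset
size) reaches 94-100% test accuracy on the synthetic classes.

The same pipeline from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "aclnet", package = "aclnet"))')
$CLI synth      --out data/raw --n 20 --seed 1
$CLI preprocess --data data/raw --out data/proc
$CLI train      --data data/proc --out runs/full --split 80-20 --variant full --seed 1
$CLI evaluate   --model runs/full/model --data data/proc --out runs/eval
$CLI ablate     --data data/proc --out runs/ablation --seeds 1,2,3
$CLI describe   --variant full     # prints the 28-row layer table
```

Every artifact-writing command records its effective configuration,
seed and artifact checksums in a `manifest.yaml`.

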