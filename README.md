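# glcmfusion

Texture analysis of lung nodules in chest CT, for image-analysis researchers
who need a self-contained, testable implementation of the
co-occurrence-plus-recurrence pipeline: multi-level Otsu segmentation
accelerated by the water strider optimization algorithm (WSA-Otsu),
gray-level co-occurrence matrix (GLCM) features in 2D / 2.5D / 3D over
*volume spaces* (slabs of consecutive slices), Haralick descriptors, and an
LSTM fusion classifier producing benign / malignant / ambiguous calls.
Everything runs on synthetic phantoms with exact ground truth — no imaging
dataset is required to build, test, or demonstrate the package.

## The methods in brief

**Segmentation.** For a histogram with level proportions `p_i`, `m` integer
thresholds partition the `L` gray levels into `m+1` classes with masses
`w_k` and means `mu_k`; the thresholds maximize the between-class variance

    fitness(t) = sum_k w_k (mu_k - mu_T)^2 .

`exhaustive_otsu()` enumerates all `choose(L-1, m)` candidates;
`wsa_otsu()` reaches the same optima by evolving a population of threshold
vectors through territory allocation, mating toward each territory's best
("female"), foraging, and larva replacement — practical where enumeration is
not.

**Texture.** GLCMs at unit displacements: 8 directions per slice in 2D
(angular order 0°–315°), 13 non-antipodal directions per 3-slice volume
space in 3D. Matrices are vectorized into per-slice / per-VS sequence steps
(or reduced to 16 Haralick descriptors each).

**Fusion.** A two-layer LSTM (128 units, relu, sequence-to-sequence then
sequence-to-one) with dense softmax head consumes the step sequence; padding
steps are masked and provably cannot change predictions. The LSTM engine —
forward pass, backpropagation through time, Adam — is implemented in the
package in base-R matrix operations.

**Evaluation.** One-vs-rest confusion counts, `F1 = 2TP/(2TP+FP+FN)` as a
one-decimal percent, macro/micro multiclass metrics, rank-based OvR ROC AUC,
stratified k-fold splits.

## Worked example

```r
library(glcmfusion)

## segmentation: recover a threshold on a two-population phantom
ph  <- make_segmentation_phantom(shape = c(9, 64, 64),
                                 means = c(60, 180), sds = c(10, 10), seed = 42)
fit <- wsa_otsu(ph$volume, m = 1, seed = 1)
fit
#> WSA-Otsu multi-level threshold segmentation
#>   m = 1 thresholds over L = 256 levels
#>   population 20 in 5 territories, 100 iterations
#>   thresholds: 127
#>   between-class variance: 3610.92
```

The threshold lands in the empty gap between the two intensity populations
(means 60 and 180), where the between-class variance is maximal —
`exhaustive_otsu()` attains the identical fitness.

```r
## classification: 30 labelled phantoms, 3D-GLCM sequences, LSTM fusion
ds   <- make_dataset(n_per_class = 10, seed = 7)
seqs <- lapply(seq_along(ds$volumes), function(i)
  nodule_feature_sequence(ds$volumes[[i]], ds$masks[[i]], label = 3, L = 16))
split <- kfold_split(30, 5, seed = 2, labels = as.character(ds$labels))[[1]]
model <- fit_fusion(seqs[split$train], ds$labels[split$train],
                    epochs = 30, seed = 7)
model
#> fusion_fit: mode glcm3d, 3 steps x f = 3328, 1905795 parameters
#>   lstm(units=128, activation=relu, return_sequences=TRUE)
#>   lstm(units=128, activation=relu, return_sequences=FALSE)
#>   dense(units=32, activation=relu)
#>   dense(units=3, activation=softmax)
#>   trained 30 epochs: loss 0.0090, accuracy 1.000

table(truth = ds$labels[split$test],
      pred = predict(model, seqs[split$test], type = "class"))
#>            pred
#> truth       benign malignant ambiguous
#>   benign         2         0         0
#>   malignant      0         2         0
#>   ambiguous      0         0         2
```

Each phantom carries a spherical nodule whose spatial texture encodes its
class (smooth field = benign, speckle = malignant, intermediate = ambiguous)
at identical marginal mean and sd, so only co-occurrence structure separates
the classes; the perfect confusion table shows the 3D-GLCM sequences carry
that structure and the fusion network learns it. The detection F-score
convention reproduces published comparison-table values from their counts,
e.g. `f1_from_counts(106, fp = 3, fn = 4)` is `96.8`.

A command-line interface wrapping the same functions is installed at
`inst/cli/glcmfusion.R`:

```sh
Rscript inst/cli/glcmfusion.R synth --n-per-class 5 --seed 7 --out phantoms/
Rscript inst/cli/glcmfusion.R segment --in phantoms/vol_001.pka \
    --thresholds 4 --optimizer wsa --seed 1 --out mask.pka
```

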