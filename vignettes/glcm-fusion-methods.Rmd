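---
title: "Volumetric GLCM texture fusion for lung nodule classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric GLCM texture fusion for lung nodule classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glcmfusion)
```

## Scope

`glcmfusion` implements a texture-based pipeline for lung nodules in chest
CT: (1) preprocessing (Hounsfield windowing, median filtering, isotropic
resampling); (2) multi-level Otsu threshold segmentation accelerated by the
water strider optimization algorithm (WSA-Otsu); (3) gray-level co-occurrence
matrix (GLCM) features computed in 2D, 2.5D, or 3D over *volume spaces* (VSs,
slabs of consecutive slices); and (4) a recurrent (LSTM) fusion classifier
that combines the per-step texture matrices into benign / malignant /
ambiguous calls. Because clinical CT archives cannot ship with a package, a
first-class synthetic-phantom module generates volumes with exactly known
segmentation and texture ground truth; every stage is tested against those
phantoms and against independent brute-force oracles.

## Segmentation: the multi-level Otsu objective

For an image quantized to $L$ gray levels with level proportions
$p_i = n_i / N$, a vector of $m$ strictly increasing integer thresholds
$t_1 < \dots < t_m$ in $[1, L-1]$ partitions the levels into $m+1$ half-open
classes $C_k = [t_{k-1}, t_k)$ (with $t_0 = 0$, $t_{m+1} = L$). With class
masses $w_k = \sum_{i \in C_k} p_i$, class means
$\mu_k = \sum_{i \in C_k} i\, p_i / w_k$ and global mean $\mu_T$, the
objective is the between-class variance

$$\mathrm{fitness}(t) = \sum_k w_k (\mu_k - \mu_T)^2 ,$$

summed over **all** $m+1$ classes of the partition (summing only $m$ of them,
as the formula is sometimes typeset, would silently drop one class; the
identity $\sum_k w_k \mu_k = \mu_T$ and the decomposition *between + within =
total variance* both require the full partition, and both are enforced by the
test suite at $10^{-9}$). Empty classes take $\mu_k = 0$ with $w_k = 0$,
avoiding 0/0 while contributing nothing.

`exhaustive_otsu()` enumerates all $\binom{L-1}{m}$ candidates (ties broken
by the lexicographically smallest vector) and serves as the ground-truth
oracle; it refuses spaces beyond a candidate cap and defers to the
metaheuristic.

## The water strider optimizer

`wsa_otsu()` evolves `pop_size` real-valued positions in $[1, L-1]^m$, each
decoded to a valid integer threshold vector (clip, round, sort, resolve
duplicates upward) whenever the objective is evaluated. Each iteration:

1. **Territory allocation** — the population is ranked by fitness and dealt
   round-robin into `territories` groups, so every territory holds a spread
   of solution qualities. The best member of a territory is its *female*.
2. **Mating** — every strider takes, with probability `mating_prob`, the step
   $X + R \cdot \mathrm{rand}$, otherwise $X + R (1 + \mathrm{rand})$, where
   $R = X_F - X$ is the signed displacement toward the female (the no-mating
   branch overshoots past her). The move is kept only when it strictly
   improves the objective.
3. **Foraging** — otherwise the strider moves $X + 2\,\mathrm{rand}\,(X_{BL} - X)$
   toward the territory best $X_{BL}$ (a switch targets the global best
   instead), and is re-evaluated.
4. **Larva replacement** — a strider still below the territory's median
   fitness is replaced by a larva drawn uniformly inside the coordinate-wise
   bounding box of its territory's members.

Two design choices matter for convergence and were made deliberately:

* **Per-coordinate uniform draws.** The `rand` factors in the mating and
  foraging steps are vectors with one independent uniform per coordinate,
  the usual elementwise reading of population-update equations. With a single
  scalar the moves only ever explore the line segment through the female,
  and in $m \ge 2$ dimensions the optimizer demonstrably stalls one integer
  step away from the optimum.
* **Relocation on collapse.** When a territory's bounding box has collapsed
  (the larva decodes to exactly the position it replaces), the strider is
  relocated uniformly in the domain — the "moved to another territory for
  more foraging" behaviour. Without it a fully collapsed population is a
  fixed point of all three operators and the search is dead for the remaining
  iterations.

With the defaults (population 20, 5 territories, 100 iterations,
`mating_prob` 0.5) the optimizer recovers the exhaustive optimum on 3-mode
$L = 64$ histograms for $m \le 3$ in at least 19 of 20 seeded runs — the
property the acceptance suite checks. Elitism is bookkeeping only: the
best-so-far trace is monotone non-decreasing by construction, whatever the
population does. Overparameterized settings (e.g. $m = 2$ thresholds on a
clean 2-mode histogram) have a near-flat fitness ridge and may occasionally
return a neighbouring vector of equal practical quality; the package makes
no optimality claim there.

Defaults for the population parameters are conventional metaheuristic
choices; they are all exposed as arguments.

## Preprocessing

* **Windowing** maps a Hounsfield interval (default −1000 to 400 HU, aerated
  lung through soft tissue) linearly onto 0–255, clipping outside, rounding
  half away from zero (platform-stable, unlike round-half-even).
* **Median filtering** is 2D per slice with a 3×3 default window and
  symmetric (edge-included) border padding. The median of an odd integer
  window is a member of the window, so the filter provably introduces no new
  intensity values — asserted per slice in the tests. A 2D-per-slice filter
  was chosen over a 3D one because slice spacing generally differs from
  in-plane spacing before resampling.
* **Isotropic resampling** uses separable linear interpolation. The sample
  count per axis is `round((n-1) * spacing / target) + 1`: point-based
  extent, both endpoints preserved (10 slices at 2 mm resample to 19 slices
  at 1 mm). Integer domains are rounded back after interpolation.
* **Pipeline order** is rescale → median filter → resample: the filter's
  no-new-values guarantee is most useful on the already-quantized gray
  image, and resampling last leaves its interpolated values untouched.

## GLCM features over volume spaces

A GLCM at displacement $d$ counts ordered voxel pairs $(a, b)$ at that
offset. Unit chessboard displacements are used throughout (pair distance 1,
the Haralick default). The canonical direction sets are:

* **2D**: 8 offsets in angular order 0°, 45°, …, 315°, with 0° = east
  $(\Delta r, \Delta c) = (0, +1)$ and the row index growing downward.
  Matrices are kept direction-resolved and asymmetric, so the 180° matrix is
  the transpose of the 0° one — each of the eight senses is a distinct
  sequence step for the fusion network.
* **3D**: the 13 offsets covering the 26 unit neighbours modulo negation, in
  lexicographic order, accumulated symmetrically (both pair orders).

For volumetric texture, a scan is partitioned into volume spaces of 3
consecutive slices (so 1 mm-isotropic data gives 1 mm³ voxels per VS); a
trailing remainder forms a short final VS rather than being dropped.
Computing the 13 matrices per VS, rather than for the whole scan at once,
keeps the computation local and the quantization level can stay higher for
the same budget; no pairs cross VS boundaries (the boundary-pair accounting
is tested explicitly).

Quantization maps gray8 to $L$ levels by $\lfloor v L / 256 \rfloor$.
Defaults: $L = 256$ for the 2D mode (the native gray resolution) and
$L = 32$ for 2.5D/3D (the per-step vector is $13 L^2$ long; 32 levels keep
it at 13 312 while preserving class-relevant contrast).

Sixteen Haralick-style descriptors summarize each normalized matrix — the
canonical fourteen (energy, contrast, correlation, variance, inverse
difference moment, sum average, sum variance, sum entropy, entropy,
difference variance, difference entropy, the two information measures of
correlation, and the maximal correlation coefficient) plus maximum
probability and dissimilarity. Entropies are in bits; the information
measures use natural logs internally (IMC1 is a base-free ratio; IMC2 uses
the standard $\sqrt{1 - e^{-2(HXY2 - HXY)}}$ form). The maximal correlation
coefficient is defined as 0 when the matrix support has fewer than two gray
levels, where the second eigenvalue does not exist.

Feature sequences are assembled by flattening each matrix row-major and
concatenating directions in canonical order: 8 steps of $L^2$ (2D), $n$
slices of $8L^2$ (2.5D), $p$ VSs of $13L^2$ (3D), or $p$ steps of $13 \times
16$ descriptors. Sequences are zero-padded to a stated maximum with a mask;
an over-long sequence is an error, never a silent truncation.

## The LSTM fusion classifier

The recurrent network is implemented in the package itself — forward pass,
backpropagation through time, and the Adam optimizer, all as dense base-R
matrix operations — with the fixed per-mode architecture:

| mode | layers |
|------|--------|
| 2D | LSTM(128, relu, seq-to-seq) → LSTM(128, relu, seq-to-one) → Dense(3, softmax) |
| 2.5D / 3D / descriptors | … → Dense(32, relu) → Dense(3, softmax) |

The "eight (or $n$, $p$) LSTMs" of the architecture tables are one weight set
unrolled over the sequence axis — directions in 2D mode, slices in 2.5D, VSs
in 3D — so information from each step conditions all subsequent steps.
Gate activations are sigmoid; the cell-candidate and output activations are
relu per the architecture table. Masked padding steps carry the hidden and
cell state through unchanged, which makes the sequence-to-one readout simply
the state after the final step and gives the padding-invariance property
*exactly* (the tests assert it at 10⁻⁶; the mechanism guarantees 0).

Training uses softmax cross-entropy, Adam at learning rate 10⁻³, batch 16,
20 epochs by default — conventional settings, all exposed. Weights are
Glorot-uniform with forget-gate bias 1. Runs are seeded and bit-reproducible;
a non-finite loss aborts with a diagnostic rather than continuing. Optional
per-feature standardization (stored with the model, applied at prediction)
is available and recommended for the descriptors mode, whose 16 summaries
span very different scales; raw GLCM probability features train well without
it. Class-weighting (inverse frequency) is available behind a flag and off
by default.

Classes are ordered benign < malignant < ambiguous; `classify()` breaks
exact probability ties toward the earlier class.

## Synthetic phantoms: what they do and do not show

The generators are pure functions of their parameters and a seed:

* `make_segmentation_phantom()` builds gray8 volumes whose background is
  split into vertical bands of Gaussian intensities (means 60/180, sd 10 by
  default — two clearly separated tissue-like populations) plus optional
  spherical inserts, with an exact region mask. With zero noise a single
  Otsu threshold separates the regions exactly.
* `make_texture_nodule()` encodes class in spatial correlation at matched
  marginal mean and sd (128 ± 40 gray): *benign* is a Gaussian random field
  smoothed at σ = 2.5 voxels (low co-occurrence contrast), *ambiguous* at
  σ = 0.8 (intermediate), *malignant* is unsmoothed speckle (high contrast).
  The three classes have non-overlapping interquartile ranges of mean 3D-GLCM
  contrast across seeds — separability is by construction, and the class ↔
  texture assignment (smooth = benign, speckled = malignant) mirrors the
  clinical intuition that irregular texture is the suspicious phenotype.
* `make_dataset()` embeds one textured spherical nodule (radius 6 voxels,
  jittered in-plane) per 64×64×9 phantom at 1 mm isotropic — 9 slices give
  exactly three 3-slice volume spaces, and the default size keeps a
  150-volume dataset generable in seconds.

Passing the end-to-end test (held-out accuracy ≥ 0.90 on 150 phantoms, 20
epochs, averaged over 3 seeds) therefore demonstrates that the feature
pipeline preserves co-occurrence information and that the recurrent fusion
learns it — it does **not** demonstrate clinical performance. Real nodules
differ in every hard way: overlapping texture distributions, anatomy and
vasculature, acquisition variation, label noise. Reproducing published
accuracies on clinical archives requires those archives and is out of scope.

## Numerical conventions

* Rounding is half-away-from-zero everywhere a deterministic integer is
  needed (gray mapping, percent formatting to one decimal).
* Normalized GLCMs sum to 1 within 10⁻¹²; a matrix that counted zero pairs
  stays all-zero rather than dividing by zero.
* AUC uses midranks (rank-based Mann–Whitney), macro averaging is the
  unweighted mean of per-class one-vs-rest AUCs, micro pools all
  (indicator, score) pairs; multiclass sensitivity/specificity are
  macro-averaged one-vs-rest rates (micro behind a flag).
* The detection F-score is $2TP / (2TP + FP + FN)$ reported as a percent at
  one decimal.
* The DICOM codec is deliberately minimal (explicit VR little endian,
  uncompressed, single-frame files, the geometry and pixel tags only): it
  round-trips with itself, orders slices by position — never filename — and
  rejects series with non-uniform slice spacing. It is not a general DICOM
  reader.

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on generated data:
segmentation oracles on $L = 64$ three-mode histograms (20 seeded optimizer
runs per threshold count, $m \le 3$); GLCM kernels against a brute-force
pair enumerator on 200 small random images; and the classification pipeline
on 150 phantoms (50 per class) with 3D-GLCM sequences at $L = 32$, a
stratified 80/20 split, 20 epochs and 3 training seeds. These sizes were
chosen as the smallest at which each property is meaningfully exercised.

## Known limitations

* No clinical-data ingestion beyond the minimal DICOM/NIfTI readers; no
  annotation-XML parsing.
* The LSTM engine is CPU-only and dense; it is sized for the package's
  sequence lengths (≤ tens of steps), not for long-sequence workloads.
* `exhaustive_otsu` is the oracle only where $\binom{L-1}{m}$ is small;
  beyond the cap the optimizer's result has no certificate.
* The phantom generator makes no attempt at anatomical realism — by design.
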