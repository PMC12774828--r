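---
title: "Contrastive spherical embeddings of SNP genotypes: models and methods"
author: "popsphere"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{popsphere methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Population-structure visualization reduces a diploid genotype matrix — N
samples by D biallelic SNPs, coded as alternate-allele counts 0/1/2 with -1
for missing — to two or three coordinates per sample. Classical choices
(PCA, t-SNE, UMAP) either favor global or local structure and do not give a
model that can be applied to new samples. popsphere implements a
self-supervised alternative: a convolutional encoder is trained with a
contrastive loss so that two stochastically perturbed views of the same
individual embed close together while different individuals repel, yielding
an embedding on the 3D unit sphere that captures structure at both scales
and generalizes to unseen or partially genotyped samples.

# The centroid-based N-pair loss

For an anchor embedding $z$, its positive $z^+$ (a second augmented view of
the same individual) and negatives $\{z_i^-\}$ (the other samples in the
batch), the classical N-pair loss is

$$L = \log\Big(1 + \sum_i \exp(z^\top z_i^- - z^\top z^+)\Big),$$

with inner products taken about the global origin, so the loss depends on
where in space a configuration sits. The centroid-based variant evaluates
every anchor–negative comparison in a local frame instead. Per negative,

$$C_i = \tfrac{1}{4}(z + 2 z_i^- + z^+),$$

all three points are shifted by $-C_i$ and divided by
$\mu_i = \max(\lVert z - C_i\rVert, \lVert z^+ - C_i\rVert,
\lVert z_i^- - C_i\rVert)$, giving normalized vectors $\tilde z$. The loss is

$$L = \log\Big(1 + \sum_i \big[\exp(\tilde z_i^\top \tilde z_i^- -
\tilde z_i^\top \tilde z_i^+) - e^{-2}\big]\Big).$$

In the best case — anchor and positive coincident, the negative anywhere
else — the construction gives $\tilde z^\top \tilde z^- = -1$ and
$\tilde z^\top \tilde z^+ = 1$ exactly, so the $e^{-2}$ offset makes that
configuration contribute zero loss. Because each term sees only
centroid-relative geometry, the loss is invariant to translating or
rotating the whole embedding; the test suite asserts both invariances and
the non-invariance of the plain N-pair loss.

On the magnitude in the scaling: the source formulation of $\mu_i$ is
sometimes written with squared norms, but only the plain magnitude makes
the best-case identities above hold ($\pm 1$ inner products); popsphere
therefore uses the magnitude, and keeps the squared variant behind
`scaleMu(..., squared = TRUE)` for comparison.

`batchLoss()` sums one term per batch member acting as the anchor. The
default negative set for each anchor is all other samples in the batch;
`loss.negatives = "inverse_distance"` instead samples negatives without
replacement with weight $1/(\text{distance}+\varepsilon)$,
$\varepsilon = 10^{-12}$.

# Augmentation

Positives are built by genotype-specific augmentation, applied in fixed
order: allele flips, then masking, then one-hot encoding.

* **Flip**: each non-missing call is moved by exactly one allele with
  probability $p_\text{flip}$: $0 \to 1$, $2 \to 1$, and $1 \to 0$ or
  $1 \to 2$ with equal probability. A single application never produces
  $0 \leftrightarrow 2$.
* **Mask**: each call becomes missing (-1) with probability
  $p_\text{mask}$.
* **One-hot**: $0 \to (1,0,0,0)$, $1 \to (0,1,0,0)$, $2 \to (0,0,1,0)$,
  $-1 \to (0,0,0,1)$; missingness is a first-class input channel rather
  than an imputed value.

Rates are drawn per sample and per training iteration as
$p \sim U(\text{rateLow}, p_\text{max})$. The published experiments use
rate bounds $U(0.01, 0.99)$, which is also the package default
(`augmentationConfig()`). Those bounds were chosen for datasets with on the
order of $10^5$ markers, where even a 99%-masked view retains a thousand
informative sites. At the desk scales used throughout this package's tests
(about $10^3$ markers) the same bounds leave single-digit numbers of
visible markers at the top of the range, and we observed that they starve
the encoder of signal; the desk-scale analyses therefore use
$p_\text{flip,max} = p_\text{mask,max} = 0.5$, stated wherever they are
used. The ablation comparison keeps the aggressive $(0.99, 0.99)$ setting,
since its point is the contrast with no augmentation at all.

With augmentation off the two views coincide, every loss term sits exactly
in the best-case configuration, and the gradient of the centroid loss
cancels identically (the test suite checks this): training without
augmentation leaves the encoder at its random initialization. This is the
mechanism behind the collapse observed in zero-augmentation ablations.

# Encoder and training

The encoder maps the one-hot (D x 4) input through 2 convolutional layers
(5 filters, kernel 3, stride 1, "same" zero padding, SiLU), a flatten, 3
dense layers of 256 units with batch normalization and SiLU, and a final
dense layer with 3 units followed by L2 normalization onto the unit
sphere. Batch normalization is applied to the dense layers only;
convolutions carry activations only. Whether the original architecture
also normalized the convolutional activations is ambiguous; a per-filter
conv batch-norm variant is available (`encoderConfig(convBatchNorm =
TRUE)`) for comparison, and the default follows the literal dense-only
description. Weights use Kaiming-uniform initialization, deterministic
given the seed.

Training: Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$), learning rate 0.001
decayed by 0.99 every 10 epochs, default 5000 epochs at batch size 64 for
paper-scale data. The decay schedule's "every 10 iterations" is read as
epochs: a per-step 0.99 decay would underflow to zero learning rate over
long runs; `lrDecayUnit = "step"` restores the literal reading. Each batch
draws fresh rates, builds two augmented views per sample, embeds both
(view 1 = anchors and negatives, view 2 = positives), and applies one Adam
update; batch-norm running statistics (momentum 0.1) accumulate during
training and are used for inference-mode embedding, so validation samples
are embedded un-augmented and deterministically, with genuinely missing
calls routed to the missing channel.

Desk-scale training parameters: the recovery, ablation and chip-masking
analyses in the tests and acceptance runs train 108 samples with batch
size 32 (at batch 64 an epoch is only two gradient steps, which converges
visibly more slowly at 300 epochs) and the augmentation bounds above; all
other settings are the defaults. These choices are fixed here once and
used unchanged everywhere.

Backpropagation through the normalization, dense, batch-norm and
convolution layers is implemented analytically and verified against
central finite differences in the test suite, as are the gradients of all
three batch losses.

# Sphere to plane: Equal Earth

Embeddings live on the unit sphere; for plotting they are mapped to the
plane with the Equal Earth pseudocylindrical projection (coefficients
$A_1 = 1.340264$, $A_2 = -0.081106$, $A_3 = 0.000893$, $A_4 = 0.003796$),
applied at unit radius: latitude $\varphi = \arcsin(x_3)$, longitude
$\lambda = \operatorname{atan2}(x_2, x_1)$, parametric latitude
$\sin\theta = \tfrac{\sqrt 3}{2}\sin\varphi$. On the unit sphere the map
is exactly equal-area (planar area equals spherical area; the test grid
asserts agreement within 0.5%). The sphere may be rotated (three Euler
angles) before projecting; rotation changes only the 2D picture, never the
3D geometry. Near the antimeridian neighbors can land on opposite edges
of the map — a plotting artifact of any sphere-to-plane projection, which
is why all quantitative metrics default to the 3D coordinates.

# Evaluation metrics

All label-based scores build on a KNN classifier (Euclidean distance,
majority vote). Deterministic tie handling: neighbor ties resolve by
reference order, vote ties by smaller mean distance then lexicographic
label — reproducibility over elegance.

* **L (local)**: 3NN accuracy for the subpopulation label on the training
  embedding, each query excluded from its own neighbor set (without
  self-exclusion the score is trivially inflated).
* **G (global)**: subpopulation mean coordinates are classified by
  superpopulation with 3NN among the centroids. With fewer than four
  subpopulations per superpopulation the score is structurally penalized
  (a perfectly separated 2x2 layout scores 0); the metric is meaningful
  when superpopulations contribute several subpopulations.
* **GE (generalization)**: 3NN accuracy of held-out samples queried
  against the training embedding. The label tier is the caller's choice;
  the package reports the subpopulation tier by default.
* **Neighbor overlap**: mean fraction of shared members between the k
  nearest neighbors under Manhattan distance on genotypes and Euclidean
  distance in the embedding, for k in 3..100.
* **Rank RMSE**: for each sample's n-th genotype-space neighbor, the root
  mean squared difference between n and that neighbor's embedding-space
  rank, n in 1..100; rank ties break by stable sort on sample index. The
  "root" is applied as the name of the quantity demands, although the
  defining sum is sometimes printed without it.

Scores are computed on the 3D spherical coordinates, not the 2D
projection: the sphere is the true geometry and the projection introduces
wrap-around artifacts. A `use2d` escape hatch exists in the internal
coordinate accessor for comparisons.

# The synthetic-data generator

`simulateHierarchical()` draws from a two-level Balding–Nichols model: per
marker an ancestral frequency $p \sim U(0.1, 0.5)$ (common variants, as
after MAF filtering); each superpopulation frequency from
$\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ with $F = F_\text{super}$, each
subpopulation frequency the same way around its superpopulation with
$F_\text{sub}$, and genotypes $\mathrm{Binomial}(2, p_\text{sub})$. The
model gives closed-form drift variance $F\,p(1-p)$, which the tests use as
an oracle. Defaults — 3 superpopulations x 3 subpopulations x 15 samples,
1000 markers, $F_\text{super} = 0.25$, $F_\text{sub} = 0.03$ — produce a
dataset whose raw-genotype 3NN subpopulation accuracy is near but below 1,
i.e. realistic two-tier structure with some overlap between sister
subpopulations.

What the generator emulates: hierarchically structured allele-frequency
drift, complete genotypes, and the SNP-chip missingness design
(`applyChipMasking()`: 80% of samples untouched, the rest split evenly
into four groups, each group sharing one random 20% marker subset set to
missing, optionally mode-filled from the untouched reference). What it
does not emulate: linkage disequilibrium, admixture, coalescent noise,
genotyping error structure, or unbalanced sampling. Passing tests on this
generator therefore demonstrate that the method recovers drift-induced
hierarchical structure, not that it handles every property of real data.

# Numerical choices and degenerate inputs

* $\mu_i$ floored at $10^{-12}$; an exactly coincident
  anchor/positive/negative triple contributes a skipped term with a
  warning.
* Mode imputation ties break toward the smaller genotype value.
* MAF is computed over non-missing calls; markers with all calls missing
  are dropped by the filter with a message.
* Chromosome labels are strings; sex-chromosome sets are configurable per
  species (`sexChromosomes("dog")` is {X, Y, 39, 40}) because file
  conventions vary. "Noninformative sites" are read as monomorphic
  markers (`dropMonomorphic()`), the minimal reading consistent with MAF
  filtering.
* The all-missing one-hot input embeds to a finite unit vector (the
  missing channel is an ordinary input pattern).
* Configuration files are YAML; flat keys mirror the function arguments.

# Problem sizes in the checks

The test suite and the acceptance analyses use desk scales chosen so the
full suite runs on a single CPU: the recovery and chip-masking runs train
108 samples x 1000 markers for 300 epochs; the augmentation ablation
trains the same design for 150 epochs over three seeds per arm. Oracle
comparisons (KNN, overlap, rank RMSE) use 25–30 point instances against
brute-force double loops.

# Known limitations

* Training is single-threaded deterministic R + BLAS; it is meant for
  desk-scale experimentation and method study, not for 10^5-marker
  production runs (the published experiments at that scale used GPU
  training over thousands of epochs).
* Batch-norm statistics are accumulated on augmented views but applied to
  clean inputs at inference; at small sample sizes this shift can cost a
  few points of L/GE. A post-training recalibration pass was explored and
  intentionally not enabled by default, to keep the training procedure
  exactly as published.
* No LD-aware augmentation; no admixed-individual simulation; VCF input,
  phased data and multi-allelic markers are out of scope.
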