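---
title: "Compressing mass spectrometry images with a contrastive encoder-decoder"
author: "msiCodec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressing mass spectrometry images with a contrastive encoder-decoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiCodec)
```

## The problem

Mass spectrometry imaging (MSI) acquires a full mass spectrum at every
pixel of a tissue section. After binning to a 0.1-Da grid a single image
easily reaches 10^3-10^4 intensity values per pixel and 10^4-10^5 pixels,
i.e. gigabytes per image. That size makes routine analyses — k-means
segmentation, t-SNE exploration, long-term storage — slow or infeasible.

msiCodec compresses each pixel's binned spectrum (length $F_s$) into a
short embedding (length $F_e$, e.g. 64) with a one-dimensional
convolutional encoder-decoder, trained per image (or per patient) so that
the embeddings (i) discriminate chemically distinct pixels, (ii) follow a
regular distribution that downstream clustering likes, and (iii) can be
decoded back to spectra with only minor loss. For a 34,840-pixel image and
$F_e = 64$ the embeddings occupy $34{,}840 \times 64 \times 4$ bytes
$\approx 8.5$ binary MB at single precision — a ~99.4% reduction relative
to a 1.5 GB raw image.

## Preprocessing

* **Binning** (`binToGrid()`): raw points are summed into the bin whose
  center is the m/z rounded to the grid. Ties at bin boundaries round half
  away from zero — one fixed rule keeps binning reproducible across
  platforms. Total intensity is conserved exactly per pixel.
* **Smoothing** (`gaussianSmooth()`): convolution with a discrete Gaussian
  ($\sigma$ = 0.1 Da by default), truncated at $4\sigma$ and renormalized
  to unit sum so interior intensity is conserved. Profile-mode spectra are
  the natural input for a convolutional network; centroided data should be
  smoothed this way first.
* **Normalization** (`normalizeIntensities()`): intensities are divided by
  the dataset-wide maximum; the scale is recorded in the codec so decoding
  restores original units exactly. The global maximum (rather than per-pixel
  scaling) preserves between-pixel intensity structure, which is part of
  the signal.

## The model

The encoder applies four 1-D convolution blocks (channels 8, 16, 32, 64;
kernel 7; stride 4; each followed by feature normalization and ReLU), then
a linear layer to $F_e$. The stride stack downsamples the spectral axis
256-fold; inputs are zero-padded to the nearest compatible length and the
padding is stripped on decode. The decoder mirrors the encoder: a linear
layer and ReLU back to the flattened convolutional shape, then transposed
convolutions in reverse order. The feature-normalization layers standardize
each channel to mean 0 / sd 1 over the batch during training and use
running statistics at inference, so encoding is deterministic and
row-independent. All of this is configurable through
`codecArchitecture()`; the defaults above are this package's declared
choice of layer sizes, suited to spectra of a few thousand bins.

## The objective

Training minimizes a weighted sum of four losses over batches of $2N$
spectra (each original paired with one noisy copy):

* **Contrastive loss** (`contrastiveLoss()`): for every ordered positive
  pair $(i, j)$,
  $\ell_{i,j} = -\log \frac{\exp(\mathrm{sim}(w_i, w_j)/\gamma)}
  {\sum_{k \ne i} \exp(\mathrm{sim}(w_i, w_k)/\gamma)}$,
  summed and scaled by $\alpha$, with $\mathrm{sim}$ the cosine
  similarity. The similarity is computed on the embeddings $w$ (standard
  contrastive-learning practice; the distribution-shaping losses below
  already operate on $w$, which identifies the network output as the
  object being shaped). Defaults: $\alpha = 1/2N$ so the term is a
  per-anchor average independent of batch size, and $\gamma = 0.5$; both
  are configurable because no canonical values exist for MSI data. The
  implementation is stabilized by row-max subtraction and is tested
  against a literal double-loop transcription of the formula.
* **Mean loss** (`meanLoss()`): $\frac{1}{2N}\sum_i \mu(w_i)^2$, keeping
  embeddings centered at zero.
* **Standard loss** (`standardLoss()`): $\frac{1}{F_e}\sum_j
  (\sigma_j(w) - 1)^2$ with the *population* standard deviation of each
  embedding feature over the batch (one convention, fixed so the oracle
  tests are exact).
* **Decoder loss** (`mseLoss()`): mean squared error between original and
  decoded spectra, averaged over all pixels and bins. High-intensity peaks
  present in many pixels dominate this mean, so rare low-intensity peaks
  are the ones at risk of being lost — an accepted property of the method.

Default weights are 0.1 / 0.01 / 0.01 for the contrastive, mean and
standard terms with a decoder weight of 0.01 (the single-image preset) or
1 (`lossWeights(preset = "cohort")`, suited to large cohorts where
reconstruction fidelity is emphasized).

### Augmentation

The positive partner of each spectrum is produced by multiplying every bin
by an independent uniform factor in $[1-\delta, 1+\delta]$, $\delta = 0.1$:
intensities move by up to 10% while peak positions — the spectral
structure — are untouched. Per-bin (rather than one global factor per
spectrum) noise was chosen because a single global factor is invisible to
the cosine similarity, which would make the positive pair trivially
similar and the contrastive signal empty. Each pair is (original, one
augmentation); zeros stay zero.

## Training

`trainCodec()` uses Adam (learning rate $10^{-3}$, weight decay $10^{-5}$,
the weight decay added to the gradient as in common deep-learning
practice), batch sample size $N = 64$ (so 128 spectra per batch), and
early stopping with patience 30 epochs on the weighted *training* loss —
no validation split is used, matching how the procedure is applied to a
single image that the codec is allowed to memorize. An epoch is one full
seeded-shuffled pass over all pixels, keeping the last incomplete batch;
an image smaller than one batch trains with a single smaller batch (with a
warning). Improvement means a relative decrease of at least $10^{-6}$ in
the weighted epoch loss; on stopping, the parameters of the best epoch are
restored, so the returned codec is never worse than any checkpointed
epoch. All randomness (initialization, shuffling, augmentation) derives
from one seed, and two runs with the same seed are bit-identical on a
single thread.

`trainPerGroup()` trains one codec per subject with per-group seeds derived
from the master seed, so the encoder captures subject-specific tissue
variation rather than inter-subject differences.

## Segmentation

* **k-means** (`kmeansSegment()`): k-means++ initialization, 10 restarts,
  Lloyd iterations, fixed seed. In practice $k$ is chosen with a margin
  (e.g. 12 for 7 expected tissue types) and the matching step merges
  redundant clusters.
* **Iterative k-means** (`iterativeKMeans()`): principal components of the
  centered features are computed once; walking the components in order of
  explained variance, each 1-D projection is clustered with k-means for
  $c \in \{2..c_{max}\}$ and scored by mean silhouette width
  (`bestCountForComponent()`). The best $c$ is accepted if its silhouette
  reaches $\tau$; otherwise the component is declared structureless
  ($c = 1$) and the walk stops. The default $\tau = 0.75$ was placed by
  measuring both regimes: k-means splits of a structureless 1-D projection
  (a single Gaussian or uniform sample) score mean silhouettes of about
  0.55–0.67, while genuinely separated 1-D clusters score 0.9 and above,
  so 0.75 sits between them with a wide margin on both sides. Accepted counts multiply
  ($k \leftarrow k \cdot c$) until $k \ge K$. The final clusters are the
  Cartesian composite of the per-component assignments with empty
  combinations dropped — the only reading under which the running product
  $k$ equals the attainable cluster count. Design choices made here, and
  why: the silhouette is undefined for $c = 1$, so a threshold $\tau$
  decides when a component has no usable structure; the 1-D projection
  (not the data restricted to a subspace) is clustered because components
  are examined one at a time; and the per-component candidate range is not
  capped by the remaining budget $K/k$, since the procedure multiplies
  freely and stops once $k \ge K$.
* **Convolutional smoothing** (`convolutionalSmooth()`): each labeled pixel
  takes the majority label of the $(2r+1)^2$ window around it (default
  radius 1, the 8-neighborhood), computed synchronously from the input
  map; ties go to the smallest label id; unlabeled pixels neither vote nor
  change. Window size and iteration count are exposed because no single
  canonical setting exists.

## Matching and accuracy

`matchClusters()` assigns every predicted cluster to the baseline class
most frequent among its pixels (majority vote), ties to the smallest class
id, independently per cluster — several clusters may map to one class,
which is exactly what merges an over-segmented prediction down to the
baseline classes. Pixels the baseline leaves unlabeled (`-1`) are excluded
from both the vote tallies and the accuracy denominator, because real
baselines (manual delineations) rarely cover the full grid; a matched
`-1` prediction on a labeled baseline pixel counts as incorrect.
`segmentationAccuracy()` is then `100 x correct / labeled`. Since the
baseline is itself the product of another method, this accuracy reads as
agreement with that method rather than absolute truth.

## The synthetic data generator

`generateLabelMap()`, `generateSignatures()` and `renderImage()` build MSI
images with known structure: a grid partitioned into contiguous tissue
classes (stripes, nested rings, or a Voronoi tessellation), each class
emitting 5 class-specific Gaussian peaks (width 0.15 Da) plus 10 shared
background peaks on a 3000-bin, 0.1-Da axis starting at m/z 100. Pixel
variation is one log-normal factor per pixel (sdlog 0.2, emulating
sample-thickness and ionization variation) plus an additive Gaussian floor
at 1% of the largest peak, clipped at zero. The default study image
(`syntheticFixture()`) is 32 x 32 pixels with 4 nested-ring classes —
small enough that the full train-encode-segment-evaluate loop runs on a
desktop CPU in minutes, and informative enough that raw-spectrum k-means
already recovers the planted classes (a property the test suite asserts,
so codec tests measure the codec rather than the fixture).

What the generator deliberately does **not** emulate: isotope patterns,
mass-accuracy drift, correlated (structured) noise, spatial intensity
gradients, and class-dependent background. Passing tests on these fixtures
therefore demonstrate that the implementation is correct and that the
method behaves as designed on well-posed inputs; they do not certify
accuracy figures on real tissue.

## Numerical choices

* The network, its backpropagation and Adam are implemented in the package
  (R with small C++ kernels for the convolution gather/scatter and
  normalization passes); analytic gradients are verified against finite
  differences in the test suite.
* Binning ties round half away from zero; Gaussian kernels truncate at
  $4\sigma$ and renormalize; the batch-normalization epsilon is $10^{-5}$
  with momentum 0.1 on running statistics.
* k-means uses 10 k-means++ restarts; constant 1-D projections short-cut
  to $c = 1$ rather than erroring.
* Embeddings are stored single precision (4 bytes/value) — the figure the
  storage arithmetic assumes; pixel tables are Parquet with float32
  intensity columns and bin centers printed with one decimal as column
  names; the codec file stores weights at full double precision so
  save/load round trips reproduce encodings bit-exactly. The codec id is
  an MD5 content hash of the canonical serialization, so any weight change
  changes the id and decoding refuses embeddings from a different codec.

## Problem sizes used by the shipped checks

The test suite and the acceptance script train on the 32 x 32 default
fixture (1024 pixels, 3000 bins) with the default batch size 64 for up to
100 epochs (early stopping applies) and run unit-level
checks on 8 x 8 to 16 x 16 images with a few hundred bins and a narrower
two-block architecture. These sizes were chosen as the smallest at which
every claimed property (loss-oracle equivalence, reconstruction quality,
segmentation recovery, iterative k-means behavior) is comfortably
exercised on a single desktop CPU.

## Known limitations

* The contrastive term is instance discrimination: every other pixel in
  the batch is a negative, including same-class pixels, and the standard
  loss pushes every embedding feature to unit variance. Together these
  make the embedding cloud nearly isotropic, so plain Euclidean k-means on
  embeddings can score *below* k-means on raw spectra when the raw spectra
  are already trivially separable (the synthetic fixtures are such a
  case). The information is nevertheless preserved: clustering the decoded
  spectra recovers the planted classes nearly perfectly, and the shipped
  acceptance script reports both numbers.
* Training cost in this implementation is CPU-bound R/BLAS; it is intended
  for method validation and moderate images, not GPU-scale cohorts.
* The contrastive temperature and weight defaults are declared choices;
  for real data they may need tuning per dataset.
* t-SNE of embeddings is out of scope here; embeddings export cleanly (the
  single-file container or Parquet) for external tools.
* The iterative k-means composite can exceed `K` clusters when the last
  accepted component multiplies past the target; this is by design
  (the procedure stops when $k \ge K$, not at exactly $K$).
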