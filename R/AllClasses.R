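#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' MSImage: a binned mass spectrometry image
#'
#' An `MSImage` holds one binned intensity vector per measured pixel of a
#' mass spectrometry image, on a shared uniform m/z bin grid. It extends
#' [SummarizedExperiment::SummarizedExperiment] with the assay storing bins
#' in rows and pixels in columns; `rowData` carries the m/z bin centers and
#' `colData` the 0-based pixel coordinates (`x` = column, `y` = row). The
#' grid need not be fully occupied: tissue sections are irregular, so
#' unmeasured pixels are simply absent.
#'
#' Validity requires a strictly increasing, uniformly spaced m/z axis
#' (relative tolerance 1e-9 on the step), finite nonnegative intensities,
#' and unique in-range pixel coordinates.
#'
#' @seealso [msImage()] for construction, [intensityMatrix()], [mzAxis()],
#'   [pixelCoords()]
#' @export
setClass("MSImage", contains = "SummarizedExperiment")

#' LabelMap: a per-pixel integer class image
#'
#' Stores one integer class label per occupied pixel of an image grid, with
#' `-1` as the "unlabeled"/background sentinel. Used both for segmentation
#' predictions and for baseline (ground-truth) annotations.
#'
#' @slot width,height grid dimensions in pixels
#' @slot coords integer matrix `[n x 2]` of 0-based `(x, y)` positions
#' @slot labels integer vector of class ids, `-1` allowed
#' @slot provenance `"prediction"` or `"baseline"`
#' @export
setClass("LabelMap",
  representation(width = "integer", height = "integer",
                 coords = "matrix", labels = "integer",
                 provenance = "character"))

setValidity("LabelMap", function(object) {
  msg <- character()
  if (nrow(object@coords) != length(object@labels))
    msg <- c(msg, "coords and labels disagree in length")
  if (ncol(object@coords) != 2L)
    msg <- c(msg, "coords must have two columns (x, y)")
  if (any(object@labels < -1L))
    msg <- c(msg, "labels must be >= -1")
  if (nrow(object@coords) > 0) {
    x <- object@coords[, 1L]; y <- object@coords[, 2L]
    if (any(x < 0L) || any(x >= object@width) ||
        any(y < 0L) || any(y >= object@height))
      msg <- c(msg, "pixel coordinates out of the [0, width) x [0, height) range")
    if (anyDuplicated(paste(x, y)))
      msg <- c(msg, "duplicate pixel coordinates")
  }
  if (!object@provenance %in% c("prediction", "baseline"))
    msg <- c(msg, "provenance must be 'prediction' or 'baseline'")
  if (length(msg)) msg else TRUE
})

#' CodecArchitecture: shape of the spectral encoder-decoder
#'
#' Describes the 1-D convolutional encoder-decoder: input length `fS`,
#' embedding length `fE`, per-block channel counts, shared kernel size and
#' stride, and whether feature (batch) normalization layers are used. The
#' decoder mirrors the encoder with transposed convolutions in reverse
#' order and reconstructs exactly `fS` values.
#'
#' @slot fS integer, number of m/z bins of the input spectra
#' @slot fE integer, embedding length
#' @slot channels integer vector, output channels of each encoder block
#' @slot kernelSize,stride integers shared by all blocks
#' @slot useNormalization logical
#' @export
setClass("CodecArchitecture",
  representation(fS = "integer", fE = "integer", channels = "integer",
                 kernelSize = "integer", stride = "integer",
                 useNormalization = "logical"))

#' Codec: a trained spectral encoder-decoder
#'
#' Bundles a [CodecArchitecture-class] with its trained weights, the batch
#' normalization running statistics used at inference time, the recorded
#' global intensity normalization scale (so decoded spectra are restored to
#' original units), and a content-hash identifier `codecId` that changes
#' whenever any weight changes.
#'
#' @slot architecture a `CodecArchitecture`
#' @slot params list of weight arrays (encoder and decoder)
#' @slot bnStats list of running mean/variance per normalization layer
#' @slot normScale numeric, the dataset-wide maximum the training image was
#'   divided by (1 if training data were not rescaled)
#' @slot padTo integer, input length after zero-padding to the stride stack
#' @slot codecId character content hash
#' @export
setClass("Codec",
  representation(architecture = "CodecArchitecture", params = "list",
                 bnStats = "list", normScale = "numeric",
                 padTo = "integer", codecId = "character"))

#' EmbeddingSet: per-pixel embeddings tied to a codec
#'
#' One fixed-length embedding per pixel, with the pixel coordinates and the
#' identifier of the codec that produced them (so decoding with a different
#' codec is refused).
#'
#' @slot coords integer matrix `[n x 2]`, 0-based `(x, y)`
#' @slot embeddings numeric matrix `[n x fE]`
#' @slot codecId character
#' @export
setClass("EmbeddingSet",
  representation(coords = "matrix", embeddings = "matrix",
                 codecId = "character"))

setValidity("EmbeddingSet", function(object) {
  msg <- character()
  if (nrow(object@coords) != nrow(object@embeddings))
    msg <- c(msg, "coords and embeddings disagree in row count")
  if (ncol(object@coords) != 2L)
    msg <- c(msg, "coords must have two columns")
  if (ncol(object@embeddings) < 1L)
    msg <- c(msg, "embedding length must be positive")
  if (length(object@codecId) != 1L)
    msg <- c(msg, "codecId must be a single string")
  if (length(msg)) msg else TRUE
})

#' MatchingTable: majority-vote map from predicted clusters to baseline classes
#'
#' For each predicted cluster id, records the baseline class that appears
#' most frequently among the cluster's pixels (ties to the smallest class
#' id), together with the full vote tallies. Clusters lying entirely on
#' unlabeled baseline pixels are unassigned (`NA`).
#'
#' @slot clusters integer vector of predicted cluster ids
#' @slot mapping integer vector parallel to `clusters`; `NA` = unassigned
#' @slot tallies integer matrix `[clusters x baseline classes]` of votes
#' @export
setClass("MatchingTable",
  representation(clusters = "integer", mapping = "integer",
                 tallies = "matrix"))

#' IterativeKMeansResult: output of silhouette-driven iterative k-means
#'
#' @slot labelMap the composite segmentation as a [LabelMap-class]
#' @slot nClusters integer, number of distinct non-empty composite clusters
#' @slot perComponentCounts integer vector, the cluster count chosen on each
#'   principal component that was used
#' @slot componentsUsed integer
#' @export
setClass("IterativeKMeansResult",
  representation(labelMap = "LabelMap", nClusters = "integer",
                 perComponentCounts = "integer", componentsUsed = "integer"))

#' SignatureSet: spectral signatures for synthetic MSI images
#'
#' Defines what each synthetic tissue class emits: class-specific Gaussian
#' peaks (disjoint across classes), shared background peaks common to all
#' classes, the peak width, and the noise model (per-pixel multiplicative
#' log-normal factor and an additive Gaussian floor).
#'
#' @slot nClasses integer
#' @slot classPeaks list of data.frames with columns `mz`, `intensity`
#' @slot backgroundPeaks data.frame with columns `mz`, `intensity`
#' @slot peakSigma numeric, Gaussian peak width in Da
#' @slot sigmaMult numeric, log-normal sdlog of the per-pixel factor
#' @slot sigmaAdd numeric, sd of additive noise (intensity units)
#' @export
setClass("SignatureSet",
  representation(nClasses = "integer", classPeaks = "list",
                 backgroundPeaks = "data.frame", peakSigma = "numeric",
                 sigmaMult = "numeric", sigmaAdd = "numeric"))

setValidity("SignatureSet", function(object) {
  msg <- character()
  if (length(object@classPeaks) != object@nClasses)
    msg <- c(msg, "one peak table per class required")
  ints <- c(unlist(lapply(object@classPeaks, function(p) p$intensity)),
            object@backgroundPeaks$intensity)
  if (length(ints) && any(ints <= 0))
    msg <- c(msg, "peak intensities must be positive")
  sig <- vapply(object@classPeaks, function(p) paste(sort(p$mz), collapse = ","), "")
  if (anyDuplicated(sig))
    msg <- c(msg, "class signatures must be pairwise distinct")
  if (length(msg)) msg else TRUE
})

#' AugmentedBatch: a contrastive training batch of spectra
#'
#' Holds `2N` spectra ordered so that rows `(2j - 1, 2j)` form the j-th
#' positive pair (original spectrum, noisy augmentation). `pairIndex[i]`
#' gives the 1-based row of row i's positive partner and is a fixed-point
#' free involution.
#'
#' @slot spectra numeric matrix `[2N x fS]`
#' @slot pairIndex integer vector of partner rows
#' @slot n integer, the batch sample size N
#' @export
setClass("AugmentedBatch",
  representation(spectra = "matrix", pairIndex = "integer", n = "integer"))

setValidity("AugmentedBatch", function(object) {
  msg <- character()
  m <- nrow(object@spectra)
  if (m %% 2L != 0L) msg <- c(msg, "row count must be even")
  if (length(object@pairIndex) != m)
    msg <- c(msg, "pairIndex length must equal the row count")
  else {
    p <- object@pairIndex
    if (any(p[p] != seq_len(m)) || any(p == seq_len(m)))
      msg <- c(msg, "pairIndex must be a fixed-point free involution")
  }
  if (2L * object@n != m) msg <- c(msg, "n inconsistent with row count")
  if (length(msg)) msg else TRUE
})
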