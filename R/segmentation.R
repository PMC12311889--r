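#' Top-peak feature extraction
#'
#' Selects the `nPeaks` m/z bins with the highest across-image mean
#' intensity (ties broken toward lower m/z) and returns the corresponding
#' intensity columns in descending-mean order. A common lightweight
#' alternative to encoding when clustering raw images is too expensive.
#'
#' @param image an [MSImage-class]
#' @param nPeaks number of bins to keep, default 128
#' @return numeric matrix `[n_pixels x nPeaks]`; the selected m/z values
#'   are in the column names
#' @export
topPeakFeatures <- function(image, nPeaks = 128L) {
  if (!isCount(nPeaks)) stopf("nPeaks must be a positive integer")
  X <- intensityMatrix(image)
  if (nPeaks > ncol(X)) stopf("nPeaks exceeds the number of bins")
  mz <- mzAxis(image)
  ord <- order(-colMeans(X), mz)[seq_len(nPeaks)]
  out <- X[, ord, drop = FALSE]
  colnames(out) <- sprintf("%.1f", mz[ord])
  out
}

## k-means++ seeding followed by Lloyd iterations; best of `nstart`
## restarts by total within-cluster sum of squares. Deterministic given the
## RNG state.
kmeansPP <- function(X, k, nstart = 10L, iterMax = 100L) {
  n <- nrow(X)
  if (k == 1L)
    return(list(cluster = rep(1L, n), totss = 0))
  best <- NULL
  for (r in seq_len(nstart)) {
    centers <- matrix(0, k, ncol(X))
    centers[1L, ] <- X[sample.int(n, 1L), ]
    d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
    for (j in 2L:k) {
      if (all(d2 <= 0)) stopf("fewer than k = %d distinct points", k)
      pick <- sample.int(n, 1L, prob = d2)
      centers[j, ] <- X[pick, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
    }
    fit <- suppressWarnings(
      stats::kmeans(X, centers = centers, iter.max = iterMax,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  list(cluster = best$cluster, totss = best$tot.withinss)
}

#' k-means segmentation of pixel features
#'
#' Clusters the pixel feature matrix (raw spectra, top-peak features or
#' embeddings) with k-means (k-means++ initialization, 10 restarts, fixed
#' seed) and maps the labels back onto the pixel grid.
#'
#' @param features numeric matrix `[n x d]`, or an [EmbeddingSet-class]
#' @param k number of clusters (`1 <= k <= n`)
#' @param coords integer matrix of 0-based pixel coordinates; taken from
#'   `features` when it is an `EmbeddingSet`
#' @param seed integer seed
#' @param width,height optional grid size
#' @return a [LabelMap-class] (provenance `"prediction"`) with labels
#'   `0 .. k-1`
#' @export
kmeansSegment <- function(features, k, coords = NULL, seed = 1L,
                          width = NULL, height = NULL) {
  if (is(features, "EmbeddingSet")) {
    coords <- features@coords
    features <- features@embeddings
  }
  features <- as.matrix(features)
  if (is.null(coords)) stopf("pixel coordinates required")
  if (!isCount(k)) stopf("k must be a positive integer")
  if (nrow(features) < k)
    stopf("cannot form %d clusters from %d pixels", k, nrow(features))
  cl <- withSeed(seed, kmeansPP(features, as.integer(k)))
  labelMap(coords, cl$cluster - 1L, width = width, height = height,
           provenance = "prediction")
}

#' Silhouette-guided cluster count for a single component
#'
#' Runs k-means on a one-dimensional projection for every candidate count
#' `c in 2..cMax` and scores each clustering by its mean silhouette width.
#' Returns the best `c` if its silhouette reaches `tau`, and 1 otherwise
#' (no usable structure on this component). Constant input returns 1.
#'
#' @param values numeric vector (scores on one principal component)
#' @param cMax largest candidate count, default 10
#' @param tau silhouette acceptance threshold, default 0.75 (structureless
#'   1-D projections score about 0.55-0.67 under k-means splits, genuinely
#'   separated clusters 0.9+, so the default sits between the regimes)
#' @param seed integer seed
#' @return the chosen cluster count `c` (integer >= 1)
#' @export
bestCountForComponent <- function(values, cMax = 10L, tau = 0.75, seed = 1L) {
  values <- as.numeric(values)
  n <- length(values)
  if (cMax < 2L) stopf("cMax must be at least 2")
  if (n <= cMax) stopf("need more points than cMax")
  if (diff(range(values)) < 1e-12 * max(1, abs(values[1L]))) return(1L)
  X <- matrix(values, ncol = 1L)
  dmat <- dist(X)
  cands <- 2L:cMax
  sil <- withSeed(seed, vapply(cands, function(cc) {
    cl <- kmeansPP(X, cc)$cluster
    if (length(unique(cl)) < 2L) return(-1)
    mean(cluster::silhouette(cl, dmat)[, "sil_width"])
  }, 0))
  bestIdx <- which.max(sil)
  if (sil[bestIdx] >= tau) cands[bestIdx] else 1L
}

#' Iterative k-means with silhouette-driven cluster counts
#'
#' Computes principal components of the (centered) feature matrix once,
#' then walks the components in order of explained variance: on each 1-D
#' projection it picks the cluster count `c` by silhouette
#' ([bestCountForComponent()]); `c = 1` stops the walk, otherwise the
#' running cluster count multiplies (`k <- k * c`) and the walk continues
#' until `k >= K`. The final segmentation is the Cartesian composite of
#' the per-component assignments, with empty composites dropped and labels
#' renumbered `0 .. k_found - 1`.
#'
#' @param features numeric matrix `[n x d]` or an [EmbeddingSet-class]
#' @param K target (maximal) number of clusters
#' @param tau silhouette threshold, default 0.75 (see
#'   [bestCountForComponent()])
#' @param cMaxPerComponent candidate count bound per component, default 10
#' @param coords,width,height grid information (see [kmeansSegment()])
#' @param seed integer seed
#' @return an [IterativeKMeansResult-class]
#' @export
iterativeKMeans <- function(features, K, tau = 0.75, cMaxPerComponent = 10L,
                            coords = NULL, seed = 1L,
                            width = NULL, height = NULL) {
  if (is(features, "EmbeddingSet")) {
    coords <- features@coords
    features <- features@embeddings
  }
  features <- as.matrix(features)
  if (is.null(coords)) stopf("pixel coordinates required")
  n <- nrow(features)
  if (!isCount(K)) stopf("K must be a positive integer")
  if (K > n) stopf("K = %d exceeds the number of pixels (%d)", K, n)
  counts <- integer()
  assignments <- list()
  if (K > 1L) {
    pc <- prcomp(features, center = TRUE, scale. = FALSE)
    scores <- pc$x
    k <- 1L; i <- 1L
    while (k < K && i <= ncol(scores)) {
      cc <- bestCountForComponent(scores[, i], cMax = cMaxPerComponent,
                                  tau = tau, seed = deriveSeed(seed, i))
      if (cc == 1L) break
      cl <- withSeed(deriveSeed(seed, i),
                     kmeansPP(matrix(scores[, i], ncol = 1L), cc)$cluster)
      counts <- c(counts, cc)
      assignments[[length(assignments) + 1L]] <- cl
      k <- k * cc
      i <- i + 1L
    }
  }
  if (!length(assignments)) {
    lab <- rep(0L, n)
  } else {
    ## composite label: lexicographic over per-component assignments,
    ## empty combinations dropped by the factor relevel
    key <- do.call(paste, c(lapply(assignments, formatC, width = 6, flag = "0"),
                            sep = "-"))
    lab <- as.integer(factor(key, levels = sort(unique(key)))) - 1L
  }
  lm <- labelMap(coords, lab, width = width, height = height,
                 provenance = "prediction")
  new("IterativeKMeansResult", labelMap = lm,
      nClusters = length(unique(lab)),
      perComponentCounts = as.integer(counts),
      componentsUsed = length(counts))
}

setMethod("show", "IterativeKMeansResult", function(object) {
  cat(sprintf("IterativeKMeansResult: %d clusters from %d components (counts: %s)\n",
              object@nClusters, object@componentsUsed,
              if (object@componentsUsed) paste(object@perComponentCounts,
                                               collapse = " x ") else "-"))
})

#' Convolutional (majority-vote) label smoothing
#'
#' Reassigns each labeled pixel to the most frequent label among itself and
#' its occupied neighbors within a `(2*radius+1)` square window. Unlabeled
#' (`-1`) pixels cast no votes and are never changed; ties resolve to the
#' smallest label id; all updates are computed synchronously from the input
#' map, repeated `iterations` times.
#'
#' @param map a [LabelMap-class]
#' @param radius window radius in pixels, default 1 (the 8-neighborhood)
#' @param iterations number of smoothing passes, default 1
#' @return the smoothed [LabelMap-class]
#' @export
convolutionalSmooth <- function(map, radius = 1L, iterations = 1L) {
  if (radius < 1L) stopf("radius must be at least 1")
  if (!nrow(map@coords)) return(map)
  M <- labelMatrix(map)
  h <- nrow(M); w <- ncol(M)
  classes <- sort(unique(map@labels[map@labels >= 0L]))
  if (length(classes) <= 1L) return(map)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  for (it in seq_len(iterations)) {
    votes <- array(0L, dim = c(h, w, length(classes)))
    for (ci in seq_along(classes)) {
      ind <- matrix(0L, h + 2L * radius, w + 2L * radius)
      ind[radius + seq_len(h), radius + seq_len(w)] <-
        (!is.na(M) & M == classes[ci]) * 1L
      acc <- matrix(0L, h, w)
      for (o in seq_len(nrow(offs)))
        acc <- acc + ind[radius + seq_len(h) + offs$dy[o],
                         radius + seq_len(w) + offs$dx[o]]
      votes[, , ci] <- acc
    }
    ## winner = smallest class id among the maxima; only labeled pixels move
    newM <- M
    tgt <- which(!is.na(M) & M >= 0L)
    vm <- matrix(votes, h * w, length(classes))[tgt, , drop = FALSE]
    win <- max.col(vm, ties.method = "first")  # columns sorted ascending
    newM[tgt] <- classes[win]
    M <- newM
  }
  lab <- M[cbind(map@coords[, 2L] + 1L, map@coords[, 1L] + 1L)]
  lab[map@labels == -1L] <- -1L
  labelMap(map@coords, lab, width = map@width, height = map@height,
           provenance = map@provenance)
}
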