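#' Generate a synthetic tissue label map
#'
#' Partitions a pixel grid into `nClasses` contiguous regions emulating
#' tissue morphology: vertical `stripes`, concentric `nested_rings`, or a
#' seeded `voronoi` tessellation. Every class occupies at least one pixel.
#'
#' @param width,height grid size in pixels
#' @param nClasses number of tissue classes (>= 1)
#' @param geometry one of `"stripes"`, `"nested_rings"`, `"voronoi"`
#' @param seed integer seed; the map is deterministic given the seed
#' @param border number of unlabeled (`-1`) border pixels, default 0
#' @return a [LabelMap-class] with provenance `"baseline"`
#' @export
generateLabelMap <- function(width, height, nClasses,
                             geometry = c("nested_rings", "stripes", "voronoi"),
                             seed = 1L, border = 0L) {
  geometry <- match.arg(geometry)
  if (!isCount(nClasses)) stopf("nClasses must be a positive integer")
  if (width * height < nClasses)
    stopf("grid too small for %d classes", nClasses)
  gx <- rep(seq_len(width) - 1L, times = height)
  gy <- rep(seq_len(height) - 1L, each = width)
  lab <- switch(geometry,
    stripes = {
      if (width < nClasses) stopf("width %d too small for %d stripes", width, nClasses)
      pmin(gx %/% max(1L, width %/% nClasses), nClasses - 1L)
    },
    nested_rings = {
      cx <- (width - 1) / 2; cy <- (height - 1) / 2
      r <- sqrt(((gx - cx) / max(cx, 0.5))^2 + ((gy - cy) / max(cy, 0.5))^2)
      ## equal-area bands of the normalized radius; clamp corners to outermost
      band <- findInterval(r, sqrt(seq_len(nClasses - 1L) / nClasses))
      pmin(band, nClasses - 1L)
    },
    voronoi = withSeed(seed, {
      sites <- cbind(runif(nClasses, 0, width - 1), runif(nClasses, 0, height - 1))
      d <- outer(gx, sites[, 1L], "-")^2 + outer(gy, sites[, 2L], "-")^2
      max.col(-d, ties.method = "first") - 1L
    }))
  if (border > 0L) {
    edge <- gx < border | gx >= width - border | gy < border | gy >= height - border
    lab[edge] <- -1L
  }
  present <- sort(unique(lab[lab >= 0L]))
  if (length(present) < nClasses)
    stopf("geometry produced only %d of %d classes; enlarge the grid",
          length(present), nClasses)
  labelMap(cbind(gx, gy), lab, width = width, height = height,
           provenance = "baseline")
}

#' Generate class-specific spectral signatures
#'
#' Draws disjoint peak positions for each class plus a set of shared
#' background peaks common to all classes, with positive mean intensities.
#' Class peaks never collide across classes, so class mean spectra are
#' separable by construction.
#'
#' @param nClasses number of classes
#' @param nBins number of m/z bins of the target axis
#' @param peaksPerClass class-specific peaks per class
#' @param seed integer seed
#' @param backgroundPeaks number of shared peaks, default 10
#' @param mzStart first bin center (Da), default 100.0
#' @param gridStep bin width (Da), default 0.1
#' @param peakSigma Gaussian peak width (Da), default 0.15
#' @param sigmaMult sdlog of the per-pixel log-normal intensity factor,
#'   default 0.2
#' @param sigmaAdd sd of additive Gaussian noise as a fraction of the
#'   largest peak intensity, default 0.01
#' @return a [SignatureSet-class]
#' @export
generateSignatures <- function(nClasses, nBins, peaksPerClass, seed = 1L,
                               backgroundPeaks = 10L, mzStart = 100.0,
                               gridStep = 0.1, peakSigma = 0.15,
                               sigmaMult = 0.2, sigmaAdd = 0.01) {
  if (!isCount(peaksPerClass)) stopf("peaksPerClass must be a positive integer")
  nPeaks <- nClasses * peaksPerClass + backgroundPeaks
  ## keep peaks a few sigma apart so signatures stay resolvable
  margin <- max(1L, ceiling(3 * peakSigma / gridStep))
  avail <- floor(nBins / (2L * margin))
  if (nPeaks > avail)
    stopf("m/z axis of %d bins too crowded for %d peaks", nBins, nPeaks)
  withSeed(seed, {
    slots <- sample(seq(margin, nBins - margin, by = 2L * margin), nPeaks)
    mzs <- mzStart + (slots - 1L) * gridStep
    heights <- runif(nPeaks, 40, 100)
    classPeaks <- vector("list", nClasses)
    for (k in seq_len(nClasses)) {
      idx <- ((k - 1L) * peaksPerClass + 1L):(k * peaksPerClass)
      classPeaks[[k]] <- data.frame(mz = mzs[idx], intensity = heights[idx])
    }
    bgIdx <- if (backgroundPeaks > 0L)
      (nClasses * peaksPerClass + 1L):nPeaks else integer()
    bg <- data.frame(mz = mzs[bgIdx], intensity = heights[bgIdx])
    new("SignatureSet", nClasses = as.integer(nClasses),
        classPeaks = classPeaks, backgroundPeaks = bg,
        peakSigma = peakSigma, sigmaMult = sigmaMult,
        sigmaAdd = sigmaAdd * max(heights))
  })
}

## Noise-free template spectrum of one class on a given axis.
signatureTemplate <- function(sig, class, mz) {
  peaks <- rbind(sig@classPeaks[[class + 1L]], sig@backgroundPeaks)
  s <- numeric(length(mz))
  for (i in seq_len(nrow(peaks)))
    s <- s + peaks$intensity[i] * exp(-(mz - peaks$mz[i])^2 / (2 * sig@peakSigma^2))
  s
}

#' Render a synthetic MS image from a label map and signatures
#'
#' Each pixel's spectrum is its class template (sum of Gaussian peak
#' profiles) scaled by one per-pixel log-normal factor, plus additive
#' Gaussian noise clipped at zero. Unlabeled (`-1`) pixels receive only the
#' background peaks.
#'
#' @param map a [LabelMap-class]
#' @param sig a [SignatureSet-class]
#' @param nBins number of m/z bins
#' @param mzStart first bin center (Da)
#' @param gridStep bin width (Da), default 0.1
#' @param seed integer seed; rendering is deterministic given
#'   `(map, sig, seed)`
#' @return an [MSImage-class]
#' @export
renderImage <- function(map, sig, nBins, mzStart = 100.0, gridStep = 0.1,
                        seed = 1L) {
  mz <- mzStart + (seq_len(nBins) - 1L) * gridStep
  lab <- map@labels
  n <- length(lab)
  templates <- lapply(0:(sig@nClasses - 1L), function(k) signatureTemplate(sig, k, mz))
  bgOnly <- {
    s <- numeric(nBins)
    for (i in seq_len(nrow(sig@backgroundPeaks)))
      s <- s + sig@backgroundPeaks$intensity[i] *
        exp(-(mz - sig@backgroundPeaks$mz[i])^2 / (2 * sig@peakSigma^2))
    s
  }
  withSeed(seed, {
    X <- matrix(0, n, nBins)
    fac <- exp(rnorm(n, 0, sig@sigmaMult))
    for (i in seq_len(n)) {
      tmpl <- if (lab[i] >= 0L) templates[[lab[i] + 1L]] else bgOnly
      X[i, ] <- tmpl * fac[i]
    }
    if (sig@sigmaAdd > 0)
      X <- X + matrix(rnorm(n * nBins, 0, sig@sigmaAdd), n, nBins)
    X[X < 0] <- 0
    msImage(X, mzAxis = mz, coords = map@coords,
            width = map@width, height = map@height)
  })
}

#' The package's default synthetic acceptance fixture
#'
#' A 32 x 32 pixel image with 4 nested-ring tissue classes on 3000 bins from
#' m/z 100.0 (step 0.1 Da), 5 class-specific peaks per class plus 10 shared
#' background peaks, peak width 0.15 Da, log-normal pixel factor (sdlog 0.2)
#' and a 1%-of-max additive noise floor.
#'
#' @param seed integer seed
#' @return list with elements `image` ([MSImage-class]), `labels`
#'   ([LabelMap-class]) and `signatures` ([SignatureSet-class])
#' @export
syntheticFixture <- function(seed = 1L) {
  map <- generateLabelMap(32L, 32L, 4L, geometry = "nested_rings",
                          seed = deriveSeed(seed, 1L))
  sig <- generateSignatures(4L, 3000L, 5L, seed = deriveSeed(seed, 2L),
                            backgroundPeaks = 10L, mzStart = 100.0,
                            gridStep = 0.1, peakSigma = 0.15)
  img <- renderImage(map, sig, nBins = 3000L, mzStart = 100.0,
                     gridStep = 0.1, seed = deriveSeed(seed, 3L))
  list(image = img, labels = map, signatures = sig)
}
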