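#' Bin raw spectra onto a uniform m/z grid
#'
#' Aggregates each raw (m/z, intensity) point into the bin whose center is
#' its m/z rounded to the grid ("round half away from zero" at bin
#' boundaries, so e.g. 500.05 goes to bin 500.1 on a 0.1-Da grid). Total
#' intensity is conserved exactly per pixel. All spectra must fall inside
#' the declared global m/z range, which defines a common axis.
#'
#' @param spectra list of raw spectra, each a list with numeric `mz`,
#'   `intensity` and integer `x`, `y` (0-based), as returned by
#'   [readImzML()]
#' @param mzRange numeric length-2 global range `(min, max)` in Da; defaults
#'   to the range observed across all spectra
#' @param gridStep bin width in Da, default 0.1
#' @param width,height optional grid dimensions
#' @return an [MSImage-class]
#' @export
binToGrid <- function(spectra, mzRange = NULL, gridStep = 0.1,
                      width = NULL, height = NULL) {
  if (gridStep <= 0) stopf("gridStep must be positive")
  if (!length(spectra)) stopf("no spectra to bin")
  if (is.null(mzRange)) {
    allmz <- unlist(lapply(spectra, `[[`, "mz"))
    if (!length(allmz)) stopf("all spectra are empty; declare mzRange explicitly")
    mzRange <- range(allmz)
  }
  loBin <- roundHalfAway(mzRange[1L] / gridStep)
  hiBin <- roundHalfAway(mzRange[2L] / gridStep)
  nBins <- as.integer(hiBin - loBin + 1L)
  mz <- (loBin + seq_len(nBins) - 1L) * gridStep
  n <- length(spectra)
  X <- matrix(0, n, nBins)
  coords <- matrix(0L, n, 2L)
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    coords[i, ] <- c(sp$x, sp$y)
    if (!length(sp$mz)) next  # empty spectrum -> all-zero row
    idx <- roundHalfAway(sp$mz / gridStep) - loBin + 1L
    if (any(idx < 1L | idx > nBins))
      stopf("spectrum %d has m/z outside the declared range [%g, %g]",
            i, mzRange[1L], mzRange[2L])
    acc <- vapply(split(sp$intensity, idx), sum, 0)
    X[i, as.integer(names(acc))] <- acc
  }
  msImage(X, mzAxis = mz, coords = coords, width = width, height = height)
}

## Discrete Gaussian kernel on the bin grid, truncated at +/- 4 sigma and
## renormalized to sum 1 so interior intensity is conserved.
gaussianKernel <- function(sigma, step) {
  half <- max(1L, ceiling(4 * sigma / step))
  off <- (-half):half
  k <- exp(-(off * step)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing of binned spectra
#'
#' Convolves every pixel's spectrum with a discrete Gaussian sampled on the
#' bin grid (truncated at 4 sigma, renormalized to unit sum). This is the
#' standard profile-mode smoothing step and is also the recommended
#' preparation for centroided data before encoding.
#'
#' @param image an [MSImage-class]
#' @param sigma kernel width in Da, default 0.1
#' @return the smoothed [MSImage-class]
#' @export
gaussianSmooth <- function(image, sigma = 0.1) {
  if (sigma <= 0) stopf("sigma must be positive")
  step <- S4Vectors::metadata(image)$mzStep
  k <- gaussianKernel(sigma, step)
  half <- (length(k) - 1L) %/% 2L
  X <- intensityMatrix(image)
  nb <- ncol(X)
  Y <- matrix(0, nrow(X), nb)
  ## convolution as a sum of shifted columns; zero padding at the edges
  for (j in seq_along(k)) {
    off <- j - half - 1L
    src <- seq_len(nb) + off
    ok <- src >= 1L & src <= nb
    Y[, which(ok)] <- Y[, which(ok)] + k[j] * X[, src[ok]]
  }
  replaceIntensities(image, Y)
}

#' Normalize intensities to \[0, 1\]
#'
#' With `method = "global_max"` divides every intensity by the dataset-wide
#' maximum and records that scale in the image metadata so decoding can
#' restore original units; `method = "none"` is the identity.
#'
#' @param image an [MSImage-class]
#' @param method `"global_max"` or `"none"`
#' @return the rescaled [MSImage-class]; retrieve the scale with
#'   [normalizationScale()]
#' @export
normalizeIntensities <- function(image, method = c("global_max", "none")) {
  method <- match.arg(method)
  if (nPixels(image) == 0L) stopf("cannot normalize an empty image")
  if (method == "none") return(image)
  X <- intensityMatrix(image)
  mx <- max(X)
  if (mx <= 0) stopf("all intensities are zero; global_max normalization undefined")
  out <- replaceIntensities(image, X / mx)
  S4Vectors::metadata(out)$normScale <- mx
  out
}

#' Multiplicative intensity augmentation
#'
#' Produces the "noisy copy" used as the positive partner in contrastive
#' training: every bin is multiplied by an independent uniform factor in
#' `[1 - delta, 1 + delta]`, perturbing intensities by up to `100 * delta`
#' percent while preserving peak locations. Zero bins stay zero.
#'
#' @param spectrum numeric vector
#' @param delta perturbation fraction in `[0, 1)`, default 0.1
#' @param seed integer seed; output is deterministic given the seed
#' @return the perturbed vector
#' @export
augmentSpectrum <- function(spectrum, delta = 0.1, seed = 1L) {
  if (delta < 0 || delta >= 1) stopf("delta must be in [0, 1)")
  if (delta == 0) return(spectrum)
  withSeed(seed, spectrum * runif(length(spectrum), 1 - delta, 1 + delta))
}

## Same noise model on a matrix without per-row seeding; used inside the
## training loop where the epoch RNG stream is already seeded.
augmentRows <- function(X, delta) {
  if (delta == 0) return(X)
  X * matrix(runif(length(X), 1 - delta, 1 + delta), nrow(X), ncol(X))
}

#' Build a contrastive training batch
#'
#' Selects `N` distinct pixels and interleaves each original spectrum with
#' one augmentation, yielding `2N` rows where rows `(2j - 1, 2j)` form the
#' j-th positive pair.
#'
#' @param image an [MSImage-class]
#' @param pixelIndices distinct 1-based pixel indices (length N)
#' @param delta augmentation fraction, default 0.1
#' @param seed integer seed
#' @return an [AugmentedBatch-class]
#' @export
makeAugmentedBatch <- function(image, pixelIndices, delta = 0.1, seed = 1L) {
  if (anyDuplicated(pixelIndices)) stopf("pixelIndices must be distinct")
  X <- intensityMatrix(image)
  if (any(pixelIndices < 1L | pixelIndices > nrow(X)))
    stopf("pixel index out of range")
  orig <- X[pixelIndices, , drop = FALSE]
  aug <- withSeed(seed, augmentRows(orig, delta))
  N <- length(pixelIndices)
  out <- matrix(0, 2L * N, ncol(X))
  out[seq(1L, 2L * N, by = 2L), ] <- orig
  out[seq(2L, 2L * N, by = 2L), ] <- aug
  pair <- as.integer(rbind(seq(2L, 2L * N, by = 2L), seq(1L, 2L * N, by = 2L)))
  new("AugmentedBatch", spectra = out, pairIndex = pair, n = as.integer(N))
}
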