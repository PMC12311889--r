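#' Construct an MSImage
#'
#' @param intensities numeric matrix `[n_pixels x F_s]` of nonnegative binned
#'   intensities, one row per pixel.
#' @param mzAxis numeric vector of ascending, uniformly spaced m/z bin
#'   centers (Da); length must equal `ncol(intensities)`.
#' @param coords integer matrix `[n_pixels x 2]` of 0-based `(x, y)` pixel
#'   positions. Not every grid cell needs to be occupied.
#' @param width,height grid dimensions; default to the smallest grid
#'   containing `coords`.
#' @param normScale optional recorded normalization scale (see
#'   [normalizeIntensities()]).
#' @return an [MSImage-class]
#' @examples
#' img <- msImage(matrix(1:4, 2, 2), mzAxis = c(100.0, 100.1),
#'                coords = cbind(c(0L, 1L), c(0L, 0L)))
#' nPixels(img)
#' @export
msImage <- function(intensities, mzAxis, coords, width = NULL, height = NULL,
                    normScale = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  dimnames(intensities) <- NULL
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("x", "y")
  if (nrow(coords) != nrow(intensities))
    stopf("coords (%d rows) and intensities (%d rows) disagree",
          nrow(coords), nrow(intensities))
  if (length(mzAxis) != ncol(intensities))
    stopf("mzAxis length (%d) must equal the number of intensity columns (%d)",
          length(mzAxis), ncol(intensities))
  if (is.null(width))
    width <- if (nrow(coords)) max(coords[, 1L]) + 1L else 0L
  if (is.null(height))
    height <- if (nrow(coords)) max(coords[, 2L]) + 1L else 0L
  checkMzAxis(mzAxis)
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stopf("intensities contain missing or non-finite values")
  if (nrow(intensities) && any(intensities < 0))
    stopf("intensities must be nonnegative")
  if (nrow(coords)) {
    if (any(coords[, 1L] < 0L) || any(coords[, 1L] >= width) ||
        any(coords[, 2L] < 0L) || any(coords[, 2L] >= height))
      stopf("pixel coordinates out of range for a %d x %d grid", width, height)
    if (anyDuplicated(paste(coords[, 1L], coords[, 2L])))
      stopf("duplicate pixel coordinates")
  }
  meta <- list(width = as.integer(width), height = as.integer(height),
               mzStep = if (length(mzAxis) > 1L) mzAxis[2L] - mzAxis[1L] else NA_real_)
  if (!is.null(normScale)) meta$normScale <- as.numeric(normScale)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensities = t(intensities)),
    rowData = S4Vectors::DataFrame(mz = as.numeric(mzAxis)),
    colData = S4Vectors::DataFrame(x = coords[, 1L], y = coords[, 2L]),
    metadata = meta)
  new("MSImage", se)
}

checkMzAxis <- function(mz) {
  if (length(mz) == 0L) stopf("empty m/z axis")
  if (length(mz) > 1L) {
    d <- diff(mz)
    if (any(d <= 0)) stopf("m/z axis must be strictly increasing")
    step <- d[1L]
    if (any(abs(d - step) > 1e-9 * abs(step)))
      stopf("m/z axis must be uniformly spaced (relative tolerance 1e-9)")
  }
  invisible(TRUE)
}

#' @describeIn msImage number of occupied pixels
#' @param x an `MSImage`
#' @export
nPixels <- function(x) ncol(SummarizedExperiment::assay(x, "intensities"))

#' @describeIn msImage m/z bin centers (Da)
#' @export
mzAxis <- function(x) SummarizedExperiment::rowData(x)$mz

#' @describeIn msImage 0-based `(x, y)` coordinates as an integer matrix
#' @export
pixelCoords <- function(x) {
  if (is(x, "MSImage")) {
    cd <- SummarizedExperiment::colData(x)
    cbind(x = cd$x, y = cd$y)
  } else if (is(x, "LabelMap")) {
    x@coords
  } else if (is(x, "EmbeddingSet")) {
    x@coords
  } else stopf("no pixel coordinates for class '%s'", class(x))
}

#' @describeIn msImage intensity matrix, pixels in rows, bins in columns
#' @export
intensityMatrix <- function(x) t(SummarizedExperiment::assay(x, "intensities"))

#' @describeIn msImage grid width in pixels
#' @export
imageWidth <- function(x) {
  if (is(x, "LabelMap")) return(as.integer(x@width))
  S4Vectors::metadata(x)$width
}

#' @describeIn msImage grid height in pixels
#' @export
imageHeight <- function(x) {
  if (is(x, "LabelMap")) return(as.integer(x@height))
  S4Vectors::metadata(x)$height
}

#' @describeIn msImage recorded intensity normalization scale, or `NULL`
#' @export
normalizationScale <- function(x) S4Vectors::metadata(x)$normScale

## Replace the assay, keeping geometry and metadata.
replaceIntensities <- function(x, newPixelsByBins) {
  SummarizedExperiment::assay(x, "intensities", withDimnames = FALSE) <- t(newPixelsByBins)
  x
}

setMethod("show", "MSImage", function(object) {
  mz <- mzAxis(object)
  cat(sprintf("MSImage: %d pixels on a %d x %d grid\n", nPixels(object),
              imageWidth(object), imageHeight(object)))
  cat(sprintf("  m/z axis: %d bins, %.1f .. %.1f Da (step %.4g)\n",
              length(mz), min(mz), max(mz), S4Vectors::metadata(object)$mzStep))
  ns <- normalizationScale(object)
  if (!is.null(ns))
    cat(sprintf("  intensities normalized (recorded scale %.6g)\n", ns))
})
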