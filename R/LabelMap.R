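#' Construct a LabelMap
#'
#' @param coords integer matrix `[n x 2]` of 0-based `(x, y)` positions
#' @param labels integer vector of class ids; `-1` marks unlabeled pixels
#' @param width,height grid dimensions (default: smallest containing grid)
#' @param provenance `"prediction"` or `"baseline"`
#' @return a [LabelMap-class]
#' @export
labelMap <- function(coords, labels, width = NULL, height = NULL,
                     provenance = c("prediction", "baseline")) {
  provenance <- match.arg(provenance)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("x", "y")
  labels <- as.integer(labels)
  if (is.null(width))
    width <- if (nrow(coords)) max(coords[, 1L]) + 1L else 0L
  if (is.null(height))
    height <- if (nrow(coords)) max(coords[, 2L]) + 1L else 0L
  new("LabelMap", width = as.integer(width), height = as.integer(height),
      coords = coords, labels = labels, provenance = provenance)
}

#' @describeIn labelMap per-pixel labels (parallel to `pixelCoords()`)
#' @param x a `LabelMap`
#' @export
pixelLabels <- function(x) x@labels

#' @describeIn labelMap the map as a `height x width` matrix, `NA` where the
#'   grid is unoccupied
#' @export
labelMatrix <- function(x) {
  m <- matrix(NA_integer_, nrow = x@height, ncol = x@width)
  if (nrow(x@coords))
    m[cbind(x@coords[, 2L] + 1L, x@coords[, 1L] + 1L)] <- x@labels
  m
}

setMethod("show", "LabelMap", function(object) {
  lab <- object@labels
  k <- length(unique(lab[lab >= 0L]))
  cat(sprintf("LabelMap (%s): %d pixels on %d x %d grid, %d classes, %d unlabeled\n",
              object@provenance, length(lab), object@width, object@height,
              k, sum(lab == -1L)))
})

## Shared guard: two maps live on the same grid with the same occupied pixels.
checkSameGrid <- function(a, b) {
  if (a@width != b@width || a@height != b@height)
    stopf("label maps disagree in grid size (%dx%d vs %dx%d)",
          a@width, a@height, b@width, b@height)
  ka <- paste(a@coords[, 1L], a@coords[, 2L])
  kb <- paste(b@coords[, 1L], b@coords[, 2L])
  if (length(ka) != length(kb) || !all(sort(ka) == sort(kb)))
    stopf("label maps occupy different pixel sets")
  invisible(TRUE)
}

#' Write / read a LabelMap as CSV
#'
#' The CSV has columns `x`, `y`, `label` (0-based coordinates, `-1` =
#' unlabeled).
#' @param map a [LabelMap-class]
#' @param path file path
#' @param provenance provenance recorded on read
#' @export
writeLabelMapCSV <- function(map, path) {
  df <- data.frame(x = map@coords[, 1L], y = map@coords[, 2L],
                   label = map@labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLabelMapCSV
#' @export
readLabelMapCSV <- function(path, provenance = "baseline") {
  df <- utils::read.csv(path)
  if (!all(c("x", "y", "label") %in% names(df)))
    stopf("label map CSV must have columns x, y, label")
  labelMap(cbind(df$x, df$y), df$label, provenance = provenance)
}

#' Write a LabelMap as a paletted PNG
#'
#' Classes are drawn in a qualitative palette; unlabeled (`-1`) and
#' unoccupied pixels are transparent.
#' @param map a [LabelMap-class]
#' @param path output file
#' @export
writeLabelMapPNG <- function(map, path) {
  m <- labelMatrix(map)
  classes <- sort(unique(map@labels[map@labels >= 0L]))
  pal <- grDevices::hcl.colors(max(length(classes), 2L), "Dark 3")
  img <- array(0, dim = c(nrow(m), ncol(m), 4L))
  for (i in seq_along(classes)) {
    rgb <- grDevices::col2rgb(pal[i]) / 255
    sel <- which(!is.na(m) & m == classes[i], arr.ind = TRUE)
    for (ch in 1:3) img[cbind(sel, ch)] <- rgb[ch]
    img[cbind(sel, 4L)] <- 1
  }
  png::writePNG(img, path)
  invisible(path)
}
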