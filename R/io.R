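## -- imzML ----------------------------------------------------------------

imzmlTypeBytes <- c("MS:1000521" = 4L, "MS:1000523" = 8L)  # 32/64-bit float

#' Read an imzML 1.1 mass spectrometry image
#'
#' Reads the XML index and the companion `.ibd` binary, supporting
#' continuous and processed binary modes with 32- or 64-bit float arrays
#' (uncompressed). Coordinates are converted from imzML's 1-based
#' convention to the package's 0-based convention. A centroid-mode flag
#' produces a warning (processing continues; Gaussian-smooth such data
#' before encoding).
#'
#' @param path path to the `.imzML` file; the `.ibd` file is expected next
#'   to it
#' @return list of raw spectra, each a list with numeric `mz`, `intensity`
#'   and integer `x`, `y`; pass to [binToGrid()]
#' @export
readImzML <- function(path) {
  doc <- xml2::read_xml(path)   # malformed XML raises here
  xml2::xml_ns_strip(doc)
  ibd <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd)) stopf("companion binary '%s' not found", ibd)
  fileCv <- xml2::xml_find_all(doc, ".//fileDescription/fileContent/cvParam")
  acc <- xml2::xml_attr(fileCv, "accession")
  if ("MS:1000127" %in% acc)
    warnf("imzML file is flagged centroid mode; consider Gaussian smoothing before encoding")
  ## referenceable param groups: accession set per group id
  groups <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  groupAcc <- lapply(groups, function(g)
    xml2::xml_attr(xml2::xml_find_all(g, "./cvParam"), "accession"))
  names(groupAcc) <- xml2::xml_attr(groups, "id")
  spectra <- xml2::xml_find_all(doc, ".//run//spectrum")
  if (!length(spectra)) stopf("no spectra found in '%s'", path)
  con <- file(ibd, "rb")
  on.exit(close(con))
  fsize <- file.size(ibd)
  lapply(spectra, function(sp) {
    posCv <- xml2::xml_find_all(sp, ".//scan/cvParam")
    pAcc <- xml2::xml_attr(posCv, "accession")
    pVal <- xml2::xml_attr(posCv, "value")
    x <- as.integer(pVal[pAcc == "IMS:1000050"][1L])
    y <- as.integer(pVal[pAcc == "IMS:1000051"][1L])
    if (is.na(x) || is.na(y)) stopf("spectrum without pixel position")
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    mz <- NULL; intensity <- NULL
    for (arr in arrays) {
      cv <- xml2::xml_find_all(arr, "./cvParam")
      aAcc <- xml2::xml_attr(cv, "accession")
      aVal <- xml2::xml_attr(cv, "value")
      ref <- xml2::xml_attr(xml2::xml_find_first(arr, "./referenceableParamGroupRef"), "ref")
      if (!is.na(ref) && !is.null(groupAcc[[ref]]))
        aAcc <- c(aAcc, groupAcc[[ref]])
      offset <- as.numeric(aVal[aAcc == "IMS:1000102"][1L])
      nvals <- as.numeric(aVal[aAcc == "IMS:1000103"][1L])
      bytes <- imzmlTypeBytes[intersect(names(imzmlTypeBytes), aAcc)][1L]
      if (is.na(offset) || is.na(nvals) || is.na(bytes))
        stopf("binary data array lacks offset/length/type metadata")
      if (offset + nvals * bytes > fsize)
        stopf("truncated .ibd: array at offset %.0f exceeds file size", offset)
      seek(con, where = offset, origin = "start")
      v <- readBin(con, "numeric", n = nvals, size = bytes, endian = "little")
      if (length(v) != nvals) stopf("truncated .ibd while reading array")
      if ("MS:1000514" %in% aAcc) mz <- v
      if ("MS:1000515" %in% aAcc) intensity <- v
    }
    if (is.null(mz) || is.null(intensity))
      stopf("spectrum at (%d, %d) lacks an m/z or intensity array", x, y)
    list(mz = mz, intensity = intensity, x = x - 1L, y = y - 1L)
  })
}

## -- columnar pixel table (Parquet) ---------------------------------------

#' Read / write MSImage pixel tables (Apache Parquet)
#'
#' The pixel table is one row per pixel: integer columns `x`, `y`, then one
#' single-precision column per m/z bin, the column names being the bin
#' centers printed with one decimal (e.g. `"422.9"`). Rows are normalized
#' to raster order (y-major, then x) on read. The write/read round trip is
#' exact at single precision.
#'
#' @param path `.parquet` file path
#' @return [readPixelTable()]: an [MSImage-class]
#' @export
readPixelTable <- function(path) {
  df <- as.data.frame(arrow::read_parquet(path))
  if (!all(c("x", "y") %in% names(df)))
    stopf("pixel table must have x and y columns")
  binCols <- setdiff(names(df), c("x", "y"))
  if (!length(binCols)) stopf("pixel table has no intensity columns")
  mz <- suppressWarnings(as.numeric(binCols))
  if (anyNA(mz)) stopf("non-numeric bin column name(s): %s",
                       paste(binCols[is.na(mz)], collapse = ", "))
  if (length(mz) > 1L) {
    d <- diff(mz)
    if (any(d <= 0) || any(abs(d - d[1L]) > 1e-9 * abs(d[1L])))
      stopf("bin columns are not uniformly spaced")
  }
  ord <- order(df$y, df$x)
  df <- df[ord, , drop = FALSE]
  X <- as.matrix(df[, binCols, drop = FALSE])
  neg <- which(X < 0, arr.ind = TRUE)
  if (nrow(neg))
    stopf("negative intensity at pixel (%d, %d), bin %s",
          df$x[neg[1L, 1L]], df$y[neg[1L, 1L]], binCols[neg[1L, 2L]])
  msImage(X, mzAxis = mz, coords = cbind(df$x, df$y))
}

#' @rdname readPixelTable
#' @param image an [MSImage-class]
#' @export
writePixelTable <- function(image, path) {
  X <- intensityMatrix(image)
  co <- pixelCoords(image)
  ord <- order(co[, 2L], co[, 1L])
  mz <- mzAxis(image)
  binNames <- sprintf("%.1f", mz)
  df <- data.frame(x = co[ord, 1L], y = co[ord, 2L], check.names = FALSE)
  Xo <- X[ord, , drop = FALSE]
  for (j in seq_along(binNames)) df[[binNames[j]]] <- Xo[, j]
  fields <- c(list(arrow::field("x", arrow::int32()),
                   arrow::field("y", arrow::int32())),
              lapply(binNames, arrow::field, type = arrow::float32()))
  tab <- arrow::arrow_table(df, schema = arrow::schema(fields))
  arrow::write_parquet(tab, path)
  invisible(path)
}

## -- embedding container --------------------------------------------------

#' Read / write embeddings (single-file binary container)
#'
#' The container stores the pixel coordinates as int32, the embedding
#' matrix as float32 (4 bytes per value, which is what the storage
#' arithmetic of [estimateEncodedSize()] assumes), and the producing
#' codec's id; write -> read is bit-exact for the embedding matrix.
#'
#' @param store an [EmbeddingSet-class]
#' @param path file path (conventionally `.emb`)
#' @export
writeEmbeddings <- function(store, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("MSIEMB01", con, nchars = 8L, eos = NULL)
  n <- nrow(store@embeddings); fe <- ncol(store@embeddings)
  writeBin(c(n, fe), con, size = 4L, endian = "little")
  id <- store@codecId
  writeBin(nchar(id, "bytes"), con, size = 4L, endian = "little")
  if (nchar(id)) writeChar(id, con, nchars = nchar(id, "bytes"), eos = NULL)
  writeBin(as.integer(t(store@coords)), con, size = 4L, endian = "little")
  writeBin(as.numeric(t(store@embeddings)), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname writeEmbeddings
#' @return [readEmbeddings()]: an [EmbeddingSet-class]
#' @export
readEmbeddings <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- tryCatch(readChar(con, 8L, useBytes = TRUE), error = function(e) "")
  if (!identical(magic, "MSIEMB01"))
    stopf("'%s' is not an embedding container", path)
  dims <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  n <- dims[1L]; fe <- dims[2L]
  idLen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(idLen) || idLen <= 0L)
    stopf("embedding container lacks a codec_id")
  id <- readChar(con, idLen, useBytes = TRUE)
  co <- readBin(con, "integer", 2L * n, size = 4L, endian = "little")
  E <- readBin(con, "numeric", n * fe, size = 4L, endian = "little")
  if (length(E) != n * fe) stopf("truncated embedding container")
  new("EmbeddingSet",
      coords = matrix(co, n, 2L, byrow = TRUE,
                      dimnames = list(NULL, c("x", "y"))),
      embeddings = matrix(E, n, fe, byrow = TRUE), codecId = id)
}

## -- storage accounting ---------------------------------------------------

#' Encoded-image storage size
#'
#' The encoded image stores `nPixels * fE` values at `bytesPerValue` bytes
#' (float32 by default). Megabytes are binary (`bytes / 1024^2`), reported
#' to one decimal, matching the convention used for MSI storage figures.
#'
#' @param nPixels number of pixels
#' @param fE embedding length
#' @param bytesPerValue bytes per stored value, default 4 (float32)
#' @return list with `bytes`, `megabytes` (exact) and `megabytesRounded`
#'   (one decimal)
#' @examples
#' estimateEncodedSize(34840, 64)   # 8.5 MB
#' @export
estimateEncodedSize <- function(nPixels, fE, bytesPerValue = 4L) {
  if (!isCount(nPixels) || !isCount(fE) || !isCount(bytesPerValue))
    stopf("all arguments must be positive integers")
  bytes <- as.numeric(nPixels) * fE * bytesPerValue
  mb <- bytes / 1024^2
  list(bytes = bytes, megabytes = mb, megabytesRounded = round(mb, 1L))
}

#' Relative storage reduction of an encoding
#'
#' `100 * (1 - encodedBytes / rawBytes)`, the "percent reduction in memory
#' usage" figure.
#'
#' @param rawBytes original storage size in bytes
#' @param encodedBytes encoded storage size in bytes
#' @return percentage
#' @export
storageReduction <- function(rawBytes, encodedBytes) {
  if (rawBytes <= 0 || encodedBytes < 0) stopf("sizes must be positive")
  100 * (1 - encodedBytes / rawBytes)
}
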