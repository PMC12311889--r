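## Shared fixtures and independent oracles, all built in code at test time.

## Small synthetic MS image (fast enough for per-test training).
smallFixture <- function(seed = 1L, width = 12L, height = 12L, nClasses = 3L,
                         nBins = 300L) {
  map <- generateLabelMap(width, height, nClasses, geometry = "stripes",
                          seed = seed)
  sig <- generateSignatures(nClasses, nBins, peaksPerClass = 3L, seed = seed,
                            backgroundPeaks = 4L)
  img <- renderImage(map, sig, nBins = nBins, seed = seed)
  list(image = img, labels = map, signatures = sig)
}

## Tiny architecture for gradient checks and shape tests.
tinyArch <- function(fS = 30L, fE = 4L) {
  codecArchitecture(fS, fE, channels = c(3L, 5L), kernelSize = 3L,
                    stride = 2L)
}

## Literal double-loop transcription of the contrastive objective: for every
## ordered positive pair (i, j), l_ij = -log(exp(sim_ij/g) / sum_{k != i}
## exp(sim_ik/g)), summed and scaled by alpha. Kept deliberately naive and
## independent of the vectorized implementation.
contrastiveOracle <- function(W, pairIndex, alpha, gamma) {
  m <- nrow(W)
  csim <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  total <- 0
  for (i in seq_len(m)) {
    j <- pairIndex[i]
    denom <- 0
    for (k in seq_len(m)) {
      if (k == i) next
      denom <- denom + exp(csim(W[i, ], W[k, ]) / gamma)
    }
    total <- total - log(exp(csim(W[i, ], W[j, ]) / gamma) / denom)
  }
  alpha * total
}

## Minimal imzML 1.1 writer (continuous or processed binary mode) used to
## exercise the reader; writes the .imzML index plus the .ibd binary.
writeImzMLFixture <- function(path, spectra, mode = c("continuous", "processed"),
                              spectrumType = "profile") {
  mode <- match.arg(mode)
  ibd <- sub("\\.imzML$", ".ibd", path)
  con <- file(ibd, "wb")
  writeBin(as.raw(1:16), con)            # UUID placeholder
  offset <- 16
  offs <- list()
  if (mode == "continuous") {
    mz <- spectra[[1]]$mz
    writeBin(as.numeric(mz), con, size = 8, endian = "little")
    mzOff <- offset; offset <- offset + 8 * length(mz)
  }
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    if (mode == "processed") {
      writeBin(as.numeric(sp$mz), con, size = 8, endian = "little")
      thisMzOff <- offset; offset <- offset + 8 * length(sp$mz)
    } else thisMzOff <- mzOff
    writeBin(as.numeric(sp$intensity), con, size = 8, endian = "little")
    offs[[i]] <- list(mz = thisMzOff, int = offset,
                      nmz = length(sp$mz), nint = length(sp$intensity))
    offset <- offset + 8 * length(sp$intensity)
  }
  close(con)
  modeAcc <- if (mode == "continuous") "IMS:1000030" else "IMS:1000031"
  typeAcc <- if (spectrumType == "profile") "MS:1000128" else "MS:1000127"
  spectrumXML <- vapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]; o <- offs[[i]]
    sprintf(paste0(
      '<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray><referenceableParamGroupRef ref="mzArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<binary/></binaryDataArray>',
      '<binaryDataArray><referenceableParamGroupRef ref="intensityArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, i - 1L, o$nint, sp$x, sp$y, o$mz, o$nmz, o$int, o$nint)
  }, "")
  xml <- sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="%s" name="%s"/>',
    '<cvParam cvRef="MS" accession="%s" name="%s spectrum"/>',
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<run id="run0"><spectrumList count="%d">%s</spectrumList></run>',
    '</mzML>'),
    modeAcc, mode, typeAcc, spectrumType,
    length(spectra), paste(spectrumXML, collapse = ""))
  writeLines(xml, path)
  invisible(path)
}

## Finite-difference gradient of a scalar function at X (matrix).
numericGradient <- function(f, X, eps = 1e-6) {
  G <- X * 0
  for (i in seq_along(X)) {
    Xp <- X; Xp[i] <- X[i] + eps
    Xm <- X; Xm[i] <- X[i] - eps
    G[i] <- (f(Xp) - f(Xm)) / (2 * eps)
  }
  G
}
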