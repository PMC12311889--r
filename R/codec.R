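#' Define a spectral encoder-decoder architecture
#'
#' The encoder applies `length(channels)` one-dimensional convolution
#' blocks (each: convolution, optional feature normalization, ReLU) with a
#' shared kernel size and stride, then a linear layer to the embedding of
#' length `fE`. The decoder mirrors it: a linear layer plus ReLU back to
#' the flattened convolutional shape, then transposed convolutions in
#' reverse order, reconstructing exactly `fS` values. Inputs are
#' zero-padded to the nearest length compatible with the stride stack; the
#' padding is recorded and stripped on decode.
#'
#' @param fS input spectrum length (number of m/z bins)
#' @param fE embedding length (e.g. 64 for a single image, 128 for large
#'   cohorts)
#' @param channels output channels of each encoder block, default
#'   `c(8, 16, 32, 64)`
#' @param kernelSize convolution kernel width, default 7
#' @param stride convolution stride (temporal downsampling per block),
#'   default 4
#' @param useNormalization apply feature (batch) normalization in each
#'   block, default `TRUE`
#' @return a [CodecArchitecture-class]
#' @export
codecArchitecture <- function(fS, fE, channels = c(8L, 16L, 32L, 64L),
                              kernelSize = 7L, stride = 4L,
                              useNormalization = TRUE) {
  if (!isCount(fS) || !isCount(fE)) stopf("fS and fE must be positive integers")
  if (kernelSize < stride) stopf("kernelSize must be >= stride")
  arch <- new("CodecArchitecture", fS = as.integer(fS), fE = as.integer(fE),
              channels = as.integer(channels),
              kernelSize = as.integer(kernelSize), stride = as.integer(stride),
              useNormalization = isTRUE(useNormalization))
  dims <- archDims(arch)   # errors at build time if shapes are impossible
  if (dims$flat < arch@fE)
    stopf("embedding length %d exceeds the flattened convolutional size %d; use fewer/narrower blocks or a smaller fE",
          arch@fE, dims$flat)
  arch
}

## Geometry of the stride stack: padded input length, per-block lengths,
## flattened size.
archDims <- function(arch) {
  B <- length(arch@channels)
  down <- as.double(arch@stride)^B
  padTo <- as.integer(ceiling(arch@fS / down) * down)
  lens <- padTo / arch@stride^(0:B)
  if (any(lens < 1)) stopf("stride stack collapses the input to nothing")
  list(B = B, padTo = padTo, lens = as.integer(lens),
       flat = as.integer(arch@channels[B] * lens[B + 1L]))
}

#' Build an untrained codec
#'
#' Initializes all weights deterministically from `seed` (Kaiming-style
#' uniform). Shape problems (e.g. an embedding longer than the flattened
#' convolutional output) are raised here, at build time.
#'
#' @param arch a [codecArchitecture()]
#' @param seed integer seed
#' @return an untrained [Codec-class] with `normScale = 1`
#' @export
buildCodec <- function(arch, seed = 1L) {
  dims <- archDims(arch)
  B <- dims$B; k <- arch@kernelSize
  ch <- c(1L, arch@channels)
  withSeed(seed, {
    params <- list()
    stats <- list()
    for (b in seq_len(B)) {
      fanIn <- ch[b] * k
      params[[sprintf("enc.conv%d.W", b)]] <- initTensor(c(ch[b], k, ch[b + 1L]), fanIn)
      params[[sprintf("enc.conv%d.b", b)]] <- as.numeric(initTensor(ch[b + 1L], fanIn))
      if (arch@useNormalization) {
        params[[sprintf("enc.bn%d.gamma", b)]] <- rep(1, ch[b + 1L])
        params[[sprintf("enc.bn%d.beta", b)]] <- rep(0, ch[b + 1L])
        stats[[sprintf("enc.bn%d", b)]] <- list(mean = rep(0, ch[b + 1L]),
                                                var = rep(1, ch[b + 1L]))
      }
    }
    params[["enc.lin.W"]] <- initTensor(c(dims$flat, arch@fE), dims$flat)
    params[["enc.lin.b"]] <- as.numeric(initTensor(arch@fE, dims$flat))
    params[["dec.lin.W"]] <- initTensor(c(arch@fE, dims$flat), arch@fE)
    params[["dec.lin.b"]] <- as.numeric(initTensor(dims$flat, arch@fE))
    for (b in rev(seq_len(B))) {
      fanIn <- ch[b + 1L] * k
      ## tconv b maps ch[b+1] channels back to ch[b]: W is [Cout, k, Cin]
      params[[sprintf("dec.tconv%d.W", b)]] <- initTensor(c(ch[b], k, ch[b + 1L]), fanIn)
      params[[sprintf("dec.tconv%d.b", b)]] <- as.numeric(initTensor(ch[b], fanIn))
      if (arch@useNormalization && b > 1L) {
        params[[sprintf("dec.bn%d.gamma", b)]] <- rep(1, ch[b])
        params[[sprintf("dec.bn%d.beta", b)]] <- rep(0, ch[b])
        stats[[sprintf("dec.bn%d", b)]] <- list(mean = rep(0, ch[b]),
                                                var = rep(1, ch[b]))
      }
    }
    codec <- new("Codec", architecture = arch, params = params,
                 bnStats = stats, normScale = 1,
                 padTo = dims$padTo, codecId = "")
    codec@codecId <- computeCodecId(codec)
    codec
  })
}

## Full forward pass. X: [n x fS] (already divided by normScale).
## Returns embeddings, reconstruction (still normalized units, fS columns),
## updated bn stats and caches for the backward pass.
codecForward <- function(codec, X, training = FALSE) {
  arch <- codec@architecture
  dims <- archDims(arch)
  B <- dims$B; s <- arch@stride
  p <- codec@params; st <- codec@bnStats
  n <- nrow(X)
  H <- array(0, dim = c(n, dims$padTo, 1L))
  H[, seq_len(arch@fS), 1L] <- X
  caches <- list(enc = vector("list", B), dec = vector("list", B))
  for (b in seq_len(B)) {
    cv <- convForward(H, p[[sprintf("enc.conv%d.W", b)]],
                      p[[sprintf("enc.conv%d.b", b)]], s)
    cache <- list(conv = cv$cache)
    H <- cv$out
    if (arch@useNormalization) {
      nm <- sprintf("enc.bn%d", b)
      bn <- bnForward(H, p[[paste0(nm, ".gamma")]], p[[paste0(nm, ".beta")]],
                      st[[nm]], training)
      st[[nm]] <- bn$stats
      cache$bn <- bn$cache
      H <- bn$out
    }
    rl <- reluForward(H)
    cache$relu <- rl$cache
    H <- rl$out
    caches$enc[[b]] <- cache
  }
  dim(H) <- c(n, dims$flat)
  encLin <- linForward(H, p[["enc.lin.W"]], p[["enc.lin.b"]])
  emb <- encLin$out
  decLin <- linForward(emb, p[["dec.lin.W"]], p[["dec.lin.b"]])
  decRelu <- reluForward(decLin$out)
  G <- decRelu$out
  dim(G) <- c(n, dims$lens[B + 1L], arch@channels[B])
  for (b in rev(seq_len(B))) {
    tc <- tconvForward(G, p[[sprintf("dec.tconv%d.W", b)]],
                       p[[sprintf("dec.tconv%d.b", b)]], s)
    cache <- list(tconv = tc$cache)
    G <- tc$out
    if (b > 1L) {
      if (arch@useNormalization) {
        nm <- sprintf("dec.bn%d", b)
        bn <- bnForward(G, p[[paste0(nm, ".gamma")]], p[[paste0(nm, ".beta")]],
                        st[[nm]], training)
        st[[nm]] <- bn$stats
        cache$bn <- bn$cache
        G <- bn$out
      }
      rl <- reluForward(G)
      cache$relu <- rl$cache
      G <- rl$out
    }
    caches$dec[[b]] <- cache
  }
  recon <- matrix(G, n, dims$padTo)[, seq_len(arch@fS), drop = FALSE]
  list(emb = emb, recon = recon, bnStats = st, caches = caches,
       encLin = encLin$cache, decLin = decLin$cache, decRelu = decRelu$cache)
}

## Backward pass: gradients of (dEmb on embeddings) + (dRecon on the
## reconstruction) wrt every parameter. Returns a flat named list matching
## codec@params.
codecBackward <- function(codec, fw, dEmb, dRecon) {
  arch <- codec@architecture
  dims <- archDims(arch)
  B <- dims$B
  p <- codec@params
  n <- nrow(dRecon)
  grads <- list()
  dG <- array(0, dim = c(n, dims$padTo, 1L))
  dG[, seq_len(arch@fS), 1L] <- dRecon
  for (b in seq_len(B)) {
    cache <- fw$caches$dec[[b]]
    if (b > 1L) {
      dG <- reluBackward(dG, cache$relu)
      if (arch@useNormalization) {
        nm <- sprintf("dec.bn%d", b)
        bb <- bnBackward(dG, p[[paste0(nm, ".gamma")]], cache$bn)
        grads[[paste0(nm, ".gamma")]] <- bb$dgamma
        grads[[paste0(nm, ".beta")]] <- bb$dbeta
        dG <- bb$dX
      }
    }
    tb <- tconvBackward(dG, p[[sprintf("dec.tconv%d.W", b)]], cache$tconv)
    grads[[sprintf("dec.tconv%d.W", b)]] <- tb$dW
    grads[[sprintf("dec.tconv%d.b", b)]] <- tb$db
    dG <- tb$dX
  }
  dim(dG) <- c(n, dims$flat)
  dG <- reluBackward(dG, fw$decRelu)
  lb <- linBackward(dG, p[["dec.lin.W"]], fw$decLin)
  grads[["dec.lin.W"]] <- lb$dW
  grads[["dec.lin.b"]] <- lb$db
  dEmbTotal <- lb$dX + dEmb
  le <- linBackward(dEmbTotal, p[["enc.lin.W"]], fw$encLin)
  grads[["enc.lin.W"]] <- le$dW
  grads[["enc.lin.b"]] <- le$db
  dH <- le$dX
  dim(dH) <- c(n, dims$lens[B + 1L], arch@channels[B])
  for (b in rev(seq_len(B))) {
    cache <- fw$caches$enc[[b]]
    dH <- reluBackward(dH, cache$relu)
    if (arch@useNormalization) {
      nm <- sprintf("enc.bn%d", b)
      bb <- bnBackward(dH, p[[paste0(nm, ".gamma")]], cache$bn)
      grads[[paste0(nm, ".gamma")]] <- bb$dgamma
      grads[[paste0(nm, ".beta")]] <- bb$dbeta
      dH <- bb$dX
    }
    cb <- convBackward(dH, p[[sprintf("enc.conv%d.W", b)]], cache$conv)
    grads[[sprintf("enc.conv%d.W", b)]] <- cb$dW
    grads[[sprintf("enc.conv%d.b", b)]] <- cb$db
    dH <- cb$dX
  }
  grads
}

#' Encode spectra into embeddings
#'
#' Runs the encoder in inference mode (running normalization statistics,
#' no stochastic components): repeated calls are identical and rows are
#' encoded independently. Intensities are divided by the codec's recorded
#' normalization scale internally, so pass spectra in original units.
#'
#' @param codec a trained [Codec-class]
#' @param x an [MSImage-class], or a numeric matrix `[n x fS]` of spectra
#' @return an [EmbeddingSet-class] when `x` is an image, otherwise a
#'   numeric matrix `[n x fE]`
#' @export
encodeSpectra <- function(codec, x) {
  isImage <- is(x, "MSImage")
  X <- if (isImage) intensityMatrix(x) else as.matrix(x)
  arch <- codec@architecture
  if (ncol(X) != arch@fS)
    stopf("spectra have %d bins but the codec expects F_s = %d", ncol(X), arch@fS)
  if (nrow(X) == 0L) {
    emb <- matrix(0, 0L, arch@fE)
  } else {
    emb <- codecForward(codec, X / codec@normScale, training = FALSE)$emb
  }
  if (isImage)
    new("EmbeddingSet", coords = pixelCoords(x), embeddings = emb,
        codecId = codec@codecId)
  else emb
}

#' Decode embeddings back into spectra
#'
#' Mirror of [encodeSpectra()]: deterministic, row-independent, and
#' un-scaled back to original intensity units using the codec's recorded
#' normalization scale. Decoding an [EmbeddingSet-class] produced by a
#' different codec is refused.
#'
#' @param codec a trained [Codec-class]
#' @param x an [EmbeddingSet-class] or a numeric matrix `[n x fE]`
#' @return numeric matrix `[n x fS]` of reconstructed spectra
#' @export
decodeEmbeddings <- function(codec, x) {
  if (is(x, "EmbeddingSet")) {
    if (!identical(x@codecId, codec@codecId))
      stopf("embeddings were produced by codec '%s' but decoding with '%s'",
            x@codecId, codec@codecId)
    E <- x@embeddings
  } else E <- as.matrix(x)
  arch <- codec@architecture
  if (ncol(E) != arch@fE)
    stopf("embeddings have %d features but the codec expects F_e = %d",
          ncol(E), arch@fE)
  if (nrow(E) == 0L) return(matrix(0, 0L, arch@fS))
  decoderForward(codec, E) * codec@normScale
}

## Decoder-only inference pass.
decoderForward <- function(codec, E) {
  arch <- codec@architecture
  dims <- archDims(arch)
  B <- dims$B; p <- codec@params; st <- codec@bnStats
  n <- nrow(E)
  G <- reluForward(linForward(E, p[["dec.lin.W"]], p[["dec.lin.b"]])$out)$out
  dim(G) <- c(n, dims$lens[B + 1L], arch@channels[B])
  for (b in rev(seq_len(B))) {
    G <- tconvForward(G, p[[sprintf("dec.tconv%d.W", b)]],
                      p[[sprintf("dec.tconv%d.b", b)]], arch@stride)$out
    if (b > 1L) {
      if (arch@useNormalization) {
        nm <- sprintf("dec.bn%d", b)
        G <- bnForward(G, p[[paste0(nm, ".gamma")]], p[[paste0(nm, ".beta")]],
                       st[[nm]], training = FALSE)$out
      }
      G <- reluForward(G)$out
    }
  }
  matrix(G, n, dims$padTo)[, seq_len(arch@fS), drop = FALSE]
}

## Canonical serialization of a codec -> file; used by save, load and the
## content hash so all three agree bit for bit.
writeCodecBinary <- function(codec, path) {
  arch <- codec@architecture
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("MSICODEC", con, nchars = 8L, eos = NULL)
  writeBin(1L, con, size = 4L, endian = "little")
  hdr <- c(arch@fS, arch@fE, length(arch@channels), arch@channels,
           arch@kernelSize, arch@stride, as.integer(arch@useNormalization),
           codec@padTo)
  writeBin(length(hdr), con, size = 4L, endian = "little")
  writeBin(as.integer(hdr), con, size = 4L, endian = "little")
  writeBin(codec@normScale, con, size = 8L, endian = "little")
  nms <- names(codec@params)
  writeBin(length(nms), con, size = 4L, endian = "little")
  for (nm in nms) {
    writeBin(nchar(nm, "bytes"), con, size = 4L, endian = "little")
    writeChar(nm, con, nchars = nchar(nm, "bytes"), eos = NULL)
    v <- codec@params[[nm]]
    writeBin(length(dim(v) %||% length(v)), con, size = 4L, endian = "little")
    writeBin(as.integer(dim(v) %||% length(v)), con, size = 4L, endian = "little")
    writeBin(as.numeric(v), con, size = 8L, endian = "little")
  }
  snms <- names(codec@bnStats)
  writeBin(length(snms), con, size = 4L, endian = "little")
  for (nm in snms) {
    writeBin(nchar(nm, "bytes"), con, size = 4L, endian = "little")
    writeChar(nm, con, nchars = nchar(nm, "bytes"), eos = NULL)
    writeBin(length(codec@bnStats[[nm]]$mean), con, size = 4L, endian = "little")
    writeBin(as.numeric(codec@bnStats[[nm]]$mean), con, size = 8L, endian = "little")
    writeBin(as.numeric(codec@bnStats[[nm]]$var), con, size = 8L, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Content hash of the canonical serialization; changes whenever any
## weight, statistic or architecture field changes.
computeCodecId <- function(codec) {
  tmp <- tempfile(fileext = ".codec")
  on.exit(unlink(tmp))
  writeCodecBinary(codec, tmp)
  unname(tools::md5sum(tmp))
}

#' Persist / restore a codec
#'
#' A codec is stored as a single binary file (architecture descriptor +
#' weight arrays + normalization statistics). The round trip reproduces
#' encoder outputs bit-identically; a corrupted or incompatible file is
#' refused with an explicit error.
#'
#' @param codec a [Codec-class]
#' @param path file path
#' @export
saveCodec <- function(codec, path) {
  writeCodecBinary(codec, path)
  invisible(path)
}

#' @rdname saveCodec
#' @return `loadCodec`: the restored [Codec-class]
#' @export
loadCodec <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- tryCatch(readChar(con, 8L, useBytes = TRUE), error = function(e) "")
  if (!identical(magic, "MSICODEC")) stopf("'%s' is not a codec file", path)
  ver <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(ver, 1L)) stopf("unsupported codec file version %s", ver)
  nh <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr <- readBin(con, "integer", nh, size = 4L, endian = "little")
  if (length(hdr) != nh) stopf("truncated codec file")
  fS <- hdr[1L]; fE <- hdr[2L]; nb <- hdr[3L]
  channels <- hdr[3L + seq_len(nb)]
  kernel <- hdr[4L + nb]; stride <- hdr[5L + nb]; useNorm <- hdr[6L + nb] == 1L
  padTo <- hdr[7L + nb]
  normScale <- readBin(con, "numeric", 1L, size = 8L, endian = "little")
  np <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  params <- list()
  for (i in seq_len(np)) {
    nc <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!length(nc)) stopf("truncated codec file")
    nm <- readChar(con, nc, useBytes = TRUE)
    nd <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    dm <- readBin(con, "integer", nd, size = 4L, endian = "little")
    v <- readBin(con, "numeric", prod(dm), size = 8L, endian = "little")
    if (length(v) != prod(dm)) stopf("truncated codec file")
    if (nd > 1L) dim(v) <- dm
    params[[nm]] <- v
  }
  ns <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  stats <- list()
  for (i in seq_len(ns)) {
    nc <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    nm <- readChar(con, nc, useBytes = TRUE)
    len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    mu <- readBin(con, "numeric", len, size = 8L, endian = "little")
    va <- readBin(con, "numeric", len, size = 8L, endian = "little")
    if (length(va) != len) stopf("truncated codec file")
    stats[[nm]] <- list(mean = mu, var = va)
  }
  arch <- codecArchitecture(fS, fE, channels, kernel, stride, useNorm)
  codec <- new("Codec", architecture = arch, params = params, bnStats = stats,
               normScale = normScale, padTo = as.integer(padTo), codecId = "")
  codec@codecId <- computeCodecId(codec)
  codec
}

#' @describeIn saveCodec the codec's content-hash identifier
#' @export
codecId <- function(codec) codec@codecId

setMethod("show", "Codec", function(object) {
  arch <- object@architecture
  cat(sprintf("Codec: F_s = %d -> F_e = %d\n", arch@fS, arch@fE))
  cat(sprintf("  encoder: %d conv blocks (channels %s, kernel %d, stride %d)%s\n",
              length(arch@channels), paste(arch@channels, collapse = ","),
              arch@kernelSize, arch@stride,
              if (arch@useNormalization) " + feature normalization" else ""))
  cat(sprintf("  normalization scale: %.6g\n", object@normScale))
  cat(sprintf("  codecId: %s\n", object@codecId))
})
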