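test_that("codec build honours the shape contract and is seed-deterministic", {
  arch <- codecArchitecture(3000L, 64L)
  c1 <- buildCodec(arch, seed = 3L)
  c2 <- buildCodec(arch, seed = 3L)
  expect_identical(c1@params, c2@params)
  expect_identical(c1@codecId, c2@codecId)
  c3 <- buildCodec(arch, seed = 4L)
  expect_false(identical(c1@params, c3@params))

  set.seed(1)
  x <- matrix(runif(3000), 1, 3000)
  emb <- encodeSpectra(c1, x)
  expect_equal(dim(emb), c(1L, 64L))
  rec <- decodeEmbeddings(c1, emb)
  expect_equal(dim(rec), c(1L, 3000L))

  ## an embedding longer than the flattened conv output fails at build time
  expect_error(codecArchitecture(64L, 64L, channels = c(2L, 2L),
                                 kernelSize = 3L, stride = 2L),
               "flattened")
})

test_that("encoding is deterministic, row-independent and shape-checked", {
  arch <- tinyArch()
  codec <- buildCodec(arch, seed = 5L)
  set.seed(2)
  X <- matrix(runif(6 * 30), 6, 30)
  E1 <- encodeSpectra(codec, X)
  E2 <- encodeSpectra(codec, X)
  expect_identical(E1, E2)
  ## single-row encoding equals the corresponding batch row
  for (i in c(1L, 4L))
    expect_equal(encodeSpectra(codec, X[i, , drop = FALSE]),
                 E1[i, , drop = FALSE], tolerance = 1e-12)
  ## degenerate and error shapes
  expect_equal(dim(encodeSpectra(codec, matrix(0, 0, 30))), c(0L, 4L))
  expect_error(encodeSpectra(codec, matrix(0, 2, 31)), "F_s")
  R1 <- decodeEmbeddings(codec, E1)
  expect_identical(R1, decodeEmbeddings(codec, E1))
  expect_equal(dim(R1), c(6L, 30L))
  expect_error(decodeEmbeddings(codec, E1[, 1:3]), "F_e")
})

test_that("codec persistence round-trips bit-exactly and refuses corrupted files", {
  codec <- buildCodec(tinyArch(), seed = 6L)
  f <- file.path(tempdir(), "tiny.codec")
  saveCodec(codec, f)
  back <- loadCodec(f)
  expect_identical(back@params, codec@params)
  expect_identical(codecId(back), codecId(codec))
  set.seed(3)
  X <- matrix(runif(4 * 30), 4, 30)
  expect_identical(encodeSpectra(back, X), encodeSpectra(codec, X))

  writeLines("not a codec", f)
  expect_error(loadCodec(f), "not a codec file")
  saveCodec(codec, f)
  raw <- readBin(f, "raw", file.size(f))
  writeBin(raw[1:100], f)
  expect_error(loadCodec(f), "truncated")
})

test_that("the codec id is a content hash: any weight change changes it", {
  codec <- buildCodec(tinyArch(), seed = 7L)
  mod <- codec
  mod@params[["enc.lin.W"]][1] <- mod@params[["enc.lin.W"]][1] + 1e-9
  mod@codecId <- msiCodec:::computeCodecId(mod)
  expect_false(identical(mod@codecId, codec@codecId))
})

test_that("decoding refuses embeddings produced by a different codec", {
  codec <- buildCodec(tinyArch(), seed = 8L)
  other <- buildCodec(tinyArch(), seed = 9L)
  set.seed(4)
  img <- msImage(matrix(runif(3 * 30), 3, 30), 100 + 0.1 * (0:29),
                 cbind(0:2, rep(0L, 3)))
  store <- encodeSpectra(codec, img)
  expect_s4_class(store, "EmbeddingSet")
  expect_error(decodeEmbeddings(other, store), "different|produced")
  expect_equal(dim(decodeEmbeddings(codec, store)), c(3L, 30L))
})

test_that("analytic network gradients agree with finite differences", {
  codec <- buildCodec(tinyArch(), seed = 10L)
  set.seed(5)
  X <- matrix(runif(6 * 30), 6, 30)
  pair <- as.integer(rbind(seq(2, 6, 2), seq(1, 6, 2)))
  w <- lossWeights()
  cp <- contrastiveParams()
  lossOf <- function(cd) {
    fw <- msiCodec:::codecForward(cd, X, training = TRUE)
    totalLoss(contrastiveLoss(fw$emb, pair, cp), meanLoss(fw$emb),
              standardLoss(fw$emb), mseLoss(X, fw$recon), w)$total
  }
  fw <- msiCodec:::codecForward(codec, X, training = TRUE)
  cg <- msiCodec:::contrastiveLossGrad(fw$emb, pair, cp)
  mg <- msiCodec:::meanLossGrad(fw$emb)
  sg <- msiCodec:::standardLossGrad(fw$emb)
  rg <- msiCodec:::mseLossGrad(X, fw$recon)
  grads <- msiCodec:::codecBackward(
    codec, fw,
    w$contrastive * cg$grad + w$mean * mg$grad + w$standard * sg$grad,
    w$decoder * rg$grad)
  eps <- 1e-5
  set.seed(6)
  for (nm in names(codec@params)) {
    v <- codec@params[[nm]]
    for (probe in seq_len(min(3L, length(v)))) {
      i <- sample(length(v), 1L)
      cp1 <- codec; cp1@params[[nm]][i] <- v[i] + eps
      cp2 <- codec; cp2@params[[nm]][i] <- v[i] - eps
      num <- (lossOf(cp1) - lossOf(cp2)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 5e-3,
                   label = sprintf("analytic grad %s[%d]", nm, i))
    }
  }
})

test_that("inference uses running statistics: encode of a trained-mode pass differs from eval mode", {
  codec <- buildCodec(tinyArch(), seed = 11L)
  set.seed(7)
  X <- matrix(runif(8 * 30), 8, 30)
  fwTrain <- msiCodec:::codecForward(codec, X, training = TRUE)
  fwEval <- msiCodec:::codecForward(codec, X, training = FALSE)
  expect_false(identical(fwTrain$emb, fwEval$emb))
  ## eval mode is unaffected by batch composition
  sub <- msiCodec:::codecForward(codec, X[1:2, , drop = FALSE], training = FALSE)
  expect_equal(sub$emb, fwEval$emb[1:2, , drop = FALSE], tolerance = 1e-12)
})
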