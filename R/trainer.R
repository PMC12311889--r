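#' Training configuration
#'
#' Defaults follow the published setting: Adam with learning rate 1e-3 and
#' weight decay 1e-5, batch sample size 64 (so 128 spectra per contrastive
#' batch), early-stopping patience of 30 epochs on the weighted training
#' loss, and 10% augmentation noise.
#'
#' @param learningRate Adam step size, default 1e-3
#' @param weightDecay L2 weight decay added to the gradient, default 1e-5
#' @param batchSize batch sample size N (>= 2), default 64
#' @param patienceEpochs epochs without improvement before stopping,
#'   default 30
#' @param maxEpochs hard epoch cap, default 500
#' @param lossWeights a [lossWeights()] object
#' @param contrastiveParams a [contrastiveParams()] object
#' @param augmentDelta augmentation fraction, default 0.1
#' @param seed integer master seed
#' @export
trainingConfig <- function(learningRate = 1e-3, weightDecay = 1e-5,
                           batchSize = 64L, patienceEpochs = 30L,
                           maxEpochs = 500L,
                           lossWeights = msiCodec::lossWeights(),
                           contrastiveParams = msiCodec::contrastiveParams(),
                           augmentDelta = 0.1, seed = 1L) {
  if (learningRate < 0) stopf("learningRate must be nonnegative")
  if (weightDecay < 0) stopf("weightDecay must be nonnegative")
  if (batchSize < 2L) stopf("batchSize must be at least 2")
  if (patienceEpochs < 1L) stopf("patienceEpochs must be at least 1")
  structure(list(learningRate = learningRate, weightDecay = weightDecay,
                 batchSize = as.integer(batchSize),
                 patienceEpochs = as.integer(patienceEpochs),
                 maxEpochs = as.integer(maxEpochs),
                 lossWeights = lossWeights,
                 contrastiveParams = contrastiveParams,
                 augmentDelta = augmentDelta, seed = seed),
            class = "trainingConfig")
}

## One Adam update over the flat parameter list (PyTorch-style: weight
## decay is added to the gradient, not decoupled).
adamStep <- function(params, grads, state, lr, wd, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (wd > 0) g <- g + wd * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a codec on an MS image
#'
#' Each epoch shuffles the pixels (seeded), forms contrastive batches of
#' `2N` spectra (original + augmentation interleaved), runs the
#' encoder-decoder forward, computes the weighted sum of the contrastive,
#' mean, standard and reconstruction (MSE) losses, and takes one Adam step
#' per batch. The best weighted epoch loss is tracked; training stops when
#' it has not improved (by at least 1e-6 relative) for `patienceEpochs`
#' epochs or when `maxEpochs` is reached, and the parameters of the best
#' epoch are restored.
#'
#' Intensities are normalized to the dataset-wide maximum before training;
#' the scale is recorded in the codec so decoding restores original units.
#'
#' @param image an [MSImage-class]
#' @param arch a [codecArchitecture()]; its `fS` must match the image
#' @param config a [trainingConfig()]
#' @param verbose print per-epoch losses, default `FALSE`
#' @return list with `codec` (trained [Codec-class]) and `history` (one
#'   data.frame row per epoch: contrastive, mean, standard, mse,
#'   weighted_total)
#' @export
trainCodec <- function(image, arch, config = trainingConfig(),
                       verbose = FALSE) {
  if (nPixels(image) == 0L) stopf("cannot train on an empty image")
  if (arch@fS != length(mzAxis(image)))
    stopf("architecture expects F_s = %d but the image has %d bins",
          arch@fS, length(mzAxis(image)))
  normed <- if (is.null(normalizationScale(image)))
    normalizeIntensities(image) else image
  scale <- normalizationScale(normed) %||% 1
  X <- intensityMatrix(normed)
  n <- nrow(X)
  N <- config$batchSize
  if (n < N)
    warnf("image has %d pixels, fewer than one batch of %d; training with a single smaller batch", n, N)
  codec <- buildCodec(arch, seed = deriveSeed(config$seed, 0L))
  codec@normScale <- scale
  w <- config$lossWeights
  cp <- config$contrastiveParams
  state <- list(t = 0L,
                m = lapply(codec@params, function(x) x * 0),
                v = lapply(codec@params, function(x) x * 0))
  history <- vector("list", config$maxEpochs)
  best <- list(loss = Inf, params = codec@params, bnStats = codec@bnStats,
               epoch = 0L)
  bad <- 0L
  epochsRun <- 0L
  withSeed(deriveSeed(config$seed, 1L), {
    for (epoch in seq_len(config$maxEpochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = N)
      comp <- matrix(NA_real_, length(starts), 4L)
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + N - 1L, n)]
        if (length(idx) < 2L) next  # a 1-pixel tail cannot form pairs
        orig <- X[idx, , drop = FALSE]
        aug <- augmentRows(orig, config$augmentDelta)
        m <- 2L * length(idx)
        Z <- matrix(0, m, ncol(X))
        Z[seq(1L, m, 2L), ] <- orig
        Z[seq(2L, m, 2L), ] <- aug
        pair <- as.integer(rbind(seq(2L, m, 2L), seq(1L, m, 2L)))
        fw <- codecForward(codec, Z, training = TRUE)
        codec@bnStats <- fw$bnStats
        cg <- contrastiveLossGrad(fw$emb, pair, cp)
        mg <- meanLossGrad(fw$emb)
        sg <- standardLossGrad(fw$emb)
        rg <- mseLossGrad(Z, fw$recon)
        tl <- totalLoss(cg$value, mg$value, sg$value, rg$value, w)
        comp[bi, ] <- c(cg$value, mg$value, sg$value, rg$value)
        dEmb <- w$contrastive * cg$grad + w$mean * mg$grad + w$standard * sg$grad
        dRecon <- w$decoder * rg$grad
        grads <- codecBackward(codec, fw, dEmb, dRecon)
        upd <- adamStep(codec@params, grads, state,
                        config$learningRate, config$weightDecay)
        codec@params <- upd$params
        state <- upd$state
      }
      mc <- colMeans(comp, na.rm = TRUE)
      if (any(!is.finite(mc)))
        stopf("training diverged: non-finite %s loss at epoch %d",
              paste(c("contrastive", "mean", "standard", "mse")[!is.finite(mc)],
                    collapse = "/"), epoch)
      epochLoss <- totalLoss(mc[1L], mc[2L], mc[3L], mc[4L], w)
      history[[epoch]] <- cbind(epoch = epoch, epochLoss$report)
      epochsRun <- epoch
      if (verbose)
        message(sprintf("epoch %3d  weighted %.6g  (c %.4g m %.4g s %.4g mse %.4g)",
                        epoch, epochLoss$total, mc[1L], mc[2L], mc[3L], mc[4L]))
      if (epochLoss$total < best$loss * (1 - 1e-6)) {
        best <- list(loss = epochLoss$total, params = codec@params,
                     bnStats = codec@bnStats, epoch = epoch)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= config$patienceEpochs) break
      }
    }
  })
  codec@params <- best$params
  codec@bnStats <- best$bnStats
  codec@codecId <- computeCodecId(codec)
  list(codec = codec, history = do.call(rbind, history[seq_len(epochsRun)]),
       bestEpoch = best$epoch)
}

#' Train one codec per subject group
#'
#' Trains independently per group (e.g. per patient, so the encoder focuses
#' on subject-specific tissue variation rather than inter-subject
#' differences), with per-group seeds derived from the master seed.
#'
#' @param images named list of [MSImage-class] objects, one per group
#' @param arch a [codecArchitecture()]
#' @param config a [trainingConfig()]
#' @return named list of `trainCodec()` results
#' @export
trainPerGroup <- function(images, arch, config = trainingConfig()) {
  if (!length(images)) stopf("empty group list")
  ids <- names(images) %||% as.character(seq_along(images))
  out <- vector("list", length(images))
  names(out) <- ids
  for (i in seq_along(images)) {
    cfg <- config
    cfg$seed <- deriveSeed(config$seed, 1000L + i)
    out[[i]] <- tryCatch(trainCodec(images[[i]], arch, cfg),
                         error = function(e)
                           stopf("group '%s': %s", ids[i], conditionMessage(e)))
  }
  out
}

#' Write a loss history to CSV
#'
#' @param history the `history` data.frame from [trainCodec()]
#' @param path output file
#' @export
writeLossHistory <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
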