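#' Contrastive loss parameters
#'
#' `alpha` scales the summed pairwise loss; the default `NULL` means
#' `1 / (2N)` so the contrastive term is a per-anchor average and therefore
#' batch-size independent. `gamma` is the softmax temperature dividing the
#' cosine similarity; smaller values sharpen the contrast.
#'
#' @param alpha positive weight constant, or `NULL` for `1 / (2N)`
#' @param gamma positive temperature, default 0.5
#' @export
contrastiveParams <- function(alpha = NULL, gamma = 0.5) {
  if (!is.null(alpha) && alpha <= 0) stopf("alpha must be positive")
  if (gamma <= 0) stopf("gamma must be positive")
  structure(list(alpha = alpha, gamma = gamma), class = "contrastiveParams")
}

#' Loss weights for the combined training objective
#'
#' Defaults are the single-image preset: contrastive 0.1, mean 0.01,
#' standard 0.01, decoder 0.01. `preset = "cohort"` raises the decoder
#' weight to 1, the setting suited to large multi-subject cohorts where
#' reconstruction fidelity is emphasized.
#'
#' @param contrastive,mean,standard,decoder nonnegative weights
#' @param preset `"single"` (default) or `"cohort"`
#' @export
lossWeights <- function(contrastive = 0.1, mean = 0.01, standard = 0.01,
                        decoder = NULL, preset = c("single", "cohort")) {
  preset <- match.arg(preset)
  if (is.null(decoder)) decoder <- if (preset == "cohort") 1 else 0.01
  w <- c(contrastive = contrastive, mean = mean, standard = standard,
         decoder = decoder)
  if (any(w < 0)) stopf("loss weights must be nonnegative")
  if (all(w == 0)) stopf("at least one loss weight must be positive")
  structure(as.list(w), class = "lossWeights")
}

#' Cosine similarity of two vectors
#'
#' @param u,v nonzero numeric vectors of equal length
#' @return `u . v / (||u|| ||v||)`, in `[-1, 1]`
#' @export
cosineSimilarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stopf("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' NT-Xent style contrastive loss over a batch of embeddings
#'
#' For each ordered positive pair `(i, j = pairIndex[i])` computes
#' `l_ij = -log( exp(sim(w_i, w_j)/gamma) / sum_{k != i} exp(sim(w_i, w_k)/gamma) )`
#' with `sim` the cosine similarity, sums over all `2N` ordered positive
#' pairs, and multiplies by `alpha`. Numerically stabilized by row-max
#' subtraction, so temperatures as small as 1e-4 do not overflow.
#'
#' @param embeddings numeric matrix `[2N x F_e]`
#' @param pairIndex 1-based fixed-point free involution giving each row's
#'   positive partner
#' @param params a [contrastiveParams()] object
#' @return scalar loss (>= 0)
#' @export
contrastiveLoss <- function(embeddings, pairIndex, params = contrastiveParams()) {
  contrastiveLossGrad(embeddings, pairIndex, params, wantGrad = FALSE)$value
}

## Value and gradient wrt the embedding matrix.
contrastiveLossGrad <- function(W, pairIndex, params, wantGrad = TRUE) {
  m <- nrow(W)
  if (m < 2L || m %% 2L != 0L) stopf("need an even batch of at least 2 embeddings")
  pairIndex <- as.integer(pairIndex)
  if (length(pairIndex) != m || any(pairIndex[pairIndex] != seq_len(m)) ||
      any(pairIndex == seq_len(m)))
    stopf("pairIndex must be a fixed-point free involution over the batch")
  alpha <- if (is.null(params$alpha)) 1 / m else params$alpha
  gamma <- params$gamma
  nrm <- sqrt(rowSums(W^2))
  if (any(nrm == 0)) stopf("zero embedding row; cosine similarity undefined")
  U <- W / nrm
  S <- tcrossprod(U)                      # cosine similarities
  L <- S / gamma
  diag(L) <- -Inf                         # k != i excluded from the denominator
  rowMax <- apply(L, 1L, max)
  E <- exp(L - rowMax)
  denom <- rowSums(E)
  pos <- cbind(seq_len(m), pairIndex)
  ll <- -(L[pos] - rowMax - log(denom))   # per ordered positive pair
  value <- alpha * sum(ll)
  if (!wantGrad) return(list(value = value))
  P <- E / denom                          # softmax over k != i (diag 0)
  G <- alpha * (P - (col(P) == pairIndex[row(P)])) / gamma
  diag(G) <- 0
  ## dL/dU_i = sum_k (G_ik + G_ki) U_k ; then through the row normalization
  M <- G + t(G)
  dU <- M %*% U
  dW <- (dU - U * rowSums(dU * U)) / nrm
  list(value = value, grad = dW)
}

#' Mean loss: keeps embeddings centered at zero
#'
#' `(1 / 2N) * sum_i mean(w_i)^2` over the batch rows.
#'
#' @param embeddings numeric matrix `[2N x F_e]`
#' @return scalar loss
#' @export
meanLoss <- function(embeddings) {
  if (!nrow(embeddings)) stopf("empty batch")
  mu <- rowMeans(embeddings)
  mean(mu^2)
}

meanLossGrad <- function(W) {
  mu <- rowMeans(W)
  list(value = mean(mu^2),
       grad = matrix(2 * mu / (nrow(W) * ncol(W)), nrow(W), ncol(W)))
}

#' Standard loss: keeps per-feature spread near one
#'
#' `(1 / F_e) * sum_j (sigma_j - 1)^2` where `sigma_j` is the population
#' standard deviation of embedding feature j across the batch.
#'
#' @param embeddings numeric matrix `[2N x F_e]`, at least two rows
#' @return scalar loss
#' @export
standardLoss <- function(embeddings) {
  if (nrow(embeddings) < 2L) stopf("standard loss needs at least two embeddings")
  mu <- colMeans(embeddings)
  sig <- sqrt(colMeans(sweep(embeddings, 2L, mu)^2))
  mean((sig - 1)^2)
}

standardLossGrad <- function(W) {
  n <- nrow(W); f <- ncol(W)
  mu <- colMeans(W)
  C <- sweep(W, 2L, mu)
  sig <- sqrt(colMeans(C^2))
  value <- mean((sig - 1)^2)
  safe <- pmax(sig, 1e-12)
  g <- 2 * (sig - 1) / (f * n * safe)     # d/dW_ij = g_j * C_ij
  list(value = value, grad = sweep(C, 2L, g, `*`))
}

#' Mean squared reconstruction error
#'
#' Mean over all entries of `(z - zTilde)^2`: the per-spectrum MSE over the
#' `F_s` bins, averaged over pixels.
#'
#' @param original,decoded numeric matrices of identical shape
#' @return scalar loss
#' @export
mseLoss <- function(original, decoded) {
  if (!identical(dim(as.matrix(original)), dim(as.matrix(decoded))))
    stopf("original and decoded spectra disagree in shape")
  mean((original - decoded)^2)
}

mseLossGrad <- function(Z, Zt) {
  d <- Zt - Z
  list(value = mean(d^2), grad = 2 * d / length(d))
}

#' Weighted total loss with a per-component report
#'
#' @param contrastive,mean,standard,mse component loss values
#' @param weights a [lossWeights()] object
#' @return list with `total` and a one-row data.frame `report` carrying the
#'   components and the weighted total
#' @export
totalLoss <- function(contrastive, mean, standard, mse,
                      weights = lossWeights()) {
  comp <- c(contrastive = contrastive, mean = mean, standard = standard,
            mse = mse)
  bad <- names(comp)[!is.finite(comp)]
  if (length(bad))
    stopf("non-finite loss component: %s", paste(bad, collapse = ", "))
  total <- weights$contrastive * contrastive + weights$mean * mean +
    weights$standard * standard + weights$decoder * mse
  list(total = total,
       report = data.frame(contrastive = contrastive, mean = mean,
                           standard = standard, mse = mse,
                           weighted_total = total))
}
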