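## Internal 1-D neural network primitives.
##
## Activations are 3-D arrays laid out [n, L, C] (batch, length, channels):
## a (length, channel) slab is then n contiguous values, so im2col /
## col2im are memcpy/axpy kernels (src/kernels.cpp) and a convolution is
## one BLAS matmul over the patch matrix. Transposed convolutions are the
## exact adjoint (col2im scatter-add), which their backward passes reuse.
## All layers return the caches their backward passes need; the analytic
## backprop is validated against finite differences in the test suite.

## For stride s and kernel k we pad so that L_out = L_in / s exactly
## (L_in divisible by s is guaranteed by input zero-padding at build time).
convPadding <- function(kernel, stride) {
  total <- kernel - stride
  if (total < 0) stopf("kernel size must be >= stride")
  padL <- total %/% 2L
  list(padL = padL, padR = total - padL)
}

## per-channel affine with dims preserved
channelAffine <- function(X, scale, shift = numeric(length(scale))) {
  d <- dim(X)
  out <- cppChannelAffine(X, as.integer(prod(d[1:2])), d[3L], scale, shift)
  dim(out) <- d
  out
}

channelAffineFlat <- function(X, m, C, scale = rep(1, C), shift = numeric(C)) {
  cppChannelAffine(X, as.integer(m), as.integer(C), scale, shift)
}

## -- convolution -----------------------------------------------------------
## X [n, L, Cin]; W [Cin, k, Cout]; b [Cout]; output [n, L/stride, Cout]
convForward <- function(X, W, b, stride) {
  d <- dim(X); n <- d[1L]; L <- d[2L]; Cin <- d[3L]
  k <- dim(W)[2L]; Cout <- dim(W)[3L]
  pd <- convPadding(k, stride)
  M <- L %/% stride
  Xcol <- cppIm2col(X, n, L, Cin, k, stride, pd$padL)
  Y <- Xcol %*% matrix(W, Cin * k, Cout)
  Y <- channelAffineFlat(Y, n * M, Cout, shift = b)
  dim(Y) <- c(n, M, Cout)
  list(out = Y, cache = list(Xcol = Xcol, dims = c(n = n, Cin = Cin, L = L,
       k = k, Cout = Cout, M = M), pd = pd, stride = stride))
}

convBackward <- function(dY, W, cache) {
  dm <- cache$dims
  n <- dm[["n"]]; Cin <- dm[["Cin"]]; L <- dm[["L"]]
  k <- dm[["k"]]; Cout <- dm[["Cout"]]; M <- dm[["M"]]
  dim(dY) <- c(n * M, Cout)
  dW <- crossprod(cache$Xcol, dY)
  dim(dW) <- c(Cin, k, Cout)
  db <- .colSums(dY, n * M, Cout)
  dXcol <- dY %*% t(matrix(W, Cin * k, Cout))
  dX <- cppCol2im(dXcol, n, Cin, L, k, cache$stride, cache$pd$padL)
  list(dX = dX, dW = dW, db = db)
}

## -- transposed convolution (exact adjoint of convForward) -----------------
## U [n, M, Cin]; W [Cout, k, Cin] (the mirror convolution's weights);
## output [n, M*stride, Cout]
tconvForward <- function(U, W, b, stride) {
  d <- dim(U); n <- d[1L]; M <- d[2L]; Cin <- d[3L]
  Cout <- dim(W)[1L]; k <- dim(W)[2L]
  Lout <- M * stride
  pd <- convPadding(k, stride)
  Um <- U
  dim(Um) <- c(n * M, Cin)
  Xcol <- Um %*% t(matrix(W, Cout * k, Cin))     # [n*M, Cout*k]
  X <- cppCol2im(Xcol, n, Cout, Lout, k, stride, pd$padL)
  X <- channelAffine(X, rep(1, Cout), b)
  list(out = X, cache = list(Um = Um, dims = c(n = n, Cin = Cin, M = M,
       k = k, Cout = Cout, Lout = Lout), pd = pd, stride = stride))
}

tconvBackward <- function(dX, W, cache) {
  dm <- cache$dims
  n <- dm[["n"]]; Cin <- dm[["Cin"]]; M <- dm[["M"]]
  k <- dm[["k"]]; Cout <- dm[["Cout"]]; Lout <- dm[["Lout"]]
  db <- .colSums(matrix(dX, n * Lout, Cout), n * Lout, Cout)
  dXcol <- cppIm2col(dX, n, Lout, Cout, k, cache$stride, cache$pd$padL)
  dU <- dXcol %*% matrix(W, Cout * k, Cin)
  dim(dU) <- c(n, M, Cin)
  dW <- crossprod(dXcol, cache$Um)
  dim(dW) <- c(Cout, k, Cin)
  list(dX = dU, dW = dW, db = db)
}

## -- batch normalization over channels -------------------------------------
## Per-channel statistics over (batch, length); running statistics are
## used at inference ("feature normalization": mean 0, sd 1).
bnForward <- function(X, gamma, beta, stats, training, momentum = 0.1,
                      eps = 1e-5) {
  d <- dim(X); m <- d[1L] * d[2L]; C <- d[3L]
  if (training) {
    mv <- cppChannelMeanVar(X, m, C)
    mu <- mv$mean; va <- mv$var
    stats$mean <- (1 - momentum) * stats$mean + momentum * mu
    stats$var <- (1 - momentum) * stats$var + momentum * va
  } else {
    mu <- stats$mean
    va <- stats$var
  }
  inv <- 1 / sqrt(va + eps)
  ap <- cppBnApply(X, m, C, mu, inv, gamma, beta)
  Xhat <- ap$xhat
  Y <- ap$y
  list(out = Y, stats = stats,
       cache = list(Xhat = Xhat, inv = inv, dims = d, training = training))
}

bnBackward <- function(dY, gamma, cache) {
  d <- cache$dims; m <- d[1L] * d[2L]; C <- d[3L]
  st <- cppBnBackwardStats(dY, cache$Xhat, m, C, gamma)
  if (cache$training) {
    ## standard batchnorm backward through the batch statistics
    dX <- cppBnBackwardInput(dY, cache$Xhat, m, C, gamma, cache$inv,
                             st$m1, st$m2)
  } else {
    dX <- cppChannelAffine(dY, m, C, gamma * cache$inv, numeric(C))
    dim(dX) <- d
  }
  list(dX = dX, dgamma = st$dgamma, dbeta = st$dbeta)
}

## -- dense + activation ----------------------------------------------------
linForward <- function(X, W, b) {
  Y <- X %*% W
  list(out = Y + rep(b, each = nrow(X)), cache = X)
}

linBackward <- function(dY, W, cache) {
  list(dX = dY %*% t(W), dW = crossprod(cache, dY), db = colSums(dY))
}

## the ReLU output doubles as the backward mask (out > 0 iff X > 0)
reluForward <- function(X) {
  out <- cppRelu(X)
  list(out = out, cache = out)
}

reluBackward <- function(dY, out) cppReluGrad(dY, out)

## Kaiming-style uniform init, U(-1/sqrt(fanIn), 1/sqrt(fanIn))
initTensor <- function(dims, fanIn) {
  b <- 1 / sqrt(fanIn)
  array(runif(prod(dims), -b, b), dim = dims)
}
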