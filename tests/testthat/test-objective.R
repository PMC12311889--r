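test_that("cosine similarity satisfies its identities and rejects zero vectors", {
  set.seed(1)
  v <- rnorm(8)
  expect_equal(cosineSimilarity(v, v), 1)
  expect_equal(cosineSimilarity(v, -v), -1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosineSimilarity(c(3, 0), c(5, 0)), 1)
  expect_error(cosineSimilarity(c(0, 0), v[1:2]), "zero vector")
})

test_that("contrastive loss is zero for a single pair and matches the closed form for orthogonal pairs", {
  ## 2N = 2: the denominator holds only the positive partner, so l = -log(1)
  W <- matrix(rnorm(2 * 6), 2, 6)
  p <- contrastiveParams(alpha = 1, gamma = 1)
  expect_equal(contrastiveLoss(W, c(2L, 1L), p), 0)
  expect_equal(contrastiveLoss(W, c(2L, 1L), contrastiveParams(alpha = 3, gamma = 0.1)), 0)

  ## N = 2, embeddings e1,e1,e2,e2 with e1 orthogonal to e2: each of the 4
  ## ordered positive pairs contributes log(1 + 2/e)
  W <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  pair <- c(2L, 1L, 4L, 3L)
  got <- contrastiveLoss(W, pair, contrastiveParams(alpha = 1, gamma = 1))
  expect_equal(got, 4 * log(1 + 2 * exp(-1)), tolerance = 1e-12)
  expect_equal(got, 2.205780, tolerance = 1e-6)
})

test_that("contrastive loss tends to sum(log(2N - 1)) as the temperature grows", {
  set.seed(7)
  W <- matrix(rnorm(8 * 5), 8, 5)
  pair <- as.integer(rbind(seq(2, 8, 2), seq(1, 8, 2)))
  p <- contrastiveParams(alpha = 1, gamma = 1e6)
  expect_equal(contrastiveLoss(W, pair, p), 8 * log(7), tolerance = 1e-4)
})

test_that("contrastive loss matches the literal double-loop oracle on random batches", {
  set.seed(11)
  for (rep in 1:20) {
    N <- sample(2:8, 1)
    fe <- sample(2:6, 1)
    W <- matrix(rnorm(2 * N * fe), 2 * N, fe)
    pair <- as.integer(rbind(seq(2, 2 * N, 2), seq(1, 2 * N, 2)))
    gamma <- runif(1, 0.2, 2)
    alpha <- runif(1, 0.1, 2)
    expect_equal(contrastiveLoss(W, pair, contrastiveParams(alpha, gamma)),
                 contrastiveOracle(W, pair, alpha, gamma), tolerance = 1e-9)
  }
})

test_that("contrastive loss is numerically stable at extreme temperatures and validates inputs", {
  W <- rbind(c(1, 0), c(0.9, 0.1), c(-1, 0), c(-0.9, -0.1))
  pair <- c(2L, 1L, 4L, 3L)
  v <- contrastiveLoss(W, pair, contrastiveParams(alpha = 1, gamma = 1e-4))
  expect_true(is.finite(v))
  expect_error(contrastiveLoss(W[0, , drop = FALSE], integer(), contrastiveParams()),
               "at least 2")
  expect_error(contrastiveLoss(W, c(1L, 2L, 3L, 4L), contrastiveParams()),
               "involution")
  expect_error(contrastiveLoss(rbind(W, 0, 0), c(2L, 1L, 4L, 3L, 6L, 5L),
                               contrastiveParams()), "zero embedding")
})

test_that("mean loss evaluates its worked examples and scales quadratically", {
  expect_equal(meanLoss(rbind(c(1, -1), c(2, -2))), 0)
  expect_equal(meanLoss(rbind(c(1, 1), c(3, 3))), 5)
  set.seed(2)
  W <- matrix(rnorm(12), 4, 3)
  expect_equal(meanLoss(3 * W), 9 * meanLoss(W))
  expect_error(meanLoss(W[0, , drop = FALSE]), "empty")
})

test_that("standard loss evaluates its worked examples (population sd convention)", {
  expect_equal(standardLoss(rbind(1, -1)), 0)       # sigma = 1
  W <- matrix(rep(c(2, 7, 1), each = 4), 4, 3)      # constant batch
  expect_equal(standardLoss(W), 1)
  expect_equal(standardLoss(rbind(2, -2)), 1)       # sigma = 2
  expect_error(standardLoss(matrix(1, 1, 3)), "at least two")
})

test_that("mean and standard losses vanish exactly on their target distribution and are positive otherwise", {
  set.seed(3)
  fe <- 6L
  ## rows with zero mean, features with population sd 1
  W <- matrix(rnorm(20 * fe), 20, fe)
  W <- W - rowMeans(W)
  expect_equal(meanLoss(W), 0)
  Wc <- sweep(W, 2, colMeans(W))
  Ws <- sweep(Wc, 2, sqrt(colMeans(Wc^2)), "/")
  expect_lt(standardLoss(Ws), 1e-20)
  expect_gt(meanLoss(W + 0.5), 0)
  expect_gt(standardLoss(2 * Ws), 0)
})

test_that("reconstruction MSE evaluates its worked example and is symmetric", {
  A <- matrix(c(0, 0, 2), 1, 3)
  B <- matrix(0, 1, 3)
  expect_equal(mseLoss(A, A), 0)
  expect_equal(mseLoss(A, B), 4 / 3)
  set.seed(4)
  X <- matrix(rnorm(15), 3, 5); Y <- matrix(rnorm(15), 3, 5)
  expect_equal(mseLoss(X, Y), mseLoss(Y, X))
  expect_error(mseLoss(X, Y[, 1:3]), "shape")
})

test_that("total loss weights components as declared and flags divergence", {
  w <- lossWeights(contrastive = 0, mean = 0, standard = 0, decoder = 1)
  expect_equal(totalLoss(5, 5, 5, 2.5, w)$total, 2.5)
  w2 <- lossWeights(contrastive = 0.1, mean = 0.01, standard = 0.01, decoder = 1)
  expect_equal(totalLoss(1, 1, 1, 1, w2)$total, 1.12)
  expect_equal(totalLoss(0, 0, 0, 0, w2)$total, 0)
  expect_error(totalLoss(NaN, 0, 0, 0, w2), "contrastive")
  expect_error(lossWeights(contrastive = 0, mean = 0, standard = 0, decoder = 0),
               "at least one")
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(5)
  W <- matrix(rnorm(8 * 4), 8, 4)
  pair <- as.integer(rbind(seq(2, 8, 2), seq(1, 8, 2)))
  cp <- contrastiveParams(alpha = 0.7, gamma = 0.6)
  checks <- list(
    list(g = msiCodec:::contrastiveLossGrad(W, pair, cp)$grad,
         f = function(X) contrastiveLoss(X, pair, cp)),
    list(g = msiCodec:::meanLossGrad(W)$grad, f = meanLoss),
    list(g = msiCodec:::standardLossGrad(W)$grad, f = standardLoss))
  for (ch in checks)
    expect_equal(ch$g, numericGradient(ch$f, W), tolerance = 1e-6)
  Z <- matrix(rnorm(12), 3, 4)
  expect_equal(msiCodec:::mseLossGrad(Z, W[1:3, ])$grad,
               numericGradient(function(Y) mseLoss(Z, Y), W[1:3, ]),
               tolerance = 1e-6)
})

test_that("contrastive loss is invariant to batch reordering with consistent pair relabeling", {
  set.seed(6)
  N <- 5L
  W <- matrix(rnorm(2 * N * 4), 2 * N, 4)
  pair <- as.integer(rbind(seq(2, 2 * N, 2), seq(1, 2 * N, 2)))
  perm <- sample(2 * N)
  inv <- order(perm)
  Wp <- W[perm, , drop = FALSE]
  pairPerm <- inv[pair[perm]]
  cp <- contrastiveParams(alpha = 1, gamma = 0.8)
  expect_equal(contrastiveLoss(Wp, pairPerm, cp), contrastiveLoss(W, pair, cp),
               tolerance = 1e-12)
})
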