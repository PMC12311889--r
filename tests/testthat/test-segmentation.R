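test_that("top-peak features select the highest-mean bins, ties to lower m/z", {
  mz <- 100 + 0.1 * (0:5)
  X <- rbind(c(0, 5, 1, 3, 3, 2),
             c(0, 5, 1, 3, 3, 2))
  img <- msImage(X, mz, cbind(0:1, c(0L, 0L)))
  F1 <- topPeakFeatures(img, 3L)
  expect_equal(colnames(F1), c("100.1", "100.3", "100.4"))  # tie 3,3 -> lower m/z first
  expect_equal(F1[1, ], c(5, 3, 3), ignore_attr = TRUE)
  ## n_peaks = F_s returns a column permutation of the full matrix
  Fall <- topPeakFeatures(img, 6L)
  expect_equal(sort(Fall[1, ]), sort(X[1, ]), ignore_attr = TRUE)
  expect_error(topPeakFeatures(img, 0L), "positive")
  expect_error(topPeakFeatures(img, 7L), "exceeds")
})

test_that("k-means segmentation separates well-separated groups and is seed-stable", {
  co <- cbind(0:19, rep(0L, 20))
  feats <- matrix(c(rep(0, 10), rep(10, 10)), ncol = 1)
  lm <- kmeansSegment(feats, 2L, coords = co, seed = 1L)
  lab <- pixelLabels(lm)
  expect_equal(length(unique(lab[1:10])), 1L)
  expect_equal(length(unique(lab[11:20])), 1L)
  expect_false(lab[1] == lab[11])
  expect_equal(pixelLabels(kmeansSegment(feats, 1L, coords = co, seed = 1L)),
               rep(0L, 20))
  set.seed(2)
  F2 <- matrix(rnorm(40 * 3), 40, 3)
  co2 <- cbind(0:39, rep(0L, 40))
  a <- kmeansSegment(F2, 4L, coords = co2, seed = 7L)
  b <- kmeansSegment(F2, 4L, coords = co2, seed = 7L)
  expect_identical(pixelLabels(a), pixelLabels(b))
  ## label sets invariant (up to permutation) under feature-column permutation
  c1 <- kmeansSegment(F2[, c(2, 3, 1)], 4L, coords = co2, seed = 7L)
  tab <- table(pixelLabels(a), pixelLabels(c1))
  expect_equal(sum(apply(tab, 1, max)), 40L)
  expect_error(kmeansSegment(F2[1:3, ], 4L, coords = co2[1:3, ]), "clusters")
})

test_that("the silhouette rule picks the planted cluster count on 1-D projections", {
  set.seed(3)
  two <- c(rnorm(100, 0, 0.1), rnorm(100, 10, 0.1))
  expect_equal(bestCountForComponent(two, seed = 1L), 2L)
  three <- c(rnorm(70, 0, 0.1), rnorm(70, 5, 0.1), rnorm(70, 10, 0.1))
  expect_equal(bestCountForComponent(three, cMax = 5L, seed = 1L), 3L)
  ## a single Gaussian has no silhouette-worthy split at the default tau
  one <- rnorm(200)
  expect_equal(bestCountForComponent(one, seed = 1L), 1L)
  expect_equal(bestCountForComponent(rep(4, 50), cMax = 10L, seed = 1L), 1L)
  ## scale invariance
  expect_equal(bestCountForComponent(two * 1e3, seed = 1L), 2L)
  expect_equal(bestCountForComponent(two * 1e-3, seed = 1L), 2L)
})

makeBlobs <- function(seed, n = 50L) {
  ## 4 blobs at (+-10, +-3): structure factorizes across the two PCs
  withr::with_seed(seed, {
    centers <- expand.grid(x = c(-10, 10), y = c(-3, 3))
    X <- do.call(rbind, lapply(seq_len(4), function(i)
      cbind(rnorm(n, centers$x[i], 0.3), rnorm(n, centers$y[i], 0.3))))
    list(X = X, truth = rep(0:3, each = n),
         coords = cbind(seq_len(4 * n) - 1L, rep(0L, 4 * n)))
  })
}

test_that("iterative k-means recovers factorized blob structure and respects its guards", {
  bl <- makeBlobs(4L)
  r <- iterativeKMeans(bl$X, K = 4L, coords = bl$coords, seed = 1L)
  expect_equal(r@nClusters, 4L)
  expect_equal(r@perComponentCounts, c(2L, 2L))
  expect_equal(r@componentsUsed, 2L)
  ## labels agree with the planted partition up to renaming
  tab <- table(pixelLabels(r@labelMap), bl$truth)
  expect_equal(sum(apply(tab, 1, max)) / length(bl$truth), 1.0)

  ## K = 1: one cluster, no component examined
  r1 <- iterativeKMeans(bl$X, K = 1L, coords = bl$coords, seed = 1L)
  expect_equal(r1@nClusters, 1L)
  expect_equal(r1@componentsUsed, 0L)

  ## single isotropic blob: c = 1 on the first component
  set.seed(5)
  iso <- matrix(rnorm(400), 200, 2)
  co <- cbind(0:199, rep(0L, 200))
  r2 <- iterativeKMeans(iso, K = 8L, coords = co, seed = 1L)
  expect_equal(r2@nClusters, 1L)
  expect_error(iterativeKMeans(iso, K = 300L, coords = co), "exceeds")
})

test_that("iterative k-means recovers the planted count across seeds", {
  hits <- vapply(1:10, function(s) {
    bl <- makeBlobs(s)
    r <- iterativeKMeans(bl$X, K = 4L, coords = bl$coords, seed = s)
    tab <- table(pixelLabels(r@labelMap), bl$truth)
    r@nClusters == 4L && sum(apply(tab, 1, max)) / length(bl$truth) >= 0.99
  }, NA)
  expect_gte(sum(hits), 9L)
})

test_that("convolutional smoothing flips isolated pixels, keeps fixed points and resolves ties downward", {
  ## homogeneous map is a fixed point
  co <- as.matrix(expand.grid(x = 0:2, y = 0:2))
  hom <- labelMap(co, rep(2L, 9))
  expect_equal(pixelLabels(convolutionalSmooth(hom)), rep(2L, 9))
  ## single deviant pixel inside a homogeneous 3x3 patch flips (8 vs 1)
  dev <- labelMap(co, c(rep(0L, 4), 1L, rep(0L, 4)))
  expect_equal(pixelLabels(convolutionalSmooth(dev)), rep(0L, 9))
  ## 2-pixel map with labels {0, 1}: tie resolves to the smallest label
  two <- labelMap(cbind(0:1, c(0L, 0L)), c(1L, 0L))
  expect_equal(pixelLabels(convolutionalSmooth(two)), c(0L, 0L))
  ## unlabeled pixels cast no votes and never change
  mx <- labelMap(co, c(rep(0L, 4), -1L, rep(1L, 4)))
  sm <- convolutionalSmooth(mx)
  expect_equal(pixelLabels(sm)[5], -1L)
  ## smoothing never introduces a label absent from the input
  set.seed(8)
  co2 <- as.matrix(expand.grid(x = 0:7, y = 0:7))
  rnd <- labelMap(co2, sample(c(-1L, 0L, 3L, 7L), 64, replace = TRUE))
  out <- convolutionalSmooth(rnd, radius = 1L, iterations = 3L)
  expect_true(all(pixelLabels(out) %in% c(-1L, 0L, 3L, 7L)))
})
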