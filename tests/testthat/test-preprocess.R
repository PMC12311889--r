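test_that("binning assigns raw points by round-half-away-from-zero and conserves intensity", {
  sp <- list(
    list(mz = c(500.04, 500.06), intensity = c(3, 2), x = 0L, y = 0L),
    list(mz = 500.05, intensity = 7, x = 1L, y = 0L))
  img <- binToGrid(sp, mzRange = c(500.0, 500.2))
  mz <- mzAxis(img)
  X <- intensityMatrix(img)
  expect_equal(mz, c(500.0, 500.1, 500.2))
  expect_equal(X[1, ], c(3, 2, 0), ignore_attr = TRUE)   # 500.04 -> .0, 500.06 -> .1
  expect_equal(X[2, ], c(0, 7, 0), ignore_attr = TRUE)   # tie at 500.05 -> .1
  ## conservation on random spectra
  set.seed(1)
  sp2 <- lapply(1:5, function(i)
    list(mz = runif(50, 100, 110), intensity = runif(50), x = i - 1L, y = 0L))
  img2 <- binToGrid(sp2, mzRange = c(100, 110))
  expect_equal(rowSums(intensityMatrix(img2)),
               vapply(sp2, function(s) sum(s$intensity), 0))
})

test_that("binning handles empty spectra and rejects out-of-range points", {
  sp <- list(list(mz = numeric(), intensity = numeric(), x = 0L, y = 0L),
             list(mz = 105, intensity = 2, x = 1L, y = 0L))
  img <- binToGrid(sp, mzRange = c(100, 110))
  expect_equal(sum(intensityMatrix(img)[1, ]), 0)
  expect_error(binToGrid(list(list(mz = 120, intensity = 1, x = 0L, y = 0L)),
                         mzRange = c(100, 110)), "outside")
})

test_that("gaussian smoothing conserves interior intensity and scales linearly", {
  mz <- 100 + 0.1 * (0:60)
  X <- matrix(0, 2, 61)
  X[1, 31] <- 1      # central unit impulse
  X[2, 31] <- 10
  img <- msImage(X, mz, cbind(0:1, c(0L, 0L)))
  sm <- gaussianSmooth(img, sigma = 0.1)
  Y <- intensityMatrix(sm)
  expect_equal(sum(Y[1, ]), 1, tolerance = 1e-9)
  expect_true(all(abs(Y[1, ] - rev(Y[1, ])) < 1e-12))    # symmetric hump
  ## impulse peak height = height x normalized kernel center weight
  k <- msiCodec:::gaussianKernel(0.1, 0.1)
  expect_equal(max(Y[2, ]), 10 * max(k), tolerance = 1e-4)
  ## commutes with scalar multiplication, preserves nonnegativity and zeros
  expect_equal(Y[2, ], 10 * Y[1, ], tolerance = 1e-12)
  expect_true(all(Y >= 0))
  z <- msImage(matrix(0, 1, 61), mz, cbind(0L, 0L))
  expect_equal(sum(intensityMatrix(gaussianSmooth(z))), 0)
  expect_error(gaussianSmooth(img, sigma = 0), "positive")
})

test_that("global-max normalization records a scale that restores original units", {
  fx <- smallFixture(seed = 2L)
  img <- fx$image
  normed <- normalizeIntensities(img)
  X <- intensityMatrix(normed)
  expect_equal(max(X), 1.0)
  s <- normalizationScale(normed)
  expect_equal(X * s, intensityMatrix(img), tolerance = 1e-12)
  expect_identical(normalizeIntensities(img, method = "none"), img)
  zero <- msImage(matrix(0, 1, 3), c(1, 2, 3), cbind(0L, 0L))
  expect_error(normalizeIntensities(zero), "zero")
})

test_that("augmentation perturbs each bin by at most delta, preserving zeros, deterministically", {
  set.seed(3)
  s <- runif(200) * rbinom(200, 1, 0.7)
  expect_identical(augmentSpectrum(s, delta = 0), s)
  a <- augmentSpectrum(s, delta = 0.1, seed = 5L)
  nz <- s > 0
  expect_true(all(a[nz] / s[nz] >= 0.9 & a[nz] / s[nz] <= 1.1))
  expect_true(all(a[!nz] == 0))
  expect_identical(augmentSpectrum(s, 0.1, seed = 5L), a)
  expect_false(identical(augmentSpectrum(s, 0.1, seed = 6L), a))
  expect_error(augmentSpectrum(s, delta = -0.1), "delta")
})

test_that("augmentation noise is centered: averaging over seeds recovers the spectrum", {
  s <- c(4, 0, 2, 8, 1)
  acc <- Reduce(`+`, lapply(1:400, function(i) augmentSpectrum(s, 0.1, seed = i)))
  expect_equal(acc / 400, s, tolerance = 0.01)
})

test_that("augmented batches interleave positive pairs with a fixed-point free involution", {
  fx <- smallFixture(seed = 4L)
  b1 <- makeAugmentedBatch(fx$image, 1L, delta = 0.1, seed = 1L)
  expect_equal(nrow(b1@spectra), 2L)
  expect_equal(b1@pairIndex, c(2L, 1L))
  set.seed(5)
  for (N in c(3L, 8L, 64L)) {
    idx <- sample(nPixels(fx$image), N)
    b <- makeAugmentedBatch(fx$image, idx, delta = 0.1, seed = 2L)
    expect_true(validObject(b))
    expect_equal(nrow(b@spectra), 2L * N)
    p <- b@pairIndex
    expect_true(all(p[p] == seq_len(2 * N)) && all(p != seq_len(2 * N)))
    ## each augmentation row is within [1-delta, 1+delta] of its partner
    orig <- b@spectra[seq(1, 2 * N, 2), , drop = FALSE]
    aug <- b@spectra[seq(2, 2 * N, 2), , drop = FALSE]
    r <- aug[orig > 0] / orig[orig > 0]
    expect_true(all(r >= 0.9 & r <= 1.1))
  }
  expect_error(makeAugmentedBatch(fx$image, c(1L, 1L)), "distinct")
})
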