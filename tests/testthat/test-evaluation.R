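gridMap <- function(labels, width = 4L, provenance = "prediction") {
  n <- length(labels)
  co <- cbind((seq_len(n) - 1L) %% width, (seq_len(n) - 1L) %/% width)
  labelMap(co, labels, width = width,
           height = max(co[, 2]) + 1L, provenance = provenance)
}

test_that("majority-vote matching maps clusters to their dominant baseline class", {
  base <- gridMap(rep(c(0L, 1L), each = 8), provenance = "baseline")
  ## prediction = permutation of baseline labels -> bijective table, 100%
  pred <- gridMap(rep(c(5L, 3L), each = 8))
  tab <- matchClusters(pred, base)
  expect_equal(clusterMapping(tab), c("3" = 1L, "5" = 0L))
  ev <- evaluateSegmentation(pred, base)
  expect_equal(ev$accuracy, 100)

  ## 60/40 majority -> class A
  base2 <- gridMap(c(rep(0L, 6), rep(1L, 4)), width = 10L, provenance = "baseline")
  pred2 <- gridMap(rep(7L, 10), width = 10L)
  expect_equal(unname(clusterMapping(matchClusters(pred2, base2))), 0L)

  ## a cluster entirely on unlabeled pixels is unassigned -> -1 after matching
  base3 <- gridMap(c(rep(-1L, 8), rep(2L, 8)), provenance = "baseline")
  pred3 <- gridMap(rep(c(4L, 9L), each = 8))
  t3 <- matchClusters(pred3, base3)
  expect_true(is.na(clusterMapping(t3)[["4"]]))
  m3 <- applyMatching(pred3, t3)
  expect_equal(pixelLabels(m3), c(rep(-1L, 8), rep(2L, 8)))

  expect_error(matchClusters(pred, gridMap(rep(0L, 8), provenance = "baseline")),
               "grid|pixel sets")
})

test_that("matching ties resolve to the smallest baseline class id", {
  base <- gridMap(rep(c(2L, 5L), 5), width = 10L, provenance = "baseline")
  pred <- gridMap(rep(0L, 10), width = 10L)
  expect_equal(unname(clusterMapping(matchClusters(pred, base))), 2L)
})

test_that("applying a matching merges clusters and validates coverage", {
  base <- gridMap(rep(0:1, each = 8), provenance = "baseline")
  ## two predicted clusters map onto one baseline class (cluster merging)
  pred <- gridMap(c(rep(3L, 4), rep(4L, 4), rep(5L, 8)))
  tab <- matchClusters(pred, base)
  m <- applyMatching(pred, tab)
  expect_equal(pixelLabels(m), rep(c(0L, 1L), each = 8))
  ## identity table leaves the map unchanged
  predId <- gridMap(rep(0:1, each = 8))
  expect_equal(pixelLabels(applyMatching(predId, matchClusters(predId, base))),
               pixelLabels(predId))
  ## missing cluster in the table is an error
  bad <- new("MatchingTable", clusters = 3L, mapping = 0L,
             tallies = matrix(4L, 1, 1, dimnames = list("3", "0")))
  expect_error(applyMatching(pred, bad), "lacks")
})

test_that("accuracy counts only baseline-labeled pixels", {
  base <- gridMap(rep(0L, 16), provenance = "baseline")
  expect_equal(segmentationAccuracy(base, base), 100)
  half <- gridMap(c(rep(0L, 8), rep(1L, 8)))
  expect_equal(segmentationAccuracy(half, base), 50)
  ## 10 labeled + 90 unlabeled, 9 of 10 correct -> 90%
  baseL <- gridMap(c(rep(3L, 10), rep(-1L, 90)), width = 10L,
                   provenance = "baseline")
  predL <- gridMap(c(rep(3L, 9), 0L, rep(3L, 90)), width = 10L)
  expect_equal(segmentationAccuracy(predL, baseL), 90)
  ## matched -1 on labeled baseline counts as incorrect
  predM <- gridMap(c(rep(3L, 9), -1L, rep(-1L, 90)), width = 10L)
  expect_equal(segmentationAccuracy(predM, baseL), 90)
  expect_error(segmentationAccuracy(predL, gridMap(rep(-1L, 100), width = 10L,
                                                   provenance = "baseline")),
               "no labeled")
})

test_that("matched accuracy is invariant under permutation of predicted cluster ids", {
  set.seed(9)
  base <- gridMap(sample(0:2, 36, replace = TRUE), width = 6L,
                  provenance = "baseline")
  predLab <- sample(0:4, 36, replace = TRUE)
  acc0 <- evaluateSegmentation(gridMap(predLab, width = 6L), base)$accuracy
  perm <- sample(0:4)
  acc1 <- evaluateSegmentation(gridMap(perm[predLab + 1L], width = 6L),
                               base)$accuracy
  expect_equal(acc0, acc1)
  expect_gte(acc0, 0); expect_lte(acc0, 100)
})

test_that("majority-vote matching is per-cluster optimal among fixed mappings", {
  set.seed(10)
  base <- gridMap(sample(0:2, 48, replace = TRUE), width = 8L,
                  provenance = "baseline")
  pred <- gridMap(sample(0:3, 48, replace = TRUE), width = 8L)
  tab <- matchClusters(pred, base)
  accBest <- segmentationAccuracy(applyMatching(pred, tab), base)
  for (rep in 1:10) {
    alt <- tab
    alt@mapping <- sample(0:2, length(alt@clusters), replace = TRUE)
    expect_lte(segmentationAccuracy(applyMatching(pred, alt), base), accBest)
  }
})
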