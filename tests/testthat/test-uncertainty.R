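test_that("delta-method SEs are positive and recorded with their level", {
  spec <- multilevelGrmSpec(nGroups = 12, groupSizes = 12,
    discrimination = rep(1.5, 4), itemDim = 1
  )
  x <- simulateGrm(spec, seed = 2)
  h <- scalability(x, level = "two")
  expect_true(all(pairSE(h)[upper.tri(pairSE(h))] > 0))
  expect_true(all(itemSE(h) > 0))
  expect_gt(totalSE(h), 0)
  expect_equal(h@level, "two")
  expect_equal(h@seMethod, "delta")
})

test_that("singleton clusters reduce two-level SEs to one-level up to G/(G-1)", {
  set.seed(8)
  m <- randomScores(60, 3, cats = 4L)
  x <- ItemScores(m, groups = paste0("r", 1:60)) # every respondent its own group
  h1 <- scalability(x, level = "one", warnLevelOne = FALSE)
  h2 <- scalability(x, level = "two")
  G <- 60
  expect_equal(totalSE(h2), totalSE(h1) * sqrt(G / (G - 1)), tolerance = 1e-12)
  expect_equal(itemSE(h2), itemSE(h1) * sqrt(G / (G - 1)), tolerance = 1e-12)
})

test_that("one-level SE shrinks at roughly the 1/sqrt(N) rate", {
  # fixed data-generating distribution, two sample sizes
  spec <- multilevelGrmSpec(nGroups = 1, groupSizes = 300, icc = 0,
    discrimination = rep(1.5, 3), itemDim = 1
  )
  spec4 <- multilevelGrmSpec(nGroups = 1, groupSizes = 1200, icc = 0,
    discrimination = rep(1.5, 3), itemDim = 1
  )
  x1 <- simulateGrm(spec, seed = 4); x1@groups <- NULL
  x4 <- simulateGrm(spec4, seed = 4); x4@groups <- NULL
  seN <- totalSE(scalability(x1, level = "one"))
  se4N <- totalSE(scalability(x4, level = "one"))
  expect_gt(seN / se4N, 1.6) # ideal ratio 2
  expect_lt(seN / se4N, 2.4)
})

test_that("one-level delta SE agrees with a row-resampling bootstrap oracle", {
  spec <- multilevelGrmSpec(nGroups = 1, groupSizes = 500, icc = 0,
    discrimination = rep(1.4, 3), itemDim = 1
  )
  x <- simulateGrm(spec, seed = 31)
  x@groups <- NULL
  se <- totalSE(scalability(x, level = "one"))
  seBoot <- rowBootstrapSE(scoreMatrix(x), B = 500, seed = 99)
  expect_lt(abs(se - seBoot) / seBoot, 0.15)
})

test_that("two-level delta SE agrees with the cluster bootstrap on clustered data", {
  spec <- multilevelGrmSpec(nGroups = 50, groupSizes = 12, icc = 0.3,
    discrimination = rep(1.5, 4), itemDim = 1
  )
  x <- simulateGrm(spec, seed = 23)
  se <- totalSE(scalability(x, level = "two"))
  bt <- clusterBootstrapSE(x, B = 600, seed = 7)
  expect_lt(abs(se - totalSE(bt)) / totalSE(bt), 0.15)
})

test_that("cluster bootstrap is seed-deterministic and vanishes for identical groups", {
  spec <- multilevelGrmSpec(nGroups = 10, groupSizes = 15, icc = 0.2,
    discrimination = rep(1.5, 3), itemDim = 1
  )
  x <- simulateGrm(spec, seed = 5)
  b1 <- clusterBootstrapSE(x, B = 200, seed = 44)
  b2 <- clusterBootstrapSE(x, B = 200, seed = 44)
  expect_identical(totalSE(b1), totalSE(b2))
  expect_identical(pairSE(b1), pairSE(b2))
  expect_false(identical(totalSE(b1), totalSE(clusterBootstrapSE(x, B = 200, seed = 45))))

  # every group an identical copy of the same score table -> no between-group
  # variation for the bootstrap to see
  block <- randomScores(12, 3, cats = 3L, seed = 1)
  Xc <- do.call(rbind, replicate(6, block, simplify = FALSE))
  xc <- ItemScores(Xc, groups = rep(paste0("g", 1:6), each = 12))
  b0 <- clusterBootstrapSE(xc, B = 200, seed = 3)
  expect_equal(totalSE(b0), 0, tolerance = 1e-12)

  expect_error(clusterBootstrapSE(x, B = 50, seed = 1), "at least 200")
  expect_error(clusterBootstrapSE(simulateGrm(
    multilevelGrmSpec(nGroups = 1, groupSizes = 30,
      discrimination = rep(1.5, 3), itemDim = 1), seed = 1
  ), B = 200), "at least 2 groups")
})

test_that("RNG state of the caller is not disturbed by seeded computations", {
  spec <- multilevelGrmSpec(nGroups = 6, groupSizes = 10,
    discrimination = rep(1.5, 3), itemDim = 1
  )
  set.seed(123)
  before <- .Random.seed
  invisible(simulateGrm(spec, seed = 9))
  expect_identical(.Random.seed, before)
})
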