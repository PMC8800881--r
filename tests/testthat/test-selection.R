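# Two well-separated blocks of strongly related items: block dimensions are
# nearly independent, so the greedy procedure should recover the blocks.
twoBlockData <- function(N = 200, seed = 1) {
  set.seed(seed)
  t1 <- rnorm(N)
  t2 <- rnorm(N)
  mk <- function(tr) pmin(3, pmax(0, round(tr + rnorm(N, sd = 0.45) + 1.5)))
  m <- cbind(
    A1 = mk(t1), A2 = mk(t1), A3 = mk(t1),
    B1 = mk(t2), B2 = mk(t2), B3 = mk(t2)
  )
  m
}

test_that("two independent blocks of strongly comonotonic items form two scales", {
  m <- twoBlockData()
  for (meth in c("classic", "testGuided")) {
    p <- runAisp(m, lowerbound = 0.3, method = meth)
    a <- scaleAssignment(p)
    expect_equal(length(unique(a[c("A1", "A2", "A3")])), 1L)
    expect_equal(length(unique(a[c("B1", "B2", "B3")])), 1L)
    expect_true(all(a > 0))
    expect_equal(max(a), 2L)
    # the oracle trace agrees in full
    expect_identical(a, oracleAisp(m, c = 0.3, method = meth))
  }
})

test_that("greedy selection matches the brute-force trace oracle on 6-item cases", {
  for (seed in c(3, 8, 15, 27)) {
    spec <- multilevelGrmSpec(nGroups = 12, groupSizes = 12, icc = 0.1,
      discrimination = rep(c(1.3, 2.2), each = 3), itemDim = c(1, 1, 1, 2, 2, 2),
      dimCor = 0.3
    )
    x <- simulateGrm(spec, seed = seed)
    for (meth in c("classic", "testGuided")) {
      for (cc in c(0.2, 0.3)) {
        got <- scaleAssignment(suppressWarnings(
          runAisp(x, lowerbound = cc, method = meth, level = "one")
        ))
        want <- oracleAisp(scoreMatrix(x), c = cc, method = meth, level = "one")
        names(want) <- names(got)
        expect_identical(got, want,
          label = sprintf("seed %d, %s, c=%.1f", seed, meth, cc)
        )
      }
    }
  }
})

test_that("partitions are deterministic and sweeps are column-consistent", {
  m <- twoBlockData(seed = 2)
  p1 <- runAisp(m, lowerbound = 0.25)
  p2 <- runAisp(m, lowerbound = 0.25)
  expect_identical(scaleAssignment(p1), scaleAssignment(p2))
  expect_identical(p1@trace, p2@trace)

  sw <- lowerboundSweep(m, lowerbounds = 0.25)
  expect_identical(sweepTable(sw)[, 1], scaleAssignment(p1))
  sw3 <- lowerboundSweep(m, lowerbounds = c(0.1, 0.25, 0.4))
  expect_identical(sweepTable(sw3)[, "0.25"], scaleAssignment(p1))
  expect_error(lowerboundSweep(m, lowerbounds = c(0.3, 0.1)), "strictly increasing")
})

test_that("every T-AISP-selected item exceeds the lowerbound in its final scale", {
  # testing H_i <= c takes sampling error into account, so acceptance implies
  # the point estimate clears c with room to spare
  for (seed in c(4, 9)) {
    x <- simulateGrm(multilevelGrmSpec(nGroups = 15, groupSizes = 14), seed = seed)
    p <- runAisp(x, lowerbound = 0.3, method = "testGuided")
    a <- scaleAssignment(p)
    for (s in seq_len(max(a))) {
      items <- names(a)[a == s]
      hi <- itemH(scalability(x, items = items, se = FALSE))
      expect_true(all(hi > 0.3))
    }
  }
})

test_that("the trace accounts exactly for the Bonferroni denominator", {
  m <- twoBlockData(seed = 6)
  p <- runAisp(m, lowerbound = 0.3, method = "testGuided")
  tr <- p@trace
  expect_equal(sum(tr$tests), max(tr$counter))
  # each logged critical value reflects the counter in force at that step
  expect_equal(tr$zCrit, qnorm(1 - p@alpha / tr$counter))
  # within a step the counter already includes the current step's tests
  firstStep <- tr[tr$phase == "start" & tr$scale == 1, ]
  expect_true(all(firstStep$counter == firstStep$counter[1]))
  expect_equal(firstStep$counter[1], sum(firstStep$tests))
})

test_that("degenerate and unscalable items are reported as 0, never dropped", {
  m <- twoBlockData(seed = 12)
  m <- cbind(m, FLAT = rep(2L, nrow(m)))
  expect_warning(p <- runAisp(m, lowerbound = 0.3), "zero variance")
  a <- scaleAssignment(p)
  expect_equal(unname(a["FLAT"]), 0L)
  expect_equal(length(a), 7L)

  # pure-noise item is retained in the output as unscalable at a high lowerbound
  set.seed(30)
  m2 <- cbind(twoBlockData(seed = 13), NOISE = sample(0:3, 200, TRUE))
  p2 <- runAisp(m2, lowerbound = 0.4)
  expect_equal(unname(scaleAssignment(p2)["NOISE"]), 0L)
})

test_that("one-level selection on clustered data warns about shrunken SEs", {
  x <- simulateGrm(multilevelGrmSpec(nGroups = 10, groupSizes = 12,
    discrimination = rep(1.8, 4), itemDim = 1
  ), seed = 3)
  expect_warning(runAisp(x, lowerbound = 0.2, level = "one"), "too small")
})
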