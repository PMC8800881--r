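test_that("delimited ingestion returns a validated matrix and design", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = c(0, 1, 1, 0), b = c(1, 1, 0, 0)), f, row.names = FALSE)
  x <- readItemScores(f)
  expect_s4_class(x, "ItemScores")
  expect_equal(dim(x), c(4L, 2L))
  expect_null(groupLabels(x))
  expect_equal(itemLabels(x), c("a", "b"))

  # group column is removed from the item set and returned as the design
  f2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = c(0, 1, 1, 0), b = c(1, 1, 0, 0),
    cls = c("u", "u", "v", "v")
  ), f2, row.names = FALSE)
  x2 <- readItemScores(f2, groupColumn = "cls")
  expect_equal(nItems(x2), 2L)
  expect_equal(nlevels(groupLabels(x2)), 2L)
  expect_error(readItemScores(f2, groupColumn = "nope"), "not found")
})

test_that("ingestion rejects missing and non-integer cells, naming them", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "NA,1", "2,2"), f)
  expect_error(readItemScores(f), "row 2.*'a'")
  expect_message(x <- readItemScores(f, dropIncomplete = TRUE), "removed 1")
  expect_equal(nRespondents(x), 2L)

  f3 <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "1.5,1"), f3)
  expect_error(readItemScores(f3), "non-integer")
  f4 <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,x", "1,2"), f4)
  expect_error(readItemScores(f4), "does not parse as integer")
})

test_that("read-write-read round trip reproduces the data exactly", {
  set.seed(42)
  x <- ItemScores(randomScores(25, 4), groups = sample(letters[1:5], 25, TRUE))
  f <- tempfile(fileext = ".csv")
  writeItemScores(x, f, groupColumn = "grp")
  x2 <- readItemScores(f, groupColumn = "grp")
  expect_identical(scoreMatrix(x2), scoreMatrix(x))
  expect_identical(as.character(groupLabels(x2)), as.character(groupLabels(x)))
  # and the tab-delimited dialect round-trips too
  ft <- tempfile(fileext = ".tsv")
  writeItemScores(x, ft)
  expect_identical(scoreMatrix(readItemScores(ft, groupColumn = "group")), scoreMatrix(x))
})

test_that("recodeReversed reflects scores, is an involution, flips covariances", {
  x <- ItemScores(cbind(a = c(2, 5, 1), b = c(1, 3, 4)), minScore = 1, maxScore = 5)
  r <- recodeReversed(x, "a")
  expect_equal(scoreMatrix(r)[, "a"], c(4, 1, 5)) # 1 + 5 - x
  expect_identical(scoreMatrix(recodeReversed(r, "a")), scoreMatrix(x))
  expect_identical(itemRange(r), itemRange(x))
  expect_error(recodeReversed(x, "zz"), "unknown item")

  set.seed(7)
  m <- randomScores(20, 3, cats = 5L)
  before <- cov(m)
  after <- cov(scoreMatrix(recodeReversed(ItemScores(m), "I2")))
  expect_equal(after["I2", "I1"], -before["I2", "I1"])
  expect_equal(after["I2", "I3"], -before["I2", "I3"])
  expect_equal(after["I1", "I3"], before["I1", "I3"])
  expect_equal(after["I2", "I2"], before["I2", "I2"])
})

test_that("validity catches out-of-range, non-integer and misaligned input", {
  expect_error(ItemScores(cbind(a = c(1, 6), b = c(1, 2)), minScore = 1, maxScore = 5),
    "outside declared range"
  )
  expect_error(ItemScores(cbind(a = c(1, 2.5), b = c(1, 2))), "non-integer")
  expect_error(ItemScores(cbind(a = 1:4, b = 4:1), groups = c("x", "y")), "one group per respondent")
})

test_that("subsetting keeps scores, design and ranges aligned", {
  x <- ItemScores(cbind(a = 1:6, b = 6:1, c = rep(2:3, 3)),
    groups = rep(c("g1", "g2"), each = 3)
  )
  s <- x[1:3, c("a", "c")]
  expect_equal(itemLabels(s), c("a", "c"))
  expect_equal(nRespondents(s), 3L)
  expect_equal(as.character(groupLabels(s)), rep("g1", 3))
  expect_equal(unname(itemRange(s)[, "max"]), c(6L, 3L))
  expect_error(x[, "zz"], "unknown item")
})

test_that("zero-variance items pass ingestion but are rejected by scalability", {
  x <- ItemScores(cbind(a = c(1, 2, 1, 2), b = c(3, 3, 3, 3)))
  expect_s4_class(x, "ItemScores")
  expect_error(scalability(x), "zero sample variance")
})
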