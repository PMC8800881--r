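test_that("Delta statistics match their closed forms and direct recomputation", {
  indep <- cbind(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))
  expect_equal(deltaStatistic(indep, "pair", "a", "b")$statistic, 0)
  perfect <- cbind(a = c(0, 0, 1, 1), b = c(0, 0, 1, 1))
  expect_equal(deltaStatistic(perfect, "pair", "a", "b")$statistic, sqrt(3))

  set.seed(14)
  m <- randomScores(100, 4, cats = 3L)
  N <- nrow(m)
  sdv <- apply(m, 2, function(v) sqrt(covN(v, v)))
  # item statistic recomputed from tabulated covariances
  i <- 2
  Si <- sum(sapply((1:4)[-i], function(j) covN(m[, i], m[, j])))
  expect_equal(
    deltaStatistic(m, "item", i)$statistic,
    unname(Si / (sdv[i] * sum(sdv[-i])) * sqrt(N - 1)),
    tolerance = 1e-12
  )
  # total statistic
  up <- combn(4, 2)
  num <- sum(apply(up, 2, function(p) covN(m[, p[1]], m[, p[2]])))
  den <- sum(apply(up, 2, function(p) sdv[p[1]] * sdv[p[2]]))
  expect_equal(deltaStatistic(m, "total")$statistic, num / den * sqrt(N - 1),
    tolerance = 1e-12
  )
  r <- deltaStatistic(m, "total")
  expect_equal(r$pValue, pnorm(r$statistic, lower.tail = FALSE))
  expect_equal(r$rejected, r$statistic >= r$zCrit)
})

test_that("Wald z test arithmetic and the 1.645 critical value", {
  r0 <- waldZ(0.4, 0.05, c = 0.4)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$pValue, 0.5)
  r <- waldZ(0.620, 0.026, c = 0.5)
  expect_equal(r$statistic, 0.12 / 0.026, tolerance = 1e-12)
  expect_equal(round(r$statistic, 3), 4.615)
  expect_equal(round(r$zCrit, 3), 1.645)
  expect_true(r$rejected)
  expect_error(waldZ(0.5, 0), "strictly positive")
  expect_error(waldZ(0.5, -1), "strictly positive")
})

test_that("range-preserving test is zero at the null and sign-consistent with Wald", {
  expect_equal(rangePreservingZ(0.37, 0.21, c = 0.37)$statistic, 0)
  expect_gt(rangePreservingZ(0.6, 0.05, c = 0.3)$statistic, 0)
  expect_lt(rangePreservingZ(0.2, 0.05, c = 0.3)$statistic, 0)
  expect_error(rangePreservingZ(1, 0.1, c = 0.3), "Hhat < 1")
})

test_that("confidence intervals match closed forms and preserve the range", {
  ci <- confidenceInterval(0.5, 0.1)
  expect_equal(ci$lower, 0.5 - qnorm(0.975) * 0.1)
  expect_equal(ci$upper, 0.5 + qnorm(0.975) * 0.1)
  expect_equal(round(unlist(ci[c("lower", "upper")]), 3), c(lower = 0.304, upper = 0.696))

  wald <- confidenceInterval(0.9, 0.1)
  rp <- confidenceInterval(0.9, 0.1, flavor = "rangePreserving")
  expect_gt(wald$upper, 1)
  expect_lt(rp$upper, 1)
  expect_lt(rp$lower, rp$upper)
  # both flavors contain the point estimate and collapse onto it as SE -> 0
  for (h in c(-0.2, 0.1, 0.55, 0.95)) {
    for (fl in c("wald", "rangePreserving")) {
      ci <- confidenceInterval(h, 0.07, flavor = fl)
      expect_lte(ci$lower, h)
      expect_gte(ci$upper, h)
      tiny <- confidenceInterval(h, 1e-9, flavor = fl)
      expect_equal(tiny$lower, h, tolerance = 1e-6)
      expect_equal(tiny$upper, h, tolerance = 1e-6)
    }
  }
})

test_that("wald z is monotone in the estimate, the null value and the SE", {
  hs <- seq(0.1, 0.9, by = 0.1)
  zs <- sapply(hs, function(h) waldZ(h, 0.05, c = 0.05)$statistic)
  expect_true(all(diff(zs) > 0))
  cs <- seq(0, 0.5, by = 0.1)
  zc <- sapply(cs, function(cc) waldZ(0.6, 0.05, c = cc)$statistic)
  expect_true(all(diff(zc) < 0))
  ses <- seq(0.02, 0.2, by = 0.02)
  zse <- sapply(ses, function(s) waldZ(0.6, s, c = 0.3)$statistic)
  expect_true(all(diff(zse) < 0))
})

test_that("the Delta test keeps its nominal size under marginal independence", {
  set.seed(2024)
  rej <- replicate(800, {
    m <- cbind(sample(0:2, 500, TRUE), sample(0:2, 500, TRUE))
    colnames(m) <- c("a", "b")
    deltaStatistic(m, "pair", "a", "b")$rejected
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})
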